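## Homology search (ungapped seed-and-extend with Karlin-Altschul
## E-values), expression quantification, TE exclusion, and the
## male-specific-expression candidate filter.

#' Karlin-Altschul lambda for an ungapped scoring scheme
#'
#' Solves sum_ij p_i p_j exp(lambda * s_ij) = 1 under uniform base
#' composition. For the default +1/-2 scheme lambda ~ 1.33.
#' @noRd
ka_lambda <- function(match = 1, mismatch = -2) {
  f <- function(l) (4 * exp(l * match) + 12 * exp(l * mismatch)) / 16 - 1
  stats::uniroot(f, c(1e-6, 10))$root
}

#' Ungapped local homology search with E-values
#'
#' Exact-word seeding (default word 11), ungapped X-drop extension with
#' match +1 / mismatch -2, one extension per (query, subject, strand,
#' diagonal), best hit per (query, subject) pair. E-values use the
#' ungapped Karlin-Altschul form `E = m n K exp(-lambda S)` with lambda
#' solved for the scoring scheme and K the standard precomputed constant
#' for +1/-2 (0.621, as shipped in the classic aligner's tables); n is
#' the total subject (database) length. Both query strands are searched.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param evalue_max report hits with E-value at or below this.
#' @param word seed word length.
#' @param match,mismatch scores.
#' @param xdrop stop extending when the running score falls this far
#'   below the best.
#' @param K Karlin-Altschul K.
#' @return data.table in 12-column tabular layout: qid, sid, pident,
#'   length, mismatches, gapopen, qstart, qend, sstart, send, evalue,
#'   bitscore (coordinates 1-based inclusive; sstart > send on the minus
#'   strand). Attributes `lambda` and `K` record the statistics.
#' @export
local_homology_search <- function(queries, subjects, evalue_max = 1e-7,
                                  word = 11L, match = 1, mismatch = -2,
                                  xdrop = 20, K = 0.621) {
  assert_that(length(queries) > 0 && length(subjects) > 0,
              "queries and subjects must be non-empty")
  if (is.null(names(queries)))
    names(queries) <- paste0("query", seq_along(queries))
  if (is.null(names(subjects)))
    names(subjects) <- paste0("subject", seq_along(subjects))
  lambda <- ka_lambda(match, mismatch)
  db_len <- sum(nchar(subjects))

  ## subject word index
  sl <- nchar(subjects)
  widx <- rbindlist(lapply(which(sl >= word), function(i) {
    n <- sl[i] - word + 1L
    data.table(w = stringi::stri_sub(rep(subjects[i], n), seq_len(n),
                                     length = word),
               sid = names(subjects)[i], spos = seq_len(n))
  }))
  if (!nrow(widx)) return(empty_hits(lambda, K))
  setkey(widx, w)

  hits <- list()
  for (qi in seq_along(queries)) {
    qname <- names(queries)[qi]
    qlen <- nchar(queries[qi])
    if (qlen < word) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") queries[[qi]] else revcomp(queries[[qi]])
      n <- qlen - word + 1L
      qw <- data.table(
        w = stringi::stri_sub(rep(q, n), seq_len(n), length = word),
        qpos = seq_len(n))
      sh <- widx[qw, on = "w", nomatch = NULL, allow.cartesian = TRUE]
      if (!nrow(sh)) next
      sh[, diag := spos - qpos]
      sh <- sh[, .(qpos = min(qpos), spos = min(spos)), by = .(sid, diag)]
      for (r in seq_len(nrow(sh))) {
        h <- extend_ungapped(q, subjects[[sh$sid[r]]], sh$qpos[r],
                             sh$spos[r], word, match, mismatch, xdrop)
        if (is.null(h)) next
        score <- h$matches * match + h$mismatches * mismatch
        bits <- (lambda * score - log(K)) / log(2)
        ev <- qlen * db_len * K * exp(-lambda * score)
        if (strand == "+") {
          qs <- h$qstart; qe <- h$qend
          ss <- h$sstart; se <- h$send
        } else {
          qs <- qlen - h$qend + 1L; qe <- qlen - h$qstart + 1L
          ss <- h$send; se <- h$sstart
        }
        hits[[length(hits) + 1L]] <- data.table(
          qid = qname, sid = sh$sid[r],
          pident = round(100 * h$matches / h$len, 2), length = h$len,
          mismatches = h$mismatches, gapopen = 0L,
          qstart = qs, qend = qe, sstart = ss, send = se,
          evalue = ev, bitscore = round(bits, 1))
      }
    }
  }
  if (!length(hits)) return(empty_hits(lambda, K))
  out <- rbindlist(hits)
  out <- out[order(-bitscore)][, head(.SD, 1L), by = .(qid, sid)]
  out <- out[evalue <= evalue_max]
  setattr(out, "lambda", lambda); setattr(out, "K", K)
  out[]
}

#' @noRd
empty_hits <- function(lambda, K) {
  out <- data.table(qid = character(), sid = character(), pident = numeric(),
                    length = integer(), mismatches = integer(),
                    gapopen = integer(), qstart = integer(), qend = integer(),
                    sstart = integer(), send = integer(), evalue = numeric(),
                    bitscore = numeric())
  setattr(out, "lambda", lambda); setattr(out, "K", K)
  out
}

#' X-drop ungapped extension around one seed
#' @noRd
extend_ungapped <- function(q, s, qpos, spos, word, match, mismatch, xdrop) {
  qlen <- nchar(q); slen <- nchar(s)
  ## overlap of the two sequences along this diagonal
  off <- spos - qpos
  q0 <- max(1L, 1L - off); q1 <- min(qlen, slen - off)
  if (q1 - q0 + 1L < word) return(NULL)
  eq <- utf8ToInt(substr(q, q0, q1)) ==
    utf8ToInt(substr(s, q0 + off, q1 + off))
  step <- ifelse(eq, match, mismatch)
  seed_a <- qpos - q0 + 1L                 # seed start within overlap
  seed_b <- seed_a + word - 1L
  ## right extension from seed end
  right <- seed_b
  if (seed_b < length(step)) {
    cs <- cumsum(step[(seed_b + 1L):length(step)])
    keep <- cs >= cummax(cs) - xdrop
    stopi <- if (all(keep)) length(cs) else which(!keep)[1L] - 1L
    if (stopi > 0L) right <- seed_b + which.max(cs[seq_len(stopi)])
    if (stopi > 0L && max(cs[seq_len(stopi)]) <= 0) right <- seed_b
  }
  ## left extension from seed start
  left <- seed_a
  if (seed_a > 1L) {
    cs <- cumsum(rev(step[seq_len(seed_a - 1L)]))
    keep <- cs >= cummax(cs) - xdrop
    stopi <- if (all(keep)) length(cs) else which(!keep)[1L] - 1L
    if (stopi > 0L && max(cs[seq_len(stopi)]) > 0)
      left <- seed_a - which.max(cs[seq_len(stopi)])
  }
  m <- sum(eq[left:right])
  len <- right - left + 1L
  list(qstart = q0 + left - 1L, qend = q0 + right - 1L,
       sstart = q0 + off + left - 1L, send = q0 + off + right - 1L,
       len = len, matches = m, mismatches = len - m)
}

#' Quantify expression of fragments per sample
#'
#' Reads are assigned with the pseudo-mapper; multi-mapping reads are
#' split equally across their best hits. With `reassign = TRUE` one
#' extra iteration re-splits multi-mapped reads in proportion to the
#' equal-split abundance estimates (a one-step stand-in for the EM of
#' full quantifiers, which stops silent homologs of highly expressed
#' fragments from accruing tie counts). Abundance is count / fragment
#' length in kb, rescaled per sample to sum to 1e6 (transcripts per
#' million).
#'
#' @param reads_by_sample named list of single-end read tables (column
#'   `seq`) or paired tables (seq1/seq2).
#' @param fragments named character vector of fragment sequences.
#' @param reassign perform one abundance-weighted reassignment iteration.
#' @param ... passed to [map_reads()].
#' @return `expression_matrix`: list with `counts` and `tpm` matrices
#'   (fragments x samples) and `lengths`.
#' @export
quantify <- function(reads_by_sample, fragments, reassign = FALSE, ...) {
  assert_that(length(fragments) > 0, "fragments must be non-empty")
  frag_names <- names(fragments)
  counts <- matrix(0, nrow = length(fragments),
                   ncol = length(reads_by_sample),
                   dimnames = list(frag_names, names(reads_by_sample)))
  lib <- setNames(numeric(length(reads_by_sample)), names(reads_by_sample))
  lens_kb <- nchar(fragments) / 1000
  for (smp in names(reads_by_sample)) {
    dt <- as.data.table(reads_by_sample[[smp]])
    lib[smp] <- nrow(dt)
    if (!nrow(dt)) next
    hits <- best_hits_per_read(dt, fragments, ...)
    if (!nrow(hits)) next
    hits[, w := 1 / .N, by = read]
    cnt <- setNames(numeric(length(fragments)), frag_names)
    agg <- hits[, .(count = sum(w)), by = contig]
    cnt[agg$contig] <- agg$count
    if (reassign) {
      rate <- cnt / lens_kb
      hits[, n_hits := .N, by = read]
      multi <- hits[n_hits > 1L]
      if (nrow(multi)) {
        multi[, w := rate[contig]]
        multi[, tot := sum(w), by = read]
        multi[, w := ifelse(tot > 0, w / tot, 1 / n_hits)]
        uniq <- hits[n_hits == 1L]
        cnt <- setNames(numeric(length(fragments)), frag_names)
        agg <- rbindlist(list(uniq[, .(read, contig, w)],
                              multi[, .(read, contig, w)]))[
                                , .(count = sum(w)), by = contig]
        cnt[agg$contig] <- agg$count
      }
    }
    counts[, smp] <- cnt
  }
  tpm <- counts
  for (smp in colnames(counts)) {
    rate <- counts[, smp] / lens_kb
    tot <- sum(rate)
    if (tot == 0) {
      warning(sprintf("no reads assigned in sample '%s'", smp))
      tpm[, smp] <- 0
    } else tpm[, smp] <- rate / tot * 1e6
  }
  structure(list(counts = counts, tpm = tpm,
                 lengths = setNames(nchar(fragments), frag_names),
                 library_sizes = lib),
            class = "expression_matrix")
}

#' Remove fragments homologous to a transposable-element library
#'
#' @param fragments named character vector.
#' @param te_library named character vector (may be empty).
#' @param evalue_max homology threshold.
#' @return fragments with TE-homologous entries removed; removed names in
#'   attribute `removed`.
#' @export
te_filter <- function(fragments, te_library, evalue_max = 1e-7) {
  if (!length(te_library) || !length(fragments)) {
    return(structure(fragments, removed = character()))
  }
  hits <- local_homology_search(fragments, te_library,
                                evalue_max = evalue_max)
  removed <- unique(hits$qid)
  structure(fragments[!names(fragments) %in% removed], removed = removed)
}

#' Candidate-filter parameters
#' @param expressed_min TPM at or above which a fragment counts as
#'   expressed (default 1).
#' @param silent_max TPM below which a fragment counts as silent
#'   (default 0.1).
#' @export
candidate_filter_params <- function(expressed_min = 1, silent_max = 0.1) {
  assert_that(silent_max < expressed_min,
              "silent_max must be below expressed_min")
  list(expressed_min = expressed_min, silent_max = silent_max)
}

#' Male-specific-expression candidate filter
#'
#' A fragment is a candidate iff its abundance is at least
#' `expressed_min` TPM in the male sample and below `silent_max` TPM in
#' every silent sample.
#'
#' @param matrix an `expression_matrix` from [quantify()].
#' @param male_sample name of the male sample.
#' @param silent_samples names of samples required to be silent.
#' @param params a [candidate_filter_params()].
#' @return character vector of candidate fragment names.
#' @export
candidate_filter <- function(matrix, male_sample, silent_samples,
                             params = candidate_filter_params()) {
  tpm <- matrix$tpm
  missing <- setdiff(c(male_sample, silent_samples), colnames(tpm))
  assert_that(length(missing) == 0,
              paste("unknown sample(s):", paste(missing, collapse = ", ")))
  expressed <- tpm[, male_sample] >= params$expressed_min
  silent <- rowSums(tpm[, silent_samples, drop = FALSE] >=
                      params$silent_max) == 0
  rownames(tpm)[expressed & silent]
}
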