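## Prefix-constrained k-mer counting, male-specific k-mer subtraction,
## read retention, and a miniature de Bruijn unitig assembler.
##
## Both strands of every read are scanned but only k-mers starting with
## the prefix base are kept: the memory-reduction convention of the
## k-mer subtraction method (an ~1/4 subsampling of k-mer space for a
## one-base prefix).

#' @noRd
new_kmer_table <- function(dt, k, prefix, sample_id) {
  setkey(dt, kmer)
  structure(dt, class = c("kmer_count_table", class(dt)),
            k = as.integer(k), prefix = prefix, sample_id = sample_id)
}

#' Extract prefix-constrained k-mers of all reads
#'
#' Every length-`k` window of each read and of its reverse complement
#' whose first base equals `prefix` increments the window's count.
#' Windows containing non-ACGT characters are skipped.
#'
#' @param reads character vector of read sequences (give both mates of a
#'   pair to count a full library).
#' @param k k-mer length.
#' @param prefix required first base.
#' @param sample_id label stored on the table.
#' @param chunk_size reads per processing chunk (memory bound).
#' @return `kmer_count_table`: data.table (kmer, count) with attributes
#'   `k`, `prefix`, `sample_id`.
#' @export
extract_kmers <- function(reads, k = 35L, prefix = "A",
                          sample_id = "sample", chunk_size = 20000L) {
  assert_that(k >= 1, "k must be >= 1")
  assert_that(nchar(prefix) == 1L, "prefix must be a single base")
  reads <- reads[nchar(reads) >= k]
  if (!length(reads)) {
    return(new_kmer_table(data.table(kmer = character(), count = integer()),
                          k, prefix, sample_id))
  }
  parts <- list()
  for (off in seq(1L, length(reads), chunk_size)) {
    chunk <- reads[off:min(off + chunk_size - 1L, length(reads))]
    km <- chunk_kmers(c(chunk, revcomp(chunk)), k, prefix)
    if (length(km))
      parts[[length(parts) + 1L]] <- data.table(kmer = km)[, .(count = .N),
                                                           by = kmer]
  }
  counts <- if (length(parts))
    rbindlist(parts)[, .(count = sum(count)), by = kmer]
  else data.table(kmer = character(), count = integer())
  new_kmer_table(counts, k, prefix, sample_id)
}

#' All prefix-anchored k-mers of a set of sequences (one strand)
#' @noRd
chunk_kmers <- function(seqs, k, prefix) {
  loc <- stringi::stri_locate_all_fixed(seqs, prefix, omit_no_match = TRUE)
  starts <- lapply(loc, function(m) m[, 1L])
  lens <- nchar(seqs)
  keep <- mapply(function(s, l) s[s + k - 1L <= l], starts, lens,
                 SIMPLIFY = FALSE)
  ns <- lengths(keep)
  if (!sum(ns)) return(character())
  from <- unlist(keep, use.names = FALSE)
  km <- stringi::stri_sub(rep(seqs, ns), from, length = k)
  ## drop windows with ambiguity codes (rare; cheap regex on survivors)
  if (any(stringi::stri_detect_regex(seqs, "[^ACGT]"))) {
    km <- km[stringi::stri_detect_regex(km, "^[ACGT]+$")]
  }
  km
}

#' Subtraction parameters
#' @param min_total minimum count for a retained k-mer (default 10).
#' @param max_total maximum count (default 1000).
#' @export
subtraction_params <- function(min_total = 10L, max_total = 1000L) {
  assert_that(min_total > 0 && min_total <= max_total,
              "need 0 < min_total <= max_total")
  list(min_total = min_total, max_total = max_total)
}

#' Identify male-specific k-mers
#'
#' A k-mer is returned iff it is present in the male table, absent from
#' every other table, and its combined count with each other sample lies
#' in `[min_total, max_total]` — which, given absence elsewhere, reduces
#' to the male count lying in that range.
#'
#' @param male `kmer_count_table` of the male sample.
#' @param others list of `kmer_count_table`s (female, each mutant).
#' @param params a [subtraction_params()].
#' @return sorted character vector of male-specific k-mers, with the
#'   male counts as an attribute `counts`.
#' @export
male_specific_kmers <- function(male, others, params = subtraction_params()) {
  for (o in others) {
    assert_that(attr(o, "k") == attr(male, "k") &&
                  attr(o, "prefix") == attr(male, "prefix"),
                "k-mer tables disagree on k or prefix")
  }
  cand <- as.data.table(male)
  for (o in others) cand <- cand[!as.data.table(o), on = "kmer"]
  cand <- cand[count >= params$min_total & count <= params$max_total]
  setorder(cand, kmer)
  structure(cand$kmer, counts = cand$count)
}

#' Retain read pairs containing at least one k-mer from a set
#'
#' A pair is retained iff any prefix-anchored k-mer of either mate, on
#' either strand, belongs to `kmer_set`. Retention is monotone in the
#' set.
#'
#' @param pairs data.table with seq1/seq2 (and any other columns).
#' @param kmer_set character vector of k-mers (all same length, same
#'   first base).
#' @param prefix anchor base of the set.
#' @return the retained subset of `pairs`.
#' @export
retain_read_pairs <- function(pairs, kmer_set, prefix = "A") {
  assert_that(length(kmer_set) > 0, "k-mer set is empty")
  k <- nchar(kmer_set[1L])
  pairs <- as.data.table(pairs)
  if (!nrow(pairs)) return(pairs)
  hit <- function(seqs) {
    both <- c(seqs, revcomp(seqs))
    loc <- stringi::stri_locate_all_fixed(both, prefix,
                                          omit_no_match = TRUE)
    starts <- lapply(loc, function(m) m[, 1L])
    lens <- nchar(both)
    keep <- mapply(function(s, l) s[s + k - 1L <= l], starts, lens,
                   SIMPLIFY = FALSE)
    ns <- lengths(keep)
    idx <- rep(seq_along(both), ns)
    km <- stringi::stri_sub(rep(both, ns),
                            unlist(keep, use.names = FALSE), length = k)
    read_idx <- ((idx - 1L) %% length(seqs)) + 1L
    hits <- km %chin% kmer_set
    out <- logical(length(seqs))
    if (any(hits)) out[unique(read_idx[hits])] <- TRUE
    out
  }
  pairs[hit(seq1) | hit(seq2)]
}

#' Miniature de Bruijn unitig assembler
#'
#' Nodes are (k-1)-mers; edges are k-mers observed at least
#' `min_support` times across the reads and their reverse complements.
#' Unbranched paths are compressed into unitigs, reverse-complement
#' duplicates removed, and contigs ordered by (length desc,
#' lexicographic).
#'
#' @param reads character vector of read sequences.
#' @param assembly_k de Bruijn k (must be < read length).
#' @param min_support minimum k-mer multiplicity for an edge.
#' @return data.table of contigs: id, sequence, length, support (mean
#'   k-mer multiplicity, rounded).
#' @export
assemble_contigs <- function(reads, assembly_k = 31L, min_support = 2L) {
  empty <- data.table(id = character(), sequence = character(),
                      length = integer(), support = numeric())
  if (!length(reads)) return(empty)
  assert_that(assembly_k < min(nchar(reads)),
              "assembly_k must be smaller than the read length")
  k <- assembly_k
  both <- c(reads, revcomp(reads))
  both <- both[!stringi::stri_detect_regex(both, "[^ACGT]")]
  lens <- nchar(both)
  ns <- lens - k + 1L
  km <- stringi::stri_sub(rep(both, ns),
                          unlist(lapply(ns, seq_len), use.names = FALSE),
                          length = k)
  tab <- data.table(kmer = km)[, .(count = .N), by = kmer]
  tab <- tab[count >= min_support]
  if (!nrow(tab)) return(empty)
  setorder(tab, kmer)                       # deterministic edge order
  pref <- substr(tab$kmer, 1L, k - 1L)
  suff <- substr(tab$kmer, 2L, k)
  nodes <- unique(c(pref, suff))
  from <- match(pref, nodes); to <- match(suff, nodes)
  n_nodes <- length(nodes)
  outdeg <- tabulate(from, n_nodes); indeg <- tabulate(to, n_nodes)
  out_edge <- integer(n_nodes)               # unique out-edge per node
  out_edge[from[outdeg[from] == 1L]] <- which(outdeg[from] == 1L)
  used <- logical(nrow(tab))

  walk <- function(e) {
    path <- e
    used[e] <<- TRUE
    repeat {
      nxt_node <- to[e]
      if (indeg[nxt_node] != 1L || outdeg[nxt_node] != 1L) break
      e2 <- out_edge[nxt_node]
      if (e2 == 0L || used[e2]) break
      used[e2] <<- TRUE
      path <- c(path, e2)
      e <- e2
    }
    path
  }

  seqs <- character()
  supports <- numeric()
  start_edges <- which(outdeg[from] != 1L | indeg[from] != 1L)
  for (e in c(start_edges, seq_len(nrow(tab)))) {   # leftovers = cycles
    if (used[e]) next
    path <- walk(e)
    seqs[length(seqs) + 1L] <- paste0(
      tab$kmer[path[1L]],
      paste(substr(tab$kmer[path[-1L]], k, k), collapse = ""))
    supports[length(seqs)] <- mean(tab$count[path])
  }
  ## canonical-strand dedupe
  rc <- revcomp(seqs)
  canon <- pmin(seqs, rc)
  keep <- !duplicated(canon)
  dt <- data.table(sequence = canon[keep], support = round(supports[keep], 1))
  dt[, length := nchar(sequence)]
  setorder(dt, -length, sequence)
  dt[, id := sprintf("contig_%04d", .I)]
  dt[, .(id, sequence, length, support)]
}
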