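## Seed-and-extend pseudo-mapper and the coverage-ratio contig filter
## that defines the Ydel assembly. The mapper is deliberately simple:
## exact seed k-mer, ungapped extension, identity/coverage thresholds.

#' Map reads onto contigs (ungapped, seed-and-extend)
#'
#' A read maps to a contig when an exact seed k-mer (tried at the read's
#' start, middle and end, on both strands) anchors an ungapped alignment
#' with >= `min_identity` matches over >= `min_coverage` of the read.
#'
#' @param seqs character vector of read sequences.
#' @param contigs named character vector of contig sequences.
#' @param seed_len exact seed length.
#' @param min_identity minimum fraction of matching bases.
#' @param min_coverage minimum aligned fraction of the read.
#' @return data.table (read = index into `seqs`, contig, identity),
#'   best identity per (read, contig).
#' @export
map_reads <- function(seqs, contigs, seed_len = 21L, min_identity = 0.9,
                      min_coverage = 0.9) {
  assert_that(length(contigs) > 0, "contigs must be non-empty")
  empty <- data.table(read = integer(), contig = character(),
                      identity = numeric())
  if (!length(seqs)) return(empty)

  ## contig k-mer index (forward strand; reads are tried on both)
  cl <- nchar(contigs)
  ok <- cl >= seed_len
  idx <- rbindlist(lapply(which(ok), function(i) {
    n <- cl[i] - seed_len + 1L
    data.table(kmer = stringi::stri_sub(rep(contigs[i], n), seq_len(n),
                                        length = seed_len),
               contig = names(contigs)[i], pos = seq_len(n))
  }))
  if (!nrow(idx)) return(empty)
  setkey(idx, kmer)

  cand <- list()
  for (orient in c("fwd", "rev")) {
    rs <- if (orient == "fwd") seqs else revcomp(seqs)
    lens <- nchar(rs)
    for (j in 1:3) {
      off <- pmax(1L, switch(j, rep(1L, length(rs)),
                             (lens - seed_len) %/% 2L + 1L,
                             lens - seed_len + 1L))
      keep <- lens >= seed_len
      if (!any(keep)) next
      sk <- stringi::stri_sub(rs[keep], off[keep], length = seed_len)
      dt <- data.table(read = which(keep), off = off[keep], kmer = sk)
      hits <- idx[dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (!nrow(hits)) next
      hits[, cstart := pos - off + 1L]
      cand[[length(cand) + 1L]] <- hits[, .(read, contig, cstart,
                                            orient = orient)]
    }
  }
  if (!length(cand)) return(empty)
  cand <- unique(rbindlist(cand))

  ## ungapped comparison at the anchored placement
  cand[, rlen := nchar(seqs)[read]]
  cand[, clen := nchar(contigs)[contig]]
  cand[, astart := pmax(cstart, 1L)]
  cand[, aend := pmin(cstart + rlen - 1L, clen)]
  cand <- cand[aend - astart + 1L >= ceiling(min_coverage * rlen)]
  if (!nrow(cand)) return(empty)
  rseq <- seqs[cand$read]
  rev_idx <- cand$orient == "rev"
  if (any(rev_idx)) rseq[rev_idx] <- revcomp(rseq[rev_idx])
  rsub <- stringi::stri_sub(rseq, cand$astart - cand$cstart + 1L,
                            cand$aend - cand$cstart + 1L)
  csub <- stringi::stri_sub(contigs[cand$contig], cand$astart, cand$aend)
  cand[, matches := mapply(function(a, b)
    sum(utf8ToInt(a) == utf8ToInt(b)), rsub, csub,
    USE.NAMES = FALSE)]
  cand[, identity := matches / (aend - astart + 1L)]
  cand <- cand[identity >= min_identity]
  if (!nrow(cand)) return(empty)
  cand[, .(identity = max(identity)), by = .(read, contig)]
}

#' Best hits per read (pair): data.table(read, contig), one row per
#' best-tying contig; a pair's hits combine both mates at the pair level.
#' @noRd
best_hits_per_read <- function(dt, contigs, ...) {
  paired <- all(c("seq1", "seq2") %in% names(dt))
  hits <- if (paired) {
    h1 <- map_reads(dt$seq1, contigs, ...)
    h2 <- map_reads(dt$seq2, contigs, ...)
    rbindlist(list(h1, h2))[, .(identity = max(identity)),
                            by = .(read, contig)]
  } else map_reads(dt$seq, contigs, ...)
  if (!nrow(hits)) return(hits[, .(read, contig)])
  hits[, best := max(identity), by = read]
  hits[identity == best, .(read, contig)]
}

#' Count mapped read pairs per contig and sample
#'
#' A pair counts once, to the contig of its best mate hit; ties are
#' split equally as fractional counts.
#'
#' @param reads_by_sample named list; each element either a paired-read
#'   table (seq1/seq2) or a single-end table (seq).
#' @param contigs named character vector of contig sequences.
#' @param ... passed to [map_reads()].
#' @return `contig_count_matrix`: list with `counts` (contigs x samples
#'   matrix), `library_sizes`, `unmapped`, `normalized = FALSE`.
#' @export
count_mapped_reads <- function(reads_by_sample, contigs, ...) {
  assert_that(length(contigs) > 0, "contigs must be non-empty")
  counts <- matrix(0, nrow = length(contigs),
                   ncol = length(reads_by_sample),
                   dimnames = list(names(contigs), names(reads_by_sample)))
  lib <- setNames(numeric(length(reads_by_sample)), names(reads_by_sample))
  unmapped <- lib
  for (smp in names(reads_by_sample)) {
    dt <- as.data.table(reads_by_sample[[smp]])
    n <- nrow(dt)
    lib[smp] <- n
    if (!n) next
    hits <- best_hits_per_read(dt, contigs, ...)
    if (!nrow(hits)) { unmapped[smp] <- n; next }
    hits[, w := 1 / .N, by = read]
    agg <- hits[, .(count = sum(w)), by = contig]
    counts[agg$contig, smp] <- agg$count
    unmapped[smp] <- n - length(unique(hits$read))
  }
  structure(list(counts = counts, library_sizes = lib, unmapped = unmapped,
                 normalized = FALSE), class = "contig_count_matrix")
}

#' Normalize counts to the male library size
#'
#' Each sample's column is scaled by `male library size / sample library
#' size`; the male column is unchanged.
#'
#' @param matrix a `contig_count_matrix`.
#' @param male name of the male sample.
#' @return normalized `contig_count_matrix`.
#' @export
normalize_counts <- function(matrix, male = "male") {
  assert_that(male %in% names(matrix$library_sizes),
              sprintf("no sample named '%s'", male))
  assert_that(all(matrix$library_sizes > 0),
              "zero library size; cannot normalize")
  scale <- matrix$library_sizes[[male]] / matrix$library_sizes
  matrix$counts <- sweep(matrix$counts, 2L, scale, `*`)
  matrix$normalized <- TRUE
  matrix
}

#' Ratio-filter parameters
#' @param female_ratio_max select when female/male falls below this
#'   (default 0.20).
#' @param mutant_ratio_max or when mutant/male falls below this
#'   (default 0.40).
#' @export
ratio_filter_params <- function(female_ratio_max = 0.20,
                                mutant_ratio_max = 0.40) {
  assert_that(female_ratio_max > 0 && female_ratio_max <= 1 &&
                mutant_ratio_max > 0 && mutant_ratio_max <= 1,
              "ratio thresholds must be in (0, 1]")
  list(female_ratio_max = female_ratio_max,
       mutant_ratio_max = mutant_ratio_max)
}

#' Select Ydel contigs by coverage ratios
#'
#' A contig is selected iff `female/male < female_ratio_max` OR
#' `mutant/male < mutant_ratio_max`. Contigs with a male count of 0 are
#' rejected and flagged. Only one mutant enters the filter (mirroring
#' the published female/male-or-mutant/male disjunction); which one is
#' the `mutant` argument.
#'
#' @param matrix a normalized `contig_count_matrix`.
#' @param params a [ratio_filter_params()].
#' @param male,female,mutant sample names.
#' @return list: `selected` (contig ids), `report` (per-contig ratios
#'   and flags).
#' @export
select_ydel_contigs <- function(matrix, params = ratio_filter_params(),
                                male = "male", female = "female",
                                mutant = "EGP14") {
  assert_that(isTRUE(matrix$normalized),
              "counts must be normalized first (see normalize_counts)")
  cn <- colnames(matrix$counts)
  assert_that(all(c(male, female, mutant) %in% cn),
              "male/female/mutant must name samples in the matrix")
  m <- matrix$counts[, male]; f <- matrix$counts[, female]
  mu <- matrix$counts[, mutant]
  report <- data.table(contig = rownames(matrix$counts),
                       male = m, female = f, mutant = mu,
                       female_ratio = ifelse(m > 0, f / m, NA_real_),
                       mutant_ratio = ifelse(m > 0, mu / m, NA_real_))
  report[, flag := ifelse(male == 0, "no_male_coverage", "")]
  report[, selected := male > 0 &
           (female_ratio < params$female_ratio_max |
              mutant_ratio < params$mutant_ratio_max)]
  list(selected = report[selected == TRUE, contig], report = report)
}
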