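## Gametolog molecular evolution: codon-aware alignment, Nei-Gojobori
## (1986) divergence with Jukes-Cantor correction, Tajima's relative-rate
## test on amino acids, and mutation-rate dating.

#' Codon-aware alignment of coding sequences
#'
#' Translates each CDS, aligns the proteins globally (BLOSUM62, affine
#' gap open 11 / extend 1), and threads the codons back through the
#' protein alignment so that gaps are always whole codons. With three
#' sequences, the second and third are each aligned to the first and the
#' two pairwise alignments are merged on the coordinates of the first.
#'
#' @param cds_list named character vector or list of 2-3 coding sequences
#'   (nucleotides, length divisible by 3, no internal stop codons; a
#'   trailing stop codon is allowed and trimmed).
#' @return An object of class `codon_alignment`: a named character vector
#'   of gapped CDS of equal length, with attribute `n_codon_columns`.
#' @examples
#' aln <- codon_align(c(a = "ATGGGTTTA", b = "ATGTTA"))
#' @export
codon_align <- function(cds_list) {
  cds <- vapply(cds_list, as.character, character(1))
  assert_that(length(cds) %in% 2:3, "codon_align() takes 2 or 3 sequences")
  if (is.null(names(cds)) || any(names(cds) == ""))
    names(cds) <- paste0("seq", seq_along(cds))
  for (nm in names(cds)) {
    assert_that(nchar(cds[nm]) %% 3 == 0,
                sprintf("sequence '%s' length is not a multiple of 3", nm))
    ## trim one trailing stop codon if present
    codons <- split_codons(cds[nm])
    if (length(codons) && translate_codons(codons[length(codons)]) == "*")
      cds[nm] <- paste(codons[-length(codons)], collapse = "")
    st <- internal_stops(cds[nm])
    if (length(st))
      stop(sprintf("internal stop codon in sequence '%s' at codon %d",
                   nm, st[1L]), call. = FALSE)
  }
  prots <- vapply(cds, function(x)
    as.character(Biostrings::translate(Biostrings::DNAString(x))), character(1))

  aln_pair <- function(p1, p2) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(p1), Biostrings::AAString(p2),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
    list(a1 = as.character(Biostrings::alignedPattern(pa)),
         a2 = as.character(Biostrings::alignedSubject(pa)))
  }

  if (length(cds) == 2L) {
    pa <- aln_pair(prots[1L], prots[2L])
    gapped_aa <- c(pa$a1, pa$a2)
  } else {
    pa12 <- aln_pair(prots[1L], prots[2L])
    pa13 <- aln_pair(prots[1L], prots[3L])
    m <- merge_on_reference(pa12, pa13)
    gapped_aa <- m
  }
  names(gapped_aa) <- names(cds)

  gapped_cds <- vapply(seq_along(cds), function(i) {
    cols <- strsplit(gapped_aa[i], "")[[1]]
    codons <- split_codons(cds[i])
    out <- character(length(cols))
    k <- 0L
    for (j in seq_along(cols)) {
      if (cols[j] == "-") out[j] <- "---"
      else { k <- k + 1L; out[j] <- codons[k] }
    }
    paste(out, collapse = "")
  }, character(1))
  names(gapped_cds) <- names(cds)

  structure(gapped_cds,
            class = "codon_alignment",
            aa = gapped_aa,
            n_codon_columns = nchar(gapped_aa[[1L]]))
}

#' Merge two pairwise alignments that share their first sequence
#' @noRd
merge_on_reference <- function(pa12, pa13) {
  r1 <- strsplit(pa12$a1, "")[[1]]; s2 <- strsplit(pa12$a2, "")[[1]]
  r2 <- strsplit(pa13$a1, "")[[1]]; s3 <- strsplit(pa13$a2, "")[[1]]
  i <- j <- 1L
  o1 <- o2 <- o3 <- character()
  while (i <= length(r1) || j <= length(r2)) {
    g1 <- i <= length(r1) && r1[i] == "-"   # insertion in seq2
    g2 <- j <= length(r2) && r2[j] == "-"   # insertion in seq3
    if (g1) {
      o1 <- c(o1, "-"); o2 <- c(o2, s2[i]); o3 <- c(o3, "-"); i <- i + 1L
    } else if (g2) {
      o1 <- c(o1, "-"); o2 <- c(o2, "-"); o3 <- c(o3, s3[j]); j <- j + 1L
    } else {
      o1 <- c(o1, r1[i]); o2 <- c(o2, s2[i]); o3 <- c(o3, s3[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  c(paste(o1, collapse = ""), paste(o2, collapse = ""), paste(o3, collapse = ""))
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon alignment: %d sequences x %d codon columns\n",
              length(x), attr(x, "n_codon_columns")))
  for (nm in names(x)) cat(sprintf("  %-12s %s...\n", nm,
                                   substr(x[[nm]], 1, 48)))
  invisible(x)
}

#' Nei-Gojobori (NG86) pairwise divergence with Jukes-Cantor correction
#'
#' Synonymous site counts are fractional (per codon position, the
#' fraction of the three possible changes that are synonymous; changes to
#' stop codons count as nonsynonymous so S + N = 3 x codons). Observed
#' differences are averaged with equal weight over all minimal
#' substitution pathways between each codon pair, excluding pathways
#' through stop codons. Proportions are corrected with the Jukes-Cantor
#' formula d = -3/4 log(1 - 4p/3).
#'
#' @param alignment a 2-sequence [codon_align()] result, or a character
#'   vector of two equal-length gap-free coding sequences.
#' @return `pairwise_divergence` list: `S`, `N` (site counts), `Sd`, `Nd`
#'   (pathway-averaged differences), `pS`, `pN`, `dS`, `dN`, `omega`,
#'   `n_codons` (gap-free codon columns compared), `n_codon_columns`
#'   (all alignment columns).
#' @export
ng86_divergence <- function(alignment) {
  if (!inherits(alignment, "codon_alignment")) {
    assert_that(length(alignment) == 2L &&
                  nchar(alignment[[1L]]) == nchar(alignment[[2L]]),
                "need a 2-sequence codon alignment")
    alignment <- structure(vapply(alignment, as.character, character(1)),
                           class = "codon_alignment",
                           n_codon_columns = nchar(alignment[[1L]]) / 3)
  }
  assert_that(length(alignment) == 2L,
              "ng86_divergence() needs exactly 2 sequences")
  cod1 <- split_codons(alignment[[1L]])
  cod2 <- split_codons(alignment[[2L]])
  keep <- !grepl("-", cod1, fixed = TRUE) & !grepl("-", cod2, fixed = TRUE)
  cod1 <- cod1[keep]; cod2 <- cod2[keep]
  assert_that(length(cod1) >= 1L, "no gap-free codon columns to compare")
  aa <- codon_aa()
  assert_that(all(aa[cod1] != "*") && all(aa[cod2] != "*"),
              "stop codon in compared columns")

  ss <- syn_sites_table()
  S <- (sum(ss[cod1]) + sum(ss[cod2])) / 2
  N <- 3 * length(cod1) - S
  assert_that(S > 0, "no synonymous sites (S = 0)")

  tabs <- pair_diff_tables()
  idx <- cbind(match(cod1, rownames(tabs$sd)), match(cod2, colnames(tabs$sd)))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p, what) {
    if (p >= 0.75)
      stop(sprintf("%s proportion %.3f >= 3/4: Jukes-Cantor distance undefined",
                   what, p), call. = FALSE)
    -0.75 * log(1 - 4 * p / 3) + 0   # +0 normalises IEEE -0
  }
  dS <- jc(pS, "synonymous")
  dN <- jc(pN, "nonsynonymous")
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN,
                 omega = if (dS > 0) dN / dS else NA_real_,
                 n_codons = length(cod1),
                 n_codon_columns = attr(alignment, "n_codon_columns")),
            class = "pairwise_divergence")
}

#' @export
print.pairwise_divergence <- function(x, ...) {
  cat(sprintf(
    "NG86 divergence over %d codons:\n  S = %.2f, N = %.2f, Sd = %.2f, Nd = %.2f\n  dS = %.4f, dN = %.4f, dN/dS = %s\n",
    x$n_codons, x$S, x$N, x$Sd, x$Nd, x$dS, x$dN,
    if (is.na(x$omega)) "undefined" else sprintf("%.4f", x$omega)))
  invisible(x)
}

#' Lineage-specific amino-acid replacement counts against an outgroup
#'
#' Over gap-free alignment columns, `m1` counts columns where `seq1`
#' differs while `seq2` equals the outgroup, and `m2` symmetrically.
#' Columns where all three states differ, or where the outgroup is the
#' odd one out, contribute to neither count.
#'
#' @param alignment a 3-sequence [codon_align()] result (amino-acid
#'   columns are used) or a named character vector of three equal-length
#'   aligned amino-acid sequences.
#' @param seq1,seq2,outgroup names of the sequences in the alignment.
#' @return list with `m1`, `m2` and per-column tallies.
#' @export
lineage_replacements <- function(alignment, seq1, seq2, outgroup) {
  aas <- if (inherits(alignment, "codon_alignment")) attr(alignment, "aa")
  else vapply(alignment, as.character, character(1))
  assert_that(all(c(seq1, seq2, outgroup) %in% names(aas)),
              "seq1/seq2/outgroup must name sequences in the alignment")
  a1 <- strsplit(aas[[seq1]], "")[[1]]
  a2 <- strsplit(aas[[seq2]], "")[[1]]
  og <- strsplit(aas[[outgroup]], "")[[1]]
  keep <- a1 != "-" & a2 != "-" & og != "-"
  a1 <- a1[keep]; a2 <- a2[keep]; og <- og[keep]
  m1 <- sum(a1 != og & a2 == og)
  m2 <- sum(a2 != og & a1 == og)
  list(m1 = m1, m2 = m2, n_columns = length(a1),
       n_diff_columns = sum(a1 != a2 | a1 != og))
}

#' Tajima's relative-rate test (1 degree of freedom)
#'
#' Given lineage-specific difference counts m1 and m2 judged against an
#' outgroup, the statistic is (m1 - m2)^2 / (m1 + m2), compared to a
#' chi-square distribution with 1 df.
#'
#' @param m1,m2 non-negative lineage-specific difference counts.
#' @return `relative_rate_result` list: `m1`, `m2`, `chi_square`,
#'   `p_value`, `informative`.
#' @examples
#' tajima_rrt(12, 3)   # chi^2 = 5.4, P ~ 0.02
#' @export
tajima_rrt <- function(m1, m2) {
  assert_that(m1 >= 0 && m2 >= 0, "m1 and m2 must be non-negative")
  if (m1 + m2 == 0) {
    res <- list(m1 = m1, m2 = m2, chi_square = 0, p_value = 1,
                informative = FALSE)
  } else {
    chi <- (m1 - m2)^2 / (m1 + m2)
    res <- list(m1 = m1, m2 = m2, chi_square = chi,
                p_value = pchisq(chi, df = 1, lower.tail = FALSE),
                informative = TRUE)
  }
  structure(res, class = "relative_rate_result")
}

#' @export
print.relative_rate_result <- function(x, ...) {
  cat(sprintf(
    "Tajima relative-rate test: m1 = %d, m2 = %d, chi^2 = %.3f, P = %.4g%s\n",
    x$m1, x$m2, x$chi_square, x$p_value,
    if (x$informative) "" else " (uninformative: m1 = m2 = 0)"))
  invisible(x)
}

#' Divergence time from synonymous divergence and a mutation rate
#'
#' T_generations = dS / (2 mu); T_years = T_generations x generation
#' time. Defaults are a per-generation mutation rate of 7.31e-9 per
#' nucleotide and 1.5 years per generation.
#'
#' @param dS synonymous divergence (substitutions per synonymous site).
#' @param mu mutations per nucleotide per generation.
#' @param generation_time years per generation.
#' @return `divergence_time` list with the inputs, `T_generations` and
#'   `T_years`.
#' @examples
#' divergence_time(0.18)   # ~12 million generations, ~18 My
#' @export
divergence_time <- function(dS, mu = 7.31e-9, generation_time = 1.5) {
  assert_that(mu > 0, "mutation rate mu must be > 0")
  assert_that(dS >= 0, "dS must be non-negative")
  assert_that(generation_time > 0, "generation_time must be > 0")
  tg <- dS / (2 * mu)
  structure(list(dS = dS, mu = mu, generation_time = generation_time,
                 T_generations = tg, T_years = tg * generation_time),
            class = "divergence_time")
}

#' @export
print.divergence_time <- function(x, ...) {
  cat(sprintf(
    "dS = %.4g, mu = %.3g/site/generation -> %.3g generations (~%.1f My at %.2g yr/gen)\n",
    x$dS, x$mu, x$T_generations, x$T_years / 1e6, x$generation_time))
  invisible(x)
}
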