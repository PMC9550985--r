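## Codon-level machinery shared by the divergence estimators and the
## gametolog simulator. Universal genetic code only (a config hook could
## swap the table; alternative codes are out of scope).

.codon_cache <- new.env(parent = emptyenv())

BASES <- c("A", "C", "G", "T")

#' All 64 codons and their amino acids (universal code, '*' = stop)
#' @noRd
codon_aa <- function() {
  if (is.null(.codon_cache$aa)) {
    gc_tab <- Biostrings::GENETIC_CODE
    ## GENETIC_CODE names are RNA-free already (T not U in Biostrings)
    .codon_cache$aa <- gc_tab
  }
  .codon_cache$aa
}

#' Translate a vector of codons to amino acids
#' @noRd
translate_codons <- function(codons) unname(codon_aa()[codons])

#' Split a CDS string into codons
#' @noRd
split_codons <- function(cds) {
  n <- nchar(cds)
  assert_that(n %% 3 == 0, "CDS length must be divisible by 3")
  if (n == 0L) return(character())
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' The 9 single-base neighbours of a codon
#' @noRd
codon_neighbours <- function(codon) {
  out <- character(9L)
  k <- 0L
  for (pos in 1:3) {
    old <- substr(codon, pos, pos)
    for (b in BASES[BASES != old]) {
      x <- codon
      substr(x, pos, pos) <- b
      k <- k + 1L
      out[k] <- x
    }
  }
  out
}

#' Nei-Gojobori synonymous site counts per codon
#'
#' For every non-stop codon, the synonymous site count is the sum over the
#' three positions of (number of the 3 possible changes that preserve the
#' amino acid) / 3. Changes that create a stop codon count as
#' nonsynonymous, so S + N = 3 exactly for every codon.
#' @noRd
syn_sites_table <- function() {
  if (is.null(.codon_cache$syn_sites)) {
    aa <- codon_aa()
    codons <- names(aa)
    s <- setNames(numeric(length(codons)), codons)
    for (cd in codons) {
      if (aa[cd] == "*") { s[cd] <- NA_real_; next }
      nb <- codon_neighbours(cd)
      s[cd] <- sum(aa[nb] == aa[cd]) / 3
    }
    .codon_cache$syn_sites <- s
  }
  .codon_cache$syn_sites
}

#' Pathway-averaged (Sd, Nd) contributions for every codon pair
#'
#' For a pair of codons differing at d positions, all d! orderings of the
#' single-base steps are enumerated; pathways passing through a stop codon
#' are discarded and the remaining pathways weighted equally. Each step is
#' synonymous iff it preserves the amino acid. If every pathway passes
#' through a stop (does not occur for observed non-stop endpoints in
#' practice, but guarded anyway), all pathways are used.
#' @noRd
pair_diff_tables <- function() {
  if (!is.null(.codon_cache$sd_mat)) {
    return(list(sd = .codon_cache$sd_mat, nd = .codon_cache$nd_mat))
  }
  aa <- codon_aa()
  codons <- names(aa)[aa != "*"]
  n <- length(codons)
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      cnt <- pathway_counts(codons[i], codons[j])
      sd[i, j] <- sd[j, i] <- cnt[1L]
      nd[i, j] <- nd[j, i] <- cnt[2L]
    }
  }
  .codon_cache$sd_mat <- sd
  .codon_cache$nd_mat <- nd
  list(sd = sd, nd = nd)
}

#' Enumerate substitution pathways between two codons -> c(Sd, Nd)
#' @noRd
pathway_counts <- function(c1, c2) {
  aa <- codon_aa()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0L) return(c(0, 0))
  perms <- permutations_of(pos)
  syn_tot <- num_tot <- 0
  valid <- 0L
  syn_all <- num_all <- 0   # fallback including stop pathways
  for (ord in perms) {
    cur <- c1
    syn <- num <- 0
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (aa[nxt] == "*" && nxt != c2) ok <- FALSE
      if (aa[nxt] == aa[cur]) syn <- syn + 1 else num <- num + 1
      cur <- nxt
    }
    syn_all <- syn_all + syn; num_all <- num_all + num
    if (ok) { syn_tot <- syn_tot + syn; num_tot <- num_tot + num; valid <- valid + 1L }
  }
  if (valid > 0L) c(syn_tot / valid, num_tot / valid)
  else c(syn_all / length(perms), num_all / length(perms))
}

#' All orderings of a small vector (d <= 3 here)
#' @noRd
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Positions of internal stop codons in a CDS (empty if clean)
#' @noRd
internal_stops <- function(cds) {
  codons <- split_codons(cds)
  which(translate_codons(codons) == "*")
}
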