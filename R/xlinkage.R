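## X-linkage segregation test: at X-linked sites sons always inherit the
## maternal allele and never the paternal one, while daughters carry the
## paternal allele. Sons' genotype calls that appear homozygous are
## treated as hemizygous-compatible (diploid callers report hemizygous X
## sites that way). Missing calls ("" or NA or "./.") are skipped
## per-individual, not treated as violations.

#' @noRd
parse_gt <- function(g) {
  if (is.na(g) || g == "" || g == "./." || g == ".") return(character())
  sort(strsplit(g, "/", fixed = TRUE)[[1L]])
}

#' Classify sites of a cross for consistency with X-linkage
#'
#' A site is *informative* iff the father carries an allele absent from
#' the mother. An informative site is *consistent* with X-linkage iff
#' (a) no son carries the paternal-specific allele, (b) every daughter
#' with a call carries it, and (c) every son's call reduces to a single
#' maternal allele. The locus verdict is `X-linked` when at least one
#' site is informative and none is violated, `rejected` on any
#' violation, and `uninformative` otherwise.
#'
#' The father's X allele is the "paternal-specific" allele daughters
#' must inherit; Y-linked paternal alleles are outside this model.
#'
#' @param cross a `cross_genotypes` table (see [simulate_cross()] /
#'   [read_cross_tsv()]).
#' @return `xlinkage_result`: list with `sites` (per-site table),
#'   `n_informative`, `n_consistent`, `verdict`.
#' @export
classify_sites <- function(cross) {
  sex <- attr(cross, "sex")
  assert_that(!is.null(sex), "cross lacks the offspring sex attribute")
  sons <- names(sex)[sex == "M"]
  daughters <- names(sex)[sex == "F"]
  assert_that(length(sons) >= 1,
              "X-linkage test undefined without sons")
  dt <- as.data.table(cross)
  res <- list()
  for (i in seq_len(nrow(dt))) {
    row <- dt[i]
    mo <- parse_gt(row$mother)
    fa <- parse_gt(row$father)
    pat <- setdiff(fa, mo)
    informative <- length(pat) > 0
    consistent <- NA
    violation <- ""
    if (informative) {
      pat <- pat[1L]
      consistent <- TRUE
      for (s in sons) {
        g <- parse_gt(row[[s]])
        if (!length(g)) next
        if (pat %in% g) {
          consistent <- FALSE
          violation <- sprintf("son %s carries paternal allele %s", s, pat)
          break
        }
        if (length(unique(g)) != 1L || !all(g %in% mo)) {
          consistent <- FALSE
          violation <- sprintf("son %s call not a single maternal allele", s)
          break
        }
      }
      if (consistent) for (d in daughters) {
        g <- parse_gt(row[[d]])
        if (!length(g)) next
        if (!pat %in% g) {
          consistent <- FALSE
          violation <- sprintf("daughter %s lacks paternal allele %s", d, pat)
          break
        }
      }
    }
    res[[i]] <- data.table(site_id = row$site_id, informative = informative,
                           consistent = consistent, violation = violation)
  }
  sites <- rbindlist(res)
  n_inf <- sum(sites$informative)
  n_con <- sum(sites$consistent %in% TRUE)
  verdict <- if (n_inf == 0) "uninformative"
  else if (n_con == n_inf) "X-linked"
  else "rejected"
  structure(list(sites = sites, n_informative = n_inf,
                 n_consistent = n_con, verdict = verdict),
            class = "xlinkage_result")
}

#' @export
print.xlinkage_result <- function(x, ...) {
  cat(sprintf("X-linkage: %s (%d/%d informative sites consistent)\n",
              x$verdict, x$n_consistent, x$n_informative))
  invisible(x)
}

#' Monte-Carlo pass rate of a non-X locus through the X-linkage test
#'
#' Estimates the probability that a single informative site of the given
#' class mimics X-linkage in a family of the given size. For an
#' autosomal site with a homozygous mother and a heterozygous father,
#' the closed form is (1/2)^(sons + daughters): every son must dodge the
#' paternal-specific allele and every daughter must draw it.
#'
#' @param n_sons,n_daughters family size.
#' @param site_class "autosome" or "X".
#' @param n_replicates Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return list: `p_pass`, `se` (binomial standard error),
#'   `n_replicates`.
#' @export
xlinkage_power <- function(n_sons = 4L, n_daughters = 6L,
                           site_class = c("autosome", "X"),
                           n_replicates = 10000L, seed = 1L) {
  site_class <- match.arg(site_class)
  assert_that(n_replicates >= 1, "n_replicates must be >= 1")
  with_seed(seed, {
    if (site_class == "X") {
      ## true X transmission always passes
      p <- 1; se <- 0
    } else {
      ## mother A/A, father A/B; children draw the paternal allele i.i.d.
      n_off <- n_sons + n_daughters
      draws <- matrix(runif(n_replicates * n_off) < 0.5, n_replicates)
      sons_ok <- if (n_sons > 0)
        rowSums(draws[, seq_len(n_sons), drop = FALSE]) == 0 else TRUE
      dgt_ok <- if (n_daughters > 0)
        rowSums(draws[, n_sons + seq_len(n_daughters), drop = FALSE]) ==
        n_daughters else TRUE
      pass <- sons_ok & dgt_ok
      p <- mean(pass)
      se <- sqrt(p * (1 - p) / n_replicates)
    }
    list(p_pass = p, se = se, n_replicates = n_replicates)
  })
}
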