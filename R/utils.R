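## Small shared helpers: RNG scoping, sequence primitives, Phred codecs.

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their `seed` argument without clobbering the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("`seed` must be a single non-negative number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage sub-seed from a master seed
#'
#' Stages of the pipeline each consume an independent substream derived
#' deterministically from (seed, tag). Kept below 2^31 - 1.
#' @noRd
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Reverse complement of DNA strings
#' @noRd
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Uniform random DNA string(s); caller controls the RNG state
#' @noRd
random_dna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = ""),
    character(1))
}

#' Phred integer vector <-> Phred+33 string
#' @noRd
phred_to_string <- function(q) intToUtf8(q + 33L)

#' @noRd
string_to_phred <- function(s) utf8ToInt(s) - 33L

#' Flip bases to a random *different* base with probability `error_rate`.
#' Vectorised over a character vector of equal-length-or-not reads.
#' @noRd
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, error_rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      substr(seqs[i], p, p) <- new
    }
  }
  seqs
}

#' Stop unless condition holds
#' @noRd
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' Half-open interval overlap
#' @noRd
overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
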