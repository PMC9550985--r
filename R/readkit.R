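## Quality trimming, reproducing the canonical leading / trailing /
## sliding-window / minimum-length recipe.

#' Trimming parameters
#'
#' Defaults reproduce the recipe `LEADING:20 TRAILING:20
#' SLIDINGWINDOW:4:28 MINLEN:40`.
#'
#' @param leading_q drop 5' bases while quality < this Phred value.
#' @param trailing_q drop 3' bases while quality < this Phred value.
#' @param window_size sliding-window width in bases.
#' @param window_q cut at the start of the first window whose mean
#'   quality falls below this value.
#' @param min_len drop reads shorter than this after trimming.
#' @export
trim_params <- function(leading_q = 20L, trailing_q = 20L, window_size = 4L,
                        window_q = 28, min_len = 40L) {
  assert_that(window_size >= 1, "window_size must be >= 1")
  assert_that(all(c(leading_q, trailing_q, window_q, min_len) >= 0),
              "trimming thresholds must be non-negative")
  structure(list(leading_q = leading_q, trailing_q = trailing_q,
                 window_size = window_size, window_q = window_q,
                 min_len = min_len), class = "trim_params")
}

#' Kept interval of a quality vector under the trimming rules; 0-length
#' result means drop. Returns c(from, to) (1-based, inclusive).
#' @noRd
trim_interval <- function(q, params) {
  n <- length(q)
  if (n == 0L) return(c(1L, 0L))
  ## (1) leading
  ok <- which(q >= params$leading_q)
  if (!length(ok)) return(c(1L, 0L))
  from <- ok[1L]
  ## (2) trailing
  ok2 <- which(q >= params$trailing_q)
  to <- ok2[length(ok2)]
  if (to < from) return(c(1L, 0L))
  ## (3) sliding window 5'->3' over the surviving segment; cut at the
  ##     start of the first full window whose mean < window_q
  seg <- q[from:to]
  w <- params$window_size
  if (length(seg) >= w) {
    cs <- cumsum(c(0, seg))
    means <- (cs[(w + 1L):length(cs)] - cs[1:(length(cs) - w)]) / w
    bad <- which(means < params$window_q)
    if (length(bad)) {
      to <- from + bad[1L] - 2L          # keep [from, window start - 1]
      if (to < from) return(c(1L, 0L))
      ## re-apply trailing trim to the cut read
      seg2 <- q[from:to]
      ok3 <- which(seg2 >= params$trailing_q)
      if (!length(ok3)) return(c(1L, 0L))
      to <- from + ok3[length(ok3)] - 1L
    }
  }
  if (to - from + 1L < params$min_len) return(c(1L, 0L))
  c(from, to)
}

#' Trim a single read
#'
#' Applies, in order: leading-quality trim, trailing-quality trim,
#' 5'->3' sliding-window cut (followed by a trailing re-trim), and the
#' minimum-length filter.
#'
#' @param seq nucleotide string.
#' @param qual Phred+33 quality string of equal length, or an integer
#'   Phred vector.
#' @param params a [trim_params()].
#' @return list(seq, qual) of the surviving substring, or `NULL` if the
#'   read is dropped.
#' @export
trim_read <- function(seq, qual, params = trim_params()) {
  q <- if (is.character(qual)) string_to_phred(qual) else as.integer(qual)
  assert_that(nchar(seq) == length(q),
              "sequence and quality lengths differ")
  iv <- trim_interval(q, params)
  if (iv[2L] < iv[1L]) return(NULL)
  list(seq = substr(seq, iv[1L], iv[2L]),
       qual = if (is.character(qual)) substr(qual, iv[1L], iv[2L])
       else q[iv[1L]:iv[2L]])
}

#' Trim paired reads, dropping a pair when either mate fails
#'
#' Trimming decisions depend only on the quality string, so unique
#' quality strings are trimmed once and the result broadcast — with a
#' constant quality model this makes pair trimming O(1) per read.
#'
#' @param pairs data.table with seq1, qual1, seq2, qual2 (id optional).
#' @param params a [trim_params()].
#' @return list: `pairs` (surviving, trimmed), `report` (counts per
#'   outcome; `kept + dropped_mate1_only + dropped_mate2_only +
#'   dropped_both = input`).
#' @export
trim_pairs <- function(pairs, params = trim_params()) {
  pairs <- as.data.table(pairs)
  n <- nrow(pairs)
  apply_side <- function(seqs, quals) {
    uq <- unique(quals)
    ivs <- vapply(uq, function(s)
      trim_interval(string_to_phred(s), params), integer(2))
    idx <- match(quals, uq)
    from <- ivs[1L, idx]; to <- ivs[2L, idx]
    keep <- to >= from
    list(seq = stringi::stri_sub(seqs, from, to),
         qual = stringi::stri_sub(quals, from, to), keep = keep)
  }
  s1 <- apply_side(pairs$seq1, pairs$qual1)
  s2 <- apply_side(pairs$seq2, pairs$qual2)
  keep <- s1$keep & s2$keep
  out <- pairs[keep]
  out[, `:=`(seq1 = s1$seq[keep], qual1 = s1$qual[keep],
             seq2 = s2$seq[keep], qual2 = s2$qual[keep])]
  report <- list(input = n, kept = sum(keep),
                 dropped_mate1_only = sum(!s1$keep & s2$keep),
                 dropped_mate2_only = sum(s1$keep & !s2$keep),
                 dropped_both = sum(!s1$keep & !s2$keep))
  list(pairs = out, report = report)
}
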