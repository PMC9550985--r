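## Independent brute-force oracles. These deliberately share no code
## with the package internals they check: everything is recomputed from
## first principles with the simplest possible enumeration.

oracle_genetic_code <- Biostrings::GENETIC_CODE

oracle_translate <- function(codon) unname(oracle_genetic_code[codon])

## NG86 synonymous site count of one codon, stops counted nonsynonymous
oracle_syn_sites <- function(codon) {
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (oracle_translate(alt) == aa) s <- s + 1 / 3
    }
  }
  s
}

## exhaustive pathway enumeration for one codon pair -> c(Sd, Nd)
oracle_pathway_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  perms <- if (length(pos) == 1) list(pos) else {
    if (length(pos) == 2) list(pos, rev(pos)) else {
      out <- list()
      for (i in 1:3) for (j in setdiff(1:3, i))
        out[[length(out) + 1]] <- pos[c(i, j, setdiff(1:3, c(i, j)))]
      out
    }
  }
  acc <- list()
  for (ord in perms) {
    cur <- c1; syn <- non <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_translate(nxt) == "*" && nxt != c2) ok <- FALSE
      if (oracle_translate(nxt) == oracle_translate(cur)) syn <- syn + 1
      else non <- non + 1
      cur <- nxt
    }
    acc[[length(acc) + 1]] <- list(ok = ok, syn = syn, non = non)
  }
  valid <- Filter(function(a) a$ok, acc)
  if (!length(valid)) valid <- acc
  c(mean(vapply(valid, `[[`, 0, "syn")),
    mean(vapply(valid, `[[`, 0, "non")))
}

## full NG86 + JC on two gap-free CDS strings
oracle_ng86 <- function(s1, s2) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- split3(s1); c2 <- split3(s2)
  S <- (sum(vapply(c1, oracle_syn_sites, 0)) +
          sum(vapply(c2, oracle_syn_sites, 0))) / 2
  N <- 3 * length(c1) - S
  sd <- nd <- 0
  for (i in seq_along(c1)) {
    cnt <- oracle_pathway_counts(c1[i], c2[i])
    sd <- sd + cnt[1]; nd <- nd + cnt[2]
  }
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sd, Nd = nd,
       dS = jc(sd / S), dN = jc(nd / N))
}

## rule-by-rule naive trimmer (leading, trailing, window, trailing again,
## minlen), returning the kept quality vector or NULL
oracle_trim <- function(q, leading = 20, trailing = 20, wsize = 4,
                        wq = 28, minlen = 40) {
  while (length(q) && q[1] < leading) q <- q[-1]
  while (length(q) && q[length(q)] < trailing) q <- q[-length(q)]
  if (length(q) >= wsize) {
    for (i in seq_len(length(q) - wsize + 1)) {
      if (mean(q[i:(i + wsize - 1)]) < wq) {
        q <- q[seq_len(i - 1)]
        break
      }
    }
    while (length(q) && q[length(q)] < trailing) q <- q[-length(q)]
  }
  if (length(q) < minlen) return(NULL)
  q
}

## every k-mer window of a string set (both strands) starting with prefix
oracle_kmers <- function(seqs, k = 35, prefix = "A") {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs)))
  out <- character()
  for (s in c(seqs, rc)) {
    n <- nchar(s)
    if (n < k) next
    win <- substring(s, 1:(n - k + 1), k:n)
    win <- win[substr(win, 1, 1) == prefix & !grepl("[^ACGT]", win)]
    out <- c(out, win)
  }
  out
}

oracle_revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

## random read helper
random_read <- function(n, min_q = 2, max_q = 40) {
  list(seq = paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
       qual = sample(min_q:max_q, n, TRUE))
}
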