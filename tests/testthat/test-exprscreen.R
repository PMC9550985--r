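set.seed(41)
rand_seq <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

test_that("local_homology_search finds identity and planted homology", {
  subj <- c(s1 = rand_seq(500))
  hits <- local_homology_search(c(q1 = subj[["s1"]]), subj)
  expect_equal(nrow(hits), 1)
  expect_lt(hits$evalue, 1e-50)
  expect_equal(hits$pident, 100)
  expect_equal(c(hits$qstart, hits$qend), c(1L, 500L))

  ## 50-base exact match planted inside a 1-kb subject
  core <- rand_seq(50)
  subj2 <- c(s = paste0(rand_seq(400), core, rand_seq(550)))
  q <- c(q = core)
  h <- local_homology_search(q, subj2)
  expect_equal(nrow(h), 1)
  expect_lte(h$sstart, 401)
  expect_gte(h$send, 450)

  ## reverse-strand hits are found (sstart > send)
  hrc <- local_homology_search(c(q = oracle_revcomp(core)), subj2)
  expect_equal(nrow(hrc), 1)
  expect_gt(hrc$sstart, hrc$send)
})

test_that("unrelated random sequences yield no hit at 1e-7", {
  set.seed(97)
  n_hits <- 0
  for (i in 1:100) {
    q <- c(q = rand_seq(200))
    s <- c(s = rand_seq(200))
    n_hits <- n_hits + nrow(local_homology_search(q, s, evalue_max = 1e-7))
  }
  expect_equal(n_hits, 0)
})

test_that("E-values decrease with score; statistics are recorded", {
  subj <- c(s = rand_seq(300))
  partial <- substr(subj[["s"]], 1, 150)
  h_full <- local_homology_search(c(q = subj[["s"]]), subj)
  h_part <- local_homology_search(c(q = partial), subj)
  expect_lt(h_full$evalue, h_part$evalue)
  expect_gt(h_full$bitscore, h_part$bitscore)
  expect_equal(round(attr(h_full, "lambda"), 2), 1.33)
  expect_equal(attr(h_full, "K"), 0.621)
})

test_that("quantify normalizes to TPM and honours length", {
  frags <- c(f1 = rand_seq(300), f2 = rand_seq(300), f3 = rand_seq(600))
  reads <- function(feat, n, len = 75) {
    starts <- sample(nchar(frags[feat]) - len + 1, n, TRUE)
    data.table::data.table(seq = substring(frags[feat], starts,
                                           starts + len - 1))
  }
  ## all reads from one fragment -> 1e6 / 0 / 0
  em <- quantify(list(s = reads("f1", 50)), frags)
  expect_equal(unname(em$tpm[, "s"]), c(1e6, 0, 0))

  ## 3:1 split over equal lengths -> 750k : 250k
  em <- quantify(list(s = rbind(reads("f1", 150), reads("f2", 50))), frags)
  expect_equal(unname(em$tpm["f1", "s"]), 750000)
  expect_equal(unname(em$tpm["f2", "s"]), 250000)

  ## equal counts, double length -> half the rate
  em <- quantify(list(s = rbind(reads("f1", 50), reads("f3", 50))), frags)
  expect_equal(unname(em$tpm["f1", "s"] / em$tpm["f3", "s"]), 2)

  ## abundance is scale-free in read depth
  em1 <- quantify(list(s = rbind(reads("f1", 60), reads("f2", 20))), frags)
  r2 <- rbind(reads("f1", 60), reads("f2", 20))
  em2 <- quantify(list(s = rbind(r2, r2)), frags)
  expect_equal(em1$tpm[, "s"] / 1e6, em2$tpm[, "s"] / 1e6, tolerance = 0.02)

  ## empty sample: zero column with warning
  expect_warning(
    em0 <- quantify(list(s = data.table::data.table(seq = rand_seq(75))),
                    c(f1 = rand_seq(300))),
    "no reads assigned")
  expect_equal(unname(em0$tpm[, "s"]), 0)
})

test_that("reassignment strips tie counts off silent twins", {
  f1 <- rand_seq(300)
  f2 <- paste0(substr(f1, 1, 150), rand_seq(150))   # shares a 150 bp head
  frags <- c(f1 = f1, f2 = f2)
  ## reads only from the shared head plus unique f1 tail
  starts <- c(rep(20, 10), rep(200, 90))
  reads <- data.table::data.table(seq = substring(f1, starts, starts + 74))
  em_eq <- quantify(list(s = reads), frags, reassign = FALSE)
  em_re <- quantify(list(s = reads), frags, reassign = TRUE)
  expect_gt(em_eq$counts["f2", "s"], 0)             # ties split equally
  expect_lt(em_re$counts["f2", "s"], em_eq$counts["f2", "s"])
  expect_lt(em_re$tpm["f2", "s"] / 1e6, 0.01)
})

test_that("te_filter removes fragments with TE homology", {
  te <- c(te1 = rand_seq(400))
  frags <- c(clean = rand_seq(500),
             dirty = paste0(rand_seq(200), substr(te[["te1"]], 101, 200),
                            rand_seq(200)))
  kept <- te_filter(frags, te)
  expect_identical(names(kept), "clean")
  expect_identical(attr(kept, "removed"), "dirty")

  ## empty TE library removes nothing
  kept2 <- te_filter(frags, character())
  expect_identical(names(kept2), names(frags))
})

test_that("candidate_filter implements the male-but-not-silent rule", {
  tpm <- rbind(cand = c(50, 0, 0, 0, 0),
               leaky = c(40, 0, 0, 0, 5),
               weak = c(0.5, 0, 0, 0, 0),
               ubiquitous = c(30, 20, 10, 10, 10))
  colnames(tpm) <- c("male", "female", "R025", "EGP14", "EGP15")
  em <- structure(list(tpm = tpm, counts = tpm, lengths = NULL),
                  class = "expression_matrix")
  out <- candidate_filter(em, "male", c("female", "R025", "EGP14", "EGP15"))
  expect_identical(out, "cand")          # EGP15 expression disqualifies leaky
  expect_error(candidate_filter(em, "male", "nosuch"), "unknown sample")
  expect_error(candidate_filter_params(expressed_min = 1, silent_max = 2),
               "below")
})
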