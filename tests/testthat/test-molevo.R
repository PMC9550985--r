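test_that("codon_align handles identical, indel and broken-frame input", {
  cds <- random_cds(40, seed = 5)
  aln <- codon_align(c(a = cds, b = cds))
  expect_false(grepl("-", aln[["a"]], fixed = TRUE))
  expect_identical(aln[["a"]], aln[["b"]])

  ## delete one whole codon from the middle -> one codon-sized gap there
  del_at <- 21L                                   # codon index
  b <- paste0(substr(cds, 1, (del_at - 1) * 3),
              substr(cds, del_at * 3 + 1, nchar(cds)))
  aln <- codon_align(c(a = cds, b = b))
  expect_identical(nchar(aln[["a"]]), nchar(aln[["b"]]))
  gaps <- gregexpr("-+", aln[["b"]])[[1]]
  expect_length(gaps, 1)
  expect_identical(attr(gaps, "match.length"), 3L)
  expect_identical(as.integer(gaps), (del_at - 1L) * 3L + 1L)
  expect_identical(gsub("-", "", aln[["b"]]), b)

  expect_error(codon_align(c(a = "ATGC", b = "ATG")), "multiple of 3")
  expect_error(codon_align(c(a = "ATGTAAAAA", b = "ATGTAAAAA")),
               "internal stop")
})

test_that("ng86_divergence matches the hand-enumerated glycine example", {
  aln <- c(a = strrep("GGT", 10), b = paste0(strrep("GGT", 9), "GGC"))
  d <- ng86_divergence(aln)
  expect_equal(d$S, 10)
  expect_equal(d$N, 20)
  expect_equal(d$Sd, 1)
  expect_equal(d$Nd, 0)
  expect_equal(d$pS, 0.1)
  expect_equal(d$dS, -0.75 * log(1 - 0.4 / 3))
  expect_equal(d$dN, 0)
})

test_that("ng86 invariants: symmetry, site conservation, pathway sums", {
  aa <- Biostrings::GENETIC_CODE
  sense <- names(aa)[aa != "*"]
  set.seed(42)
  for (i in 1:50) {
    c1 <- paste(sample(sense, 30, TRUE), collapse = "")
    c2 <- paste(sample(sense, 30, TRUE), collapse = "")
    ok <- tryCatch({
      d12 <- ng86_divergence(c(a = c1, b = c2)); TRUE
    }, error = function(e) FALSE)     # skip pairs beyond the JC domain
    if (!ok) next
    d21 <- ng86_divergence(c(a = c2, b = c1))
    expect_equal(d12$dS, d21$dS)
    expect_equal(d12$dN, d21$dN)
    expect_equal(d12$S + d12$N, 3 * 30)
    expect_equal(d12$Sd + d12$Nd,
                 sum(substring(c1, 1:90, 1:90) != substring(c2, 1:90, 1:90)))
  }
})

test_that("every two-difference codon pair splits into exactly 2 changes", {
  aa <- Biostrings::GENETIC_CODE
  sense <- names(aa)[aa != "*"]
  for (c1 in sense) {
    for (c2 in sense) {
      nd <- sum(substring(c1, 1:3, 1:3) != substring(c2, 1:3, 1:3))
      if (nd != 2) next
      cnt <- oracle_pathway_counts(c1, c2)
      expect_equal(sum(cnt), 2)
    }
  }
})

test_that("Jukes-Cantor correction approaches identity at small p", {
  aln <- c(a = strrep("GGT", 10000),
           b = paste0("GGC", strrep("GGT", 9999)))
  d <- ng86_divergence(aln)
  expect_equal(d$pS, 1e-4)
  expect_lt(abs(d$dS / d$pS - 1), 1e-3)
})

test_that("tajima_rrt reproduces the 12-vs-3 replacement test", {
  r <- tajima_rrt(12, 3)
  expect_equal(r$chi_square, 5.4)
  expect_equal(round(r$p_value, 2), 0.02)

  expect_equal(tajima_rrt(5, 5)$chi_square, 0)
  expect_equal(tajima_rrt(5, 5)$p_value, 1)
  expect_equal(tajima_rrt(3, 12)$p_value, tajima_rrt(12, 3)$p_value)

  r0 <- tajima_rrt(0, 0)
  expect_false(r0$informative)
  expect_equal(r0$p_value, 1)

  ## p decreases with |m1 - m2| at fixed total
  ps <- vapply(0:7, function(k) tajima_rrt(7 + k, 7 - k)$p_value, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("lineage_replacements counts per the outgroup condition", {
  aln <- c(s1 = "AAAA", s2 = "ABBB", og = "ABBB")
  lr <- lineage_replacements(aln, "s1", "s2", "og")
  expect_equal(lr$m1, 3)                   # s1 differs while s2 == og
  expect_equal(lr$m2, 0)
  ## seq1 equal to the outgroup, seq2 diverged
  aln2 <- c(s1 = "QQQQ", s2 = "QRRR", og = "QQQQ")
  lr2 <- lineage_replacements(aln2, "s1", "s2", "og")
  expect_equal(lr2$m1, 0)
  expect_equal(lr2$m2, 3)
  ## odd-one-out outgroup and all-different columns count for neither
  aln3 <- c(s1 = "AA", s2 = "AA", og = "AB")
  lr3 <- lineage_replacements(aln3, "s1", "s2", "og")
  expect_equal(lr3$m1 + lr3$m2, 0)
  aln4 <- c(s1 = "AC", s2 = "AD", og = "AE")
  lr4 <- lineage_replacements(aln4, "s1", "s2", "og")
  expect_equal(lr4$m1 + lr4$m2, 0)
  ## all identical
  aln5 <- c(s1 = "AA", s2 = "AA", og = "AA")
  lr5 <- lineage_replacements(aln5, "s1", "s2", "og")
  expect_equal(c(lr5$m1, lr5$m2), c(0, 0))
})

test_that("divergence_time arithmetic and errors", {
  dt <- divergence_time(0.18, mu = 7.31e-9, generation_time = 1.5)
  expect_equal(dt$T_generations, 0.18 / (2 * 7.31e-9))
  expect_equal(round(dt$T_generations / 1e6), 12)
  expect_equal(round(dt$T_years / 1e6), 18)
  expect_equal(dt$T_years / dt$T_generations, 1.5)

  expect_equal(divergence_time(0)$T_generations, 0)
  expect_equal(divergence_time(0.1, mu = 1e-8)$T_generations, 5e6)
  expect_error(divergence_time(0.1, mu = 0), "mu")
})
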