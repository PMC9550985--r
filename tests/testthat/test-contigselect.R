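set.seed(31)
ctg_a <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
ctg_b <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")

test_that("map_reads anchors exact and near-exact reads, both strands", {
  contigs <- c(c1 = ctg_a, c2 = ctg_b)
  read <- substr(ctg_a, 101, 200)
  h <- map_reads(read, contigs)
  expect_equal(h$contig, "c1")
  expect_equal(h$identity, 1)

  ## reverse-complement read maps too
  h <- map_reads(oracle_revcomp(read), contigs)
  expect_equal(h$contig, "c1")

  ## a read from nowhere does not map
  other <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  expect_equal(nrow(map_reads(other, contigs)), 0)

  ## below-identity read (20 complemented bases in 100) is rejected
  bad <- read
  substr(bad, 40, 59) <- chartr("ACGT", "TGCA", substr(bad, 40, 59))
  expect_equal(nrow(map_reads(bad, contigs)), 0)
})

test_that("count_mapped_reads splits ties and records library sizes", {
  contigs <- c(c1 = ctg_a, c2 = ctg_a, c3 = ctg_b)   # c1 == c2
  reads <- data.table::data.table(seq = substr(ctg_a, 51, 150))
  ccm <- count_mapped_reads(list(s = reads), contigs)
  expect_equal(ccm$counts["c1", "s"], 0.5)
  expect_equal(ccm$counts["c2", "s"], 0.5)
  expect_equal(ccm$counts["c3", "s"], 0)
  expect_equal(ccm$library_sizes[["s"]], 1)

  ## unmapped reads are reported
  reads2 <- data.table::data.table(
    seq = c(substr(ctg_b, 1, 100),
            paste(rep("ACGT", 25), collapse = "")))
  ccm2 <- count_mapped_reads(list(s = reads2), contigs)
  expect_equal(ccm2$unmapped[["s"]], 1)

  ## paired reads count once per pair
  pr <- data.table::data.table(seq1 = substr(ctg_b, 1, 100),
                               seq2 = oracle_revcomp(substr(ctg_b, 201, 300)))
  ccm3 <- count_mapped_reads(list(s = pr), contigs)
  expect_equal(sum(ccm3$counts[, "s"]), 1)
})

test_that("normalize_counts scales columns to the male library", {
  ccm <- structure(list(
    counts = matrix(c(10, 20, 4, 10), 2,
                    dimnames = list(c("c1", "c2"), c("male", "female"))),
    library_sizes = c(male = 1000, female = 2000),
    unmapped = c(male = 0, female = 0), normalized = FALSE),
    class = "contig_count_matrix")
  nm <- normalize_counts(ccm, male = "male")
  expect_equal(nm$counts[, "male"], c(c1 = 10, c2 = 20))   # unchanged
  expect_equal(nm$counts[, "female"], c(c1 = 2, c2 = 5))   # halved
  ## column totals scale by exactly the library factor
  expect_equal(sum(nm$counts[, "female"]),
               sum(ccm$counts[, "female"]) * 1000 / 2000)

  ccm$library_sizes["female"] <- 0
  expect_error(normalize_counts(ccm), "library size")

  ## equal library sizes leave the matrix unchanged
  ccm$library_sizes <- c(male = 500, female = 500)
  expect_equal(normalize_counts(ccm)$counts, ccm$counts)
})

test_that("select_ydel_contigs implements the ratio disjunction", {
  mk <- function(male, female, mutant) {
    m <- cbind(male = male, female = female, EGP14 = mutant)
    rownames(m) <- paste0("c", seq_along(male))
    structure(list(counts = m,
                   library_sizes = c(male = 1, female = 1, EGP14 = 1),
                   unmapped = NULL, normalized = TRUE),
              class = "contig_count_matrix")
  }
  ## 5% female ratio: selected; OR branch: 25%/35%: selected;
  ## 50%/50%: rejected; no male coverage: rejected + flagged
  sel <- select_ydel_contigs(mk(c(100, 100, 100, 0),
                                c(5, 25, 50, 10),
                                c(90, 35, 50, 10)))
  expect_setequal(sel$selected, c("c1", "c2"))
  expect_equal(sel$report[contig == "c4", flag], "no_male_coverage")

  ## monotone in both thresholds
  sel2 <- select_ydel_contigs(mk(c(100, 100, 100, 0),
                                 c(5, 25, 50, 10),
                                 c(90, 35, 50, 10)),
                              ratio_filter_params(0.6, 0.6))
  expect_true(all(sel$selected %in% sel2$selected))

  ## unnormalized input is refused
  m <- mk(1, 1, 1); m$normalized <- FALSE
  expect_error(select_ydel_contigs(m), "normalized")
})

test_that("copy-number signal: X contigs ~2x female, Y contigs ~0", {
  cfg <- sim_config(seed = 12, autosome_length = 12000L, x_length = 9000L,
                    y_shared_length = 2000L, y_specific_length = 5000L,
                    deletion_intervals = list(EGP14 = c(500L, 4500L),
                                              R025 = c(1000L, 4000L)),
                    focal_gene = list(start = 1500L, cds_codons = 96L))
  sys <- simulate_system(cfg)
  ## one X-origin contig, one autosome-origin, one Y-specific-origin
  contigs <- c(
    x_ctg = substr(sys$individuals$male$chrX, 4001, 4600),
    a_ctg = substr(sys$individuals$male$chrA_1, 2001, 2600),
    ## a window of the Y-specific region free of planted features
    y_ctg = substr(sys$individuals$male$chrY, 3201 + 2000, 3800 + 2000))
  reads <- list(
    male = simulate_reads(sys$individuals$male, coverage = 30,
                          error_rate = 0, seed = 1, individual = "male"),
    female = simulate_reads(sys$individuals$female, coverage = 30,
                            error_rate = 0, seed = 2, individual = "female"))
  ccm <- normalize_counts(count_mapped_reads(reads, contigs))
  r <- ccm$counts[, "female"] / ccm$counts[, "male"]
  expect_lt(abs(r[["a_ctg"]] - 1), 0.35)
  expect_lt(abs(r[["x_ctg"]] - 2), 0.7)
  expect_equal(r[["y_ctg"]], 0)
})
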