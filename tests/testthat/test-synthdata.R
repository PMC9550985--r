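mini_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    seed = seed,
    autosome_length = 12000L, x_length = 9000L,
    y_shared_length = 2000L, y_specific_length = 5000L,
    deletion_intervals = list(EGP14 = c(500L, 4500L),
                              R025 = c(1000L, 4000L)),
    focal_gene = list(start = 1500L, cds_codons = 96L)), list(...))
  do.call(sim_config, args)
}

test_that("simulate_system is deterministic and honours the deletions", {
  cfg <- mini_cfg(seed = 9)
  s1 <- simulate_system(cfg)
  s2 <- simulate_system(cfg)
  expect_identical(s1$individuals, s2$individuals)
  expect_identical(s1$truth, s2$truth)

  ## structure: female has two X, no Y; male one X and one Y
  expect_true("chrY" %in% names(s1$individuals$male))
  expect_false("chrY" %in% names(s1$individuals$female))
  expect_identical(sum(grepl("^chrX", names(s1$individuals$female))), 2L)

  ## mutant Y = male Y minus the interval
  del <- cfg$deletion_intervals$EGP14 + cfg$y_shared_length
  y <- s1$individuals$male$chrY
  expect_identical(s1$individuals$EGP14$chrY,
                   paste0(substr(y, 1, del[1]),
                          substr(y, del[2] + 1, nchar(y))))

  ## homozygous background by default
  expect_identical(s1$individuals$male$chrA_1, s1$individuals$male$chrA_2)
})

test_that("a covering deletion removes every focal-specific 35-mer", {
  cfg <- mini_cfg(seed = 2)
  sys <- simulate_system(cfg)
  tr <- sys$truth[feature == "focal_y" & individual == "male"]
  focal <- substr(sys$individuals$male$chrY, tr$start + 1, tr$end)
  focal_kmers <- oracle_kmers(focal, k = 35, prefix = "A")
  ## the mutant Y retains no focal 35-mer (the X gametolog may share
  ## conserved windows, so only the Y is enumerated)
  mutant_y_kmers <- oracle_kmers(sys$individuals$EGP14$chrY, 35, "A")
  expect_gt(length(focal_kmers), 0)
  expect_length(intersect(focal_kmers, mutant_y_kmers), 0)
})

test_that("y_specific_length = 0 leaves male and female differing only in X/Y dose", {
  cfg <- sim_config(seed = 3, y_specific_length = 0L,
                    deletion_intervals = list(),
                    autosome_length = 12000L, x_length = 9000L,
                    y_shared_length = 2000L)
  sys <- simulate_system(cfg)
  ## the Y is then just the shared head of the X
  expect_identical(sys$individuals$male$chrY,
                   substr(sys$individuals$male$chrX, 1, 2000))
  expect_false(any(c("focal_y", "te_copy") %in% sys$truth$feature))
})

test_that("deletion intervals must cover the focal gene and stay in range", {
  expect_error(mini_cfg(deletion_intervals = list(EGP14 = c(4000L, 6000L))),
               "within")
  expect_error(mini_cfg(deletion_intervals = list(EGP14 = c(2000L, 4500L),
                                                  R025 = c(1000L, 4000L))),
               "cover the focal gene")
})

test_that("evolve_gametolog_trio degenerate and invalid targets", {
  anc <- random_cds(50, seed = 4)
  zero <- list(x = c(dS = 0, omega = 0), y = c(dS = 0, omega = 0),
               outgroup = c(dS = 0, omega = 0))
  trio <- evolve_gametolog_trio(anc, zero, seed = 1)
  expect_identical(trio$x_cds, anc)
  expect_identical(trio$y_cds, anc)
  expect_identical(trio$outgroup_cds, anc)

  ## omega 0 on a branch keeps the protein identical
  syn_only <- list(x = c(dS = 0.2, omega = 0), y = c(dS = 0, omega = 0),
                   outgroup = c(dS = 0, omega = 0))
  trio <- evolve_gametolog_trio(anc, syn_only, seed = 2)
  expect_false(identical(trio$x_cds, anc))
  tr <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s)))
  expect_identical(tr(trio$x_cds), tr(anc))

  bad <- list(x = c(dS = 50, omega = 1), y = c(dS = 0, omega = 0),
              outgroup = c(dS = 0, omega = 0))
  expect_error(evolve_gametolog_trio(anc, bad, seed = 1), "JC")
})

test_that("gsf preset recovers its divergence targets on long genes", {
  ## 1,200-codon scaled-down check (the acceptance suite runs the full
  ## 3,000-codon x 10-seed version)
  dS <- numeric(3)
  for (s in 1:3) {
    anc <- random_cds(1200, seed = 100 + s)
    trio <- evolve_gametolog_trio(anc, gsf_preset(), seed = 200 + s)
    dS[s] <- ng86_divergence(codon_align(c(x = trio$x_cds,
                                           y = trio$y_cds)))$dS
  }
  expect_lt(abs(mean(dS) - 0.18), 0.03)
})

test_that("simulate_reads: exact substrings without error, count model, determinism", {
  genome <- list(chr1 = random_cds(400, seed = 8))   # 1.2 kb
  reads <- simulate_reads(genome, coverage = 30, read_length = 100,
                          error_rate = 0, insert_mean = 300, insert_sd = 30,
                          seed = 5, individual = "ind")
  expect_equal(nrow(reads), round(30 * 1200 / 200))
  g <- genome$chr1
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(g)))
  for (i in seq_len(nrow(reads))) {
    expect_true(grepl(reads$seq1[i], g, fixed = TRUE) ||
                  grepl(reads$seq1[i], rc, fixed = TRUE))
    expect_true(grepl(reads$seq2[i], g, fixed = TRUE) ||
                  grepl(reads$seq2[i], rc, fixed = TRUE))
  }
  ## truth intervals are real template intervals
  expect_true(all(reads$start >= 0 & reads$end <= nchar(g)))
  expect_true(all(substring(g, reads$start + 1, reads$start + 100) ==
                    reads$seq1))

  r2 <- simulate_reads(genome, coverage = 30, read_length = 100,
                       error_rate = 0, insert_mean = 300, insert_sd = 30,
                       seed = 5, individual = "ind")
  expect_identical(reads, r2)

  expect_error(simulate_reads(list(chr1 = "ACGT"), read_length = 100,
                              seed = 1), "read_length")
})

test_that("simulate_expression_reads follows the design", {
  feats <- c(f1 = random_cds(200, seed = 1), f2 = random_cds(200, seed = 2))
  design <- list(male = c(f1 = 3, f2 = 1), female = c(f2 = 1))
  rs <- simulate_expression_reads(feats, design, n_reads = 4000,
                                  read_length = 75, error_rate = 0, seed = 3)
  ## zero-abundance feature yields no reads
  expect_false(any(rs$female$feature == "f1"))
  ## 3:1 abundance at equal length -> ~3:1 reads (multinomial, 3 sigma)
  n1 <- sum(rs$male$feature == "f1")
  p <- n1 / 4000
  expect_lt(abs(p - 0.75), 3 * sqrt(0.75 * 0.25 / 4000))

  empty <- simulate_expression_reads(feats, list(male = c(f1 = 1)),
                                     n_reads = 0, seed = 1)
  expect_equal(nrow(empty$male), 0)
  expect_error(simulate_expression_reads(feats, list(s = c(f1 = 0)),
                                         n_reads = 10, seed = 1),
               "abundances are 0")
})

test_that("simulate_cross transmits X and autosomal sites correctly", {
  cfg <- mini_cfg(seed = 6)
  cross <- simulate_cross(cfg, seed = 7)
  sex <- attr(cross, "sex")
  expect_equal(sum(sex == "M"), 4)        # study family size
  expect_equal(sum(sex == "F"), 6)
  sons <- names(sex)[sex == "M"]
  daughters <- names(sex)[sex == "F"]
  dt <- as.data.table(cross)
  for (i in which(dt$class == "X")) {
    row <- dt[i]
    mo <- strsplit(row$mother, "/")[[1]][1]
    fa <- row$father
    for (s in sons)
      expect_identical(row[[s]], paste(mo, mo, sep = "/"))
    for (d in daughters)
      expect_identical(row[[d]], paste(sort(c(mo, fa)), collapse = "/"))
  }
  ## autosomal offspring alleles all drawn from the parents
  for (i in which(dt$class == "autosome")) {
    row <- dt[i]
    par <- unique(c(strsplit(row$mother, "/")[[1]],
                    strsplit(row$father, "/")[[1]]))
    for (o in c(sons, daughters))
      expect_true(all(strsplit(row[[o]], "/")[[1]] %in% par))
  }
})

test_that("cross tables round-trip through TSV", {
  cfg <- mini_cfg(seed = 6)
  cross <- simulate_cross(cfg, seed = 7)
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  write_cross_tsv(cross, p)
  back <- read_cross_tsv(p)
  expect_identical(attr(back, "sex"), attr(cross, "sex"))
  expect_equal(as.data.frame(back), as.data.frame(cross))
})
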