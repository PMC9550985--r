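## Synthetic-data generator. Emulates the study system: a near-homozygous
## inbred line with an XY male, an XX female, and hermaphroditic mutants
## whose Y chromosome lost an interval of the Y-specific region; a focal
## X/Y gametolog pair at a target synonymous divergence with lineage-
## specific dN/dS; paired-end DNA reads, per-sample expression read sets,
## and a two-parent sexed cross.

#' Build and validate a simulation configuration
#'
#' Defaults describe the package's standard world: a 200-kb haploid
#' genome (120-kb autosome, 50-kb X, 10-kb Y region shared with the X
#' plus a 20-kb Y-specific region), two deletion mutants whose deletions
#' both cover the focal gene, a 96-codon focal CDS (288 nt), and the
#' `gsf` divergence preset (X:Y synonymous divergence 0.18, X-lineage
#' dN/dS 0.38 and Y-lineage 0.08 against an outgroup at ~93% identity).
#'
#' @param seed master seed; all stage streams derive from it.
#' @param autosome_length,x_length,y_shared_length,y_specific_length
#'   chromosome part lengths in bases.
#' @param deletion_intervals named list of `c(start, end)` half-open
#'   0-based intervals on the Y-specific region, one per mutant.
#' @param focal_gene list with `start` (offset on the Y-specific region)
#'   and `cds_codons` (CDS length in codons, default 96).
#' @param gsf_preset per-branch `(dS, omega)` targets; see [gsf_preset()].
#' @param coverage fold coverage per haplotype copy (a diploid autosome
#'   thus receives twice this depth).
#' @param read_length,error_rate,insert_mean,insert_sd,quality
#'   read-simulation parameters; `quality` is
#'   `list(phred, tail5, tail3, tail_phred)`.
#' @param expression_design named list: sample -> named numeric vector of
#'   relative abundances over transcript features. `NULL` installs the
#'   default five-sample flower-bud design (male, female, three mutants)
#'   in which only the male expresses the focal gene.
#' @param rna_reads,rna_read_length expression read-set parameters.
#' @param cross list with `n_sons`, `n_daughters`, `n_sites`.
#' @param heterozygosity residual per-base heterozygosity of the inbred
#'   background (0 = fully homozygous, the default).
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       autosome_length = 120000L,
                       x_length = 50000L,
                       y_shared_length = 10000L,
                       y_specific_length = 20000L,
                       deletion_intervals = list(EGP14 = c(6000L, 14000L),
                                                 R025  = c(8000L, 12000L)),
                       focal_gene = list(start = 9000L, cds_codons = 96L),
                       gsf_preset = NULL,
                       coverage = 30,
                       read_length = 100L,
                       error_rate = 0.002,
                       insert_mean = 300,
                       insert_sd = 30,
                       quality = list(phred = 35L, tail5 = 3L, tail3 = 3L,
                                      tail_phred = 15L),
                       expression_design = NULL,
                       rna_reads = 20000L,
                       rna_read_length = 75L,
                       cross = list(n_sons = 4L, n_daughters = 6L,
                                    n_sites = 60L),
                       heterozygosity = 0) {
  if (is.null(gsf_preset))
    gsf_preset <- get("gsf_preset", envir = parent.env(environment()),
                      mode = "function")()
  cfg <- list(seed = seed, autosome_length = autosome_length,
              x_length = x_length, y_shared_length = y_shared_length,
              y_specific_length = y_specific_length,
              deletion_intervals = deletion_intervals,
              focal_gene = focal_gene, gsf_preset = gsf_preset,
              coverage = coverage, read_length = read_length,
              error_rate = error_rate, insert_mean = insert_mean,
              insert_sd = insert_sd, quality = quality,
              expression_design = expression_design,
              rna_reads = rna_reads, rna_read_length = rna_read_length,
              cross = cross, heterozygosity = heterozygosity)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  assert_that(cfg$seed >= 0, "seed must be non-negative")
  for (f in c("autosome_length", "x_length", "y_shared_length",
              "y_specific_length"))
    assert_that(cfg[[f]] >= 0, paste(f, "must be non-negative"))
  assert_that(cfg$error_rate >= 0 && cfg$error_rate < 1,
              "error_rate must be in [0, 1)")
  assert_that(cfg$focal_gene$cds_codons %% 1 == 0 &&
                cfg$focal_gene$cds_codons > 0,
              "focal CDS length must be a positive codon count")
  cds_len <- 3L * cfg$focal_gene$cds_codons
  for (nm in names(cfg$deletion_intervals)) {
    iv <- cfg$deletion_intervals[[nm]]
    assert_that(length(iv) == 2L && iv[1L] >= 0 && iv[1L] < iv[2L] &&
                  iv[2L] <= cfg$y_specific_length,
                sprintf("deletion interval of '%s' must lie within [0, y_specific_length)", nm))
  }
  if (cfg$y_specific_length > 0) {
    fg <- c(cfg$focal_gene$start, cfg$focal_gene$start + cds_len)
    assert_that(fg[1L] >= 0 && fg[2L] <= cfg$y_specific_length,
                "focal gene does not fit on the Y-specific region")
    for (nm in names(cfg$deletion_intervals)) {
      iv <- cfg$deletion_intervals[[nm]]
      assert_that(iv[1L] <= fg[1L] && iv[2L] >= fg[2L],
                  sprintf("deletion of '%s' must cover the focal gene", nm))
    }
  }
  assert_that(cfg$heterozygosity >= 0 && cfg$heterozygosity < 1,
              "heterozygosity must be in [0, 1)")
  assert_that(cfg$cross$n_sons + cfg$cross$n_daughters >= 1,
              "cross must have at least one offspring")
  invisible(cfg)
}

#' The gsf divergence preset
#'
#' Per-branch synonymous-divergence and dN/dS targets for the focal
#' gametolog trio, solved once so that the resulting *pairwise* NG86
#' estimates hit the documented targets: X:Y synonymous divergence 0.18
#' (0.09 per branch), X-vs-outgroup dN/dS 0.38, Y-vs-outgroup dN/dS
#' 0.08, and ~93% nucleotide identity between Y and the outgroup (the
#' outgroup branch carries dS 0.136 at dN/dS 0.09). See the methods
#' vignette for the derivation.
#'
#' @return named list of `c(dS, omega)` per branch (`x`, `y`, `outgroup`).
#' @export
gsf_preset <- function() {
  list(x        = c(dS = 0.09,  omega = 0.8182),
       y        = c(dS = 0.09,  omega = 0.0649),
       outgroup = c(dS = 0.136, omega = 0.09))
}

#' Generate a random stop-free CDS
#'
#' @param n_codons CDS length in codons (an ATG start is imposed).
#' @param seed RNG seed.
#' @return nucleotide string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, seed = 1L) {
  with_seed(seed, {
    aa <- codon_aa()
    sense <- names(aa)[aa != "*"]
    paste(c("ATG", sample(sense, n_codons - 1L, replace = TRUE)),
          collapse = "")
  })
}

#' Evolve an X/Y gametolog pair plus outgroup from an ancestral CDS
#'
#' Each branch receives an exact number of synonymous and nonsynonymous
#' single-base changes, placed codon-wise at distinct codons, so that the
#' *expected* NG86 estimates match the branch targets: the change counts
#' are the targets mapped back through the Jukes-Cantor correction
#' (`p = 3/4 (1 - exp(-4 d / 3))`) times the ancestral site counts.
#' Substitutions creating stop codons are rejected.
#'
#' @param ancestor_cds ancestral coding sequence (length divisible by 3,
#'   no internal stops).
#' @param branch_params named list of branch targets `c(dS, omega)` for
#'   `x`, `y` and `outgroup` (see [gsf_preset()]).
#' @param seed RNG seed.
#' @return list with `x_cds`, `y_cds`, `outgroup_cds`, `ancestor_cds`.
#' @export
evolve_gametolog_trio <- function(ancestor_cds,
                                  branch_params = gsf_preset(),
                                  seed = 1L) {
  assert_that(nchar(ancestor_cds) %% 3 == 0,
              "ancestor CDS length must be divisible by 3")
  assert_that(length(internal_stops(ancestor_cds)) == 0,
              "ancestor CDS contains an internal stop codon")
  for (b in branch_params) {
    p_syn <- 0.75 * (1 - exp(-4 * b[["dS"]] / 3))
    p_non <- 0.75 * (1 - exp(-4 * b[["dS"]] * b[["omega"]] / 3))
    assert_that(p_syn < 0.75 && p_non < 0.75,
                "branch target implies p >= 3/4: JC correction undefined")
  }
  with_seed(seed, {
    anc <- split_codons(ancestor_cds)
    list(x_cds = paste(evolve_branch(anc, branch_params$x), collapse = ""),
         y_cds = paste(evolve_branch(anc, branch_params$y), collapse = ""),
         outgroup_cds = paste(evolve_branch(anc, branch_params$outgroup),
                              collapse = ""),
         ancestor_cds = ancestor_cds)
  })
}

#' Place exact syn/nonsyn change counts on one branch (RNG flows from caller)
#' @noRd
evolve_branch <- function(codons, params) {
  dS <- params[["dS"]]; omega <- params[["omega"]]
  if (dS == 0 || length(codons) == 0L) return(codons)
  ss <- syn_sites_table()
  aa <- codon_aa()
  S <- sum(ss[codons]); N <- 3 * length(codons) - S
  p_syn <- 0.75 * (1 - exp(-4 * dS / 3))
  p_non <- 0.75 * (1 - exp(-4 * dS * omega / 3))
  need <- c(S = round(p_syn * S), N = round(p_non * N))
  order <- sample(length(codons))
  types <- sample(rep(c("S", "N"), times = need))
  ti <- 1L
  for (ci in order) {
    if (ti > length(types)) break
    type <- types[ti]
    nb <- codon_neighbours(codons[ci])
    nb <- nb[aa[nb] != "*"]
    nb <- if (type == "S") nb[aa[nb] == aa[codons[ci]]]
    else nb[aa[nb] != aa[codons[ci]]]
    if (!length(nb)) next                 # e.g. ATG/TGG have no syn change
    codons[ci] <- sample(nb, 1L)
    ti <- ti + 1L
  }
  if (ti <= length(types))
    warning("could not place all targeted substitutions (sequence too short)")
  codons
}

#' Simulate the whole study system
#'
#' Generates the male, female and mutant genomes plus the transcript
#' features used by the expression screen. The male carries an autosome
#' pair, one X and one Y (shared region + Y-specific region); the female
#' carries two X copies and no Y; each mutant equals the male with its
#' deletion interval excised from the Y-specific region. Planted
#' features (recorded in `$truth`, 0-based half-open): the focal Y gene
#' and its X gametolog, a transposable-element copy and a diverged
#' autosome-duplicate copy inside the deleted interval, and two autosomal
#' control genes.
#'
#' @param config a [sim_config()].
#' @return `genome_set` list: `individuals` (named lists of haplotype
#'   sequences), `truth` (feature table), `transcripts`, `te_library`,
#'   `cds` (the gametolog trio), `config`.
#' @export
simulate_system <- function(config) {
  validate_sim_config(config)
  cfg <- config
  cds_len <- 3L * cfg$focal_gene$cds_codons

  anc <- random_cds(cfg$focal_gene$cds_codons, derive_seed(cfg$seed, "anc"))
  trio <- evolve_gametolog_trio(anc, cfg$gsf_preset,
                                derive_seed(cfg$seed, "trio"))

  with_seed(derive_seed(cfg$seed, "genome"), {
    autosome <- random_dna(1L, cfg$autosome_length)
    x_chrom <- random_dna(1L, cfg$x_length)
    y_shared <- if (cfg$y_shared_length > 0)
      substr(x_chrom, 1L, min(cfg$y_shared_length, cfg$x_length))
    else ""
    y_spec <- if (cfg$y_specific_length > 0)
      random_dna(1L, cfg$y_specific_length) else ""

    ## autosomal control features are plain substrings of the autosome,
    ## placed at fixed fractions of its length
    assert_that(cfg$autosome_length >= 10000,
                "autosome_length must be at least 10 kb")
    dup_at0 <- as.integer(0.40 * cfg$autosome_length)    # 0-based
    hk_at0 <- as.integer(0.65 * cfg$autosome_length)

    truth <- list()
    plant <- function(seq, insert, at) {       # 0-based position
      stopifnot(at + nchar(insert) <= nchar(seq))
      paste0(substr(seq, 1L, at), insert,
             substr(seq, at + nchar(insert) + 1L, nchar(seq)))
    }

    te_library <- transcripts <- character()
    if (cfg$y_specific_length > 0) {
      ## focal Y gene inside every deletion interval
      fg0 <- cfg$focal_gene$start
      y_spec <- plant(y_spec, trio$y_cds, fg0)
      truth[[length(truth) + 1L]] <- data.table(
        feature = "focal_y", chrom = "chrY",
        start = cfg$y_shared_length + fg0,
        end = cfg$y_shared_length + fg0 + cds_len, strand = "+")

      ## a TE copy and an autosome-duplicate copy, both inside the
      ## intersection of the deletion intervals when it is large enough
      isect <- c(max(vapply(cfg$deletion_intervals, `[`, 0, 1L)),
                 min(vapply(cfg$deletion_intervals, `[`, 0, 2L)))
      te_seq <- random_dna(1L, 600L)
      te_library <- c(te_consensus = te_seq)
      slots <- setdiff_slots(isect, c(fg0, fg0 + cds_len))
      te_at <- place_in_slots(slots, 600L)
      if (!is.na(te_at)) {
        y_spec <- plant(y_spec, te_seq, te_at)
        truth[[length(truth) + 1L]] <- data.table(
          feature = "te_copy", chrom = "chrY",
          start = cfg$y_shared_length + te_at,
          end = cfg$y_shared_length + te_at + 600L, strand = "+")
        slots <- setdiff_slots_multi(slots, c(te_at, te_at + 600L))
      }
      dup_auto <- substr(autosome, dup_at0 + 1L, dup_at0 + 500L)
      dup_y <- mutate_seq(dup_auto, 0.08)
      dup_at <- place_in_slots(slots, 500L)
      if (!is.na(dup_at)) {
        y_spec <- plant(y_spec, dup_y, dup_at)
        truth[[length(truth) + 1L]] <- data.table(
          feature = "dup_copy_y", chrom = "chrY",
          start = cfg$y_shared_length + dup_at,
          end = cfg$y_shared_length + dup_at + 500L, strand = "+")
      }
    }

    ## X gametolog: planted away from the shared head of the X
    x_at <- max(cfg$y_shared_length, 0L) + 5000L
    assert_that(x_at + cds_len <= cfg$x_length,
                "x_length too short to host the X gametolog")
    x_chrom <- plant(x_chrom, trio$x_cds, x_at)
    truth[[length(truth) + 1L]] <- data.table(
      feature = "gsfx", chrom = "chrX", start = x_at,
      end = x_at + cds_len, strand = "+")

    truth[[length(truth) + 1L]] <- data.table(
      feature = "dup_auto", chrom = "chrA", start = dup_at0,
      end = dup_at0 + 500L, strand = "+")
    truth[[length(truth) + 1L]] <- data.table(
      feature = "housekeeping", chrom = "chrA", start = hk_at0,
      end = hk_at0 + 900L, strand = "+")

    y_chrom <- paste0(y_shared, y_spec)

    transcripts <- c(
      focal_y = trio$y_cds,
      gsfx = trio$x_cds,
      dup_auto = substr(autosome, dup_at0 + 1L, dup_at0 + 500L),
      housekeeping = substr(autosome, hk_at0 + 1L, hk_at0 + 900L),
      te_frag = if (length(te_library)) te_library[["te_consensus"]]
      else NULL)

    het <- function(s) if (cfg$heterozygosity > 0)
      mutate_seq(s, cfg$heterozygosity) else s

    male <- list(chrA_1 = autosome, chrA_2 = het(autosome),
                 chrX = x_chrom, chrY = y_chrom)
    female <- list(chrA_1 = autosome, chrA_2 = het(autosome),
                   chrX_1 = x_chrom, chrX_2 = het(x_chrom))
    individuals <- list(male = male, female = female)
    for (nm in names(cfg$deletion_intervals)) {
      iv <- cfg$deletion_intervals[[nm]] + cfg$y_shared_length
      mut <- male
      mut$chrY <- paste0(substr(y_chrom, 1L, iv[1L]),
                         substr(y_chrom, iv[2L] + 1L, nchar(y_chrom)))
      individuals[[nm]] <- mut
    }
  })

  truth <- rbindlist(truth)
  truth <- expand_truth(truth, individuals, cfg)

  structure(list(individuals = individuals, truth = truth,
                 transcripts = transcripts, te_library = te_library,
                 cds = trio, config = cfg),
            class = "genome_set")
}

#' Per-individual truth rows, with chrY coordinates shifted past deletions
#' @noRd
expand_truth <- function(truth, individuals, cfg) {
  if (!nrow(truth)) return(truth)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i]
    for (ind in names(individuals)) {
      haps <- individuals[[ind]]
      if (tr$chrom != "chrY") {
        if (any(grepl(paste0("^", tr$chrom), names(haps))))
          rows[[length(rows) + 1L]] <- data.table(individual = ind, tr)
        next
      }
      if (!"chrY" %in% names(haps)) next
      iv <- cfg$deletion_intervals[[ind]]
      if (is.null(iv)) {
        rows[[length(rows) + 1L]] <- data.table(individual = ind, tr)
        next
      }
      del <- iv + cfg$y_shared_length
      if (overlaps(tr$start, tr$end, del[1L], del[2L])) next   # excised
      shift <- if (tr$start >= del[2L]) del[2L] - del[1L] else 0L
      sh <- copy(tr)
      sh$start <- sh$start - shift; sh$end <- sh$end - shift
      rows[[length(rows) + 1L]] <- data.table(individual = ind, sh)
    }
  }
  rbindlist(rows)
}

#' Mutate a fraction of bases to a random different base
#' @noRd
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  for (p in pos) {
    old <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(BASES, old), 1L)
  }
  seq
}

## -- interval bookkeeping for feature placement -------------------------

#' Free slots of `interval` after removing `used` (both half-open)
#' @noRd
setdiff_slots <- function(interval, used) {
  slots <- list()
  if (used[1L] - interval[1L] > 0)
    slots[[length(slots) + 1L]] <- c(interval[1L], used[1L])
  if (interval[2L] - used[2L] > 0)
    slots[[length(slots) + 1L]] <- c(used[2L], interval[2L])
  slots
}

#' @noRd
setdiff_slots_multi <- function(slots, used) {
  out <- list()
  for (s in slots) {
    if (!overlaps(s[1L], s[2L], used[1L], used[2L])) {
      out[[length(out) + 1L]] <- s
    } else {
      out <- c(out, setdiff_slots(s, c(max(s[1L], used[1L]),
                                       min(s[2L], used[2L]))))
    }
  }
  out
}

#' First slot that fits `len`, with a small margin; NA if none
#' @noRd
place_in_slots <- function(slots, len, margin = 100L) {
  for (s in slots) {
    if (s[2L] - s[1L] >= len + 2L * margin) return(s[1L] + margin)
  }
  NA_integer_
}

## -- read simulation ----------------------------------------------------

#' Simulate paired-end reads with per-base errors and Phred qualities
#'
#' Each haplotype sequence is covered at `coverage` fold, so a diploid
#' chromosome (two listed haplotypes) receives twice that depth; this is
#' what makes X-linked contigs show a female/male mapped ratio of ~2.
#' Read names encode the origin: `individual|chrom|start-end|i` with the
#' 0-based half-open template interval.
#'
#' @param genome a `genome_set` (all individuals) or a named character
#'   vector/list of haplotype sequences for a single individual.
#' @param coverage fold coverage per haplotype copy.
#' @param read_length read length in bases.
#' @param error_rate per-base probability of flipping to a random
#'   different base.
#' @param insert_mean,insert_sd insert-size model (normal, clamped to
#'   `[read_length, haplotype length]`). The study does not state library
#'   insert sizes; these defaults are documented, not calibrated.
#' @param quality list `(phred, tail5, tail3, tail_phred)`: constant
#'   Phred with optionally degraded 5'/3' tails.
#' @param seed RNG seed.
#' @param individual id used in read names when `genome` is a plain
#'   haplotype list.
#' @return data.table: individual, id, chrom, start, end, seq1, qual1,
#'   seq2, qual2.
#' @export
simulate_reads <- function(genome, coverage = 15, read_length = 100L,
                           error_rate = 0.002, insert_mean = 300,
                           insert_sd = 30,
                           quality = list(phred = 35L, tail5 = 0L,
                                          tail3 = 0L, tail_phred = 15L),
                           seed = 1L, individual = "sample") {
  assert_that(coverage > 0, "coverage must be > 0")
  sets <- if (inherits(genome, "genome_set")) genome$individuals
  else setNames(list(as.list(genome)), individual)
  for (ind in names(sets)) {
    lens <- nchar(unlist(sets[[ind]]))
    assert_that(all(read_length <= lens[lens > 0]),
                sprintf("read_length %d exceeds a chromosome of '%s'",
                        read_length, ind))
  }
  qual1 <- make_quality(read_length, quality)
  out <- with_seed(seed, {
    res <- list()
    for (ind in names(sets)) {
      for (chrom in names(sets[[ind]])) {
        s <- sets[[ind]][[chrom]]
        len <- nchar(s)
        if (len == 0L) next
        n_pairs <- round(coverage * len / (2 * read_length))
        if (n_pairs == 0L) next
        ins <- pmin(pmax(round(rnorm(n_pairs, insert_mean, insert_sd)),
                         read_length), len)
        start0 <- floor(runif(n_pairs, 0, len - ins + 1))  # 0-based
        m1 <- stringi::stri_sub(s, start0 + 1L, length = read_length)
        m2 <- revcomp(stringi::stri_sub(s, start0 + ins - read_length + 1L,
                                        length = read_length))
        m1 <- inject_errors(m1, error_rate)
        m2 <- inject_errors(m2, error_rate)
        res[[length(res) + 1L]] <- data.table(
          individual = ind,
          id = sprintf("%s|%s|%d-%d|%d", ind, chrom, start0, start0 + ins,
                       seq_len(n_pairs)),
          chrom = chrom, start = as.integer(start0),
          end = as.integer(start0 + ins),
          seq1 = m1, qual1 = qual1, seq2 = m2, qual2 = qual1)
      }
    }
    rbindlist(res)
  })
  out
}

#' @noRd
make_quality <- function(read_length, quality) {
  q <- rep(quality$phred, read_length)
  t5 <- min(quality$tail5 %||% 0L, read_length)
  t3 <- min(quality$tail3 %||% 0L, read_length)
  if (t5 > 0) q[seq_len(t5)] <- quality$tail_phred
  if (t3 > 0) q[read_length - seq_len(t3) + 1L] <- quality$tail_phred
  phred_to_string(q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate per-sample expression read sets
#'
#' Single-end reads are drawn from transcript features with probability
#' proportional to `abundance x length`; a feature with abundance 0 in a
#' sample yields no reads there.
#'
#' @param features named character vector of feature sequences.
#' @param design named list: sample -> named numeric abundance vector
#'   (names must be features).
#' @param n_reads reads per sample.
#' @param read_length read length (must not exceed the shortest expressed
#'   feature).
#' @param error_rate per-base error probability.
#' @param phred constant base quality.
#' @param seed RNG seed.
#' @return named list of data.tables (id, feature, seq, qual).
#' @export
simulate_expression_reads <- function(features, design, n_reads = 20000L,
                                      read_length = 75L, error_rate = 0.002,
                                      phred = 35L, seed = 1L) {
  assert_that(length(features) > 0, "features must be non-empty")
  qual <- phred_to_string(rep(phred, read_length))
  with_seed(seed, {
    out <- list()
    for (smp in names(design)) {
      ab <- design[[smp]]
      assert_that(all(ab >= 0), "abundances must be non-negative")
      assert_that(all(names(ab) %in% names(features)),
                  sprintf("unknown feature in design of sample '%s'", smp))
      w <- ab * nchar(features[names(ab)])
      assert_that(sum(w) > 0,
                  sprintf("all abundances are 0 in sample '%s'", smp))
      expressed <- names(w)[w > 0]
      assert_that(all(read_length <= nchar(features[expressed])),
                  "read_length exceeds an expressed feature")
      if (n_reads == 0L) {
        out[[smp]] <- data.table(id = character(), feature = character(),
                                 seq = character(), qual = character())
        next
      }
      feat <- sample(names(w), n_reads, replace = TRUE, prob = w / sum(w))
      len <- nchar(features[feat])
      start0 <- floor(runif(n_reads, 0, len - read_length + 1))
      sq <- stringi::stri_sub(features[feat], start0 + 1L,
                              length = read_length)
      rc <- runif(n_reads) < 0.5
      sq[rc] <- revcomp(sq[rc])
      sq <- inject_errors(sq, error_rate)
      out[[smp]] <- data.table(
        id = sprintf("%s|%s|%d-%d|%d", smp, feat, start0,
                     start0 + read_length, seq_len(n_reads)),
        feature = feat, seq = sq, qual = qual)
    }
    out
  })
}

#' Simulate a two-parent cross with sexed offspring
#'
#' X-linked sites follow X transmission (sons hemizygous for a maternal
#' allele, daughters maternal + paternal); autosomal sites follow
#' Mendelian biallelic transmission. The inbred background makes the
#' mother homozygous at every site. Family size defaults to the study
#' design of 4 sons and 6 daughters.
#'
#' @param config a [sim_config()] (only the `cross` block is used).
#' @param seed RNG seed.
#' @return `cross_genotypes`: data.table of sites (mother, father, one
#'   column per offspring, `class` = truth site class) with attribute
#'   `sex` naming each offspring's sex. Sons' X genotypes are reported
#'   homozygous, as a diploid caller would.
#' @export
simulate_cross <- function(config, seed = 1L) {
  cr <- config$cross
  n_off <- cr$n_sons + cr$n_daughters
  assert_that(n_off >= 1, "cross must have at least one offspring")
  offspring <- c(if (cr$n_sons > 0) paste0("son_", seq_len(cr$n_sons)),
                 if (cr$n_daughters > 0)
                   paste0("daughter_", seq_len(cr$n_daughters)))
  sex <- setNames(rep(c("M", "F"), c(cr$n_sons, cr$n_daughters)), offspring)
  n_x <- ceiling(cr$n_sites / 2); n_a <- cr$n_sites - n_x
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(cr$n_sites)) {
      cls <- if (i <= n_x) "X" else "autosome"
      a <- sample(BASES, 2L)
      m_allele <- a[1L]
      f_allele <- if (runif(1) < 0.8) a[2L] else a[1L]  # mostly informative
      mother <- paste(m_allele, m_allele, sep = "/")
      if (cls == "X") {
        father <- f_allele                       # hemizygous call
        gts <- vapply(offspring, function(o) {
          if (sex[o] == "M") paste(m_allele, m_allele, sep = "/")
          else paste(sort(c(m_allele, f_allele)), collapse = "/")
        }, character(1))
      } else {
        father <- paste(sort(c(sample(c(m_allele, f_allele), 1L), f_allele)),
                        collapse = "/")
        fa <- strsplit(father, "/")[[1L]]
        gts <- vapply(offspring, function(o)
          paste(sort(c(m_allele, sample(fa, 1L))), collapse = "/"),
          character(1))
      }
      rows[[i]] <- c(list(site_id = sprintf("site_%03d", i), class = cls,
                          mother = mother, father = father), as.list(gts))
    }
    dt <- rbindlist(rows)
    structure(dt, class = c("cross_genotypes", class(dt)), sex = sex)
  })
}

#' Write cross genotypes as TSV (sex header line + one row per site)
#' @param cross a `cross_genotypes` table.
#' @param path output path.
#' @export
write_cross_tsv <- function(cross, path) {
  sex <- attr(cross, "sex")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#sex\t", paste(names(sex), sex, sep = "=",
                                    collapse = "\t")), con)
  writeLines(paste(names(cross), collapse = "\t"), con)
  writeLines(do.call(paste, c(as.list(cross), sep = "\t")), con)
  invisible(path)
}

#' Read cross genotypes written by [write_cross_tsv()]
#' @param path input path.
#' @export
read_cross_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- strsplit(sub("^#sex\t", "", hdr), "\t")[[1L]]
  parts <- do.call(rbind, strsplit(kv, "=", fixed = TRUE))
  sex <- setNames(parts[, 2L], parts[, 1L])
  dt <- fread(path, skip = 1L, header = TRUE, colClasses = "character")
  structure(dt, class = c("cross_genotypes", class(dt)), sex = sex)
}
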