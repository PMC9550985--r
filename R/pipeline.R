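## Orchestration: generate an on-disk fixture and run the end-to-end
## flow (trim -> k-mer subtraction -> retention -> assembly -> ratio
## filter -> homology/expression screen -> segregation -> molecular
## evolution), persisting intermediates and emitting a run report.

#' Fixture presets
#'
#' `gsf-default` is the standard world: a 200-kb haploid genome at 15x
#' per haplotype copy (30x on the diploid autosome). `gsf-mini` is a
#' quarter-scale version used by the unit tests.
#' @noRd
fixture_presets <- function() {
  list(
    "gsf-default" = function(seed) sim_config(seed = seed),
    "gsf-mini" = function(seed) sim_config(
      seed = seed,
      autosome_length = 30000L, x_length = 15000L,
      y_shared_length = 3000L, y_specific_length = 6000L,
      deletion_intervals = list(EGP14 = c(1000L, 5500L),
                                R025 = c(1500L, 5000L)),
      focal_gene = list(start = 2000L, cds_codons = 96L),
      rna_reads = 6000L)
  )
}

#' Default five-sample flower-bud expression design
#'
#' Only the male expresses the focal Y gene; the dysfunctional X
#' gametolog is silent in early flower buds of both sexes (it is a
#' transcriptome entry with zero bud abundance); the autosome-duplicate
#' and housekeeping genes are on everywhere; the TE fragment is
#' male-only (its genomic copy sits in the deleted interval).
#' @noRd
default_expression_design <- function(features) {
  base <- c(housekeeping = 500, dup_auto = 300)
  has_te <- "te_frag" %in% names(features)
  male <- c(focal_y = 200, base, if (has_te) c(te_frag = 150))
  list(male = male, female = base,
       R025 = base, EGP14 = base, EGP15 = base)
}

#' Write a complete runnable input bundle for a preset
#'
#' Produces, under `out_dir`: per-genotype paired DNA FASTQ, per-sample
#' RNA FASTQ, transcript and TE FASTA, the gametolog CDS trio, the truth
#' BED, the cross TSV, and `manifest.json` describing the bundle. The
#' returned object is the run configuration consumed by [run_all()].
#'
#' @param preset preset name (see `Details`).
#' @param seed master seed.
#' @param out_dir output directory (created).
#' @return invisibly, the `run_config` list.
#' @export
make_fixture <- function(preset = "gsf-default", seed = 1L, out_dir) {
  presets <- fixture_presets()
  if (!preset %in% names(presets))
    stop(sprintf("unknown preset '%s'; available: %s", preset,
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- presets[[preset]](seed)
  sys <- simulate_system(cfg)

  dna_paths <- list()
  for (ind in names(sys$individuals)) {
    reads <- simulate_reads(
      setNames(unlist(sys$individuals[[ind]]), names(sys$individuals[[ind]])),
      coverage = cfg$coverage, read_length = cfg$read_length,
      error_rate = cfg$error_rate, insert_mean = cfg$insert_mean,
      insert_sd = cfg$insert_sd, quality = cfg$quality,
      seed = derive_seed(cfg$seed, paste0("dna_", ind)), individual = ind)
    prefix <- file.path(out_dir, paste0("dna_", ind))
    write_fastq_pairs(reads, prefix)
    dna_paths[[ind]] <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  }

  design <- cfg$expression_design %||%
    default_expression_design(sys$transcripts)
  rna <- simulate_expression_reads(
    sys$transcripts, design, n_reads = cfg$rna_reads,
    read_length = cfg$rna_read_length, error_rate = cfg$error_rate,
    seed = derive_seed(cfg$seed, "rna"))
  rna_paths <- list()
  for (smp in names(rna)) {
    p <- file.path(out_dir, paste0("rna_", smp, ".fastq"))
    write_fastq(rna[[smp]]$id, rna[[smp]]$seq, rna[[smp]]$qual, p)
    rna_paths[[smp]] <- p
  }

  write_fasta(sys$transcripts, file.path(out_dir, "transcripts.fa"))
  write_fasta(sys$te_library, file.path(out_dir, "te_library.fa"))
  write_fasta(c(gsfy = sys$cds$y_cds, gsfx = sys$cds$x_cds,
                outgroup = sys$cds$outgroup_cds),
              file.path(out_dir, "gametolog_cds.fa"))
  write_bed(sys$truth, file.path(out_dir, "truth.bed"))
  cross <- simulate_cross(cfg, derive_seed(cfg$seed, "cross"))
  write_cross_tsv(cross, file.path(out_dir, "cross.tsv"))

  config <- list(
    preset = preset, seed = seed, out_dir = out_dir,
    dna = dna_paths, rna = rna_paths,
    transcripts = file.path(out_dir, "transcripts.fa"),
    te_library = file.path(out_dir, "te_library.fa"),
    cds = file.path(out_dir, "gametolog_cds.fa"),
    cross = file.path(out_dir, "cross.tsv"),
    truth = file.path(out_dir, "truth.bed"),
    male = "male", female = "female", ratio_mutant = "EGP14",
    params = list(trim = unclass(trim_params()),
                  subtraction = subtraction_params(),
                  kmer = list(k = 35L, prefix = "A"),
                  assembly = list(k = 31L, min_support = 2L),
                  mapper = list(seed_len = 21L, min_identity = 0.9,
                                min_coverage = 0.9),
                  ratio = ratio_filter_params(),
                  expr = list(filter = candidate_filter_params(),
                              evalue_max = 1e-7, reassign = TRUE),
                  molevo = list(mu = 7.31e-9, generation_time = 1.5)),
    stages = list(trim = TRUE, subtract = TRUE, assemble = TRUE,
                  select = TRUE, expression = TRUE, segregate = TRUE,
                  molevo = TRUE))
  jsonlite::write_json(config, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config)
}

#' Run the full pipeline
#'
#' Executes the stages in order, persisting intermediates under
#' `config$out_dir` and aborting with the stage name on error. Full
#' per-sample k-mer tables are summarized rather than serialized (they
#' dwarf every other intermediate); the male-specific set is written in
#' full.
#'
#' @param config a run configuration from [make_fixture()] (or the
#'   parsed `manifest.json`).
#' @return `run_report` list of per-stage records.
#' @export
run_all <- function(config) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, preset = config$preset)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  p <- config$params
  on <- function(s) isTRUE(config$stages[[s]])

  ## -- trim -------------------------------------------------------------
  dna <- stage("trim", {
    lapply(config$dna, function(paths) {
      pr <- read_fastq_pairs(paths[1L], paths[2L])
      if (on("trim")) trim_pairs(pr, p$trim) else list(pairs = pr,
                                                       report = NULL)
    })
  })
  report$trim <- lapply(dna, `[[`, "report")
  dna <- lapply(dna, `[[`, "pairs")

  contigs <- NULL
  if (on("subtract")) {
    ## -- k-mer subtraction ---------------------------------------------
    kmers <- stage("kmers", {
      lapply(names(dna), function(smp)
        extract_kmers(c(dna[[smp]]$seq1, dna[[smp]]$seq2),
                      k = p$kmer$k, prefix = p$kmer$prefix,
                      sample_id = smp))
    })
    names(kmers) <- names(dna)
    male <- config$male
    ms <- stage("subtract",
                male_specific_kmers(kmers[[male]],
                                    kmers[names(kmers) != male],
                                    p$subtraction))
    writeLines(ms, file.path(out_dir, "male_specific_kmers.txt"))
    report$kmers <- list(
      table_sizes = lapply(kmers, nrow),
      male_specific = length(ms))

    ## -- retention + assembly ------------------------------------------
    retained <- stage("retain",
                      retain_read_pairs(dna[[male]], ms,
                                        prefix = p$kmer$prefix))
    write_fastq_pairs(retained, file.path(out_dir, "retained"))
    report$retained <- list(pairs = nrow(retained),
                            of = nrow(dna[[male]]))

    contigs_dt <- if (on("assemble"))
      stage("assemble",
            assemble_contigs(c(retained$seq1, retained$seq2),
                             assembly_k = p$assembly$k,
                             min_support = p$assembly$min_support))
    else NULL
    if (!is.null(contigs_dt)) {
      contigs <- setNames(contigs_dt$sequence, contigs_dt$id)
      write_fasta(contigs, file.path(out_dir, "contigs.fa"))
      report$assembly <- list(contigs = length(contigs),
                              total_bases = sum(nchar(contigs)))
    }
  }

  ## -- ratio selection --------------------------------------------------
  selected <- NULL
  if (on("select") && !is.null(contigs) && length(contigs)) {
    sel <- stage("select", {
      ccm <- count_mapped_reads(dna, contigs,
                                seed_len = p$mapper$seed_len,
                                min_identity = p$mapper$min_identity,
                                min_coverage = p$mapper$min_coverage)
      ccm <- normalize_counts(ccm, male = config$male)
      select_ydel_contigs(ccm, p$ratio, male = config$male,
                          female = config$female,
                          mutant = config$ratio_mutant)
    })
    fwrite(sel$report, file.path(out_dir, "contig_ratios.tsv"), sep = "\t")
    selected <- contigs[sel$selected]
    write_fasta(selected, file.path(out_dir, "ydel_contigs.fa"))
    report$selection <- list(selected = length(selected),
                             of = length(contigs))
  }

  ## -- homology / expression screen ------------------------------------
  if (on("expression") && !is.null(selected) && length(selected)) {
    screen <- stage("screen", {
      transcripts <- read_fasta(config$transcripts)
      te_lib <- tryCatch(read_fasta(config$te_library),
                         error = function(e) character())
      hits <- local_homology_search(transcripts, selected,
                                    evalue_max = p$expr$evalue_max)
      expressed <- transcripts[names(transcripts) %in% unique(hits$qid)]
      rna <- lapply(config$rna, read_fastq)
      em <- quantify(rna, expressed,
                     reassign = isTRUE(p$expr$reassign),
                     seed_len = p$mapper$seed_len,
                     min_identity = p$mapper$min_identity,
                     min_coverage = p$mapper$min_coverage)
      kept <- te_filter(expressed, te_lib,
                        evalue_max = p$expr$evalue_max)
      silent <- setdiff(names(config$rna), config$male)
      cand <- candidate_filter(em, config$male, silent, p$expr$filter)
      cand <- intersect(cand, names(kept))
      list(hits = hits, expressed = expressed, em = em,
           te_removed = attr(kept, "removed"), candidates = cand)
    })
    fwrite(screen$hits, file.path(out_dir, "ydel_hits.tsv"), sep = "\t")
    fwrite(data.table(fragment = rownames(screen$em$tpm), screen$em$tpm),
           file.path(out_dir, "expression_tpm.tsv"), sep = "\t")
    writeLines(screen$candidates, file.path(out_dir, "candidates.txt"))
    report$screen <- list(
      expressed_ydel_fragments = length(screen$expressed),
      te_removed = screen$te_removed,
      candidates = screen$candidates)
  } else if (on("expression")) {
    report$screen <- list(skipped = "no selected contigs")
  } else {
    report$screen <- list(skipped = "stage disabled",
                          candidates = NULL)
  }

  ## -- segregation ------------------------------------------------------
  if (on("segregate")) {
    seg <- stage("segregate", {
      cross <- read_cross_tsv(config$cross)
      sex <- attr(cross, "sex")
      ## sites are grouped into loci by their (truth) class: the X-linked
      ## sites are the focal locus, autosomal sites the control locus
      split_cross <- function(cls) {
        sub <- as.data.table(cross)[class == cls][, class := NULL]
        structure(sub, class = c("cross_genotypes", class(sub)), sex = sex)
      }
      focal <- classify_sites(split_cross("X"))
      control <- if (any(cross$class == "autosome"))
        classify_sites(split_cross("autosome")) else NULL
      list(focal = focal, control = control)
    })
    fwrite(seg$focal$sites, file.path(out_dir, "xlinkage_sites.tsv"),
           sep = "\t")
    report$segregation <- list(
      verdict = seg$focal$verdict,
      n_informative = seg$focal$n_informative,
      n_consistent = seg$focal$n_consistent,
      control_verdict = if (!is.null(seg$control)) seg$control$verdict)
  }

  ## -- molecular evolution ---------------------------------------------
  if (on("molevo")) {
    mol <- stage("molevo", {
      cds <- read_fasta(config$cds)
      aln_xy <- codon_align(cds[c("gsfx", "gsfy")])
      div_xy <- ng86_divergence(aln_xy)
      div_xo <- ng86_divergence(codon_align(cds[c("gsfx", "outgroup")]))
      div_yo <- ng86_divergence(codon_align(cds[c("gsfy", "outgroup")]))
      aln3 <- codon_align(cds[c("gsfx", "gsfy", "outgroup")])
      lr <- lineage_replacements(aln3, "gsfx", "gsfy", "outgroup")
      rrt <- tajima_rrt(lr$m1, lr$m2)
      dt <- divergence_time(div_xy$dS, mu = p$molevo$mu,
                            generation_time = p$molevo$generation_time)
      list(dS_xy = div_xy$dS, dN_xy = div_xy$dN,
           omega_x_outgroup = div_xo$omega,
           omega_y_outgroup = div_yo$omega,
           m1 = lr$m1, m2 = lr$m2, chi_square = rrt$chi_square,
           p_value = rrt$p_value,
           T_generations = dt$T_generations, T_years = dt$T_years)
    })
    report$molevo <- mol
  }

  report <- structure(report, class = "run_report")
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  write_report_md(report, file.path(out_dir, "report.md"))
  report
}

#' @noRd
write_report_md <- function(report, path) {
  ln <- c("# ydelscan run report", "",
          sprintf("- preset: %s, seed: %s", report$preset, report$seed))
  if (!is.null(report$retained))
    ln <- c(ln, sprintf("- retained pairs: %d of %d",
                        report$retained$pairs, report$retained$of))
  if (!is.null(report$assembly))
    ln <- c(ln, sprintf("- contigs: %d (%d bases)",
                        report$assembly$contigs, report$assembly$total_bases))
  if (!is.null(report$selection))
    ln <- c(ln, sprintf("- Ydel contigs selected: %d of %d",
                        report$selection$selected, report$selection$of))
  if (!is.null(report$screen$candidates))
    ln <- c(ln, sprintf("- candidates: %s",
                        paste(report$screen$candidates, collapse = ", ")))
  if (!is.null(report$segregation))
    ln <- c(ln, sprintf("- X-linkage verdict: %s",
                        report$segregation$verdict))
  if (!is.null(report$molevo))
    ln <- c(ln, sprintf(
      "- dS(x:y) = %.3f; omega X/outgroup = %.2f, Y/outgroup = %.2f; RRT m1=%d m2=%d P=%.3g; T ~ %.2g generations (%.1f My)",
      report$molevo$dS_xy, report$molevo$omega_x_outgroup,
      report$molevo$omega_y_outgroup, report$molevo$m1, report$molevo$m2,
      report$molevo$p_value, report$molevo$T_generations,
      report$molevo$T_years / 1e6))
  writeLines(ln, path)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(paste(capture_md(x), collapse = "\n"), "\n")
  invisible(x)
}

#' @noRd
capture_md <- function(report) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_report_md(report, tmp)
  readLines(tmp)
}
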