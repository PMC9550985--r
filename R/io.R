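## Plain-text file formats used across the pipeline. FASTA goes through
## Biostrings; FASTQ is written/read as 4-line Phred+33 records over R
## connections (gzip-transparent), since qualities travel as plain
## strings inside the package.

#' Write named sequences to FASTA
#' @param seqs named character vector of nucleotide sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path input path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write reads to FASTQ (Phred+33)
#' @param ids,seqs,quals parallel character vectors.
#' @param path output path (".gz" suffix compresses).
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  assert_that(length(ids) == length(seqs) && length(seqs) == length(quals),
              "ids, seqs and quals must have equal length")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(ids))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  invisible(path)
}

#' Read FASTQ into a data.table (id, seq, qual)
#' @param path input path (gzip transparent).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  assert_that(length(lines) %% 4 == 0, "truncated FASTQ record")
  if (!length(lines))
    return(data.table(id = character(), seq = character(), qual = character()))
  ids <- sub("^@", "", lines[seq(1L, length(lines), 4L)])
  ids <- sub("\\s.*$", "", ids)
  data.table(id = ids,
             seq = lines[seq(2L, length(lines), 4L)],
             qual = lines[seq(4L, length(lines), 4L)])
}

#' Read a pair of FASTQ files into a paired-read table
#' @param path1,path2 mate FASTQ paths.
#' @export
read_fastq_pairs <- function(path1, path2) {
  m1 <- read_fastq(path1); m2 <- read_fastq(path2)
  assert_that(nrow(m1) == nrow(m2), "mate files differ in record count")
  data.table(id = sub("/[12]$", "", m1$id),
             seq1 = m1$seq, qual1 = m1$qual,
             seq2 = m2$seq, qual2 = m2$qual)
}

#' Write a paired-read table to two FASTQ files
#' @param pairs data.table with id, seq1, qual1, seq2, qual2.
#' @param prefix path prefix; writes `<prefix>_1.fastq` and `<prefix>_2.fastq`.
#' @export
write_fastq_pairs <- function(pairs, prefix) {
  p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
  write_fastq(paste0(pairs$id, "/1"), pairs$seq1, pairs$qual1, p1)
  write_fastq(paste0(pairs$id, "/2"), pairs$seq2, pairs$qual2, p2)
  invisible(c(p1, p2))
}

#' Write truth intervals as BED (0-based, half-open)
#' @param truth data.table with chrom, start, end, feature, strand (and
#'   optionally individual, appended to the name field).
#' @param path output path.
#' @export
write_bed <- function(truth, path) {
  name <- if ("individual" %in% names(truth))
    paste(truth$feature, truth$individual, sep = "|") else truth$feature
  bed <- data.table(chrom = truth$chrom, start = truth$start, end = truth$end,
                    name = name, score = 0L, strand = truth$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file written by [write_bed()]
#' @param path input path.
#' @export
read_bed <- function(path) {
  bed <- fread(path, header = FALSE,
               col.names = c("chrom", "start", "end", "name", "score", "strand"))
  parts <- tstrsplit(bed$name, "|", fixed = TRUE)
  out <- data.table(feature = parts[[1L]],
                    individual = if (length(parts) > 1L) parts[[2L]] else NA,
                    chrom = bed$chrom, start = bed$start, end = bed$end,
                    strand = bed$strand)
  out
}

#' Serialize a k-mer count table as sorted two-column TSV
#'
#' A single comment header records k, prefix and sample id.
#' @param tab a `kmer_count_table` from [extract_kmers()].
#' @param path output path.
#' @export
write_kmer_table <- function(tab, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("#k=%d\tprefix=%s\tsample=%s",
                     attr(tab, "k"), attr(tab, "prefix"),
                     attr(tab, "sample_id")), con)
  dt <- as.data.table(tab)[order(kmer)]
  if (nrow(dt)) writeLines(paste(dt$kmer, dt$count, sep = "\t"), con)
  invisible(path)
}

#' Read a k-mer count table written by [write_kmer_table()]
#' @param path input path.
#' @export
read_kmer_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- strsplit(sub("^#", "", hdr), "\t")[[1L]]
  kv <- do.call(rbind, strsplit(meta, "=", fixed = TRUE))
  meta <- setNames(kv[, 2L], kv[, 1L])
  dt <- fread(path, skip = 1L, header = FALSE, col.names = c("kmer", "count"))
  new_kmer_table(dt, k = as.integer(meta[["k"]]), prefix = meta[["prefix"]],
                 sample_id = meta[["sample"]])
}
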