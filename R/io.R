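#' @title Standard-format input/output
#' @description FASTA via Biostrings, BED/GFF3 via rtracklayer (both
#'   normalised to 0-based half-open coordinates internally), FASTQ with
#'   Phred+33 validation, and header-row TSV tables.
#' @name formats
NULL

#' Write gene sequences to FASTA
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read gene sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))
  stats::setNames(as.character(s), names(s))
}

#' Write reads to FASTQ (Phred+33, constant quality)
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @param quality_char Quality character applied to every base
#'   (default `"I"`, Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  lines <- as.vector(rbind(paste0("@", ids), unname(reads), "+",
                           strrep(quality_char, nchar(reads))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file with validation
#'
#' Malformed records (bad header/separator lines, quality/sequence
#' length mismatch, quality characters outside the Phred+33 printable
#' range `!`..`~`) are rejected with the offending line number.
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ: line count ", length(lines),
         " is not a multiple of 4")
  n <- length(lines) / 4
  i1 <- seq(1, by = 4, length.out = n)
  bad <- which(!startsWith(lines[i1], "@"))
  if (length(bad))
    stop("malformed FASTQ header at line ", i1[bad[1]])
  bad <- which(!startsWith(lines[i1 + 2], "+"))
  if (length(bad))
    stop("malformed FASTQ separator at line ", i1[bad[1]] + 2)
  seqs <- lines[i1 + 1]
  quals <- lines[i1 + 3]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("quality length differs from sequence length at line ",
         i1[bad[1]] + 3)
  bad <- which(grepl("[^!-~]", quals))
  if (length(bad))
    stop("non-Phred+33 quality character at line ", i1[bad[1]] + 3)
  stats::setNames(seqs, sub("\\s.*$", "", substring(lines[i1], 2)))
}

#' Read gene positions from BED or GFF3
#'
#' Both dialects are normalised to the package's internal convention:
#' 0-based half-open `[start, end)`. BED is already 0-based half-open;
#' GFF3's 1-based inclusive `[start, end]` becomes `[start - 1, end)`.
#' Format is chosen by file extension (`.bed` vs `.gff`/`.gff3`).
#'
#' @param path Path to a BED (>= 4 columns) or GFF3 file (gene ids taken
#'   from the `ID` or `Name` attribute).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
read_gene_positions <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- if (!is.null(gr$name)) gr$name else
      sprintf("gene%06d", seq_along(gr))
  } else if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      as.character(gr$Name)
  } else stop("unsupported positions format: .", ext)
  # GRanges is 1-based inclusive regardless of source dialect
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write gene positions as 6-column BED
#'
#' @param positions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), `gene_id`, optional `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(positions, path) {
  strand <- if ("strand" %in% names(positions)) positions$strand else "+"
  strand[!strand %in% c("+", "-")] <- "."
  df <- data.frame(positions$chrom, positions$start, positions$end,
                   positions$gene_id, 0L, strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write / read a TSV table with a header row
#'
#' @param x data.frame.
#' @param path File path.
#' @return `write_tsv`: `path` invisibly; `read_tsv`: data.frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
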