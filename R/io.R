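# Standard-format I/O. FASTA/FASTQ go through Biostrings; gene/repeat
# interval annotation accepts data.frames directly or GFF3/BED files via
# rtracklayer when installed.

#' Read a FASTQ file (Sanger Phred+33)
#'
#' @param path FASTQ file path.
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  validate_fastq(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) diagnose_fastq(path, conditionMessage(e)))
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

diagnose_fastq <- function(path, msg) {
  validate_fastq(path, context = msg)
  stopf("malformed FASTQ '%s': %s", path, msg)
}

# structural check of a 4-line-record FASTQ; errors name the first bad
# record (Biostrings itself accepts some malformed quality lines)
validate_fastq <- function(path, context = NULL) {
  lines <- readLines(path, warn = FALSE)
  suffix <- if (is.null(context)) "" else paste0(" (", context, ")")
  if (length(lines) %% 4 != 0) {
    stopf("malformed FASTQ '%s': %d lines is not a multiple of 4%s",
          path, length(lines), suffix)
  }
  ids <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(ids, "@") | nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stopf("malformed FASTQ '%s': record %d ('%s') is invalid%s",
          path, bad[1], sub("^@", "", ids[bad[1]]), suffix)
  }
  invisible(path)
}

#' Write reads to FASTQ (Sanger Phred+33)
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  out <- as.vector(rbind(paste0("@", reads$id), reads$seq,
                         "+", reads$qual))
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(norm_dna(seqs)), path)
  invisible(path)
}

#' Read gene/repeat interval annotation
#'
#' Accepts a data.frame (columns `chrom`, `start`, `end`, `strand`, `type`;
#' 0-based half-open) and returns it unchanged, or imports a GFF3/BED file
#' via rtracklayer and converts to that layout.
#'
#' @param x data.frame or file path.
#' @return annotation data.frame with 0-based half-open intervals.
#' @export
read_annotation <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end", "strand", "type") %in% names(x)))
    return(x)
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stopf("reading annotation files requires the rtracklayer package")
  }
  g <- rtracklayer::import(x)
  data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g) - 1L,
             end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             type = if (!is.null(g$type)) as.character(g$type) else "feature",
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
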