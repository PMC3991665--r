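# Seven-step elimination cascade for raw small-RNA reads.
#
# Each raw read is assigned exactly one fate: the first rule it fails, or
# "clean". The cascade order is: (1) low quality, (2) 5' adapter
# contamination, (3) missing 3' adapter (trimmed from survivors),
# (4) empty insert, (5) polyA insert, (6) insert length outside the
# 18--30 nt analysis window. Step (7), the length distribution summary, is
# part of the cleaning report.

#' Read-cleaning options
#'
#' The source protocol defines neither "low quality" nor "polyA"
#' operationally, so both are explicit knobs: a read is low-quality when
#' more than `max_low_frac` of its bases fall below Phred `quality_floor`;
#' an insert is polyA when at least `polya_frac` of its bases are A or it
#' contains a run of `polya_run` A's. The 3' adapter is located by the
#' leftmost occurrence of its first `adapter3_seed` bases allowing
#' `adapter3_seed_mm` mismatches (one per 10 nt); 5' adapter contamination
#' is an exact match of any 5'-adapter suffix of at least `min_overlap5` nt
#' at the read start.
#'
#' @param ... overrides for individual options.
#' @return named list of cleaning options.
#' @export
clean_opts <- function(...) {
  o <- list(quality_floor = 10L, max_low_frac = 0.2,
            min_overlap5 = 10L, adapter3_seed = 10L, adapter3_seed_mm = 1L,
            polya_frac = 0.8, polya_run = 10L,
            min_len = 18L, max_len = 30L)
  over <- list(...)
  bad <- setdiff(names(over), names(o))
  if (length(bad)) stopf("clean_opts: unknown option(s): %s",
                         paste(bad, collapse = ", "))
  o[names(over)] <- over
  o
}

READ_FATES <- c("clean", "low_quality", "adapter5_contaminant",
                "no_3p_adapter", "no_insert", "polyA", "length_out_of_range")

# fraction of bases below the Phred floor, per read (Sanger Phred+33)
low_quality_fraction <- function(quals, floor) {
  vapply(quals, function(q) {
    if (!nzchar(q)) return(1)
    mean(utf8ToInt(q) - 33L < floor)
  }, numeric(1), USE.NAMES = FALSE)
}

# TRUE where the read starts with a 5'-adapter suffix of >= min_overlap nt
detect_adapter5 <- function(seqs, adapter5, min_overlap) {
  n <- nchar(adapter5)
  if (n < min_overlap) return(rep(FALSE, length(seqs)))
  hit <- rep(FALSE, length(seqs))
  for (k in min_overlap:n) {
    hit <- hit | startsWith(seqs, substr(adapter5, n - k + 1L, n))
  }
  hit
}

# leftmost start of the 3'-adapter seed in each read (NA when absent)
find_adapter3 <- function(seqs, adapter3, seed_len, seed_mm) {
  seed <- substr(adapter3, 1L, min(seed_len, nchar(adapter3)))
  subj <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::vmatchPattern(seed, subj, max.mismatch = seed_mm)
  starts <- S4Vectors::elementNROWS(m)
  pos <- rep(NA_integer_, length(seqs))
  has <- starts > 0
  if (any(has)) {
    pos[has] <- vapply(IRanges::start(m)[has], min, integer(1))
  }
  pos
}

is_polya <- function(seqs, frac, run) {
  n <- nchar(seqs)
  a <- nchar(gsub("[^A]", "", seqs))
  (n > 0 & a / pmax(n, 1L) >= frac) | grepl(strrep("A", run), seqs, fixed = TRUE)
}

#' Clean raw small-RNA reads
#'
#' Applies the elimination cascade to one library. Reads can be given as a
#' data.frame (`id`, `seq`, `qual`) or as a FASTQ path (Sanger Phred+33).
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`, or a FASTQ
#'   file path.
#' @param adapter5,adapter3 adapter sequences (RNA or DNA alphabet).
#' @param opts options from [clean_opts()].
#' @return list with `inserts` (data.frame `id`, `seq` of clean trimmed
#'   inserts), `fates` (factor over all raw reads) and `report` (per-rule
#'   removal counts, clean/unique totals and the 18--30 nt length
#'   histogram).
#' @export
clean_reads <- function(reads, adapter5, adapter3, opts = clean_opts()) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  stopifnot(is.data.frame(reads), all(c("id", "seq", "qual") %in% names(reads)))
  if (!nzchar(adapter5) || !nzchar(adapter3)) {
    stopf("clean_reads: adapters must be non-empty")
  }
  adapter5 <- norm_dna(adapter5)
  adapter3 <- norm_dna(adapter3)
  seqs <- norm_dna(reads$seq)
  n <- length(seqs)
  fate <- rep(NA_character_, n)

  r1 <- low_quality_fraction(reads$qual, opts$quality_floor) > opts$max_low_frac
  fate[r1] <- "low_quality"

  todo <- is.na(fate)
  r2 <- detect_adapter5(seqs, adapter5, opts$min_overlap5)
  fate[todo & r2] <- "adapter5_contaminant"

  todo <- is.na(fate)
  apos <- rep(NA_integer_, n)
  if (any(todo)) {
    apos[todo] <- find_adapter3(seqs[todo], adapter3,
                                opts$adapter3_seed, opts$adapter3_seed_mm)
  }
  fate[todo & is.na(apos)] <- "no_3p_adapter"

  insert <- ifelse(is.na(apos), NA_character_,
                   substr(seqs, 1L, pmax(apos - 1L, 0L)))
  todo <- is.na(fate)
  fate[todo & nchar(insert) == 0] <- "no_insert"

  todo <- is.na(fate)
  r5 <- rep(FALSE, n)
  r5[todo] <- is_polya(insert[todo], opts$polya_frac, opts$polya_run)
  fate[todo & r5] <- "polyA"

  todo <- is.na(fate)
  len <- nchar(insert)
  fate[todo & (len < opts$min_len | len > opts$max_len)] <- "length_out_of_range"

  fate[is.na(fate)] <- "clean"
  fate <- factor(fate, levels = READ_FATES)
  keep <- fate == "clean"
  inserts <- data.frame(id = reads$id[keep], seq = insert[keep],
                        stringsAsFactors = FALSE)
  list(inserts = inserts, fates = fate,
       report = cleaning_report(fate, inserts$seq, opts))
}

cleaning_report <- function(fate, clean_seqs, opts) {
  removed <- table(fate)[setdiff(READ_FATES, "clean")]
  hist <- tabulate(factor(nchar(clean_seqs),
                          levels = opts$min_len:opts$max_len),
                   nbins = opts$max_len - opts$min_len + 1L)
  names(hist) <- opts$min_len:opts$max_len
  list(raw_total = length(fate),
       removed = as.integer(removed) |> setNames(names(removed)),
       clean_total = sum(fate == "clean"),
       unique_tags = length(unique(clean_seqs)),
       length_histogram = hist)
}

#' Collapse clean inserts into unique tags with per-library counts
#'
#' @param control,treatment character vectors of clean insert sequences
#'   (one element per surviving read) for each library.
#' @return data.frame of unique tags: `tag_id`, `sequence`,
#'   `count_control`, `count_treatment`, ordered by total count (ties by
#'   sequence).
#' @export
collapse_unique <- function(control, treatment = character(0)) {
  control <- norm_dna(control)
  treatment <- norm_dna(treatment)
  seqs <- sort(unique(c(control, treatment)))
  tc <- table(factor(control, levels = seqs))
  tt <- table(factor(treatment, levels = seqs))
  out <- data.frame(sequence = seqs,
                    count_control = as.integer(tc),
                    count_treatment = as.integer(tt),
                    stringsAsFactors = FALSE)
  out <- out[order(-(out$count_control + out$count_treatment), out$sequence), ]
  out$tag_id <- sprintf("tag_%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("tag_id", "sequence", "count_control", "count_treatment")]
}

#' Count-weighted tag length distribution
#'
#' @param tags data.frame from [collapse_unique()].
#' @param min_len,max_len histogram range in nt.
#' @return data.frame `length`, `count_control`, `count_treatment` with
#'   read-count-weighted totals per length bin.
#' @export
length_distribution <- function(tags, min_len = 18L, max_len = 30L) {
  lens <- factor(nchar(tags$sequence), levels = min_len:max_len)
  data.frame(
    length = min_len:max_len,
    count_control = as.integer(tapply(tags$count_control, lens, sum,
                                      default = 0L)),
    count_treatment = as.integer(tapply(tags$count_treatment, lens, sum,
                                        default = 0L)))
}
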