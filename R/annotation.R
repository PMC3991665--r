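# Tag annotation: exact-match genome mapping, known-miRNA identification,
# structural ncRNA / exon / intron classification, siRNA duplex detection,
# and single-category priority resolution.

ANNOTATION_PRIORITY <- c("rRNA_etc_genbank", "rRNA_etc_rfam", "known_miRNA",
                         "repeat", "exon", "intron", "siRNA_candidate")
ANNOTATION_CATEGORIES <- c(ANNOTATION_PRIORITY, "unannotated")

#' Map unique tags to the genome by exact match
#'
#' Finds every exact occurrence of each tag on both strands. Tags with more
#' genomic copies than `max_copies` are flagged (`excluded = TRUE`) so the
#' novel-miRNA search can skip them.
#'
#' @param tags character vector of tag sequences (T/U normalized
#'   internally) or a data.frame with a `sequence` column.
#' @param genome named character vector of chromosome sequences.
#' @param max_copies copy-number flag threshold (default 20).
#' @return data.frame of hits: `tag`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `copy_number`, `excluded`. The hit substring
#'   (reverse-complemented for minus-strand hits) equals the tag exactly.
#' @export
map_to_genome <- function(tags, genome, max_copies = 20L) {
  if (is.data.frame(tags)) tags <- tags$sequence
  tags <- norm_dna(tags)
  if (length(genome) == 0 || any(!nzchar(genome))) {
    stopf("map_to_genome: empty genome")
  }
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  uniq <- unique(tags)
  hits <- list()
  for (chrom in names(genome)) {
    subject <- Biostrings::DNAString(genome[[chrom]])
    for (strand in c("+", "-")) {
      query <- if (strand == "+") uniq else revcomp(uniq)
      by_w <- split(seq_along(uniq), nchar(query))
      for (ix in by_w) {
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(query[ix]))
        m <- Biostrings::matchPDict(pd, subject)
        cnt <- S4Vectors::elementNROWS(m)
        found <- which(cnt > 0)
        for (k in found) {
          st <- IRanges::start(m[[k]])
          hits[[length(hits) + 1L]] <- data.frame(
            tag = uniq[ix[k]], chrom = chrom,
            start = st - 1L, end = st - 1L + nchar(uniq[ix[k]]),
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(tag = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), copy_number = integer(),
                      excluded = logical(), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, hits)
  cn <- table(hits$tag)
  hits$copy_number <- as.integer(cn[hits$tag])
  hits$excluded <- hits$copy_number > max_copies
  hits <- hits[order(hits$tag, hits$chrom, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Identify known miRNAs by perfect match
#'
#' A tag is a known miRNA iff its sequence is identical (after T/U
#' normalization) to a reference mature sequence, or is an exact substring
#' of a reference precursor. One mismatch is already disqualifying.
#'
#' @param tags character vector of tag sequences.
#' @param matures named character vector of reference mature sequences.
#' @param precursors optional named character vector of reference
#'   precursors.
#' @return data.frame `tag`, `known_miRNA` (logical), `family` (name of
#'   the matching reference, NA when unmatched).
#' @export
match_known_mirnas <- function(tags, matures, precursors = NULL) {
  if (length(matures) == 0 && length(precursors) == 0) {
    stopf("match_known_mirnas: empty reference")
  }
  if (anyDuplicated(names(matures)) || anyDuplicated(names(precursors))) {
    stopf("match_known_mirnas: duplicate reference ids")
  }
  tags <- norm_dna(tags)
  fam <- rep(NA_character_, length(tags))
  if (length(matures)) {
    matures <- norm_dna(matures)
    fam <- names(matures)[match(tags, matures)]
  }
  if (!is.null(precursors) && length(precursors)) {
    precursors <- norm_dna(precursors)
    need <- which(is.na(fam))
    for (i in need) {
      hit <- which(vapply(precursors, function(p) grepl(tags[i], p,
                                                        fixed = TRUE),
                          logical(1)))
      if (length(hit)) fam[i] <- names(precursors)[hit[1]]
    }
  }
  data.frame(tag = tags, known_miRNA = !is.na(fam), family = fam,
             stringsAsFactors = FALSE)
}

#' Classify tags against ncRNA references and gene structure
#'
#' A tag matches an ncRNA reference set when it is an exact substring of
#' any reference sequence; it matches exon/intron when one of its genome
#' hits overlaps an annotated interval by at least 1 nt on the same
#' strand. A tag may match several categories here; [resolve_priority()]
#' reduces them to one.
#'
#' @param tags character vector of tag sequences.
#' @param hits genome hits from [map_to_genome()].
#' @param genbank,rfam named character vectors of structural ncRNA
#'   reference sequences (rRNA/tRNA/snoRNA/snRNA-like).
#' @param gene_annotation data.frame (`chrom`, `start`, `end`, `strand`,
#'   `type` with exon/intron rows; 0-based half-open) or GFF3/BED path.
#' @param repeats optional repeat intervals in the same layout.
#' @param genome_lengths optional named vector to validate annotation
#'   intervals against.
#' @return logical data.frame, one row per tag, one column per candidate
#'   category.
#' @export
classify_other <- function(tags, hits, genbank = NULL, rfam = NULL,
                           gene_annotation = NULL, repeats = NULL,
                           genome_lengths = NULL) {
  tags <- norm_dna(tags)
  out <- data.frame(tag = tags, stringsAsFactors = FALSE)
  out$rRNA_etc_genbank <- substring_match(tags, genbank)
  out$rRNA_etc_rfam <- substring_match(tags, rfam)
  out$exon <- rep(FALSE, length(tags))
  out$intron <- rep(FALSE, length(tags))
  out$repeat_ <- rep(FALSE, length(tags))
  if (!is.null(gene_annotation)) {
    ga <- read_annotation(gene_annotation)
    validate_intervals(ga, genome_lengths)
    out$exon <- overlap_match(tags, hits, ga[ga$type == "exon", ])
    out$intron <- overlap_match(tags, hits, ga[ga$type == "intron", ])
  }
  if (!is.null(repeats)) {
    rp <- read_annotation(repeats)
    validate_intervals(rp, genome_lengths)
    out$repeat_ <- overlap_match(tags, hits, rp)
  }
  names(out)[names(out) == "repeat_"] <- "repeat"
  out
}

substring_match <- function(tags, refs) {
  if (is.null(refs) || length(refs) == 0) return(rep(FALSE, length(tags)))
  refs <- norm_dna(refs)
  vapply(tags, function(t) any(vapply(refs, function(r)
    grepl(t, r, fixed = TRUE), logical(1))), logical(1), USE.NAMES = FALSE)
}

validate_intervals <- function(anno, genome_lengths) {
  if (is.null(genome_lengths)) return(invisible())
  bad <- anno$start < 0 |
    anno$end > genome_lengths[anno$chrom] |
    is.na(genome_lengths[anno$chrom])
  if (any(bad)) {
    stopf("annotation interval outside genome: %s:%d-%d",
          anno$chrom[which(bad)[1]], anno$start[which(bad)[1]],
          anno$end[which(bad)[1]])
  }
  invisible()
}

# same-strand >= 1 nt overlap between any hit of a tag and any interval
overlap_match <- function(tags, hits, anno) {
  if (is.null(anno) || nrow(anno) == 0 || nrow(hits) == 0) {
    return(rep(FALSE, length(tags)))
  }
  h <- GenomicRanges::GRanges(hits$chrom,
                              IRanges::IRanges(hits$start + 1L, hits$end),
                              strand = hits$strand)
  a <- GenomicRanges::GRanges(anno$chrom,
                              IRanges::IRanges(anno$start + 1L, anno$end),
                              strand = anno$strand)
  ov <- GenomicRanges::countOverlaps(h, a, minoverlap = 1L,
                                     ignore.strand = FALSE) > 0
  tags %in% hits$tag[ov]
}

#' Detect siRNA candidate duplex pairs
#'
#' Reports pairs of 22--24 nt tags mapping to opposite strands of the same
#' locus such that each strand's 3' end overhangs the other by exactly
#' 2 nt (the canonical siRNA duplex signature): the minus-strand hit
#' starts and ends exactly 2 nt to the left of the plus-strand hit.
#'
#' @param hits genome hits from [map_to_genome()].
#' @param len_range allowed tag lengths (default 22--24 nt).
#' @return data.frame of candidate pairs (`tag_plus`, `tag_minus`,
#'   `chrom`, `start_plus`, `start_minus`) plus a `tags` attribute-free
#'   convenience column set; zero rows when none.
#' @export
identify_sirna_candidates <- function(hits, len_range = c(22L, 24L)) {
  empty <- data.frame(tag_plus = character(), tag_minus = character(),
                      chrom = character(), start_plus = integer(),
                      start_minus = integer(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  len <- hits$end - hits$start
  h <- hits[len >= len_range[1] & len <= len_range[2], , drop = FALSE]
  hp <- h[h$strand == "+", , drop = FALSE]
  hm <- h[h$strand == "-", , drop = FALSE]
  if (nrow(hp) == 0 || nrow(hm) == 0) return(empty)
  key_p <- paste(hp$chrom, hp$start - 2L, hp$end - 2L)
  key_m <- paste(hm$chrom, hm$start, hm$end)
  m <- match(key_p, key_m)
  ok <- !is.na(m)
  if (!any(ok)) return(empty)
  data.frame(tag_plus = hp$tag[ok], tag_minus = hm$tag[m[ok]],
             chrom = hp$chrom[ok], start_plus = hp$start[ok],
             start_minus = hm$start[m[ok]], stringsAsFactors = FALSE)
}

#' Resolve one annotation category per tag
#'
#' Applies the priority order GenBank ncRNA > Rfam ncRNA > known miRNA >
#' repeat > exon > intron (> siRNA candidate); tags matching nothing are
#' `unannotated` and form the novel-miRNA search space. Resolution is a
#' pure function of the category set.
#'
#' @param categories logical data.frame with a `tag` column and one column
#'   per candidate category (missing columns are treated as all-FALSE).
#' @return data.frame `tag`, `category` (factor over the full category
#'   set).
#' @export
resolve_priority <- function(categories) {
  n <- nrow(categories)
  cat <- rep("unannotated", n)
  for (lvl in rev(ANNOTATION_PRIORITY)) {
    if (lvl %in% names(categories)) {
      v <- categories[[lvl]]
      cat[!is.na(v) & v] <- lvl
    }
  }
  data.frame(tag = categories$tag,
             category = factor(cat, levels = ANNOTATION_CATEGORIES),
             stringsAsFactors = FALSE)
}

#' Annotate collapsed tags end to end
#'
#' Runs genome mapping, known-miRNA matching, ncRNA/exon/intron/repeat
#' classification and siRNA detection, then resolves a single category per
#' tag.
#'
#' @param tags data.frame from [collapse_unique()].
#' @param genome named character vector of chromosome sequences.
#' @param known_matures,known_precursors known miRNA references.
#' @param genbank,rfam structural ncRNA reference sets.
#' @param gene_annotation,repeats interval annotation (see
#'   [classify_other()]).
#' @param max_copies genomic copy-number flag threshold.
#' @return list with `records` (tag, category, family), `hits`,
#'   `sirna_pairs` and `summary` (per-category tag and read counts, the
#'   pie-chart partition).
#' @export
annotate_tags <- function(tags, genome, known_matures = NULL,
                          known_precursors = NULL, genbank = NULL,
                          rfam = NULL, gene_annotation = NULL,
                          repeats = NULL, max_copies = 20L) {
  seqs <- norm_dna(tags$sequence)
  hits <- map_to_genome(seqs, genome, max_copies = max_copies)
  known <- if (length(known_matures) || length(known_precursors)) {
    match_known_mirnas(seqs, known_matures %||% character(0),
                       known_precursors)
  } else {
    data.frame(tag = seqs, known_miRNA = FALSE, family = NA_character_,
               stringsAsFactors = FALSE)
  }
  cats <- classify_other(seqs, hits, genbank = genbank, rfam = rfam,
                         gene_annotation = gene_annotation, repeats = repeats,
                         genome_lengths = nchar(genome))
  sirna <- identify_sirna_candidates(hits)
  cats$known_miRNA <- known$known_miRNA
  cats$siRNA_candidate <- seqs %in% c(sirna$tag_plus, sirna$tag_minus)
  rec <- resolve_priority(cats)
  rec$family <- known$family
  counts <- tags$count_control + tags$count_treatment
  summary <- data.frame(
    category = ANNOTATION_CATEGORIES,
    unique_tags = as.integer(table(rec$category)[ANNOTATION_CATEGORIES]),
    total_reads = as.integer(tapply(counts, rec$category, sum,
                                    default = 0L)[ANNOTATION_CATEGORIES]),
    stringsAsFactors = FALSE)
  list(records = rec, hits = hits, sirna_pairs = sirna, summary = summary)
}
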