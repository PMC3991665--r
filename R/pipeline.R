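#' Run the full small RNA-seq analysis pipeline on two libraries
#'
#' Convenience composition of the stage functions: clean both libraries,
#' collapse to unique tags, annotate against the references with priority
#' resolution, predict novel miRNAs from the unannotated genome-mapped
#' tags, and compute the differential expression table over known + novel
#' miRNAs.
#'
#' @param reads_control,reads_treatment raw reads per library (data.frame
#'   `id`/`seq`/`qual` or FASTQ path).
#' @param genome named character vector of chromosome sequences (or FASTA
#'   path).
#' @param adapter5,adapter3 adapter sequences.
#' @param known_matures,genbank,rfam reference sets (named character
#'   vectors or FASTA paths).
#' @param gene_annotation exon/intron intervals (data.frame or GFF3/BED
#'   path), optional.
#' @param clean_options options from [clean_opts()].
#' @param novel_parameters parameters from [novel_params()].
#' @param predict logical: run the (folding-engine dependent) novel miRNA
#'   stage.
#' @return list with `clean` (per-library cleaning results), `tags`,
#'   `annotation`, `novel`, `de` (differential expression over known and
#'   novel miRNA tags) and `de_selected` (up/down lists).
#' @export
run_pipeline <- function(reads_control, reads_treatment, genome,
                         adapter5, adapter3,
                         known_matures = NULL, genbank = NULL, rfam = NULL,
                         gene_annotation = NULL,
                         clean_options = clean_opts(),
                         novel_parameters = novel_params(),
                         predict = folding_engine_available()) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  as_ref <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) read_fasta(x)
    else x
  }
  known_matures <- as_ref(known_matures)
  genbank <- as_ref(genbank)
  rfam <- as_ref(rfam)
  cc <- clean_reads(reads_control, adapter5, adapter3, clean_options)
  ct <- clean_reads(reads_treatment, adapter5, adapter3, clean_options)
  tags <- collapse_unique(cc$inserts$seq, ct$inserts$seq)
  ann <- annotate_tags(tags, genome, known_matures = known_matures,
                       genbank = genbank, rfam = rfam,
                       gene_annotation = gene_annotation,
                       max_copies = novel_parameters$max_copies)
  novel <- NULL
  if (predict) {
    un <- ann$records$tag[ann$records$category == "unannotated"]
    hits <- ann$hits[ann$hits$tag %in% un & !ann$hits$excluded, , drop = FALSE]
    novel <- predict_novel(genome, hits, counts = tags,
                           params = novel_parameters)
  }
  # expression over identified miRNAs: known families + novel matures
  known_tags <- tags[ann$records$category == "known_miRNA", , drop = FALSE]
  rows <- known_tags
  if (!is.null(novel) && nrow(novel)) {
    nt <- tags[norm_dna(tags$sequence) %in% norm_dna(novel$tag), , drop = FALSE]
    rows <- rbind(rows, nt)
  }
  de <- NULL
  de_selected <- NULL
  if (nrow(rows)) {
    de <- de_table(rows[, c("tag_id", "count_control", "count_treatment")],
                   total_control = cc$report$clean_total,
                   total_treatment = ct$report$clean_total)
    de_selected <- select_differential(de)
  }
  list(clean = list(control = cc, treatment = ct), tags = tags,
       annotation = ann, novel = novel, de = de, de_selected = de_selected)
}
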