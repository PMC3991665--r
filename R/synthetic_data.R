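# Synthetic small RNA-seq experiment with planted ground truth.
#
# Generates a random genome carrying planted miRNA hairpin precursors,
# known-miRNA loci, structural ncRNA decoys (rRNA/tRNA/snoRNA/snRNA),
# genes with exon/intron fragments, and non-hairpin decoy loci; then
# samples paired control/treatment raw-read libraries with adapter-flanked
# inserts, per-class contaminants matching the cleaning cascade, and known
# between-library fold changes. A machine-readable truth table makes every
# downstream stage verifiable by recovery.

NCRNA_CLASSES <- c("rRNA", "tRNA", "snoRNA", "snRNA")
CONTAMINANT_CLASSES <- c("low_quality", "adapter5_contaminant",
                         "no_3p_adapter", "no_insert", "polyA",
                         "short_insert")

#' Configuration for a synthetic small RNA-seq experiment
#'
#' Defaults emulate the study design: two libraries (control vs osmotic
#' treatment) of tens of thousands of reads dominated by 21--24 nt tags,
#' the published 5'/3' adapter sequences, and a small contaminant fraction
#' in each cleaning-rule class.
#'
#' @param genome_length genome size in nt (at least 10 kb).
#' @param gc_fraction target genome G+C fraction in (0, 1).
#' @param n_planted_mirnas number of criteria-compliant hairpin loci whose
#'   matures are to be discovered as novel miRNAs.
#' @param n_known_mirnas number of planted loci whose matures are also in
#'   the known-mature reference set.
#' @param n_decoy_loci loci per structural ncRNA class (rRNA, tRNA,
#'   snoRNA, snRNA).
#' @param n_genes genes, each expressing one exon and one intron fragment.
#' @param n_decoy_tags non-hairpin intergenic decoy loci (unannotated tags
#'   that must not be accepted as novel miRNAs).
#' @param read_depth raw reads per library.
#' @param read_length raw read length in nt.
#' @param adapter_5p,adapter_3p adapter sequences (the published small-RNA
#'   library adapters by default; RNA or DNA alphabet).
#' @param de_spec named numeric vector of true fold changes
#'   (treatment/control) keyed by planted miRNA locus id; unlisted loci
#'   have fold change 1.
#' @param contaminant_fractions named fractions of `read_depth` per
#'   contaminant class (see `CONTAMINANT_CLASSES`); must sum below 1.
#' @param mature_length planted mature length in nt (18--25; 21 by
#'   default, the dominant class in plant libraries).
#' @param stem_ext extra stem base pairs flanking the miRNA/miRNA* duplex
#'   on each side of the planted precursor.
#' @param loop_length terminal loop length of planted precursors.
#' @param error_rate uniform per-base substitution rate on clean inserts.
#' @param minus_strand_fraction fraction of hairpin loci planted on the
#'   minus strand.
#' @param seed integer RNG seed; identical configs give byte-identical
#'   outputs.
#' @return validated config list of class `mirsim_config`.
#' @export
simulation_config <- function(genome_length = 100000L,
                              gc_fraction = 0.5,
                              n_planted_mirnas = 20L,
                              n_known_mirnas = 5L,
                              n_decoy_loci = 3L,
                              n_genes = 3L,
                              n_decoy_tags = 20L,
                              read_depth = 20000L,
                              read_length = 50L,
                              adapter_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                              adapter_3p = "TCGTATGCCGTCTTCTGCTTGT",
                              de_spec = NULL,
                              contaminant_fractions = NULL,
                              mature_length = 21L,
                              stem_ext = 15L,
                              loop_length = 10L,
                              error_rate = 0,
                              minus_strand_fraction = 0.25,
                              seed = 1L) {
  if (is.null(contaminant_fractions)) {
    contaminant_fractions <- setNames(rep(0.02, length(CONTAMINANT_CLASSES)),
                                      CONTAMINANT_CLASSES)
  }
  cf <- contaminant_fractions
  stopifnot(all(names(cf) %in% CONTAMINANT_CLASSES))
  miss <- setdiff(CONTAMINANT_CLASSES, names(cf))
  cf[miss] <- 0
  cf <- cf[CONTAMINANT_CLASSES]
  if (any(cf < 0 | cf > 1) || sum(cf) >= 1) {
    stopf("contaminant fractions must lie in [0,1] and sum below 1")
  }
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stopf("gc_fraction must lie in (0,1)")
  }
  if (genome_length < 10000) {
    stopf("genome_length must be at least 10 kb")
  }
  if (mature_length < 18 || mature_length > 25) {
    stopf("mature_length must lie in [18, 25]")
  }
  cfg <- list(genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction,
              n_planted_mirnas = as.integer(n_planted_mirnas),
              n_known_mirnas = as.integer(n_known_mirnas),
              n_decoy_loci = as.integer(n_decoy_loci),
              n_genes = as.integer(n_genes),
              n_decoy_tags = as.integer(n_decoy_tags),
              read_depth = as.integer(read_depth),
              read_length = as.integer(read_length),
              adapter_5p = norm_dna(adapter_5p),
              adapter_3p = norm_dna(adapter_3p),
              de_spec = de_spec,
              contaminant_fractions = cf,
              mature_length = as.integer(mature_length),
              stem_ext = as.integer(stem_ext),
              loop_length = as.integer(loop_length),
              error_rate = error_rate,
              minus_strand_fraction = minus_strand_fraction,
              seed = as.integer(seed))
  if (!is.null(de_spec)) {
    ids <- mirna_ids(cfg)
    bad <- setdiff(names(de_spec), ids)
    if (length(bad)) {
      stopf("de_spec refers to unplanted miRNA id(s): %s",
            paste(bad, collapse = ", "))
    }
    if (any(de_spec <= 0)) stopf("de_spec fold changes must be positive")
  }
  # an adapter-dimer read must fail rule 4, not rule 2
  if (detect_adapter5(cfg$adapter_3p, cfg$adapter_5p, 10L)) {
    stopf("adapter_3p may not begin with an adapter_5p suffix")
  }
  structure(cfg, class = "mirsim_config")
}

mirna_ids <- function(config) sprintf("mir_%03d", seq_len(config$n_planted_mirnas))

# --- tag construction ------------------------------------------------------

random_dna_vec <- function(n, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  m <- matrix(sample(BASES, n * len, replace = TRUE, prob = p), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# A valid expressed tag must be indistinguishable from a real insert: it
# must survive every cleaning rule when wrapped as insert + 3' adapter.
tag_ok <- function(tag, config, gc_range = NULL) {
  len <- nchar(tag)
  if (len < 18 || len > 30) return(FALSE)
  if (!is.null(gc_range)) {
    gc <- gc_fraction(tag)
    if (gc < gc_range[1] || gc > gc_range[2]) return(FALSE)
  }
  if (is_polya(tag, 0.8, 10L)) return(FALSE)
  probe <- paste0(tag, config$adapter_3p)
  if (detect_adapter5(probe, config$adapter_5p, 10L)) return(FALSE)
  pos <- find_adapter3(probe, config$adapter_3p, 10L, 1L)
  isTRUE(pos == len + 1L)
}

make_tag <- function(config, len, gc_range = NULL, gc = NULL,
                     taken = character(0), max_tries = 200L) {
  gc <- gc %||% config$gc_fraction
  for (i in seq_len(max_tries)) {
    tag <- random_dna(1, gc = gc, length = len)
    if (tag_ok(tag, config, gc_range) && !(tag %in% taken)) return(tag)
  }
  stopf("failed to construct a valid tag after %d tries", max_tries)
}

# --- genome and loci -------------------------------------------------------

locus_plan <- function(config) {
  prec_len <- 2L * config$stem_ext + 2L * config$mature_length +
    config$loop_length
  plan <- data.frame(locus_id = character(), class = character(),
                     length = integer(), stringsAsFactors = FALSE)
  add <- function(ids, class, len) {
    rbind(plan, data.frame(locus_id = ids, class = class, length = len,
                           stringsAsFactors = FALSE))
  }
  if (config$n_planted_mirnas > 0) {
    plan <- add(mirna_ids(config), "mirna", prec_len)
  }
  if (config$n_known_mirnas > 0) {
    plan <- add(sprintf("kmir_%02d", seq_len(config$n_known_mirnas)),
                "known_mirna", config$mature_length)
  }
  for (cl in NCRNA_CLASSES) {
    if (config$n_decoy_loci > 0) {
      plan <- add(sprintf("%s_%02d", cl, seq_len(config$n_decoy_loci)), cl, 80L)
    }
  }
  if (config$n_genes > 0) {
    plan <- add(sprintf("gene_%02d", seq_len(config$n_genes)), "gene", 170L)
  }
  if (config$n_decoy_tags > 0) {
    plan <- add(sprintf("decoy_%02d", seq_len(config$n_decoy_tags)), "decoy", 24L)
  }
  plan
}

#' Generate a random genome with reserved loci slots
#'
#' Produces a random single-chromosome genome at the requested GC fraction
#' and reserves non-overlapping slots (with generous spacing) for every
#' locus the configuration plants. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (named character vector, chromosome `chr1`),
#'   `slots` (data.frame of reserved intervals, 0-based half-open) and an
#'   empty `truth` skeleton.
#' @export
generate_genome <- function(config) {
  withr::with_seed(config$seed, generate_genome_impl(config))
}

generate_genome_impl <- function(config, gap_min = 400L, margin = 500L) {
  plan <- locus_plan(config)
  n <- nrow(plan)
  total <- sum(plan$length)
  free <- config$genome_length - total - 2L * margin
  if (n > 0 && free < (n - 1L) * gap_min) {
    stopf(paste("slot demand (%d loci, %d nt + spacing) exceeds genome",
                "capacity (%d nt); increase genome_length"),
          n, total, config$genome_length)
  }
  genome <- random_dna(config$genome_length, gc = config$gc_fraction)
  slots <- plan
  if (n > 0) {
    slots <- plan[sample.int(n), , drop = FALSE]
    spare <- free - (n - 1L) * gap_min
    extra <- if (n > 1) {
      cuts <- sort(sample.int(spare + 1L, n - 1L, replace = TRUE) - 1L)
      diff(c(0L, cuts))
    } else integer(0)
    gaps <- c(0L, rep(gap_min, n - 1L) + extra)
    starts <- margin + cumsum(gaps) + cumsum(c(0L, head(slots$length, -1L)))
    slots$start <- as.integer(starts)
    slots$end <- slots$start + slots$length
    slots$strand <- "+"
    is_h <- slots$class == "mirna"
    nh <- sum(is_h)
    if (nh > 0) {
      minus <- sample(c("-", "+"), nh, replace = TRUE,
                      prob = c(config$minus_strand_fraction,
                               1 - config$minus_strand_fraction))
      slots$strand[is_h] <- minus
    }
    rownames(slots) <- NULL
  } else {
    slots$start <- integer(0); slots$end <- integer(0)
    slots$strand <- character(0)
  }
  list(genome = c(chr1 = genome), slots = slots, truth = empty_truth())
}

empty_truth <- function() {
  data.frame(locus_id = character(), class = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             tag = character(), locus_start = integer(), locus_end = integer(),
             base_weight = numeric(), fold_change = numeric(),
             count_control = integer(), count_treatment = integer(),
             stringsAsFactors = FALSE)
}

#' Plant a criteria-compliant hairpin precursor into a genome
#'
#' Builds a precursor by design -- extended stem, the mature on one arm,
#' a perfectly complementary star on the other, and a short terminal
#' loop -- verifies it against the novel-miRNA candidate criteria with the
#' folding engine (when available), and writes it into the genome at the
#' given position. Retries with fresh stem extensions and loops up to
#' `max_tries` before raising a construction error.
#'
#' @param genome named character vector of chromosome sequences.
#' @param mature mature sequence, 18--25 nt.
#' @param chrom chromosome name.
#' @param at 0-based start of the precursor slot.
#' @param strand `"+"` or `"-"`.
#' @param stem_ext,loop_length stem extension and loop length in nt.
#' @param gc GC fraction for the random stem extension and loop.
#' @param params criteria parameters for verification ([novel_params()]).
#' @param verify fold-verify the construct (default: when the engine is
#'   available).
#' @param max_tries construction attempts before giving up.
#' @return list with the modified `genome`, `precursor` sequence and
#'   0-based half-open `precursor_interval` and `mature_interval`.
#' @export
plant_hairpin <- function(genome, mature, chrom = "chr1", at, strand = "+",
                          stem_ext = 15L, loop_length = 10L, gc = 0.5,
                          params = novel_params(),
                          verify = folding_engine_available(),
                          max_tries = 25L) {
  mlen <- nchar(mature)
  if (mlen < 18 || mlen > 25) stopf("mature length must lie in [18, 25]")
  mature <- norm_dna(mature)
  last_flags <- NULL
  for (i in seq_len(max_tries)) {
    ext <- random_dna(1, gc = gc, length = stem_ext)
    loop <- random_dna(1, gc = 0.3, length = loop_length)
    prec <- paste0(ext, mature, loop, revcomp(mature), revcomp(ext))
    au <- au_fraction(prec)
    if (au < 0.32 || au > 0.68) next
    if (verify) {
      ev <- evaluate_hairpin(prec, stem_ext + 1L, mlen, params)
      last_flags <- ev$flags
      if (!ev$accept) next
    }
    plen <- nchar(prec)
    insert_seq <- if (strand == "+") prec else revcomp(prec)
    g <- genome[[chrom]]
    if (at < 0 || at + plen > nchar(g)) stopf("precursor slot outside genome")
    substr(g, at + 1L, at + plen) <- insert_seq
    genome[[chrom]] <- g
    m_off <- if (strand == "+") stem_ext else plen - stem_ext - mlen
    return(list(genome = genome, precursor = prec,
                precursor_interval = c(at, at + plen),
                mature_interval = c(at + m_off, at + m_off + mlen),
                star_seq = revcomp(mature)))
  }
  stopf("failed to construct a compliant hairpin after %d tries%s", max_tries,
        if (is.null(last_flags)) "" else paste0(
          " (last failing criteria: ",
          paste(names(last_flags)[!last_flags], collapse = ", "), ")"))
}

#' Build the full synthetic genome with all planted loci
#'
#' Generates the genome, plants hairpin miRNA loci, known-miRNA loci,
#' structural ncRNA loci, genes (exon/intron fragments) and non-hairpin
#' decoys into the reserved slots, and assembles the truth table,
#' gene-annotation intervals and reference sequence sets.
#'
#' @param config a [simulation_config()].
#' @return object of class `mirsim`: list with `config`, `genome`, `truth`
#'   (one row per expressed tag), `annotation` (exon/intron intervals),
#'   `references` (known matures, GenBank-like and Rfam-like ncRNA sets)
#'   and `precursors`.
#' @export
build_simulation <- function(config = simulation_config()) {
  withr::with_seed(config$seed, build_simulation_impl(config))
}

build_simulation_impl <- function(config) {
  gg <- generate_genome_impl(config)
  genome <- gg$genome
  slots <- gg$slots
  truth <- list()
  anno <- list()
  precursors <- list()
  refs <- list(known_matures = character(), genbank = character(),
               rfam = character())
  taken <- character(0)
  for (i in seq_len(nrow(slots))) {
    s <- slots[i, ]
    cl <- s$class
    if (cl == "mirna") {
      mature <- make_tag(config, config$mature_length,
                         gc_range = c(0.40, 0.60), taken = taken)
      taken <- c(taken, mature)
      ph <- plant_hairpin(genome, mature,
                          chrom = "chr1", at = s$start, strand = s$strand,
                          stem_ext = config$stem_ext,
                          loop_length = config$loop_length,
                          gc = config$gc_fraction)
      genome <- ph$genome
      precursors[[length(precursors) + 1L]] <- data.frame(
        locus_id = s$locus_id, sequence = ph$precursor,
        start = ph$precursor_interval[1], end = ph$precursor_interval[2],
        strand = s$strand, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- truth_row(
        s$locus_id, "mirna", ph$mature_interval[1], ph$mature_interval[2],
        s$strand, mature, s$start, s$end)
    } else if (cl == "known_mirna") {
      mature <- make_tag(config, config$mature_length, taken = taken)
      taken <- c(taken, mature)
      g <- genome[["chr1"]]
      substr(g, s$start + 1L, s$end) <- mature
      genome[["chr1"]] <- g
      refs$known_matures[s$locus_id] <- mature
      truth[[length(truth) + 1L]] <- truth_row(
        s$locus_id, "known_mirna", s$start, s$end, "+", mature,
        s$start, s$end)
    } else if (cl %in% NCRNA_CLASSES) {
      repeat {
        locus <- random_dna(1, gc = config$gc_fraction, length = s$length)
        tlen <- sample(21:24, 1)
        off <- sample.int(s$length - tlen + 1L, 1)
        tag <- substr(locus, off, off + tlen - 1L)
        if (tag_ok(tag, config) && !(tag %in% taken)) break
      }
      taken <- c(taken, tag)
      g <- genome[["chr1"]]
      substr(g, s$start + 1L, s$end) <- locus
      genome[["chr1"]] <- g
      set <- if (cl %in% c("rRNA", "tRNA")) "genbank" else "rfam"
      refs[[set]][s$locus_id] <- locus
      truth[[length(truth) + 1L]] <- truth_row(
        s$locus_id, cl, s$start + off - 1L, s$start + off - 1L + tlen, "+",
        tag, s$start, s$end)
    } else if (cl == "gene") {
      repeat {
        locus <- random_dna(1, gc = config$gc_fraction, length = s$length)
        e_off <- sample.int(60L - 21L + 1L, 1)
        i_off <- 60L + sample.int(50L - 21L + 1L, 1)
        etag <- substr(locus, e_off, e_off + 20L)
        itag <- substr(locus, i_off, i_off + 20L)
        if (tag_ok(etag, config) && tag_ok(itag, config) &&
            !(etag %in% taken) && !(itag %in% taken) && etag != itag) break
      }
      taken <- c(taken, etag, itag)
      g <- genome[["chr1"]]
      substr(g, s$start + 1L, s$end) <- locus
      genome[["chr1"]] <- g
      anno[[length(anno) + 1L]] <- data.frame(
        chrom = "chr1",
        start = s$start + c(0L, 60L, 110L),
        end = s$start + c(60L, 110L, 170L),
        strand = "+", type = c("exon", "intron", "exon"),
        gene = s$locus_id, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- truth_row(
        paste0(s$locus_id, "_exon"), "exon",
        s$start + e_off - 1L, s$start + e_off + 20L, "+", etag,
        s$start, s$end)
      truth[[length(truth) + 1L]] <- truth_row(
        paste0(s$locus_id, "_intron"), "intron",
        s$start + i_off - 1L, s$start + i_off + 20L, "+", itag,
        s$start, s$end)
    } else if (cl == "decoy") {
      tlen <- sample(21:24, 1)
      tag <- make_tag(config, tlen, taken = taken)
      taken <- c(taken, tag)
      g <- genome[["chr1"]]
      substr(g, s$start + 1L, s$start + tlen) <- tag
      genome[["chr1"]] <- g
      truth[[length(truth) + 1L]] <- truth_row(
        s$locus_id, "decoy", s$start, s$start + tlen, "+", tag,
        s$start, s$end)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else empty_truth()
  if (nrow(truth)) {
    truth$base_weight <- stats::rlnorm(nrow(truth), 0, 0.5)
    truth$fold_change <- 1
    if (!is.null(config$de_spec)) {
      m <- match(names(config$de_spec), truth$locus_id)
      truth$fold_change[m] <- as.numeric(config$de_spec)
    }
  }
  # a few reference matures that are not planted anywhere
  extra <- vapply(1:3, function(i) make_tag(config, config$mature_length,
                                            taken = taken), character(1))
  refs$known_matures[sprintf("kmir_ref_only_%d", 1:3)] <- extra
  structure(list(config = config, genome = genome, truth = truth,
                 annotation = if (length(anno)) do.call(rbind, anno) else NULL,
                 references = refs,
                 precursors = if (length(precursors))
                   do.call(rbind, precursors) else NULL),
            class = "mirsim")
}

truth_row <- function(id, class, start, end, strand, tag,
                      locus_start, locus_end) {
  data.frame(locus_id = id, class = class, chrom = "chr1",
             start = as.integer(start), end = as.integer(end),
             strand = strand, tag = tag,
             locus_start = as.integer(locus_start),
             locus_end = as.integer(locus_end),
             base_weight = NA_real_, fold_change = NA_real_,
             count_control = NA_integer_, count_treatment = NA_integer_,
             stringsAsFactors = FALSE)
}

# --- read simulation -------------------------------------------------------

#' Simulate paired control/treatment raw-read libraries
#'
#' Samples reads from the planted loci (Poisson counts proportional to
#' locus weight, scaled in the treatment library by the true fold change),
#' wraps inserts with the 3' adapter and random downstream bases, applies
#' uniform substitution noise, and injects contaminant reads for each
#' cleaning-rule class. Per-read truth labels are kept alongside.
#'
#' @param sim a `mirsim` object from [build_simulation()].
#' @return list with `reads` (per-library data.frames `id`, `seq`, `qual`,
#'   `label`), the updated `truth` table (true per-library clean counts)
#'   and `contaminant_counts` (planted reads per class and library).
#' @export
simulate_libraries <- function(sim) {
  stopifnot(inherits(sim, "mirsim"))
  config <- sim$config
  withr::with_seed(config$seed + 1L, simulate_libraries_impl(sim, config))
}

simulate_libraries_impl <- function(sim, config) {
  truth <- sim$truth
  n_cont <- round(config$contaminant_fractions * config$read_depth)
  clean_target <- config$read_depth - sum(n_cont)
  w <- truth$base_weight
  reads <- list()
  cont_counts <- list()
  for (lib in c("control", "treatment")) {
    fc <- if (lib == "treatment") truth$fold_change else rep(1, nrow(truth))
    lambda <- if (nrow(truth)) clean_target * (w * fc) / sum(w) else numeric(0)
    counts <- if (length(lambda)) stats::rpois(length(lambda), lambda) else integer(0)
    truth[[paste0("count_", lib)]] <- counts
    tags <- rep(truth$tag, counts)
    labels <- rep(truth$locus_id, counts)
    tags <- mutate_reads(tags, config$error_rate)
    lr <- build_reads(tags, labels, config)
    cr <- contaminant_reads(n_cont, config)
    all <- rbind(lr, cr)
    ord <- sample.int(nrow(all))
    all <- all[ord, , drop = FALSE]
    all$id <- sprintf("%s_%06d", lib, seq_len(nrow(all)))
    rownames(all) <- NULL
    reads[[lib]] <- all[, c("id", "seq", "qual", "label")]
    cont_counts[[lib]] <- n_cont
  }
  list(reads = reads, truth = truth,
       contaminant_counts = data.frame(
         class = CONTAMINANT_CLASSES,
         control = as.integer(cont_counts$control),
         treatment = as.integer(cont_counts$treatment),
         stringsAsFactors = FALSE))
}

mutate_reads <- function(tags, error_rate) {
  if (error_rate <= 0 || length(tags) == 0) return(tags)
  lens <- nchar(tags)
  n_err <- stats::rbinom(length(tags), lens, error_rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(tags[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1),
                      character(1))
    tags[i] <- paste(ch, collapse = "")
  }
  tags
}

pad_to_length <- function(core, read_length, gc) {
  need <- pmax(read_length - nchar(core), 0L)
  pads <- character(length(core))
  for (i in seq_along(core)) {
    pads[i] <- if (need[i] > 0) random_dna(1, gc = gc, length = need[i]) else ""
  }
  substr(paste0(core, pads), 1L, read_length)
}

build_reads <- function(inserts, labels, config) {
  if (length(inserts) == 0) {
    return(data.frame(seq = character(), qual = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  seqs <- pad_to_length(paste0(inserts, config$adapter_3p),
                        config$read_length, config$gc_fraction)
  data.frame(seq = seqs,
             qual = strrep("I", config$read_length),
             label = labels, stringsAsFactors = FALSE)
}

contaminant_reads <- function(n_cont, config) {
  out <- list()
  rl <- config$read_length
  hi <- strrep("I", rl)
  n_low <- ceiling(0.3 * rl)
  lo <- paste0(strrep("I", rl - n_low), strrep("#", n_low))
  a3 <- config$adapter_3p
  a5 <- config$adapter_5p
  mk <- function(n, class, core_fun, qual) {
    if (n <= 0) return(NULL)
    seqs <- vapply(seq_len(n), function(i) core_fun(), character(1))
    seqs <- pad_to_length(seqs, rl, config$gc_fraction)
    data.frame(seq = seqs, qual = qual, label = class,
               stringsAsFactors = FALSE)
  }
  fresh_tag <- function() make_tag(config, 21L)
  out$low_quality <- mk(n_cont[["low_quality"]], "low_quality",
                        function() paste0(fresh_tag(), a3), lo)
  a5suf <- substr(a5, nchar(a5) - 11L, nchar(a5))
  out$adapter5 <- mk(n_cont[["adapter5_contaminant"]], "adapter5_contaminant",
                     function() paste0(a5suf, fresh_tag(), a3), hi)
  no_seed_pad <- function(tag) {
    repeat {
      pad <- random_dna(1, gc = config$gc_fraction,
                        length = rl - nchar(tag))
      read <- paste0(tag, pad)
      if (is.na(find_adapter3(read, a3, 10L, 1L))) return(read)
    }
  }
  out$no_adapter <- mk(n_cont[["no_3p_adapter"]], "no_3p_adapter",
                       function() no_seed_pad(fresh_tag()), hi)
  out$no_insert <- mk(n_cont[["no_insert"]], "no_insert",
                      function() a3, hi)
  out$polya <- mk(n_cont[["polyA"]], "polyA",
                  function() paste0(strrep("A", 21L), a3), hi)
  short_tag <- function() {
    repeat {
      t <- random_dna(1, gc = config$gc_fraction, length = sample(10:17, 1))
      probe <- paste0(t, a3)
      if (!is_polya(t, 0.8, 10L) &&
          !detect_adapter5(probe, a5, 10L) &&
          isTRUE(find_adapter3(probe, a3, 10L, 1L) == nchar(t) + 1L)) return(t)
    }
  }
  out$short <- mk(n_cont[["short_insert"]], "short_insert",
                  function() paste0(short_tag(), a3), hi)
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(seq = character(), qual = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write a simulated experiment to disk
#'
#' Emits genome FASTA, loci GFF3 (classes as feature types), per-library
#' FASTQ (Sanger Phred+33) with per-read truth label TSVs, the truth
#' table TSV and the reference FASTA sets.
#'
#' @param sim a `mirsim` object.
#' @param libs result of [simulate_libraries()].
#' @param dir output directory (created if missing).
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, libs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gff = file.path(dir, "loci.gff3"),
             truth = file.path(dir, "truth.tsv"),
             known = file.path(dir, "known_matures.fa"),
             genbank = file.path(dir, "ncrna_genbank.fa"),
             rfam = file.path(dir, "ncrna_rfam.fa"))
  write_fasta(sim$genome, paths[["genome"]])
  truth <- libs$truth
  gff <- sprintf("chr1\tmirseed_sim\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                 truth$class, truth$start + 1L, truth$end, truth$strand,
                 truth$locus_id)
  writeLines(c("##gff-version 3", gff), paths[["gff"]])
  write_tsv(truth, paths[["truth"]])
  if (length(sim$references$known_matures)) {
    write_fasta(sim$references$known_matures, paths[["known"]])
  }
  if (length(sim$references$genbank)) {
    write_fasta(sim$references$genbank, paths[["genbank"]])
  }
  if (length(sim$references$rfam)) {
    write_fasta(sim$references$rfam, paths[["rfam"]])
  }
  for (lib in names(libs$reads)) {
    fq <- file.path(dir, paste0("reads_", lib, ".fastq"))
    write_fastq(libs$reads[[lib]], fq)
    write_tsv(libs$reads[[lib]][, c("id", "label")],
              file.path(dir, paste0("labels_", lib, ".tsv")))
    paths[[paste0("fastq_", lib)]] <- fq
  }
  invisible(paths)
}
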