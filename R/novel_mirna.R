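# Novel miRNA prediction from unannotated genome-mapped tags.
#
# Candidate precursors are excised around each tag hit, folded with the
# thermodynamic engine, the miRNA/miRNA* duplex is measured from the
# dot-bracket structure, and candidates are filtered by the classical
# plant parameter set plus the hairpin candidate criteria (stem-loop fold,
# mature on one arm, duplex mismatch limit, intact star, MFE/MFEI/A+U).

#' Default novel-miRNA prediction parameters
#'
#' The plant parameter set: mature length 18--25 nt, star length 20--23 nt,
#' at most 20 genomic copies, precursor MFE at most -18 kcal/mol, at most
#' 300 nt between miRNA and miRNA*, at least 16 duplex base pairs, bulge at
#' most 4 nt, duplex asymmetry at most 4 nt, 20 nt precursor flank; plus
#' candidate filters: fewer than 6 duplex mismatches, MFEI at least 0.85
#' (common plant practice; configurable), A+U fraction within 30--70%.
#'
#' @param ... overrides for individual parameters.
#' @return named list of parameters.
#' @export
novel_params <- function(...) {
  p <- list(
    flank = 20L,            # flank sequence length of the precursor (nt)
    max_space = 300L,       # maximal space between miRNA and miRNA* (nt)
    max_copies = 20L,       # maximal genomic copy number of a candidate tag
    mfe_max = -18,          # maximal precursor free energy (kcal/mol)
    min_pairs = 16L,        # minimal miRNA/miRNA* base pairs
    max_bulge = 4L,         # maximal duplex bulge (nt)
    max_asym = 4L,          # maximal duplex asymmetry (nt)
    max_mismatch = 6L,      # mismatches must be strictly below this
    mfei_min = 0.85,
    au_range = c(0.30, 0.70),
    mature_len_range = c(18L, 25L),
    star_len_range = c(20L, 23L),
    homology_matures = NULL,   # optional known matures for the substitution
    homology_max_subst = 4L    # filter; NULL disables it (default)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stopf("novel_params: unknown parameter(s): %s",
                         paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

#' Fold a candidate precursor sequence
#'
#' Thin, validated wrapper over the folding engine for a single precursor
#' window. Deterministic for a given input.
#'
#' @param sequence nucleotide sequence, length at least 40 nt.
#' @return list with `sequence` (RNA), `structure` (dot-bracket) and `mfe`
#'   (kcal/mol).
#' @export
fold_precursor <- function(sequence) {
  if (nchar(sequence) < 40) {
    stopf("fold_precursor: sequence shorter than 40 nt (%d)", nchar(sequence))
  }
  if (grepl("[^ACGUTacgut]", sequence)) {
    stopf("fold_precursor: non-ACGU characters in input")
  }
  r <- rna_fold(sequence)
  list(sequence = r$sequence, structure = r$structure, mfe = r$mfe)
}

#' Measure the miRNA/miRNA* duplex from a folded precursor
#'
#' Locates the star strand as the pairing partner of the mature with the
#' 2-nt 3' overhang convention (the Dicer cleavage signature), and measures
#' duplex geometry: base pairs, mismatches (mature positions without a
#' partner on the star arm), longest single-strand bulge, strand asymmetry,
#' spacing between mature and star, and whether the star overlaps the
#' terminal loop.
#'
#' @param fold a fold result (list or one-row data.frame with `sequence`
#'   and `structure`).
#' @param mature_start,mature_end 1-based inclusive mature coordinates
#'   within the folded sequence.
#' @return list of duplex metrics; `n_base_pairs` is 0 when the mature is
#'   entirely unpaired (criteria will then fail downstream).
#' @export
measure_duplex <- function(fold, mature_start, mature_end) {
  structure <- fold$structure
  n <- nchar(structure)
  ms <- as.integer(mature_start); me <- as.integer(mature_end)
  stopifnot(ms >= 1, me <= n, ms < me)
  pt <- pair_table(structure)
  mlen <- me - ms + 1L
  idx <- ms:me
  partner <- pt[idx]
  # duplex pairs: mature positions paired outside the mature itself
  duplex <- partner != 0 & (partner < ms | partner > me)
  n_bp <- sum(duplex)
  loops <- hairpin_loops(pt)
  res <- list(
    n_base_pairs = n_bp,
    n_mismatches = mlen - n_bp,
    max_bulge = NA_integer_, asymmetry = NA_integer_,
    spacing = NA_integer_,
    star_start = NA_integer_, star_end = NA_integer_,
    star_seq = NA_character_,
    star_contains_loop = NA, mature_in_loop = overlaps_any(ms, me, loops)
  )
  if (n_bp == 0) {
    res$max_bulge <- 0L; res$asymmetry <- 0L
    res$star_contains_loop <- FALSE
    return(res)
  }
  dpos <- idx[duplex]
  q <- pt[dpos]
  # projected star with 2-nt 3' overhang: the star 5' end pairs mature
  # position (me - 2), the star 3' end extends 2 nt past the partner of ms
  anchors <- dpos[dpos <= max(me - 2L, ms)]
  i_hi <- if (length(anchors)) max(anchors) else max(dpos)
  i_lo <- min(dpos)
  a <- pt[i_hi] - ((me - 2L) - i_hi)
  b <- pt[i_lo] + 2L + (i_lo - ms)
  star_start <- max(1L, min(a, b))
  star_end <- min(n, max(a, b))
  # paired span on each strand (overhangs excluded)
  m_span <- range(dpos)
  s_span <- range(q)
  u_m <- sum(pt[m_span[1]:m_span[2]] == 0)
  u_s <- sum(pt[s_span[1]:s_span[2]] == 0)
  res$max_bulge <- max(longest_zero_run(pt[m_span[1]:m_span[2]]),
                       longest_zero_run(pt[s_span[1]:s_span[2]]))
  res$asymmetry <- abs(u_m - u_s)
  res$spacing <- if (star_start > me) {
    star_start - me - 1L
  } else if (star_end < ms) {
    ms - star_end - 1L
  } else 0L
  res$star_start <- star_start
  res$star_end <- star_end
  res$star_seq <- substr(fold$sequence, star_start, star_end)
  res$star_contains_loop <- overlaps_any(s_span[1], s_span[2], loops)
  res
}

overlaps_any <- function(start, end, intervals) {
  if (nrow(intervals) == 0) return(FALSE)
  any(start <= intervals[, "end"] & end >= intervals[, "start"])
}

longest_zero_run <- function(x) {
  r <- rle(x == 0)
  z <- r$lengths[r$values]
  if (length(z) == 0) 0L else max(z)
}

#' Minimum free energy index
#'
#' MFEI = (|MFE| / length x 100) / GC%, the standard normalization of
#' hairpin stability by length and base composition; genuine plant miRNA
#' precursors typically exceed 0.85.
#'
#' @param sequence precursor sequence.
#' @param mfe minimum free energy in kcal/mol (non-positive for a stable
#'   fold).
#' @return positive numeric MFEI (0 when MFE is 0); NA with a rejection
#'   downstream when GC is 0.
#' @export
compute_mfei <- function(sequence, mfe) {
  gc <- gc_fraction(sequence)
  len <- nchar(sequence)
  ifelse(gc > 0, (abs(mfe) / len * 100) / (gc * 100), NA_real_)
}

#' Apply the hairpin candidate criteria
#'
#' Evaluates the six candidate criteria and the duplex parameter limits for
#' one candidate. Rejection reasons are enumerated per criterion, never
#' silent.
#'
#' @param candidate list with fields `mfe`, `mfei`, `au`, `n_base_pairs`,
#'   `n_mismatches`, `max_bulge`, `asymmetry`, `spacing`,
#'   `star_contains_loop`, `mature_in_loop`, `mature_len`, `star_len`,
#'   `mature_seq` (only needed for the optional homology filter).
#' @param params parameter list from [novel_params()].
#' @return list with `accept` (logical) and `flags`, a named logical vector
#'   with one entry per criterion.
#' @export
apply_criteria <- function(candidate, params = novel_params()) {
  cd <- candidate
  flags <- c(
    hairpin = isTRUE(cd$n_base_pairs > 0) && isTRUE(cd$mfe < 0),
    mature_on_arm = isTRUE(!cd$mature_in_loop),
    duplex_mismatch = isTRUE(cd$n_mismatches < params$max_mismatch),
    star_intact = isTRUE(!cd$star_contains_loop) &&
      isTRUE(cd$max_bulge <= params$max_bulge),
    thermodynamic = isTRUE(cd$mfe <= params$mfe_max) &&
      isTRUE(!is.na(cd$mfei) && cd$mfei >= params$mfei_min) &&
      isTRUE(cd$au >= params$au_range[1] && cd$au <= params$au_range[2]),
    duplex_geometry = isTRUE(cd$n_base_pairs >= params$min_pairs) &&
      isTRUE(cd$asymmetry <= params$max_asym) &&
      isTRUE(cd$spacing <= params$max_space),
    length_ok = isTRUE(cd$mature_len >= params$mature_len_range[1] &&
                         cd$mature_len <= params$mature_len_range[2]) &&
      isTRUE(!is.na(cd$star_len) &&
               cd$star_len >= params$star_len_range[1] &&
               cd$star_len <= params$star_len_range[2])
  )
  if (!is.null(params$homology_matures)) {
    flags <- c(flags, homology = min_substitutions(
      cd$mature_seq, params$homology_matures) <= params$homology_max_subst)
  }
  list(accept = all(flags), flags = flags)
}

# Minimal substitution count between a tag and any reference mature over
# all equal-length sliding alignments (no indels).
min_substitutions <- function(tag, matures) {
  tag <- norm_dna(tag)
  matures <- norm_dna(matures)
  tv <- strsplit(tag, "")[[1]]
  best <- Inf
  for (m in matures) {
    mv <- strsplit(m, "")[[1]]
    short <- if (length(tv) <= length(mv)) tv else mv
    long <- if (length(tv) <= length(mv)) mv else tv
    k <- length(long) - length(short)
    for (off in 0:k) {
      d <- sum(short != long[(1 + off):(off + length(short))]) +
        k  # unaligned overhang counts as substitutions
      best <- min(best, d)
    }
  }
  best
}

#' Evaluate a precursor window against the candidate criteria
#'
#' Folds the window, measures the miRNA/miRNA* duplex for a mature at a
#' known position, computes MFEI and A+U content, and applies the criteria.
#'
#' @param sequence precursor window sequence.
#' @param mature_start 1-based start of the mature within the window.
#' @param mature_len mature length in nt.
#' @param params parameter list from [novel_params()].
#' @param fold optional precomputed fold result for `sequence`.
#' @return list with `accept`, `flags`, `metrics` (duplex metrics, MFE,
#'   MFEI, A+U) and the fold result.
#' @export
evaluate_hairpin <- function(sequence, mature_start, mature_len,
                             params = novel_params(), fold = NULL) {
  if (is.null(fold)) fold <- fold_precursor(sequence)
  me <- mature_start + mature_len - 1L
  dup <- measure_duplex(fold, mature_start, me)
  cand <- c(dup, list(
    mfe = fold$mfe,
    mfei = compute_mfei(sequence, fold$mfe),
    au = au_fraction(sequence),
    mature_len = mature_len,
    star_len = if (is.na(dup$star_start)) NA_integer_ else
      dup$star_end - dup$star_start + 1L,
    mature_seq = substr(sequence, mature_start, me)
  ))
  crit <- apply_criteria(cand, params)
  list(accept = crit$accept, flags = crit$flags, metrics = cand, fold = fold)
}

#' Excise candidate precursor windows around unannotated hits
#'
#' For each genome hit of an unannotated tag, two windows are generated so
#' the star arm can lie on either side of the mature: one extending
#' `max_space + flank` downstream (mature on the 5' arm) and one extending
#' the same amount upstream (mature on the 3' arm), each with the `flank`
#' on the near side. Windows truncated at a chromosome edge are flagged.
#' Tags with more than `max_copies` genomic copies are excluded.
#'
#' @param hits data.frame of genome hits (columns `tag`, `chrom`, `start`,
#'   `end` 0-based half-open, `strand`, `copy_number`) as produced by
#'   [map_to_genome()].
#' @param genome named character vector of chromosome sequences.
#' @param params parameter list from [novel_params()].
#' @return data.frame of windows with fold-orientation coordinates: `seq`
#'   (already reverse-complemented for minus-strand hits), `mature_offset`
#'   (1-based within `seq`), genomic `win_start`/`win_end`, `arm`,
#'   `truncated`.
#' @export
excise_windows <- function(hits, genome, params = novel_params()) {
  hits <- hits[hits$copy_number <= params$max_copies, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    clen <- nchar(genome[[h$chrom]])
    for (arm in c("5p", "3p")) {
      # genomic extension direction depends on strand and arm
      right <- (arm == "5p") == (h$strand == "+")
      if (right) {
        ws <- h$start - params$flank
        we <- h$end + params$max_space + params$flank
      } else {
        ws <- h$start - params$max_space - params$flank
        we <- h$end + params$flank
      }
      truncated <- ws < 0 || we > clen
      ws <- max(0L, ws); we <- min(clen, we)
      seq <- substr(genome[[h$chrom]], ws + 1L, we)
      if (h$strand == "+") {
        off <- h$start - ws + 1L
      } else {
        seq <- revcomp(seq)
        off <- we - h$end + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        tag = h$tag, chrom = h$chrom, hit_start = h$start, hit_end = h$end,
        strand = h$strand, arm = arm, win_start = ws, win_end = we,
        mature_offset = off, truncated = truncated, seq = seq,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(tag = character(), chrom = character(),
                      hit_start = integer(), hit_end = integer(),
                      strand = character(), arm = character(),
                      win_start = integer(), win_end = integer(),
                      mature_offset = integer(), truncated = logical(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Predict novel miRNAs from unannotated genome-mapped tags
#'
#' End-to-end composition of window excision, folding, duplex measurement
#' and criteria filtering. Each candidate window is folded once to locate
#' the star arm; the minimal precursor (mature-to-star span plus flanks) is
#' then re-excised and re-folded, and the criteria are applied to that
#' precursor. Accepted candidates whose precursors overlap on the same
#' chromosome are deduplicated to the lowest-MFE candidate (ties broken by
#' leftmost coordinate).
#'
#' @param genome named character vector of chromosome sequences.
#' @param hits unannotated-tag genome hits (see [excise_windows()]).
#' @param counts optional data.frame with per-tag library support (columns
#'   `sequence`, `count_control`, `count_treatment`).
#' @param params parameter list from [novel_params()].
#' @return data.frame of accepted novel miRNAs: precursor coordinates and
#'   sequence, dot-bracket structure, mature and star sequences, MFE, MFEI,
#'   A+U fraction, duplex metrics and per-library read support.
#' @export
predict_novel <- function(genome, hits, counts = NULL,
                          params = novel_params()) {
  empty <- data.frame(
    tag = character(), chrom = character(), strand = character(),
    precursor_start = integer(), precursor_end = integer(),
    precursor_seq = character(), structure = character(),
    mature_seq = character(), star_seq = character(),
    mfe = numeric(), mfei = numeric(), au = numeric(),
    n_base_pairs = integer(), n_mismatches = integer(),
    max_bulge = integer(), asymmetry = integer(), spacing = integer(),
    count_control = integer(), count_treatment = integer(),
    stringsAsFactors = FALSE)
  win <- excise_windows(hits, genome, params)
  if (nrow(win) == 0) return(empty)
  folds <- rna_fold(win$seq)
  # stage 1: locate the star inside each wide window
  prec <- list()
  for (i in seq_len(nrow(win))) {
    w <- win[i, ]
    mlen <- nchar(w$tag)
    me <- w$mature_offset + mlen - 1L
    if (me > nchar(w$seq) || w$mature_offset < 1) next
    dup <- measure_duplex(folds[i, ], w$mature_offset, me)
    if (dup$n_base_pairs == 0 || is.na(dup$star_start)) next
    if (dup$spacing > params$max_space) next
    lo <- max(1L, min(w$mature_offset, dup$star_start) - params$flank)
    hi <- min(nchar(w$seq), max(me, dup$star_end) + params$flank)
    pseq <- substr(w$seq, lo, hi)
    if (nchar(pseq) < 40) next
    prec[[length(prec) + 1L]] <- cbind(
      w, p_lo = lo, p_hi = hi, p_seq = pseq,
      p_moff = w$mature_offset - lo + 1L, stringsAsFactors = FALSE)
  }
  if (length(prec) == 0) return(empty)
  prec <- do.call(rbind, prec)
  # stage 2: re-fold the minimal precursor and apply the criteria
  pfolds <- rna_fold(prec$p_seq)
  acc <- list()
  for (i in seq_len(nrow(prec))) {
    p <- prec[i, ]
    mlen <- nchar(p$tag)
    ev <- evaluate_hairpin(p$p_seq, p$p_moff, mlen, params,
                           fold = as.list(pfolds[i, ]))
    if (!ev$accept) next
    # precursor genomic interval (fold orientation -> genome)
    if (p$strand == "+") {
      gs <- p$win_start + p$p_lo - 1L
      ge <- p$win_start + p$p_hi
    } else {
      n <- p$win_end - p$win_start
      gs <- p$win_start + (n - p$p_hi)
      ge <- p$win_start + (n - p$p_lo + 1L)
    }
    acc[[length(acc) + 1L]] <- data.frame(
      tag = p$tag, chrom = p$chrom, strand = p$strand,
      precursor_start = gs, precursor_end = ge,
      precursor_seq = ev$fold$sequence, structure = ev$fold$structure,
      mature_seq = norm_rna(p$tag), star_seq = ev$metrics$star_seq,
      mfe = ev$fold$mfe, mfei = ev$metrics$mfei, au = ev$metrics$au,
      n_base_pairs = ev$metrics$n_base_pairs,
      n_mismatches = ev$metrics$n_mismatches,
      max_bulge = ev$metrics$max_bulge, asymmetry = ev$metrics$asymmetry,
      spacing = ev$metrics$spacing, stringsAsFactors = FALSE)
  }
  if (length(acc) == 0) return(empty)
  acc <- do.call(rbind, acc)
  acc <- dedup_overlapping(acc)
  if (!is.null(counts)) {
    m <- match(norm_dna(acc$tag), norm_dna(counts$sequence))
    acc$count_control <- counts$count_control[m]
    acc$count_treatment <- counts$count_treatment[m]
  } else {
    acc$count_control <- NA_integer_
    acc$count_treatment <- NA_integer_
  }
  rownames(acc) <- NULL
  acc
}

# Keep the lowest-MFE candidate among precursors that overlap on the same
# chromosome (any strand); ties broken by leftmost start.
dedup_overlapping <- function(acc) {
  ord <- order(acc$mfe, acc$precursor_start)
  acc <- acc[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(acc))
  for (i in seq_len(nrow(acc))) {
    if (!keep[i]) next
    if (i == nrow(acc)) break
    j <- (i + 1):nrow(acc)
    ov <- keep[j] & acc$chrom[j] == acc$chrom[i] &
      acc$precursor_start[j] < acc$precursor_end[i] &
      acc$precursor_end[j] > acc$precursor_start[i]
    keep[j][ov] <- FALSE
  }
  acc <- acc[keep, , drop = FALSE]
  acc[order(acc$chrom, acc$precursor_start), , drop = FALSE]
}
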