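# Plant miRNA target prediction: penalty-based complementarity scoring
# over transcript windows, inhibition-mode classification by central
# mismatch position, and target-site accessibility (UPE).

#' Target-prediction parameters
#'
#' The published threshold set: maximum expectation 3.0, complementarity
#' scoring span under 20 nt (the miRNA length), UPE below 25 kcal/mol with
#' 17 nt upstream / 13 nt downstream accessibility flanks, and central
#' mismatches at miRNA positions 9--11 indicating translational
#' inhibition. Penalty weights follow the established plant target-scoring
#' scheme: mismatch 1, G:U wobble 0.5, gap 2, doubled inside the seed
#' (miRNA positions 2--13).
#'
#' @param ... overrides for individual parameters.
#' @return named list of parameters.
#' @export
target_params <- function(...) {
  p <- list(max_expectation = 3.0,
            w_mismatch = 1, w_wobble = 0.5, w_gap = 2,
            seed_range = c(2L, 13L), seed_multiplier = 2,
            central_range = c(9L, 11L),
            max_gaps = 1L,
            upe_max = 25, flank_up = 17L, flank_down = 13L,
            use_upe = NULL)  # NULL: on when the folding engine is present
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stopf("target_params: unknown parameter(s): %s",
                         paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

# pair class of miRNA base (RNA, 5'->3') vs target base at the opposing
# position: 2 = Watson-Crick, 1 = G:U wobble, 0 = mismatch
pair_class <- function(m, t) {
  wc <- (m == "A" & t == "T") | (m == "U" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G")
  wo <- (m == "G" & t == "T") | (m == "U" & t == "G")
  ifelse(wc, 2L, ifelse(wo, 1L, 0L))
}

#' Score a miRNA against one target-site window
#'
#' Penalty score over the antiparallel miRNA/target duplex: miRNA position
#' i (from the 5' end) faces target position (window length - i + 1).
#' Mismatch costs 1, G:U wobble 0.5, gap 2; penalties are doubled within
#' the seed (miRNA positions 2--13). Lower is better; 0 is perfect
#' complementarity. Windows one nucleotide longer or shorter than the
#' miRNA are aligned with a single gap at the best position. Ambiguous
#' bases score as mismatches.
#'
#' @param mirna mature miRNA sequence (5'->3').
#' @param window target-site sequence (5'->3', same length as the miRNA,
#'   or +/- 1 when one gap is allowed).
#' @param params parameters from [target_params()].
#' @return list with `expectation`, `classes` (per-miRNA-position pair
#'   class: 2 WC, 1 wobble, 0 mismatch, -1 gap) and a 3-line `alignment`
#'   string.
#' @export
score_site <- function(mirna, window, params = target_params()) {
  m <- strsplit(norm_rna(mirna), "")[[1]]
  t_rev <- rev(strsplit(norm_dna(window), "")[[1]])  # target base facing each miRNA position
  lm <- length(m); lt <- length(t_rev)
  weight <- rep(1, lm)
  sr <- params$seed_range
  weight[seq_len(lm) >= sr[1] & seq_len(lm) <= sr[2]] <- params$seed_multiplier
  score_ungapped <- function(tv) {
    cls <- pair_class(m, tv)
    pen <- ifelse(cls == 2L, 0, ifelse(cls == 1L, params$w_wobble,
                                       params$w_mismatch))
    list(expectation = sum(pen * weight), classes = cls)
  }
  if (lt == lm) {
    best <- score_ungapped(t_rev)
  } else if (abs(lt - lm) == 1 && params$max_gaps >= 1) {
    best <- NULL
    if (lt == lm + 1) {
      # extra target base: bulge in the target, try every deletion point
      for (g in seq_len(lt)) {
        sc <- score_ungapped(t_rev[-g])
        gpos <- min(g, lm)
        sc$expectation <- sc$expectation + params$w_gap * weight[gpos]
        if (is.null(best) || sc$expectation < best$expectation) best <- sc
      }
    } else {
      # missing target base: gap opposite one miRNA position
      for (g in seq_len(lm)) {
        tv <- append(t_rev, "-", after = g - 1L)
        cls <- pair_class(m, tv)
        cls[g] <- -1L
        pen <- ifelse(cls == 2L, 0, ifelse(cls == 1L, params$w_wobble,
                                           params$w_mismatch))
        pen[g] <- params$w_gap
        e <- sum(pen * weight)
        if (is.null(best) || e < best$expectation) {
          best <- list(expectation = e, classes = cls)
        }
      }
    }
  } else {
    stopf("score_site: window length must equal the miRNA length (+/- %d)",
          params$max_gaps)
  }
  best$alignment <- alignment_string(m, best$classes)
  best
}

alignment_string <- function(m, cls) {
  sym <- ifelse(cls == 2L, "|", ifelse(cls == 1L, "o",
                                       ifelse(cls == -1L, "-", " ")))
  paste0("miRNA  5' ", paste(m, collapse = ""), " 3'\n",
         "          ", paste(sym, collapse = ""), "\n")
}

#' Scan transcripts for miRNA target sites
#'
#' Slides the miRNA over every ungapped window of each transcript, keeps
#' windows whose expectation does not exceed the threshold, classifies the
#' inhibition mode, optionally filters by target-site accessibility (UPE),
#' and deduplicates overlapping candidate sites to the best-scoring one.
#' Gapped alignments of individual sites are available via [score_site()].
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param params parameters from [target_params()].
#' @return data.frame of target sites: `mirna`, `transcript`, `start`,
#'   `end` (1-based inclusive on the transcript), `expectation`, `upe`
#'   (NA when the engine is unavailable), `mode`, `alignment`.
#' @export
scan_transcripts <- function(mirnas, transcripts, params = target_params()) {
  if (length(transcripts) == 0) stopf("scan_transcripts: empty transcriptome")
  upe_auto <- is.null(params$use_upe)
  use_upe <- params$use_upe %||% folding_engine_available()
  out <- list()
  for (mi in seq_along(mirnas)) {
    mirna <- norm_rna(mirnas[[mi]])
    mname <- names(mirnas)[mi] %||% paste0("mirna_", mi)
    for (ti in seq_along(transcripts)) {
      tseq <- norm_dna(transcripts[[ti]])
      tname <- names(transcripts)[ti] %||% paste0("tx_", ti)
      cand <- scan_one(mirna, tseq, params)
      if (nrow(cand) == 0) next
      cand$mirna <- mname
      cand$transcript <- tname
      out[[length(out) + 1L]] <- cand
    }
  }
  if (length(out) == 0) return(empty_sites())
  sites <- do.call(rbind, out)
  sites <- dedup_sites(sites)
  sites$mode <- vapply(sites$classes, classify_mode_classes,
                       character(1), params = params)
  sites$upe <- NA_real_
  if (use_upe && nrow(sites) > 0) {
    for (i in seq_len(nrow(sites))) {
      sites$upe[i] <- compute_upe(transcripts[[sites$transcript[i]]],
                                  sites$start[i], sites$end[i],
                                  flank_up = params$flank_up,
                                  flank_down = params$flank_down)
    }
    sites <- sites[sites$upe < params$upe_max, , drop = FALSE]
  } else if (!use_upe && upe_auto) {
    warning("folding engine unavailable: UPE not computed, ",
            "accessibility filter skipped", call. = FALSE)
  }
  sites$classes <- NULL
  rownames(sites) <- NULL
  sites[, c("mirna", "transcript", "start", "end", "expectation", "upe",
            "mode", "alignment")]
}

empty_sites <- function() {
  data.frame(mirna = character(), transcript = character(),
             start = integer(), end = integer(), expectation = numeric(),
             upe = numeric(), mode = character(), alignment = character(),
             stringsAsFactors = FALSE)
}

# vectorized ungapped scan of one miRNA over one transcript
scan_one <- function(mirna, tseq, params) {
  m <- strsplit(mirna, "")[[1]]
  lm <- length(m)
  lt <- nchar(tseq)
  if (lt < lm) {
    return(data.frame(start = integer(), end = integer(),
                      expectation = numeric(), alignment = character(),
                      classes = I(list()), stringsAsFactors = FALSE))
  }
  tv <- strsplit(tseq, "")[[1]]
  starts <- seq_len(lt - lm + 1L)
  weight <- rep(1, lm)
  sr <- params$seed_range
  weight[seq_len(lm) >= sr[1] & seq_len(lm) <= sr[2]] <- params$seed_multiplier
  # miRNA position i faces target position start + lm - i
  pen <- matrix(0, nrow = length(starts), ncol = lm)
  for (i in seq_len(lm)) {
    tb <- tv[starts + (lm - i)]
    cls <- pair_class(m[i], tb)
    pen[, i] <- ifelse(cls == 2L, 0,
                       ifelse(cls == 1L, params$w_wobble,
                              params$w_mismatch)) * weight[i]
  }
  e <- rowSums(pen)
  hit <- which(e <= params$max_expectation)
  rows <- lapply(hit, function(h) {
    sc <- score_site(mirna, substr(tseq, starts[h], starts[h] + lm - 1L),
                     params)
    data.frame(start = starts[h], end = starts[h] + lm - 1L,
               expectation = sc$expectation, alignment = sc$alignment,
               classes = I(list(sc$classes)), stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      expectation = numeric(), alignment = character(),
                      classes = I(list()), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# best site per (mirna, transcript, overlapping interval)
dedup_sites <- function(sites) {
  ord <- order(sites$mirna, sites$transcript, sites$expectation, sites$start)
  sites <- sites[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (!keep[i] || i == nrow(sites)) next
    j <- (i + 1):nrow(sites)
    ov <- keep[j] & sites$mirna[j] == sites$mirna[i] &
      sites$transcript[j] == sites$transcript[i] &
      sites$start[j] <= sites$end[i] & sites$end[j] >= sites$start[i]
    keep[j][ov] <- FALSE
  }
  sites[keep, , drop = FALSE]
}

#' Classify a target site as cleavage or translational inhibition
#'
#' Translational inhibition iff a true mismatch or gap (wobbles pair)
#' falls at a central miRNA position (9--11 by default); otherwise the
#' site is called cleavage.
#'
#' @param site a site scored by [score_site()] (list with `classes`), or a
#'   raw classes vector.
#' @param params parameters from [target_params()].
#' @return `"cleavage"` or `"translational_inhibition"`.
#' @export
classify_mode <- function(site, params = target_params()) {
  cls <- if (is.list(site) && !is.null(site$classes)) site$classes else site
  classify_mode_classes(cls, params)
}

classify_mode_classes <- function(cls, params) {
  cr <- params$central_range
  central <- cls[seq_along(cls) >= cr[1] & seq_along(cls) <= cr[2]]
  if (any(central <= 0L)) "translational_inhibition" else "cleavage"
}

#' Target-site accessibility (UPE)
#'
#' Energy to unpair the target site in its local context: the transcript
#' window spanning the site plus `flank_up` nt upstream and `flank_down`
#' nt downstream is folded with and without the site constrained
#' single-stranded; UPE is the free-energy difference.
#'
#' @param transcript transcript sequence.
#' @param site_start,site_end 1-based inclusive site interval.
#' @param flank_up,flank_down accessibility flanks in nt.
#' @return UPE in kcal/mol, or NA when the folding engine is unavailable.
#' @export
compute_upe <- function(transcript, site_start, site_end,
                        flank_up = 17L, flank_down = 13L) {
  if (!folding_engine_available()) return(NA_real_)
  lt <- nchar(transcript)
  lo <- max(1L, site_start - flank_up)
  hi <- min(lt, site_end + flank_down)
  ctx <- substr(transcript, lo, hi)
  unpairing_energy(ctx, site_start - lo + 1L, site_end - lo + 1L)
}
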