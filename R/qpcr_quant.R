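# Relative quantification of qPCR Ct tables by the delta-delta-Ct method
# against an internal reference gene (ef1a in the source design), with
# replicate summaries and sequencing-concordance reporting.

#' Per-replicate delta-Ct against the reference gene
#'
#' Technical replicates are averaged within each biological replicate
#' first; then delta-Ct = Ct(assay) - Ct(reference) per (condition,
#' biological replicate). Assumes 100% amplification efficiency (the
#' delta-delta-Ct model).
#'
#' @param ct data.frame with columns `id`, `condition` (control/
#'   treatment), `bio_rep`, `tech_rep`, `ct` (cycles, > 0).
#' @param reference id of the internal reference gene (default `"ef1a"`).
#' @return data.frame `id`, `condition`, `bio_rep`, `dct`.
#' @export
delta_ct <- function(ct, reference = "ef1a") {
  stopifnot(all(c("id", "condition", "bio_rep", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stopf("delta_ct: Ct values must be positive")
  if (!reference %in% ct$id) {
    stopf("delta_ct: reference gene '%s' not in the Ct table", reference)
  }
  agg <- stats::aggregate(ct ~ id + condition + bio_rep, data = ct, FUN = mean)
  ref <- agg[agg$id == reference, c("condition", "bio_rep", "ct")]
  names(ref)[3] <- "ct_ref"
  out <- merge(agg[agg$id != reference, ], ref,
               by = c("condition", "bio_rep"), all.x = TRUE)
  if (anyNA(out$ct_ref)) {
    bad <- out[is.na(out$ct_ref), ][1, ]
    stopf("delta_ct: no reference Ct for condition '%s', replicate %s",
          bad$condition, bad$bio_rep)
  }
  out$dct <- out$ct - out$ct_ref
  out[order(out$id, out$condition, out$bio_rep),
      c("id", "condition", "bio_rep", "dct")]
}

#' Relative fold changes by delta-delta-Ct
#'
#' delta-delta-Ct = delta-Ct(treatment) - delta-Ct(control), paired by
#' biological replicate; fold change = 2^-ddCt per replicate, reported as
#' mean and SD over biological replicates. log2(fold change) = -ddCt
#' exactly.
#'
#' @param dct data.frame from [delta_ct()].
#' @return data.frame `id`, `fold_change` (mean), `sd`, `n` (biological
#'   replicates), `log2_fold` (mean of per-replicate log2 folds).
#' @export
ddct_fold_change <- function(dct) {
  ids <- unique(dct$id)
  rows <- lapply(ids, function(g) {
    d <- dct[dct$id == g, ]
    ctrl <- d[d$condition == "control", ]
    trt <- d[d$condition == "treatment", ]
    reps <- intersect(ctrl$bio_rep, trt$bio_rep)
    if (length(reps) == 0) {
      stopf("ddct_fold_change: no paired replicates for '%s'", g)
    }
    ddct <- trt$dct[match(reps, trt$bio_rep)] -
      ctrl$dct[match(reps, ctrl$bio_rep)]
    folds <- 2^(-ddct)
    data.frame(id = g, fold_change = mean(folds),
               sd = if (length(folds) > 1) stats::sd(folds) else 0,
               n = length(folds), log2_fold = mean(-ddct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Builds a Ct table in which each assay's true treatment/control fold
#' change is specified, with optional Gaussian Ct noise; the noiseless
#' table inverts exactly under [ddct_fold_change()].
#'
#' @param true_folds named numeric vector of treatment/control fold
#'   changes per assay.
#' @param n_bio,n_tech biological and technical replicates (3 x 2 by
#'   default).
#' @param noise_sd Gaussian Ct noise standard deviation (cycles).
#' @param base_ct,ref_ct control-condition assay and reference Ct levels.
#' @param reference reference gene id.
#' @param seed RNG seed (only used when noise_sd > 0).
#' @return Ct table data.frame for [delta_ct()].
#' @export
simulate_ct_table <- function(true_folds, n_bio = 3L, n_tech = 2L,
                              noise_sd = 0, base_ct = 25, ref_ct = 20,
                              reference = "ef1a", seed = 1L) {
  build <- function() {
    rows <- list()
    for (cond in c("control", "treatment")) {
      for (b in seq_len(n_bio)) {
        for (te in seq_len(n_tech)) {
          assay_ct <- rep(base_ct, length(true_folds))
          if (cond == "treatment") assay_ct <- assay_ct - log2(true_folds)
          rows[[length(rows) + 1L]] <- data.frame(
            id = c(reference, names(true_folds)),
            condition = cond, bio_rep = b, tech_rep = te,
            ct = c(ref_ct, assay_ct),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    if (noise_sd > 0) out$ct <- out$ct + stats::rnorm(nrow(out), 0, noise_sd)
    out
  }
  if (noise_sd > 0) withr::with_seed(seed, build()) else build()
}

#' Concordance between qPCR, sequencing and target expression
#'
#' For each miRNA, flags whether (a) the qPCR direction matches the
#' sequencing regulation call and (b) the miRNA and its predicted target
#' move in opposite directions in qPCR. miRNAs with both flags true are
#' the potential stress-responsive set.
#'
#' @param mirna_folds data.frame from [ddct_fold_change()] for the
#'   miRNAs.
#' @param target_folds data.frame from [ddct_fold_change()] for the
#'   target genes.
#' @param pairs data.frame `mirna`, `target` linking each miRNA to its
#'   predicted target gene.
#' @param seq_calls data.frame `mirna`, `call` (up/down) from sequencing.
#' @return data.frame `mirna`, `target`, `mirna_direction`,
#'   `target_direction`, `seq_call`, `matches_sequencing`,
#'   `anticorrelated_with_target`, `drought_responsive`.
#' @export
concordance_report <- function(mirna_folds, target_folds, pairs, seq_calls) {
  dir_of <- function(lf) ifelse(lf > 0, "up", ifelse(lf < 0, "down", "flat"))
  m <- match(pairs$mirna, mirna_folds$id)
  t <- match(pairs$target, target_folds$id)
  s <- match(pairs$mirna, seq_calls$mirna)
  mdir <- dir_of(mirna_folds$log2_fold[m])
  tdir <- dir_of(target_folds$log2_fold[t])
  scall <- as.character(seq_calls$call[s])
  out <- data.frame(
    mirna = pairs$mirna, target = pairs$target,
    mirna_direction = mdir, target_direction = tdir, seq_call = scall,
    matches_sequencing = !is.na(scall) & mdir == scall,
    anticorrelated_with_target = (mdir == "up" & tdir == "down") |
      (mdir == "down" & tdir == "up"),
    stringsAsFactors = FALSE)
  out$drought_responsive <- out$matches_sequencing &
    out$anticorrelated_with_target
  out
}
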