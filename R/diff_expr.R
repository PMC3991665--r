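# Count-based differential expression between two libraries: TPM
# normalization, log2 fold changes with a pseudo-value for zeros, and the
# Audic-Claverie exact count test.

#' Tags-per-million normalization
#'
#' normalized expression = count / library clean-read total x 10^6.
#'
#' @param count integer vector of raw tag/miRNA counts.
#' @param library_total total clean reads in the library (> 0).
#' @return numeric TPM vector.
#' @export
normalize_tpm <- function(count, library_total) {
  if (length(library_total) != 1 || is.na(library_total) ||
      library_total <= 0) {
    stopf("normalize_tpm: library_total must be a single positive count")
  }
  if (any(count < 0)) stopf("normalize_tpm: negative counts")
  count / library_total * 1e6
}

#' Log2 fold change of treatment over control TPM
#'
#' Zero TPMs are replaced by a pseudo-value (0.01 TPM by default) for the
#' ratio only, so a miRNA absent from both libraries has fold change
#' exactly 0.
#'
#' @param tpm_treatment,tpm_control numeric TPM vectors.
#' @param pseudo pseudo-TPM substituted for zeros.
#' @return numeric log2(treatment/control).
#' @export
fold_change <- function(tpm_treatment, tpm_control, pseudo = 0.01) {
  log2(pmax(tpm_treatment, pseudo) / pmax(tpm_control, pseudo))
}

#' Audic-Claverie probability of observing y given x
#'
#' The exact count statistic for two libraries of depths N1 (where x was
#' seen) and N2 (where y was seen):
#' p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1)),
#' evaluated in log space so counts up to 10^7 are stable.
#'
#' @param y,x non-negative counts (vectorized over `y`).
#' @param n1,n2 library totals.
#' @param log return the log probability.
#' @return numeric probabilities.
#' @export
ac_pmf <- function(y, x, n1, n2, log = FALSE) {
  if (any(c(x, y) < 0)) stopf("ac_pmf: negative counts")
  if (n1 <= 0 || n2 <= 0) stopf("ac_pmf: library totals must be positive")
  r <- n2 / n1
  lp <- y * base::log(r) + lgamma(x + y + 1) - lgamma(x + 1) -
    lgamma(y + 1) - (x + y + 1) * log1p(r)
  if (log) lp else exp(lp)
}

#' Two-sided exact test for a count difference between two libraries
#'
#' The default (`tail = "conditional"`) conditions on the observed total
#' t = x + y: under the null of equal underlying proportions, x follows
#' Binomial(t, N1/(N1+N2)), and the two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed one.
#' This is the classic exact two-Poisson-sample test, asymptotically
#' equivalent to the Audic-Claverie statistic, and is exactly invariant
#' under swapping the libraries (x, N1) <-> (y, N2).
#'
#' `tail = "ac_minlik"` instead keeps the Audic-Claverie conditional
#' p(.|x) of [ac_pmf()] and sums p(y'|x) over all y' whose probability
#' does not exceed that of the observed y; this variant is not exactly
#' swap-symmetric (p(y|x; N1, N2) = (N2/N1) p(x|y; N2, N1)).
#'
#' @param x,y observed counts in the two libraries (vectorized, recycled).
#' @param n1,n2 library totals.
#' @param tail two-sided tail definition, `"conditional"` or
#'   `"ac_minlik"`.
#' @return numeric p-values in \[0, 1\].
#' @export
ac_test <- function(x, y, n1, n2, tail = c("conditional", "ac_minlik")) {
  tail <- match.arg(tail)
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  vapply(seq_len(n), function(i) ac_test_one(x[i], y[i], n1, n2, tail),
         numeric(1))
}

ac_test_one <- function(x, y, n1, n2, tail) {
  if (tail == "conditional") {
    t <- x + y
    if (t == 0) return(1)
    q <- n1 / (n1 + n2)
    # only the central quantile range carries mass; both excluded tails are
    # at least as extreme as the observation, so they join the sum
    lo <- max(0, stats::qbinom(1e-16, t, q) - 10)
    hi <- min(t, stats::qbinom(1e-16, t, q, lower.tail = FALSE) + 10)
    ks <- lo:hi
    pm <- stats::dbinom(ks, t, q)
    p_obs <- stats::dbinom(x, t, q)
    return(min(1, sum(pm[pm <= p_obs * (1 + 1e-9)]) +
                 stats::pbinom(lo - 1, t, q) +
                 stats::pbinom(hi, t, q, lower.tail = FALSE)))
  }
  # Audic-Claverie minimum-likelihood tail over p(.|x): p(.|x) has the
  # shape of a negative binomial with size x+1 and success probability
  # n1/(n1+n2), whose extreme quantiles bound the support carrying mass
  size <- x + 1
  prob <- n1 / (n1 + n2)
  lo <- max(0, stats::qnbinom(1e-16, size, prob) - 10)
  hi <- stats::qnbinom(1e-16, size, prob, lower.tail = FALSE) + 10
  lo <- min(lo, y); hi <- max(hi, y)
  ys <- lo:hi
  pm <- ac_pmf(ys, x, n1, n2)
  p_obs <- ac_pmf(y, x, n1, n2)
  min(1, sum(pm[pm <= p_obs * (1 + 1e-9)]))
}

#' Per-miRNA differential expression table
#'
#' Computes TPMs, log2 fold change (treatment/control, with the zero
#' pseudo-value), the two-sided Audic-Claverie p-value and the regulation
#' call at the 2-fold threshold for each count row.
#'
#' @param counts data.frame with an id column (first column or `id`) and
#'   integer columns `count_control`, `count_treatment`.
#' @param total_control,total_treatment library clean-read totals.
#' @param fc_threshold fold-change threshold for the up/down call
#'   (default 2).
#' @param pseudo pseudo-TPM for zeros.
#' @param adjust add a Benjamini-Hochberg adjusted p-value column.
#' @return data.frame `id`, counts, `tpm_control`, `tpm_treatment`,
#'   `log2fc`, `p_value` (and `p_adj`), `call` in {up, down, unchanged}.
#' @export
de_table <- function(counts, total_control, total_treatment,
                     fc_threshold = 2, pseudo = 0.01, adjust = FALSE) {
  id <- if ("id" %in% names(counts)) counts$id else counts[[1]]
  x <- counts$count_control
  y <- counts$count_treatment
  tpm_c <- normalize_tpm(x, total_control)
  tpm_t <- normalize_tpm(y, total_treatment)
  lfc <- fold_change(tpm_t, tpm_c, pseudo = pseudo)
  p <- ac_test(x, y, total_control, total_treatment)
  thr <- log2(fc_threshold)
  call <- ifelse(lfc >= thr, "up", ifelse(lfc <= -thr, "down", "unchanged"))
  out <- data.frame(id = id, count_control = x, count_treatment = y,
                    tpm_control = tpm_c, tpm_treatment = tpm_t,
                    log2fc = lfc, p_value = p,
                    call = factor(call, levels = c("up", "down", "unchanged")),
                    stringsAsFactors = FALSE)
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Select differentially expressed miRNAs at a fold threshold
#'
#' @param de data.frame from [de_table()].
#' @param fc_threshold fold-change threshold (default 2, i.e. |log2fc| >=
#'   1).
#' @return list with `up` and `down` data.frames, each sorted by |log2fc|
#'   descending (ties by id).
#' @export
select_differential <- function(de, fc_threshold = 2) {
  thr <- log2(fc_threshold)
  up <- de[de$log2fc >= thr, , drop = FALSE]
  down <- de[de$log2fc <= -thr, , drop = FALSE]
  up <- up[order(-abs(up$log2fc), up$id), , drop = FALSE]
  down <- down[order(-abs(down$log2fc), down$id), , drop = FALSE]
  rownames(up) <- rownames(down) <- NULL
  list(up = up, down = down)
}

#' Expression-ratio classes for the scatter plot
#'
#' Classifies each miRNA by the treatment/control expression ratio into
#' the three plotted classes: ratio > 2, 1/2 < ratio <= 2, ratio <= 1/2.
#'
#' @param de data.frame from [de_table()].
#' @return factor with levels `ratio_gt_2`, `ratio_mid`, `ratio_le_half`.
#' @export
ratio_classes <- function(de) {
  ratio <- 2^de$log2fc
  cls <- ifelse(ratio > 2, "ratio_gt_2",
                ifelse(ratio <= 0.5, "ratio_le_half", "ratio_mid"))
  factor(cls, levels = c("ratio_gt_2", "ratio_mid", "ratio_le_half"))
}
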