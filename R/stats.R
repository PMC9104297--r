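#' Pearson product-moment correlation
#'
#' Thin validated wrapper around the standard estimator: equal lengths of at
#' least 3 and non-constant inputs are required, otherwise the correlation
#' is undefined.
#'
#' @param x,y Numeric series of equal length.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  stats::cor(x, y)
}

#' Normality gate: one-sample Kolmogorov-Smirnov test
#'
#' Standardises the sample to zero mean and unit SD and applies the
#' one-sample KS test against the standard normal. The gate passes when the
#' KS p-value is at least `level`. A zero-variance sample fails with the
#' `degenerate` attribute set.
#'
#' @param sample Numeric vector, length at least 4.
#' @param level Gate level (default 0.05).
#' @return Logical flag (`TRUE` = consistent with normality) with attributes
#'   `p_value` and `degenerate`.
#' @export
normality_gate <- function(sample, level = 0.05) {
  if (length(sample) < 4) stop("need at least 4 observations", call. = FALSE)
  s <- stats::sd(sample)
  if (!(s > 0)) {
    return(structure(FALSE, p_value = NA_real_, degenerate = TRUE))
  }
  z <- (sample - mean(sample)) / s
  p <- suppressWarnings(stats::ks.test(z, "pnorm"))$p.value
  structure(p >= level, p_value = p, degenerate = FALSE)
}

#' Compare an EDA index between baseline and stress stages
#'
#' The gated two-sample procedure: each group is screened with the
#' one-sample KS [normality_gate()]; if both groups look normal a two-sided
#' paired t-test is used (observations are paired by subject), otherwise a
#' two-sided Wilcoxon rank sum test on the two groups (a signed-rank
#' fallback, which keeps the pairing, is available via `fallback`).
#'
#' @param values_baseline,values_stress Per-subject index values, paired by
#'   position; equal lengths of at least 5.
#' @param cfg An [pipeline_config()]; supplies the significance level.
#' @param fallback Non-normal fallback test: `"rank_sum"` (default) or
#'   `"signed_rank"`.
#' @return A one-row data.frame: `stat_name`, `statistic`, `p_value`,
#'   `normal_gate_passed`, `significant`.
#' @export
compare_stages <- function(values_baseline, values_stress,
                           cfg = pipeline_config(),
                           fallback = c("rank_sum", "signed_rank")) {
  fallback <- match.arg(fallback)
  if (length(values_baseline) != length(values_stress))
    stop("pairing error: groups must have equal length", call. = FALSE)
  if (length(values_baseline) < 5)
    stop("need at least 5 pairs", call. = FALSE)
  gb <- normality_gate(values_baseline)
  gs <- normality_gate(values_stress)
  gate <- isTRUE(gb) && isTRUE(gs)
  if (gate) {
    ht <- stats::t.test(values_stress, values_baseline, paired = TRUE)
    stat_name <- "paired_t"
  } else if (fallback == "rank_sum") {
    ht <- suppressWarnings(stats::wilcox.test(values_stress, values_baseline,
                                              exact = FALSE, correct = TRUE))
    stat_name <- "rank_sum"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values_stress, values_baseline,
                                              paired = TRUE, exact = FALSE,
                                              correct = TRUE))
    stat_name <- "signed_rank"
  }
  p <- unname(ht$p.value)
  # an all-ties / zero-variance comparison carries no evidence against the null
  if (is.na(p) || is.nan(p)) p <- 1
  data.frame(stat_name = stat_name, statistic = unname(ht$statistic),
             p_value = p, normal_gate_passed = gate,
             significant = p < cfg$significance_level,
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC for separating stress from baseline
#'
#' Sweeps a decision threshold over all distinct observed values (plus
#' infinite endpoints); a sample is predicted positive (stress) when its
#' value is at least the threshold. Ties share a threshold point. The AUC is
#' the trapezoidal area under the (FPR, TPR) path, which equals the
#' normalised Mann-Whitney U statistic. Indices that decrease under stress
#' yield AUC below 0.5 and are reported as-is.
#'
#' @param values_baseline,values_stress Index values for the negative
#'   (baseline) and positive (stress) class; at least 2 each.
#' @return A list of class `eda_roc`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
#' @examples
#' roc_curve(c(1, 3), c(2, 4))$auc # 0.75
roc_curve <- function(values_baseline, values_stress) {
  if (length(values_baseline) < 2 || length(values_stress) < 2)
    stop("undefined AUC: need at least 2 values per class", call. = FALSE)
  thr <- c(Inf, sort(unique(c(values_baseline, values_stress)),
                     decreasing = TRUE))
  tpr <- vapply(thr, function(h) mean(values_stress >= h), numeric(1))
  fpr <- vapply(thr, function(h) mean(values_baseline >= h), numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "eda_roc")
}

#' @export
print.eda_roc <- function(x, ...) {
  cat(sprintf("<eda_roc> AUC = %.4f over %d threshold points\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Count subjects whose site correlation exceeds a cut, per stage
#'
#' Used to track progressive hydration of a slow site: for each stage, the
#' number of subjects whose within-subject correlation with the reference
#' site is strictly greater than `cut`. Subjects missing in any stage are
#' excluded from all stages (with a warning) so counts stay comparable.
#'
#' @param entries A data.frame with columns `subject_id`, `stage`, `r`.
#' @param cut Correlation cut (strict inequality), default 0.5.
#' @param stage_order Order in which stages are reported; defaults to order
#'   of first appearance.
#' @return A data.frame with columns `stage` and `n_above`.
#' @export
hydration_progression <- function(entries, cut = 0.5, stage_order = NULL) {
  stopifnot(all(c("subject_id", "stage", "r") %in% names(entries)))
  if (is.null(stage_order)) stage_order <- unique(entries$stage)
  tab <- table(entries$subject_id)
  complete <- names(tab)[tab == length(stage_order)]
  dropped <- setdiff(unique(entries$subject_id), complete)
  if (length(dropped) > 0)
    warning("excluding subject(s) missing in some stage: ",
            paste(dropped, collapse = ", "))
  entries <- entries[entries$subject_id %in% complete, , drop = FALSE]
  n_above <- vapply(stage_order, function(st) {
    sum(entries$r[entries$stage == st] > cut)
  }, numeric(1))
  data.frame(stage = stage_order, n_above = as.integer(n_above),
             stringsAsFactors = FALSE)
}
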