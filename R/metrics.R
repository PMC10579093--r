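#' Confusion-matrix screening metrics
#'
#' Sensitivity, specificity, PPV and NPV from confusion counts. A zero
#' denominator leaves the metric undefined (`NA`). Report tables print
#' percentages rounded to one decimal, half away from zero.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return List with the four proportions plus the counts and Youden `J`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec,
       ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
       youden_j = if (is.na(sens) || is.na(spec)) NA_real_
                  else sens + spec - 1)
}

#' ROC curve and AUC
#'
#' AUC via the rank statistic (equivalent to the pairwise concordance
#' probability with ties counted 1/2). Higher scores must indicate the
#' positive class.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1/TRUE = positive).
#' @return List with `auc`, `n_pos`, `n_neg` and the ROC `curve`
#'   (`data.frame` of threshold, sensitivity, specificity).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- candidate_thresholds(scores)
  curve <- do.call(rbind, lapply(thr, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               sensitivity = sum(pred & labels == 1) / n_pos,
               specificity = sum(!pred & labels == 0) / n_neg)
  }))
  list(auc = auc, n_pos = n_pos, n_neg = n_neg, curve = curve)
}

candidate_thresholds <- function(scores) {
  u <- sort(unique(scores))
  c(u[1] - 1, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
    u[length(u)] + 1)
}

#' Hanley-McNeil standard error of an AUC
#'
#' `SE^2 = [A(1-A) + (n1-1)(Q1 - A^2) + (n2-1)(Q2 - A^2)] / (n1 n2)` with
#' `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`.
#'
#' @param auc AUC in `[0, 1]`.
#' @param n_pos,n_neg Class sizes.
#' @return The standard error, on the same scale as the AUC.
#' @export
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Hanley-McNeil confidence interval
#'
#' Normal-approximation interval, endpoints clamped to `[0, 1]`.
#'
#' @inheritParams hanley_mcneil_se
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hanley_mcneil_ci <- function(auc, n_pos, n_neg, level = 0.95) {
  se <- hanley_mcneil_se(auc, n_pos, n_neg)
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

#' Youden-optimal operating point
#'
#' Exhaustively searches the midpoints of adjacent distinct scores (plus
#' sentinels beyond both extremes) for the threshold maximizing
#' `J = sensitivity + specificity - 1`; ties break toward higher
#' sensitivity (the lower threshold).
#'
#' @inheritParams roc_auc
#' @return List with `threshold`, `youden_j` and the confusion counts and
#'   metrics at the operating point (prediction rule: `score >=
#'   threshold` is positive).
#' @export
youden_operating_point <- function(scores, labels) {
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  best <- NULL
  # ascending thresholds + strict improvement keeps the lowest threshold
  # among ties, i.e. the tie-break toward higher sensitivity
  for (t in sort(candidate_thresholds(scores))) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    j <- tp / n_pos + (n_neg - fp) / n_neg - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(t = t, j = j, tp = tp, fp = fp)
    }
  }
  cm <- confusion_metrics(best$tp, best$fp, n_neg - best$fp,
                          n_pos - best$tp)
  c(list(threshold = best$t, youden_j = best$j), cm)
}

#' Prevalence calibration context
#'
#' Packages the study and target-population prevalences used to calibrate
#' predictive values. The study publishing this pipeline printed
#' `pi_study = 49/328` (the autistic:neurotypical *ratio*); the positive
#' *fraction* of the same cohort is `49/377`. Only the fraction convention
#' makes the calibrated PPV/NPV equal the values a cohort sampled at the
#' population prevalence would produce, so both presets are available.
#'
#' @param pi_study Study prevalence in (0, 1), or a preset name
#'   (`"printed"` = 49/328, `"fraction"` = 49/377).
#' @param pi_population Target population prevalence (default 1/44, the
#'   2018 US autism prevalence).
#' @param beta F-score weight (default 1).
#' @return List with the prevalences, `beta` and the odds ratio `rho_star`.
#' @export
calibration_context <- function(pi_study = "printed",
                                pi_population = 1 / 44, beta = 1) {
  if (is.character(pi_study))
    pi_study <- switch(pi_study, printed = 49 / 328, fraction = 49 / 377,
                       stop("unknown preset: ", pi_study))
  if (pi_study <= 0 || pi_study >= 1 || pi_population <= 0 ||
      pi_population >= 1)
    stop("prevalences must be in (0, 1)")
  rho_star <- pi_study * (1 - pi_population) /
    (pi_population * (1 - pi_study))
  list(pi_study = pi_study, pi_population = pi_population, beta = beta,
       rho_star = rho_star)
}

#' Prevalence-calibrated predictive values
#'
#' Re-expresses PPV, NPV and the F-beta score at a reference population
#' prevalence through the study-to-population odds ratio
#' `rho* = pi_study (1 - pi_pop) / (pi_pop (1 - pi_study))`:
#' `PPV_C = TP / (TP + rho* FP)`,
#' `NPV_C = rho* TN / (FN + rho* TN)`, and `F_beta,C` combines the
#' calibrated precision with the (prevalence-invariant) sensitivity.
#'
#' @inheritParams confusion_metrics
#' @param context A [calibration_context()].
#' @return List with `ppv_c`, `npv_c`, `f_beta_c` and the context.
#' @export
calibrate_predictive_values <- function(tp, fp, tn, fn,
                                        context = calibration_context()) {
  r <- context$rho_star
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ppv_c <- if (tp + r * fp > 0) tp / (tp + r * fp) else NA_real_
  npv_c <- if (fn + r * tn > 0) r * tn / (fn + r * tn) else NA_real_
  b2 <- context$beta^2
  f_c <- if (!is.na(ppv_c) && !is.na(sens) && (b2 * sens + ppv_c) > 0)
    (1 + b2) * ppv_c * sens / (b2 * sens + ppv_c) else NA_real_
  list(ppv_c = ppv_c, npv_c = npv_c, f_beta_c = f_c, context = context)
}

#' Stratified diagnostic-accuracy report
#'
#' One row per stratum: n, per-class correct/incorrect counts, AUC with
#' Hanley-McNeil SE, sensitivity, specificity, and raw plus calibrated
#' PPV/NPV. By default the global Youden threshold is shared across
#' strata; `per_stratum = TRUE` re-optimizes per stratum. Strata missing a
#' class get `NA` AUC; empty strata are omitted.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (1 = positive).
#' @param strata Factor/character vector of stratum membership.
#' @param context A [calibration_context()].
#' @param per_stratum Re-optimize the operating point per stratum?
#' @param threshold Optional fixed threshold (otherwise the global Youden
#'   point).
#' @return `data.frame` with one row per stratum plus a `"(all)"` row.
#' @export
stratified_report <- function(scores, labels, strata = NULL,
                              context = calibration_context(),
                              per_stratum = FALSE, threshold = NULL) {
  labels <- as.numeric(labels)
  if (is.null(strata)) strata <- rep("(all)", length(scores))
  if (is.null(threshold))
    threshold <- youden_operating_point(scores, labels)$threshold
  levels <- unique(c("(all)", as.character(strata)))
  rows <- lapply(levels, function(s) {
    idx <- if (s == "(all)") rep(TRUE, length(scores)) else strata == s
    if (!any(idx)) return(NULL)
    sc <- scores[idx]; lb <- labels[idx]
    thr <- threshold
    auc <- se <- NA_real_
    if (length(unique(lb)) == 2) {
      r <- roc_auc(sc, lb)
      auc <- r$auc
      se <- hanley_mcneil_se(auc, r$n_pos, r$n_neg)
      if (per_stratum) thr <- youden_operating_point(sc, lb)$threshold
    }
    pred <- sc >= thr
    cm <- confusion_metrics(sum(pred & lb == 1), sum(pred & lb == 0),
                            sum(!pred & lb == 0), sum(!pred & lb == 1))
    cal <- calibrate_predictive_values(cm$tp, cm$fp, cm$tn, cm$fn, context)
    data.frame(stratum = s, n = sum(idx), n_pos = sum(lb == 1),
               n_neg = sum(lb == 0), tp = cm$tp, fp = cm$fp, tn = cm$tn,
               fn = cm$fn, threshold = thr, auc = auc, auc_se = se,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               ppv = cm$ppv, npv = cm$npv, ppv_c = cal$ppv_c,
               npv_c = cal$npv_c, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
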