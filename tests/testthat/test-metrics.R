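# confusion counts reconstructed from the published stratified report
# (per-class correct/incorrect counts); printed percentages at one decimal
table3_rows <- list(
  boys = list(tp = 33, fn = 5, tn = 123, fp = 35,
              sens = 86.8, spec = 77.8, ppv = 48.5, npv = 96.1),
  girls = list(tp = 10, fn = 1, tn = 142, fp = 28,
               sens = 90.9, spec = 83.5, ppv = 26.3, npv = 99.3),
  asd_vs_nonasd = list(tp = 40, fn = 9, tn = 343, fp = 83,
                       sens = 81.6, spec = 80.5, ppv = 32.5, npv = 97.4),
  asdddld_vs_nt = list(tp = 79, fn = 68, tn = 267, fp = 61,
                       sens = 53.7, spec = 81.4, ppv = 56.4, npv = 79.7),
  ddld_vs_nt = list(tp = 54, fn = 44, tn = 227, fp = 101,
                    sens = 55.1, spec = 69.2, ppv = 34.8, npv = 83.8))

test_that("confusion metrics reproduce the published worked examples", {
  for (nm in names(table3_rows)) {
    r <- table3_rows[[nm]]
    cm <- confusion_metrics(r$tp, r$fp, r$tn, r$fn)
    expect_equal(phenoscreen:::round_half_up(100 * cm$sensitivity, 1),
                 r$sens, info = nm)
    expect_equal(phenoscreen:::round_half_up(100 * cm$specificity, 1),
                 r$spec, info = nm)
    expect_equal(phenoscreen:::round_half_up(100 * cm$ppv, 1), r$ppv,
                 info = nm)
    expect_equal(phenoscreen:::round_half_up(100 * cm$npv, 1), r$npv,
                 info = nm)
  }
  # perfect classifier
  cm <- confusion_metrics(10, 0, 20, 0)
  expect_equal(c(cm$sensitivity, cm$specificity, cm$ppv, cm$npv),
               rep(1, 4))
  expect_equal(cm$youden_j, 1)
  # undefined metrics are missing, not zero
  expect_true(is.na(confusion_metrics(0, 0, 5, 0)$sensitivity))
  expect_error(confusion_metrics(-1, 0, 0, 0))
})

test_that("AUC: trivial cases, tie convention and brute-force equivalence", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(0, 0, 0, 1, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
  set.seed(30)
  for (i in 1:30) {
    n <- sample(8:20, 1)
    sc <- round(runif(n), 1)  # ties likely
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb)$auc, bf_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil SE: closed-form worked example and limits", {
  expect_equal(round(hanley_mcneil_se(0.899, 49, 328), 3), 0.030)
  expect_equal(hanley_mcneil_se(1, 49, 328), 0)
  ci <- hanley_mcneil_ci(0.98, 20, 50)
  expect_lte(ci[2], 1)
  expect_gte(ci[1], 0)
})

test_that("Youden operating point matches exhaustive search", {
  r <- youden_operating_point(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_equal(r$youden_j, 1)
  expect_equal(youden_operating_point(rep(1, 6),
                                      c(0, 1, 0, 1, 0, 1))$youden_j, 0)
  set.seed(31)
  for (i in 1:30) {
    n <- sample(10:30, 1)
    sc <- round(runif(n), 1)
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    fast <- youden_operating_point(sc, lb)
    slow <- bf_youden(sc, lb)
    expect_equal(fast$youden_j, slow$j, tolerance = 1e-12)
    expect_equal(fast$sensitivity, slow$sensitivity, tolerance = 1e-12)
  }
})

test_that("prevalence calibration: identity, perfect test, conventions", {
  # equal prevalences -> rho* = 1 -> calibrated equals raw
  ctx <- calibration_context(pi_study = 0.3, pi_population = 0.3)
  expect_equal(ctx$rho_star, 1)
  cal <- calibrate_predictive_values(30, 20, 40, 10, ctx)
  cm <- confusion_metrics(30, 20, 40, 10)
  expect_equal(cal$ppv_c, cm$ppv)
  expect_equal(cal$npv_c, cm$npv)
  # perfect test: calibrated values are 1 at any prevalence
  cal_p <- calibrate_predictive_values(30, 0, 40, 0,
                                       calibration_context("printed"))
  expect_equal(cal_p$ppv_c, 1)
  expect_equal(cal_p$npv_c, 1)
  expect_equal(cal_p$f_beta_c, 1)
  # presets
  expect_equal(calibration_context("printed")$pi_study, 49 / 328)
  expect_equal(calibration_context("fraction")$pi_study, 49 / 377)
  expect_error(calibration_context(pi_study = 1.2), "\\(0, 1\\)")
  # the fraction convention equals the analytic population-deployment
  # predictive values for the study-sized confusion table
  tp <- 43; fp <- 63; tn <- 265; fn <- 6
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  pi_pop <- 1 / 44
  ppv_pop <- sens * pi_pop / (sens * pi_pop + (1 - spec) * (1 - pi_pop))
  npv_pop <- spec * (1 - pi_pop) /
    (spec * (1 - pi_pop) + (1 - sens) * pi_pop)
  cal_f <- calibrate_predictive_values(
    tp, fp, tn, fn, calibration_context("fraction", pi_pop))
  expect_equal(cal_f$ppv_c, ppv_pop, tolerance = 1e-12)
  expect_equal(cal_f$npv_c, npv_pop, tolerance = 1e-12)
})

test_that("stratified report: degenerate stratum, additivity, fixture rows", {
  set.seed(32)
  sc <- runif(60)
  lb <- rbinom(60, 1, 0.4)
  # constant stratum equals the unstratified row
  rep1 <- stratified_report(sc, lb, rep("x", 60))
  expect_equal(nrow(rep1), 2)  # "(all)" + "x", identical metrics
  expect_equal(rep1$auc[1], rep1$auc[2])
  expect_equal(rep1$tp[1], rep1$tp[2])
  # two disjoint strata: confusion counts sum to the global counts
  strata <- rep(c("a", "b"), each = 30)
  rep2 <- stratified_report(sc, lb, strata)
  tot <- rep2[rep2$stratum == "(all)", ]
  expect_equal(sum(rep2$tp[rep2$stratum != "(all)"]), tot$tp)
  expect_equal(sum(rep2$fn[rep2$stratum != "(all)"]), tot$fn)
  expect_equal(sum(rep2$fp[rep2$stratum != "(all)"]), tot$fp)
  expect_equal(sum(rep2$tn[rep2$stratum != "(all)"]), tot$tn)
  # sex-stratified fixture reconstructed from the published counts
  mk <- function(r, stratum) {
    data.frame(
      score = c(rep(1, r$tp), rep(0, r$fn), rep(0, r$tn), rep(1, r$fp)),
      label = c(rep(1, r$tp + r$fn), rep(0, r$tn + r$fp)),
      stratum = stratum)
  }
  df <- rbind(mk(table3_rows$boys, "boys"), mk(table3_rows$girls, "girls"))
  rep3 <- stratified_report(df$score, df$label, df$stratum, threshold = 0.5)
  for (s in c("boys", "girls")) {
    row <- rep3[rep3$stratum == s, ]
    r <- table3_rows[[s]]
    expect_equal(phenoscreen:::round_half_up(100 * row$sensitivity, 1),
                 r$sens)
    expect_equal(phenoscreen:::round_half_up(100 * row$specificity, 1),
                 r$spec)
    expect_equal(phenoscreen:::round_half_up(100 * row$ppv, 1), r$ppv)
    expect_equal(phenoscreen:::round_half_up(100 * row$npv, 1), r$npv)
  }
})

test_that("report-table rounding is half away from zero", {
  expect_equal(phenoscreen:::round_half_up(86.85, 1), 86.9)
  expect_equal(phenoscreen:::round_half_up(-2.35, 1), -2.4)
  expect_equal(phenoscreen:::round_half_up(0.05, 1), 0.1)
})
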