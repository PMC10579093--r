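#' Default end-to-end pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param ensemble An [ensemble_config()].
#' @param contrast Diagnostic contrast (see [train_ensemble()]).
#' @param include_mchat Use the questionnaire score as a feature.
#' @param calibration A [calibration_context()].
#' @param quality_threshold Re-administration threshold.
#' @param seed Master seed applied to sub-configs lacking one.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            ensemble = ensemble_config(K = 100),
                            contrast = "asd_vs_nt",
                            include_mchat = FALSE,
                            calibration = calibration_context(),
                            quality_threshold = 0.75, seed = 1L) {
  cohort$seed <- as.integer(seed)
  ensemble$seed <- as.integer(seed)
  structure(list(cohort = cohort, ensemble = ensemble, contrast = contrast,
                 include_mchat = include_mchat, calibration = calibration,
                 quality_threshold = quality_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' simulate -> train -> attribute -> quality -> evaluate -> report. Writes
#' cohort, metrics, ROC, attribution and quality tables as CSV plus a JSON
#' manifest capturing every seed and parameter, and returns all stage
#' outputs invisibly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing files.
#' @return (Invisibly) list with `cohort`, `ensemble`, `attribution`,
#'   `quality`, `metrics`, `importance` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- generate_cohort(config$cohort)
  ens <- train_ensemble(cohort, config$contrast, config$ensemble,
                        include_mchat = config$include_mchat)
  att <- attribute(ens)
  dec <- decompose_missingness(att$phi, att$missing_mask)
  phi_norm <- normalize_attribution(att$phi)
  imp <- attribution_importance(phi_norm)
  G <- predictive_power_weights(att$phi[, app_variable_names(),
                                        drop = FALSE],
                                att$missing_mask[, app_variable_names(),
                                                 drop = FALSE])
  rho <- ifelse(is.na(as.matrix(
    cohort[cohort$child_id %in% ens$child_id, app_variable_names()])), 0, 1)
  Q <- as.numeric(rho %*% G)
  metrics <- stratified_report(ens$mean_prob, ens$y,
                               context = config$calibration)
  op <- youden_operating_point(ens$mean_prob, ens$y)
  manifest <- list(
    package_version = as.character(utils::packageVersion("phenoscreen")),
    seed = config$seed, contrast = config$contrast,
    include_mchat = config$include_mchat,
    ensemble = config$ensemble[c("K", "folds", "nrounds", "max_depth",
                                 "learning_rate", "colsample_bytree",
                                 "gamma", "lambda", "conclusive_threshold",
                                 "seed")],
    sentinel = as.list(ens$sentinel),
    calibration = config$calibration[c("pi_study", "pi_population", "beta")],
    youden_threshold = op$threshold)
  out <- list(cohort = cohort, ensemble = ens,
              attribution = list(raw = att, decomposed = dec,
                                 normalized = phi_norm),
              quality = data.frame(child_id = ens$child_id, Q = Q,
                                   readminister = Q < config$quality_threshold,
                                   stringsAsFactors = FALSE),
              metrics = metrics, importance = imp, weights = G,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    roc <- roc_auc(ens$mean_prob, ens$y)$curve
    utils::write.csv(roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
    att_tab <- data.frame(child_id = ens$child_id,
                          as.data.frame(phi_norm), check.names = FALSE)
    utils::write.csv(att_tab, file.path(out_dir, "attributions.csv"),
                     row.names = FALSE)
    utils::write.csv(imp, file.path(out_dir, "importance.csv"),
                     row.names = FALSE)
    utils::write.csv(out$quality, file.path(out_dir, "quality.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' Individualized administration report for one child
#'
#' Assembles the per-child report: quality score, prediction confidence
#' and conclusiveness, predicted label at the operating threshold, the
#' child's variable values with cohort reference quantiles (from the
#' synthetic cohort itself, labeled as such), signed normalized
#' contributions, and the missing-variable list with their missingness
#' contributions. Misclassified children render identically - the report
#' explains the prediction it made.
#'
#' @param run Output of [run_pipeline()].
#' @param child_id Child identifier.
#' @return List of class `child_report` (JSON-serializable via
#'   [jsonlite::toJSON]).
#' @export
build_child_report <- function(run, child_id) {
  ens <- run$ensemble
  i <- match(child_id, ens$child_id)
  missing_stage <- c(ensemble = is.na(i),
                     quality = !child_id %in% run$quality$child_id)
  if (any(missing_stage))
    stop("child ", child_id, " absent from stage(s): ",
         paste(names(missing_stage)[missing_stage], collapse = ", "))
  conf <- prediction_confidence(ens$votes[i, ],
                                ens$config$conclusive_threshold)
  thr <- run$manifest$youden_threshold
  vars <- app_variable_names()
  phi_n <- run$attribution$normalized[i, ]
  phi_z_raw <- run$attribution$decomposed$phi_z[i, ]
  tot <- sum(abs(run$attribution$raw$phi[i, ]))
  phi_z_n <- if (tot > 0) phi_z_raw / tot else phi_z_raw
  mask <- run$attribution$raw$missing_mask[i, vars]
  ref <- lapply(vars, function(v) {
    x <- run$cohort[[v]]
    g <- split(x, run$cohort$diagnosis)
    lapply(g, function(xx)
      as.list(stats::quantile(xx, c(0.1, 0.25, 0.5, 0.75, 0.9),
                              na.rm = TRUE)))
  })
  names(ref) <- vars
  contrib <- data.frame(
    variable = ens$feature_names,
    value = as.numeric(ens$X[i, ]) * NA^(ens$missing_mask[i, ]),
    contribution = as.numeric(phi_n),
    direction = ifelse(phi_n >= 0, "toward_autism", "toward_neurotypical"),
    stringsAsFactors = FALSE)
  structure(list(
    child_id = child_id,
    schema_version = "1.0",
    quality_score = run$quality$Q[run$quality$child_id == child_id],
    confidence_score = conf$confidence_score,
    conclusive = conf$conclusive,
    predicted_label = if (ens$mean_prob[i] >= thr) "positive" else
      "negative",
    diagnosis = ens$diagnosis[i],
    contributions = contrib,
    missing_variables = vars[mask],
    missingness_contributions = setNames(as.numeric(phi_z_n[vars][mask]),
                                         vars[mask]),
    reference_distributions = ref,
    reference_source = "synthetic cohort quantiles"), class = "child_report")
}
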