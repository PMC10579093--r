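#' Ensemble training configuration
#'
#' Hyperparameters of the K-member gradient-boosted tree ensemble. The
#' defaults follow the published analysis: K = 1000 members, stratified
#' fivefold splits reshuffled per member, 100 boosting rounds, maximum
#' tree depth 3, learning rate 0.15, 80% column subsampling per tree,
#' minimum split loss (gamma) 0.1, L2 penalty (lambda) 0.1, exact split
#' enumeration, binary logistic objective, positive-class training weight
#' equal to the imbalance ratio, and a conclusive-prediction threshold of
#' 0.8 on the vote average.
#'
#' @param K Number of ensemble members (independently shuffled 5-fold
#'   splits; each member scores every child exactly once, out of fold).
#' @param folds Number of cross-validation folds.
#' @param nrounds,max_depth,learning_rate,colsample_bytree,gamma,lambda,
#'   min_child_weight Base-learner hyperparameters.
#' @param conclusive_threshold Vote-average threshold for a conclusive
#'   prediction, in (0.5, 1].
#' @param seed Master seed; member seeds are derived by a counter-based
#'   scheme so increasing K leaves earlier members unchanged.
#' @param keep_models Keep fitted member models (needed for attribution).
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(K = 1000, folds = 5, nrounds = 100,
                            max_depth = 3, learning_rate = 0.15,
                            colsample_bytree = 0.8, gamma = 0.1,
                            lambda = 0.1, min_child_weight = 1,
                            conclusive_threshold = 0.8, seed = 1L,
                            keep_models = TRUE) {
  stopifnot(K >= 1, folds >= 2, conclusive_threshold > 0.5,
            conclusive_threshold <= 1, nrounds >= 1, max_depth >= 1,
            learning_rate > 0, colsample_bytree > 0, colsample_bytree <= 1)
  structure(as.list(environment()), class = "ensemble_config")
}

contrast_groups <- function(contrast) {
  switch(contrast,
    asd_vs_nt = list(pos = "ASD", neg = "NT"),
    asd_vs_nonasd = list(pos = "ASD", neg = c("NT", "DDLD")),
    asdddld_vs_nt = list(pos = c("ASD", "DDLD"), neg = "NT"),
    ddld_vs_nt = list(pos = "DDLD", neg = "NT"),
    asd_vs_ddld = list(pos = "ASD", neg = "DDLD"),
    stop("unknown contrast: ", contrast))
}

# out-of-range sentinel encoding for missing cells: strictly below every
# observed value of each variable
encode_missing <- function(X) {
  sent <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    obs <- v[is.finite(v)]
    if (length(obs) == 0) { lo <- 0; rng <- 1 } else {
      lo <- min(obs); rng <- max(obs) - lo
    }
    sent[j] <- lo - 10 * max(rng, 1)
    X[!is.finite(v), j] <- sent[j]
  }
  list(X = X, sentinel = setNames(sent, colnames(X)))
}

stratified_folds <- function(strata, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(strata))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  })
}

#' Train the K-member gradient-boosted ensemble
#'
#' Each member uses an independently shuffled fivefold split stratified by
#' the full three-group diagnosis; its models are trained on four folds
#' and score only the held-out fold, so every child receives exactly one
#' out-of-fold probability per member. Missing cells are sentinel-encoded
#' out of range so split search can treat missingness as information;
#' positive training instances are weighted by the negative:positive
#' imbalance ratio of each training split.
#'
#' @param cohort Cohort `data.frame` (from [generate_cohort()] or
#'   [read_cohort_csv()]).
#' @param contrast One of `"asd_vs_nt"`, `"asd_vs_nonasd"`,
#'   `"asdddld_vs_nt"`, `"ddld_vs_nt"`, `"asd_vs_ddld"`.
#' @param config An [ensemble_config()].
#' @param include_mchat Add the questionnaire score as a 24th feature.
#' @return An object of class `st_ensemble` with out-of-fold probability
#'   and vote matrices (`n x K`), mean probabilities, confidence scores,
#'   fold bookkeeping and (optionally) the fitted member models.
#' @export
train_ensemble <- function(cohort, contrast = "asd_vs_nt",
                           config = ensemble_config(),
                           include_mchat = FALSE) {
  stopifnot(inherits(config, "ensemble_config"))
  grp <- contrast_groups(contrast)
  keep <- cohort$diagnosis %in% c(grp$pos, grp$neg)
  df <- cohort[keep, , drop = FALSE]
  y <- as.numeric(df$diagnosis %in% grp$pos)
  if (length(unique(y)) < 2) stop("need both classes present")
  feats <- app_variable_names()
  if (include_mchat) feats <- c(feats, "mchat_score")
  X_raw <- as.matrix(df[, feats, drop = FALSE])
  storage.mode(X_raw) <- "double"
  enc <- encode_missing(X_raw)
  X <- enc$X
  n <- nrow(X)
  K <- config$K
  prob <- matrix(NA_real_, n, K)
  fold_of <- matrix(NA_integer_, n, K)
  members <- if (config$keep_models) vector("list", K) else NULL
  strata <- df$diagnosis
  for (m in seq_len(K)) {
    seed_m <- derive_seed(config$seed, m)
    fold <- stratified_folds(strata, config$folds, seed_m)
    fold_of[, m] <- fold
    fold_models <- if (config$keep_models) vector("list", config$folds)
    for (f in seq_len(config$folds)) {
      tr <- fold != f
      w <- rep(1, sum(tr))
      n_pos <- sum(y[tr] == 1); n_neg <- sum(y[tr] == 0)
      if (n_pos == 0 || n_neg == 0)
        stop("a training split lost one class; use more data or fewer folds")
      w[y[tr] == 1] <- n_neg / n_pos
      model <- .gbt_fit_cpp(X[tr, , drop = FALSE], y[tr], w,
                            as.integer(config$nrounds),
                            as.integer(config$max_depth),
                            config$learning_rate, config$colsample_bytree,
                            config$gamma, config$lambda,
                            config$min_child_weight, 0.0,
                            derive_seed(seed_m, f))
      margin <- .gbt_predict_cpp(model, X[!tr, , drop = FALSE])
      prob[!tr, m] <- plogis(margin)
      if (config$keep_models) fold_models[[f]] <- model
    }
    if (config$keep_models) members[[m]] <- fold_models
  }
  votes <- prob >= 0.5
  structure(list(config = config, contrast = contrast,
                 child_id = df$child_id, y = y, diagnosis = df$diagnosis,
                 feature_names = feats, sentinel = enc$sentinel, X = X,
                 missing_mask = !is.finite(X_raw),
                 prob = prob, votes = votes,
                 mean_prob = rowMeans(prob),
                 confidence = rowMeans(votes),
                 fold_of = fold_of, members = members),
            class = "st_ensemble")
}

#' Prediction confidence score
#'
#' The mean of the K binary out-of-fold votes; conclusive when at least
#' `threshold` of the members agree (score `>= threshold` or
#' `<= 1 - threshold`).
#'
#' @param votes Logical/numeric vector of member votes for one child.
#' @param threshold Conclusive threshold in (0.5, 1].
#' @return List with `confidence_score` and `conclusive`.
#' @export
prediction_confidence <- function(votes, threshold = 0.8) {
  if (length(votes) == 0) stop("empty vote vector")
  stopifnot(threshold > 0.5, threshold <= 1)
  score <- mean(as.numeric(votes))
  list(confidence_score = score,
       conclusive = score >= threshold || score <= 1 - threshold)
}

#' Filter administrations by prediction confidence
#'
#' Retains children whose confidence score is within `t` of either
#' extreme (`<= t` or `>= 1 - t`); retention is monotone in `t`.
#'
#' @param scores Numeric vector of confidence scores in `[0, 1]`.
#' @param t Margin in (0, 0.5).
#' @return Logical vector: retained.
#' @export
filter_by_confidence <- function(scores, t) {
  if (length(t) != 1 || !is.finite(t) || t <= 0 || t >= 0.5)
    stop("t must be in (0, 0.5)")
  scores <= t | scores >= 1 - t
}
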