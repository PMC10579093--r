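#' Per-child raw attributions from the ensemble
#'
#' Exact Shapley values of each member's margin output, computed only for
#' children held out of that member's training folds and averaged across
#' the K members. For every member model the additivity identity
#' `sum_k phi_k + base = margin` holds to machine precision.
#'
#' @param ensemble A fitted `st_ensemble` (trained with
#'   `keep_models = TRUE`).
#' @return List with `phi` (n x p raw attribution matrix, margin scale),
#'   `bias` (per-child expected value), `margin` (per-child mean
#'   out-of-fold margin) and `missing_mask`.
#' @export
attribute <- function(ensemble) {
  stopifnot(inherits(ensemble, "st_ensemble"))
  if (is.null(ensemble$members))
    stop("ensemble was trained with keep_models = FALSE")
  X <- ensemble$X
  n <- nrow(X); p <- ncol(X)
  K <- ensemble$config$K
  folds <- ensemble$config$folds
  phi <- matrix(0, n, p, dimnames = list(NULL, ensemble$feature_names))
  bias <- numeric(n)
  margin <- numeric(n)
  for (m in seq_len(K)) {
    fold <- ensemble$fold_of[, m]
    for (f in seq_len(folds)) {
      idx <- which(fold == f)
      if (length(idx) == 0) next
      sh <- .gbt_shap_cpp(ensemble$members[[m]][[f]],
                          X[idx, , drop = FALSE])
      phi[idx, ] <- phi[idx, ] + sh[, seq_len(p), drop = FALSE]
      bias[idx] <- bias[idx] + sh[, p + 1]
      margin[idx] <- margin[idx] + rowSums(sh)
    }
  }
  list(phi = phi / K, bias = bias / K, margin = margin / K,
       missing_mask = ensemble$missing_mask)
}

#' Normalize an attribution vector (or matrix rows)
#'
#' Divides each entry by the L1 norm of the child's attribution vector so
#' the absolute normalized contributions sum to 1, preserving signs
#' (positive pushes toward the positive/autism class). An all-zero vector
#' stays zero and is flagged.
#'
#' @param phi Numeric vector, or matrix with one row per child.
#' @return Same shape as `phi`; attribute `"no_attribution"` flags
#'   all-zero rows.
#' @export
normalize_attribution <- function(phi) {
  if (is.null(dim(phi))) {
    tot <- sum(abs(phi))
    out <- if (tot > 0) phi / tot else phi
    attr(out, "no_attribution") <- tot == 0
    return(out)
  }
  tot <- rowSums(abs(phi))
  scale <- ifelse(tot > 0, tot, 1)
  out <- phi / scale
  attr(out, "no_attribution") <- tot == 0
  out
}

#' Decompose attributions into observed and missingness parts
#'
#' The attribution of a missing variable measures the effect of the
#' variable *being missing*, not of its value; it is moved wholly into the
#' missingness slot `phi_Z` and the observed slot is zeroed. Total L1 mass
#' is conserved per child.
#'
#' @param phi Raw (or normalized) attribution matrix, children x variables.
#' @param missing_mask Logical matrix of the same shape: TRUE = missing.
#' @return List with `phi_obs`, `phi_z` and `missingness_share` (cohort
#'   mean of per-child |phi_Z| mass over total mass, in percent).
#' @export
decompose_missingness <- function(phi, missing_mask) {
  phi <- as.matrix(phi)
  if (!all(dim(phi) == dim(missing_mask)))
    stop("mask and attribution dimensions differ")
  phi_z <- phi
  phi_z[!missing_mask] <- 0
  phi_obs <- phi
  phi_obs[missing_mask] <- 0
  tot <- rowSums(abs(phi_obs)) + rowSums(abs(phi_z))
  share <- ifelse(tot > 0, rowSums(abs(phi_z)) / tot, 0)
  list(phi_obs = phi_obs, phi_z = phi_z,
       missingness_share = 100 * mean(share[tot > 0]))
}

#' Per-variable importance
#'
#' Mean absolute (normalized) attribution per variable with its SD,
#' ranked in descending order.
#'
#' @param phi Attribution matrix, children x variables (typically
#'   normalized).
#' @return `data.frame` with `variable`, `importance`, `sd`, sorted
#'   descending.
#' @export
attribution_importance <- function(phi) {
  phi <- as.matrix(phi)
  if (nrow(phi) < 1) stop("need at least one child")
  if (is.null(colnames(phi)))
    colnames(phi) <- paste0("V", seq_len(ncol(phi)))
  imp <- colMeans(abs(phi))
  sds <- apply(abs(phi), 2, stats::sd)
  out <- data.frame(variable = colnames(phi), importance = imp, sd = sds,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' Main-effect versus interaction share
#'
#' Exact Shapley interaction values of each member's margin, averaged
#' across members (out-of-fold only); the main-effect share is the mean
#' over children of the diagonal L1 mass over total L1 mass. Main and
#' interaction shares sum to 100 exactly; a stump-only ensemble
#' (`max_depth = 1`) has interaction share 0.
#'
#' @param ensemble A fitted `st_ensemble` with kept models.
#' @return List with `main_pct`, `interaction_pct` and the per-child
#'   shares.
#' @export
interaction_share <- function(ensemble) {
  stopifnot(inherits(ensemble, "st_ensemble"))
  if (is.null(ensemble$members))
    stop("ensemble was trained with keep_models = FALSE")
  X <- ensemble$X
  n <- nrow(X); p <- ncol(X)
  K <- ensemble$config$K
  inter <- array(0, c(p, p, n))
  for (m in seq_len(K)) {
    fold <- ensemble$fold_of[, m]
    for (f in seq_len(ensemble$config$folds)) {
      idx <- which(fold == f)
      if (length(idx) == 0) next
      a <- .gbt_shap_inter_cpp(ensemble$members[[m]][[f]],
                               X[idx, , drop = FALSE])
      inter[, , idx] <- inter[, , idx] + a
    }
  }
  inter <- inter / K
  diag_mass <- vapply(seq_len(n),
                      function(i) sum(abs(diag(inter[, , i]))), numeric(1))
  tot_mass <- vapply(seq_len(n),
                     function(i) sum(abs(inter[, , i])), numeric(1))
  ok <- tot_mass > 0
  main <- ifelse(ok, diag_mass / pmax(tot_mass, 1e-300), 1)
  list(main_pct = 100 * mean(main[ok]),
       interaction_pct = 100 * mean(1 - main[ok]),
       per_child_main = 100 * main)
}
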