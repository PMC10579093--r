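#' Per-variable confidence scores from an availability record
#'
#' Aggregated variables score the ratio of available constituent
#' measurements over the maximum; the two response-to-name variables score
#' the fraction of valid name calls out of three; the four touch variables
#' score `min(touches, 15) / 15` when the game was administered and 0
#' otherwise; a missing variable always scores 0.
#'
#' @param available,maximum Named integer vectors (aggregated variables):
#'   available and maximum constituent measurement counts.
#' @param valid_name_calls Number of valid name-call experiments (0-3).
#' @param n_touches Number of screen touches.
#' @param game_administered Was the bubble game administered?
#' @param missing Named logical vector over variables: TRUE if the
#'   variable value is missing.
#' @return Named numeric vector of confidence scores in `[0, 1]` over the
#'   23 app variables.
#' @export
variable_confidence <- function(available, maximum, valid_name_calls = 3,
                                n_touches = 0, game_administered = TRUE,
                                missing = NULL) {
  if (any(available > maximum[names(available)]))
    stop("available measurements exceed the maximum")
  if (valid_name_calls < 0 || valid_name_calls > 3)
    stop("valid name calls must be between 0 and 3")
  vars <- app_variable_names()
  rho <- setNames(numeric(length(vars)), vars)
  agg <- intersect(names(available), vars)
  rho[agg] <- available[agg] / maximum[agg]
  rho[c("rtn_proportion", "rtn_delay")] <- valid_name_calls / 3
  touch_vars <- c("touch_popping_rate", "touch_error_sd",
                  "touch_average_length", "touch_average_applied_force")
  rho[touch_vars] <- if (game_administered) min(n_touches, 15) / 15 else 0
  if (!is.null(missing)) rho[names(missing)[missing]] <- 0
  rho
}

#' Administration quality score
#'
#' `Q = sum_k G_k * rho_k`: per-variable confidence scores weighted by the
#' variables' normalized predictive power. Q is 0 when everything is
#' missing and 1 when every variable carries its maximum information.
#'
#' @param rho Named numeric confidence vector in `[0, 1]`.
#' @param G Named numeric predictive-power weights, non-negative, summing
#'   to 1 (see [predictive_power_weights()]).
#' @return The quality score in `[0, 1]`.
#' @export
quality_score <- function(rho, G) {
  if (any(G < 0)) stop("negative weights")
  if (abs(sum(G) - 1) > 1e-6) stop("weights must sum to 1")
  if (any(rho < 0 | rho > 1)) stop("confidence scores must be in [0, 1]")
  if (!is.null(names(G)) && !is.null(names(rho))) G <- G[names(rho)]
  sum(G * rho)
}

#' Predictive-power weights for the quality score
#'
#' Normalized per-variable importance computed from observed-only
#' attributions: attributions of missing cells are set to 0 before taking
#' mean absolute values, then the vector is scaled to sum to 1. Without a
#' fitted model, uniform weights are the fallback.
#'
#' @param phi Raw attribution matrix (children x variables), or `NULL`
#'   for the uniform fallback.
#' @param missing_mask Logical matrix aligned with `phi`.
#' @return Named weight vector summing to 1.
#' @export
predictive_power_weights <- function(phi = NULL, missing_mask = NULL) {
  vars <- app_variable_names()
  if (is.null(phi))
    return(setNames(rep(1 / length(vars), length(vars)), vars))
  phi <- as.matrix(phi)
  if (!is.null(missing_mask)) phi[missing_mask] <- 0
  imp <- colMeans(abs(phi))
  if (sum(imp) == 0) return(setNames(rep(1 / ncol(phi), ncol(phi)),
                                     colnames(phi)))
  imp / sum(imp)
}

#' Flag an administration for re-administration
#'
#' @param Q Quality score in `[0, 1]`.
#' @param threshold Quality threshold in (0, 1); strictly below flags.
#' @return TRUE if the app should be re-administered.
#' @export
flag_readministration <- function(Q, threshold = 0.75) {
  stopifnot(threshold > 0, threshold < 1)
  Q < threshold
}

#' Quality assessment of one extracted session
#'
#' Convenience wrapper combining the confidence scores attached by
#' [extract_all()] with predictive-power weights.
#'
#' @param app_vars An `app_variable_vector` from [extract_all()].
#' @param G Predictive-power weights (default uniform).
#' @param threshold Re-administration threshold.
#' @return List with `rho`, `Q` and `readminister`.
#' @export
assess_quality <- function(app_vars, G = predictive_power_weights(),
                           threshold = 0.75) {
  stopifnot(inherits(app_vars, "app_variable_vector"))
  Q <- quality_score(app_vars$rho, G)
  list(rho = app_vars$rho, Q = Q,
       readminister = flag_readministration(Q, threshold))
}
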