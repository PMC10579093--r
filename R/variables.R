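#' The 23 canonical app variables
#'
#' The screening app derives 23 behavioral variables per administration:
#' 19 camera-based (facing forward, social gaze, gaze/speech coupling,
#' facial dynamics complexity, head movement, response to name, blink rate)
#' and 4 touch-based (bubble-popping game). Several camera variables are
#' computed separately for social and nonsocial movie segments.
#'
#' @return Character vector of the 23 variable names, in canonical order.
#' @export
app_variable_names <- function() {
  c("facing_forward_social", "facing_forward_nonsocial",
    "gaze_percent_social", "gaze_silhouette", "gaze_speech_correlation",
    "mouth_complexity_social", "mouth_complexity_nonsocial",
    "eyebrows_complexity_social", "eyebrows_complexity_nonsocial",
    "head_movement_social", "head_movement_nonsocial",
    "head_complexity_social", "head_complexity_nonsocial",
    "head_acceleration_social", "head_acceleration_nonsocial",
    "rtn_proportion", "rtn_delay",
    "blink_rate_social", "blink_rate_nonsocial",
    "touch_popping_rate", "touch_error_sd",
    "touch_average_length", "touch_average_applied_force")
}

# Per-variable generative metadata: the transform mapping the latent
# standard-normal scale to the natural scale, a typical neurotypical
# location, and the default autistic-vs-neurotypical standardized shift on
# the latent scale. Signs follow the clinical direction: autistic toddlers
# show lower facing-forward and social-gaze fractions, longer name-response
# delays, lower response proportions and more (and more complex) head
# movement. Magnitudes are stand-ins chosen once so that the default cohort
# supports a cross-validated AUC near 0.9; they are not estimates of any
# study distribution.
variable_meta <- function() {
  v <- app_variable_names()
  meta <- data.frame(
    variable = v,
    transform = c("logit100", "logit100",
                  "logit100", "logit_pm1", "logit_pm1",
                  "lognorm", "lognorm", "lognorm", "lognorm",
                  "lognorm", "lognorm", "lognorm", "lognorm",
                  "lognorm", "lognorm",
                  "logit01", "lognorm",
                  "lognorm", "lognorm",
                  "logit01", "lognorm", "lognorm", "lognorm"),
    nt_location = c(88, 85,
                    65, 0.55, 0.50,
                    1.2, 1.1, 1.0, 0.9,
                    8, 9, 1.3, 1.2,
                    40, 45,
                    0.85, 1.2,
                    12, 14,
                    0.75, 0.06, 0.25, 1.0),
    effect = c(-1.1, -0.6,
               -1.1, -0.5, -0.6,
               -0.3, -0.2, -0.3, -0.2,
               0.7, 0.5, 0.3, 0.2,
               0.5, 0.3,
               -0.8, 1.0,
               -0.3, -0.1,
               -0.3, 0.3, -0.2, 0.2),
    missing_rate = c(0.05, 0.05,
                     0.08, 0.08, 0.08,
                     0.05, 0.05, 0.05, 0.05,
                     0.05, 0.05, 0.05, 0.05,
                     0.05, 0.05,
                     0.12, 0.12,
                     0.05, 0.05,
                     0.10, 0.10, 0.10, 0.10),
    stringsAsFactors = FALSE)
  rownames(meta) <- v
  meta
}

#' Default autistic-vs-neurotypical effect sizes
#'
#' Standardized mean shifts (latent scale, units of the neurotypical SD)
#' applied by [generate_cohort()]. Negative values mean the autistic group
#' is lower on that variable.
#'
#' @return Named numeric vector over the 23 app variables.
#' @export
default_effect_sizes <- function() {
  m <- variable_meta()
  setNames(m$effect, m$variable)
}

#' Default per-variable missingness rates
#'
#' @return Named numeric vector of missing-at-random probabilities.
#' @export
default_missingness_rates <- function() {
  m <- variable_meta()
  setNames(m$missing_rate, m$variable)
}

# map latent N(0,1) draws to the natural scale of each variable
latent_to_natural <- function(z, variable) {
  m <- variable_meta()[variable, ]
  loc <- m$nt_location
  switch(m$transform,
    logit100 = 100 * plogis(qlogis(loc / 100) + 0.5 * z),
    logit01  = plogis(qlogis(loc) + 0.5 * z),
    logit_pm1 = 2 * plogis(qlogis((loc + 1) / 2) + 0.5 * z) - 1,
    lognorm  = loc * exp(0.3 * z),
    stop("unknown transform"))
}
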