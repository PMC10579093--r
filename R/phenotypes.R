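#' Phenotype extraction parameters
#'
#' Thresholds and parameters for computing the 23 app variables from
#' session signals. The published analysis states the filter rules but not
#' their numeric values (they live in the cited computer-vision method
#' papers); these defaults are standard practice and fully exposed.
#'
#' @param eye_open_min Minimum eye-openness for a facing-forward frame.
#' @param gaze_margin Fraction of screen size allowed beyond the screen
#'   bounds for "gaze at or close to the screen".
#' @param head_vel_max Maximum head angular velocity (deg/s) for a "steady"
#'   face.
#' @param entropy_m Embedding length for sample entropy.
#' @param entropy_r Tolerance as a fraction of the series SD.
#' @param entropy_scales Integer scales for the multiscale coarse-graining.
#' @param rtn_window Response window (s) after the name-call offset.
#' @param rtn_yaw_threshold Yaw change (deg) counting as a head turn.
#' @param rtn_sustain_frames Frames the turn must be sustained.
#' @param rtn_min_valid Minimum fraction of valid frames in the response
#'   window for a call to count as a valid experiment.
#' @param blink_threshold Eye-openness level whose downward crossing marks
#'   a blink.
#' @param blink_refractory Minimum time (s) between counted blinks.
#' @param min_valid_frac Minimum fraction of a movie's frames that must be
#'   valid for that movie to contribute a measurement.
#' @return An object of class `phenotype_config`.
#' @export
phenotype_config <- function(eye_open_min = 0.5, gaze_margin = 0.1,
                             head_vel_max = 30, entropy_m = 2,
                             entropy_r = 0.2, entropy_scales = 1:5,
                             rtn_window = 3, rtn_yaw_threshold = 20,
                             rtn_sustain_frames = 5, rtn_min_valid = 0.5,
                             blink_threshold = 0.5, blink_refractory = 0.25,
                             min_valid_frac = 0.3) {
  stopifnot(eye_open_min > 0, gaze_margin > 0, head_vel_max > 0,
            entropy_m >= 1, entropy_r > 0, length(entropy_scales) >= 1,
            all(entropy_scales >= 1), rtn_window > 0,
            rtn_yaw_threshold > 0, rtn_sustain_frames >= 1,
            blink_threshold > 0, blink_refractory >= 0,
            min_valid_frac > 0, min_valid_frac <= 1)
  structure(as.list(environment()), class = "phenotype_config")
}

# ---- low-level statistics -------------------------------------------------

#' Multiscale entropy of a time series
#'
#' Mean over scales of the sample entropy of the coarse-grained series
#' (non-overlapping window means). The tolerance is `r` times the SD of
#' the *original* series at every scale, the standard multiscale
#' convention.
#' A constant series has entropy 0; scales whose entropy is undefined (no
#' template matches) are dropped from the mean.
#'
#' @param series Numeric vector.
#' @param m Embedding length.
#' @param r Tolerance as fraction of the series SD.
#' @param scales Integer coarse-graining scales.
#' @return Mean sample entropy across scales, or `NA` if the series is too
#'   short (`length < 10 * max(scales)`) or no scale is defined.
#' @export
multiscale_entropy <- function(series, m = 2, r = 0.2, scales = 1:5) {
  series <- as.numeric(series)
  if (length(series) < 10 * max(scales)) return(NA_real_)
  tol <- r * stats::sd(series)
  if (!is.finite(tol)) return(NA_real_)
  ent <- vapply(scales, function(tau) {
    cg <- coarse_grain(series, tau)
    .sampen_cpp(cg, as.integer(m), tol)
  }, numeric(1))
  if (all(is.na(ent))) NA_real_ else mean(ent, na.rm = TRUE)
}

coarse_grain <- function(x, tau) {
  if (tau == 1) return(x)
  n <- floor(length(x) / tau)
  colMeans(matrix(x[seq_len(n * tau)], nrow = tau))
}

#' Mean silhouette coefficient
#'
#' Cluster-cohesion statistic over Euclidean distances: for each point,
#' `s = (b - a) / max(a, b)` with `a` the mean distance to its own cluster
#' and `b` the mean distance to the nearest other cluster; singleton
#' clusters score 0.
#'
#' @param x Numeric matrix (rows = points).
#' @param cluster Integer cluster assignment.
#' @return Mean silhouette over all points.
#' @export
silhouette_mean <- function(x, cluster) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(cluster) == n, n >= 2)
  d <- as.matrix(stats::dist(x))
  ids <- sort(unique(cluster))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1)
    b <- min(vapply(ids[ids != cluster[i]],
                    function(k) mean(d[i, cluster == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# ---- frame-level helpers --------------------------------------------------

# angular velocity (deg/s) from frame-to-frame pose differences
pose_speed <- function(yaw, pitch, roll, fps) {
  d <- sqrt(diff(yaw)^2 + diff(pitch)^2 + diff(roll)^2) * fps
  c(d[1], d)  # pad so length matches frames
}

facing_forward_flags <- function(fr, fps, config) {
  vel <- pose_speed(fr$yaw, fr$pitch, fr$roll, fps)
  in_screen <- fr$gaze_x >= -config$gaze_margin &
    fr$gaze_x <= 1 + config$gaze_margin &
    fr$gaze_y >= -config$gaze_margin & fr$gaze_y <= 1 + config$gaze_margin
  fr$eye_openness > config$eye_open_min &
    in_screen & !is.na(in_screen) & vel < config$head_vel_max
}

seg_frames <- function(signals, name) {
  signals$frames[signals$frames$segment == name, , drop = FALSE]
}

usable_segment <- function(fr, config) {
  nrow(fr) > 0 && mean(fr$valid) >= config$min_valid_frac &&
    sum(fr$valid) >= 1
}

# average a per-segment statistic over the usable segments of a class;
# returns value, rho (= usable / maximum per the layout) and reason
aggregate_segments <- function(signals, class, config, seg_fun) {
  segs <- signals$layout$name[signals$layout$class == class]
  if (length(segs) == 0)
    return(list(value = NA_real_, rho = 0, reason = "no_segments_of_class"))
  vals <- numeric(0)
  for (nm in segs) {
    fr <- seg_frames(signals, nm)
    if (!usable_segment(fr, config)) next
    v <- seg_fun(fr[fr$valid, , drop = FALSE])
    if (is.finite(v)) vals <- c(vals, v)
  }
  if (length(vals) == 0)
    return(list(value = NA_real_, rho = 0, reason = "below_valid_minimum"))
  list(value = mean(vals), rho = length(vals) / length(segs), reason = NA)
}

# ---- individual phenotype operations --------------------------------------

#' Facing-forward fraction
#'
#' Percentage of valid frames in movies of the requested class that pass
#' all three attention filters (eyes open, gaze at or near the screen,
#' steady head), averaged over the movies of that class.
#'
#' @param signals A `session_signals` object.
#' @param class `"social"` or `"nonsocial"`.
#' @param config A [phenotype_config()].
#' @return List with `value` (percent), `rho` and `reason`.
#' @export
facing_forward_fraction <- function(signals, class,
                                    config = phenotype_config()) {
  fps <- signals$meta$fps
  aggregate_segments(signals, class, config, function(fr)
    100 * mean(facing_forward_flags(fr, fps, config)))
}

#' Gaze percent social
#'
#' Percentage of facing-forward time spent gazing at the social half of
#' the screen, averaged over the two split-screen social-preference movies.
#'
#' @inheritParams facing_forward_fraction
#' @export
gaze_percent_social <- function(signals, config = phenotype_config()) {
  split_gaze_stat(signals, config, function(fr, social_left) {
    on_left <- fr$gaze_x < 0.5
    100 * mean(if (social_left) on_left else !on_left)
  })
}

#' Gaze silhouette score
#'
#' Mean silhouette coefficient of facing-forward gaze points under a
#' 2-cluster centroid partition (10 restarts), averaged over the two
#' social-preference movies. Measures how tightly gaze concentrates on the
#' two on-screen targets.
#'
#' @inheritParams facing_forward_fraction
#' @export
gaze_silhouette <- function(signals, config = phenotype_config()) {
  sub_seed <- derive_seed(signals$meta$seed %||% 0, 7701)
  split_gaze_stat(signals, config, function(fr, social_left) {
    pts <- cbind(fr$gaze_x, fr$gaze_y)
    if (nrow(pts) < 4 || nrow(unique(pts)) < 2) return(NA_real_)
    km <- with_seed(sub_seed, stats::kmeans(pts, 2, nstart = 10))
    silhouette_mean(pts, km$cluster)
  })
}

split_gaze_stat <- function(signals, config, fun) {
  lay <- signals$layout
  segs <- lay$name[which(lay$split_screen %in% TRUE)]
  if (length(segs) == 0)
    return(list(value = NA_real_, rho = 0, reason = "no_segments_of_class"))
  fps <- signals$meta$fps
  vals <- numeric(0)
  for (nm in segs) {
    fr <- seg_frames(signals, nm)
    if (nrow(fr) == 0) next
    frv <- fr[fr$valid, , drop = FALSE]
    ff <- if (nrow(frv)) facing_forward_flags(frv, fps, config) else logical(0)
    if (sum(ff) / nrow(fr) < config$min_valid_frac) next
    social_left <- identical(lay$social_half[lay$name == nm], "left")
    v <- fun(frv[ff, , drop = FALSE], social_left)
    if (is.finite(v)) vals <- c(vals, v)
  }
  if (length(vals) == 0)
    return(list(value = NA_real_, rho = 0, reason = "below_valid_minimum"))
  list(value = mean(vals), rho = length(vals) / length(segs), reason = NA)
}

#' Gaze-speech correlation
#'
#' Pearson correlation, at zero lag, between the signed gaze side (-1
#' left, +1 right) and the active-speaker side during the conversation
#' movie. Only facing-forward frames enter; a constant gaze side leaves
#' the correlation undefined (missing).
#'
#' @inheritParams facing_forward_fraction
#' @export
gaze_speech_correlation <- function(signals, config = phenotype_config()) {
  lay <- signals$layout
  segs <- lay$name[lay$class == "conversation"]
  if (length(segs) == 0)
    return(list(value = NA_real_, rho = 0, reason = "no_segments_of_class"))
  fps <- signals$meta$fps
  turn <- signals$meta$speaker_turn %||% 3
  nm <- segs[1]
  fr <- seg_frames(signals, nm)
  frv <- fr[fr$valid, , drop = FALSE]
  ff <- if (nrow(frv)) facing_forward_flags(frv, fps, config) else logical(0)
  if (nrow(fr) == 0 || sum(ff) / nrow(fr) < config$min_valid_frac)
    return(list(value = NA_real_, rho = 0, reason = "below_valid_minimum"))
  frf <- frv[ff, , drop = FALSE]
  t0 <- lay$t0[lay$name == nm]
  gaze_side <- sign(frf$gaze_x - 0.5)
  spk <- speaker_side(frf$t - t0, turn)
  if (length(unique(gaze_side)) < 2 || length(unique(spk)) < 2)
    return(list(value = NA_real_, rho = 0, reason = "constant_series"))
  list(value = stats::cor(gaze_side, spk), rho = 1, reason = NA)
}

#' Head movement statistics
#'
#' Per movie class: `rate` = mean frame-to-frame angular displacement
#' (Euclidean norm over yaw/pitch/roll) times the frame rate (deg/s);
#' `acceleration` = mean norm of second differences times the frame rate
#' squared (deg/s^2); `complexity` = multiscale entropy of the
#' displacement series. Averaged over the usable movies of the class.
#'
#' @inheritParams facing_forward_fraction
#' @return List of three `value`/`rho`/`reason` triples: `rate`,
#'   `complexity`, `acceleration`.
#' @export
head_movement_stats <- function(signals, class,
                                config = phenotype_config()) {
  fps <- signals$meta$fps
  rate <- aggregate_segments(signals, class, config, function(fr) {
    if (nrow(fr) < 3) return(NA_real_)
    mean(sqrt(diff(fr$yaw)^2 + diff(fr$pitch)^2 + diff(fr$roll)^2)) * fps
  })
  accel <- aggregate_segments(signals, class, config, function(fr) {
    if (nrow(fr) < 4) return(NA_real_)
    d2 <- function(x) diff(diff(x))
    mean(sqrt(d2(fr$yaw)^2 + d2(fr$pitch)^2 + d2(fr$roll)^2)) * fps^2
  })
  cmplx <- aggregate_segments(signals, class, config, function(fr) {
    if (nrow(fr) < 3) return(NA_real_)
    disp <- sqrt(diff(fr$yaw)^2 + diff(fr$pitch)^2 + diff(fr$roll)^2)
    multiscale_entropy(disp, config$entropy_m, config$entropy_r,
                       config$entropy_scales)
  })
  list(rate = rate, complexity = cmplx, acceleration = accel)
}

#' Facial dynamics complexity
#'
#' Multiscale entropy of the landmark-centroid trace (mouth or eyebrow
#' region) during movies of a class, averaged over usable movies.
#'
#' @inheritParams facing_forward_fraction
#' @param region `"mouth"` or `"eyebrows"`.
#' @export
facial_complexity <- function(signals, region, class,
                              config = phenotype_config()) {
  col <- switch(region, mouth = "mouth_y", eyebrows = "brow_y",
                stop("unknown region"))
  aggregate_segments(signals, class, config, function(fr)
    multiscale_entropy(fr[[col]], config$entropy_m, config$entropy_r,
                       config$entropy_scales))
}

#' Response to name
#'
#' A response is a sustained yaw change exceeding the configured threshold
#' whose onset falls strictly after the name-call offset and within the
#' response window; the delay is measured from call offset to turn onset.
#' A call is a valid experiment when the child is sufficiently visible
#' during the window.
#'
#' @inheritParams facing_forward_fraction
#' @return List with `proportion`, `delay` (each `value`/`rho`/`reason`).
#' @export
response_to_name <- function(signals, config = phenotype_config()) {
  nc <- signals$name_calls
  fr <- signals$frames
  valid_calls <- 0L
  responded <- 0L
  delays <- numeric(0)
  for (k in seq_len(nrow(nc))) {
    off <- nc$offset[k]
    win <- fr[fr$t > off & fr$t <= off + config$rtn_window, , drop = FALSE]
    base_fr <- fr[fr$t >= off - 0.5 & fr$t <= off & fr$valid, , drop = FALSE]
    if (nrow(win) == 0 || mean(win$valid) < config$rtn_min_valid ||
        nrow(base_fr) == 0) next
    valid_calls <- valid_calls + 1L
    baseline <- stats::median(base_fr$yaw)
    wv <- win[win$valid, , drop = FALSE]
    exceed <- abs(wv$yaw - baseline) >= config$rtn_yaw_threshold
    pre_turned <- abs(base_fr$yaw[nrow(base_fr)] - baseline) >=
      config$rtn_yaw_threshold
    r <- rle(exceed)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    onset_idx <- NA_integer_
    for (j in seq_along(r$values)) {
      if (!r$values[j] || r$lengths[j] < config$rtn_sustain_frames) next
      if (j == 1 && pre_turned) next  # turn began before the call offset
      onset_idx <- starts[j]
      break
    }
    if (!is.na(onset_idx)) {
      responded <- responded + 1L
      delays <- c(delays, wv$t[onset_idx] - off)
    }
  }
  rho <- valid_calls / 3
  if (valid_calls == 0)
    return(list(
      proportion = list(value = NA_real_, rho = 0, reason = "no_valid_calls"),
      delay = list(value = NA_real_, rho = 0, reason = "no_valid_calls")))
  list(proportion = list(value = responded / valid_calls, rho = rho,
                         reason = NA),
       delay = if (responded > 0)
         list(value = mean(delays), rho = rho, reason = NA)
       else list(value = NA_real_, rho = rho, reason = "no_responses"))
}

#' Blink rate
#'
#' Downward threshold crossings of the eye-openness trace with a
#' refractory period, normalized by valid observation time (blinks/min),
#' averaged over the usable movies of a class.
#'
#' @inheritParams facing_forward_fraction
#' @export
blink_rate <- function(signals, class, config = phenotype_config()) {
  fps <- signals$meta$fps
  aggregate_segments(signals, class, config, function(fr) {
    eo <- fr$eye_openness
    if (length(eo) < 2) return(NA_real_)
    below <- eo < config$blink_threshold
    crossings <- which(below[-1] & !below[-length(below)]) + 1
    if (length(crossings) > 1) {
      keep <- c(TRUE, diff(fr$t[crossings]) > config$blink_refractory)
      crossings <- crossings[keep]
    }
    minutes <- length(eo) / fps / 60
    length(crossings) / minutes
  })
}

#' Touch metrics from the bubble-popping game
#'
#' Popping rate (popped / touches), SD of the distance from touch to the
#' nearest bubble center (touches with no bubble on screen are excluded
#' from the error but count in the rate denominator), mean finger
#' trajectory length and mean applied force.
#'
#' @inheritParams facing_forward_fraction
#' @return List of four `value`/`rho`/`reason` triples.
#' @export
touch_metrics <- function(signals, config = phenotype_config()) {
  lay <- signals$layout
  game_segs <- lay$name[lay$class == "game"]
  dropped <- attr(signals, "dropped_segments") %||% character()
  administered <- length(game_segs) > 0 && !all(game_segs %in% dropped)
  tc <- signals$touches
  n <- nrow(tc)
  rho <- if (administered) min(n, 15) / 15 else 0
  mk <- function(value, reason = NA)
    list(value = value, rho = rho, reason = reason)
  if (!administered || n == 0) {
    na <- list(value = NA_real_, rho = rho,
               reason = if (administered) "no_touches" else
                 "game_not_administered")
    return(list(touch_popping_rate = na, touch_error_sd = na,
                touch_average_length = na,
                touch_average_applied_force = na))
  }
  with_bubble <- is.finite(tc$bubble_x) & is.finite(tc$bubble_y)
  err <- sqrt((tc$x - tc$bubble_x)^2 + (tc$y - tc$bubble_y)^2)[with_bubble]
  list(touch_popping_rate = mk(mean(tc$popped)),
       touch_error_sd = if (sum(with_bubble) >= 2) mk(stats::sd(err))
                        else mk(NA_real_, "too_few_bubble_touches"),
       touch_average_length = mk(mean(tc$traj_length)),
       touch_average_applied_force = mk(mean(tc$force)))
}

#' Extract all 23 app variables from one session
#'
#' Total function over (possibly degraded) sessions: variables that cannot
#' be computed are flagged missing with a reason code and confidence 0;
#' nothing is imputed.
#'
#' @inheritParams facing_forward_fraction
#' @return An object of class `app_variable_vector`: list with `values`
#'   (named numeric, NA = missing), `rho` (named confidence scores in
#'   `[0, 1]`) and `reason` (named character).
#' @export
extract_all <- function(signals, config = phenotype_config()) {
  res <- list()
  res$facing_forward_social <- facing_forward_fraction(signals, "social", config)
  res$facing_forward_nonsocial <-
    facing_forward_fraction(signals, "nonsocial", config)
  res$gaze_percent_social <- gaze_percent_social(signals, config)
  res$gaze_silhouette <- gaze_silhouette(signals, config)
  res$gaze_speech_correlation <- gaze_speech_correlation(signals, config)
  res$mouth_complexity_social <-
    facial_complexity(signals, "mouth", "social", config)
  res$mouth_complexity_nonsocial <-
    facial_complexity(signals, "mouth", "nonsocial", config)
  res$eyebrows_complexity_social <-
    facial_complexity(signals, "eyebrows", "social", config)
  res$eyebrows_complexity_nonsocial <-
    facial_complexity(signals, "eyebrows", "nonsocial", config)
  hs <- head_movement_stats(signals, "social", config)
  hn <- head_movement_stats(signals, "nonsocial", config)
  res$head_movement_social <- hs$rate
  res$head_movement_nonsocial <- hn$rate
  res$head_complexity_social <- hs$complexity
  res$head_complexity_nonsocial <- hn$complexity
  res$head_acceleration_social <- hs$acceleration
  res$head_acceleration_nonsocial <- hn$acceleration
  rtn <- response_to_name(signals, config)
  res$rtn_proportion <- rtn$proportion
  res$rtn_delay <- rtn$delay
  res$blink_rate_social <- blink_rate(signals, "social", config)
  res$blink_rate_nonsocial <- blink_rate(signals, "nonsocial", config)
  res <- c(res, touch_metrics(signals, config))
  vars <- app_variable_names()
  res <- res[vars]
  values <- vapply(res, function(x) as.numeric(x$value), numeric(1))
  rho <- vapply(res, function(x) x$rho, numeric(1))
  reason <- vapply(res, function(x) as.character(x$reason %||% NA),
                   character(1))
  # a missing variable always has confidence 0
  rho[is.na(values)] <- 0
  structure(list(values = setNames(values, vars),
                 rho = setNames(rho, vars),
                 reason = setNames(reason, vars)),
            class = "app_variable_vector")
}
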