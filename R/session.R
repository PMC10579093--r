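#' Script for one synthetic app administration
#'
#' Defines the movie schedule and the scripted behavior a synthetic child
#' exhibits, so that every downstream phenotype has a known ground truth.
#' The default schedule mirrors the app design: social and nonsocial
#' movies, two split-screen social-preference movies, one conversation
#' movie with alternating speakers, and a bubble-popping game; the child's
#' name is called exactly three times.
#'
#' @param segments `data.frame` with columns `name`, `class`
#'   (`social`/`nonsocial`/`conversation`/`game`), `duration` (s),
#'   `split_screen` (logical), `social_half` (`"left"`/`"right"`/NA),
#'   `social_gaze_p`, `facing_forward_p`, `blink_rate` (blinks/min),
#'   `head_amplitude` (mean angular speed, deg/s).
#' @param name_calls `data.frame` with columns `onset` (s), `duration` (s),
#'   `respond` (logical), `delay` (s, offset-to-turn).
#' @param touch `list(n_touches, pop_p, error_sd, traj_length, force,
#'   force_sd)` describing the bubble game.
#' @param speech_follow_p Probability per frame that gaze follows the
#'   active speaker during the conversation movie.
#' @param speaker_turn Duration (s) of each speaker's turn.
#' @param fps Frame rate (Hz); the app records at 30 fps.
#' @return An object of class `session_script`.
#' @export
session_script <- function(segments = default_segments(),
                           name_calls = data.frame(
                             onset = c(75, 160, 250), duration = 1,
                             respond = TRUE, delay = 1.0),
                           touch = list(n_touches = 20, pop_p = 0.8,
                                        error_sd = 0.05, traj_length = 0.25,
                                        force = 1.0, force_sd = 0.2),
                           speech_follow_p = 0.9, speaker_turn = 3,
                           fps = 30) {
  if (fps <= 0) stop("frame rate must be positive")
  if (nrow(name_calls) != 3) stop("the name is called exactly three times")
  stopifnot(all(segments$duration > 0))
  p_cols <- c("social_gaze_p", "facing_forward_p")
  for (pc in p_cols)
    if (any(segments[[pc]] < 0 | segments[[pc]] > 1, na.rm = TRUE))
      stop("scripted probabilities must be in [0, 1]")
  segments$t0 <- cumsum(c(0, segments$duration))[seq_len(nrow(segments))]
  structure(list(segments = segments, name_calls = name_calls,
                 touch = touch, speech_follow_p = speech_follow_p,
                 speaker_turn = speaker_turn, fps = fps),
            class = "session_script")
}

#' @rdname session_script
#' @export
default_segments <- function() {
  data.frame(
    name = c("social_1", "nonsocial_1", "social_pref_1", "social_pref_2",
             "conversation", "social_2", "nonsocial_2", "game"),
    class = c("social", "nonsocial", "social", "social", "conversation",
              "social", "nonsocial", "game"),
    duration = c(60, 60, 30, 30, 45, 30, 60, 60),
    split_screen = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    social_half = c(NA, NA, "left", "right", NA, NA, NA, NA),
    social_gaze_p = c(NA, NA, 0.75, 0.75, NA, NA, NA, NA),
    facing_forward_p = c(0.9, 0.85, 0.9, 0.9, 0.9, 0.9, 0.85, NA),
    blink_rate = c(12, 14, 12, 12, 12, 12, 14, NA),
    head_amplitude = c(8, 9, 8, 8, 8, 8, 9, NA),
    stringsAsFactors = FALSE)
}

#' Generate frame-wise session signals from a script
#'
#' Emits gaze screen coordinates (normalized, origin top-left), head pose
#' (yaw/pitch/roll, degrees), eye openness, mouth and eyebrow landmark
#' centroid traces, and event logs (name calls, touches). All scripted
#' quantities are recoverable by the phenotype extractors within stated
#' tolerances (round-trip contract).
#'
#' @param script A [session_script()].
#' @param seed Integer seed.
#' @return An object of class `session_signals`: list with `frames`
#'   (`data.frame`), `name_calls`, `touches`, `layout` and `meta`.
#' @export
generate_session <- function(script = session_script(), seed = 1L) {
  stopifnot(inherits(script, "session_script"))
  fps <- script$fps
  segs <- script$segments
  with_seed(seed, {
    frames_list <- list()
    for (s in seq_len(nrow(segs))) {
      seg <- segs[s, ]
      nf <- round(seg$duration * fps)
      t <- seg$t0 + (seq_len(nf) - 1) / fps
      if (seg$class == "game") {
        # camera variables are not computed during the game
        frames_list[[s]] <- data.frame(
          t = t, segment = seg$name, class = seg$class, valid = FALSE,
          gaze_x = NA_real_, gaze_y = NA_real_, yaw = 0, pitch = 0, roll = 0,
          eye_openness = NA_real_, mouth_y = NA_real_, brow_y = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      # head pose: sinusoid whose mean absolute derivative (4 * A * f)
      # equals the scripted amplitude, plus mild jitter
      f0 <- 0.25
      A <- seg$head_amplitude / (4 * f0)
      phase <- runif(1, 0, 2 * pi)
      yaw <- A * sin(2 * pi * f0 * (t - seg$t0) + phase)
      pitch <- 0.2 * A * sin(2 * pi * f0 * (t - seg$t0) + phase + 1)
      roll <- rnorm(nf, 0, 0.2)
      # gaze target
      if (isTRUE(seg$split_screen)) {
        social_x <- if (seg$social_half == "left") 0.25 else 0.75
        on_social <- runif(nf) < seg$social_gaze_p
        gx <- ifelse(on_social, social_x, 1 - social_x) + rnorm(nf, 0, 0.08)
        gx <- pmin(pmax(gx, 0.02), 0.98)
        # keep jitter from crossing the midline
        gx <- ifelse(on_social == (seg$social_half == "left"),
                     pmin(gx, 0.49), pmax(gx, 0.51))
      } else if (seg$class == "conversation") {
        side <- speaker_side(t - seg$t0, script$speaker_turn)
        follow <- runif(nf) < script$speech_follow_p
        shown <- ifelse(follow, side, -side)
        gx <- 0.5 + shown * 0.25 + rnorm(nf, 0, 0.06)
        gx <- ifelse(shown > 0, pmax(gx, 0.51), pmin(gx, 0.49))
      } else {
        gx <- 0.5 + rnorm(nf, 0, 0.12)
      }
      gy <- 0.5 + rnorm(nf, 0, 0.1)
      # eye openness with scripted Poisson blinks (4-frame closures)
      eo <- pmin(1, pmax(0.75 + rnorm(nf, 0, 0.05), 0.55))
      n_blinks <- rpois(1, seg$blink_rate * seg$duration / 60)
      if (n_blinks > 0) {
        starts <- sort(sample(seq_len(max(1, nf - 4)), min(n_blinks, nf %/% 8)))
        # enforce separation so blinks stay countable
        keep <- c(TRUE, diff(starts) > 10)
        for (b in starts[keep]) eo[b:min(nf, b + 3)] <- 0.05
      }
      # facing-forward violations: off-screen gaze for scripted fraction
      away <- runif(nf) >= seg$facing_forward_p
      gx[away] <- 1.3 + abs(rnorm(sum(away), 0, 0.1))
      frames_list[[s]] <- data.frame(
        t = t, segment = seg$name, class = seg$class, valid = TRUE,
        gaze_x = gx, gaze_y = gy, yaw = yaw, pitch = pitch, roll = roll,
        eye_openness = eo,
        mouth_y = 0.7 + 0.02 * rnorm(nf),
        brow_y = 0.3 + 0.015 * rnorm(nf),
        stringsAsFactors = FALSE)
    }
    frames <- do.call(rbind, frames_list)
    # name-call responses: yaw step beginning `delay` s after call offset
    nc <- script$name_calls
    nc$offset <- nc$onset + nc$duration
    for (k in seq_len(nrow(nc))) {
      if (!isTRUE(nc$respond[k])) next
      t_turn <- nc$offset[k] + nc$delay[k]
      idx <- frames$t >= t_turn & frames$t <= t_turn + 1.5
      frames$yaw[idx] <- frames$yaw[idx] + 45
    }
    # touches during the game
    gseg <- segs[segs$class == "game", ]
    touches <- NULL
    if (nrow(gseg) >= 1) {
      tc <- script$touch
      nt <- tc$n_touches
      if (nt > 0) {
        bx <- runif(nt, 0.1, 0.9); by <- runif(nt, 0.1, 0.9)
        err <- matrix(rnorm(2 * nt, 0, tc$error_sd), ncol = 2)
        touches <- data.frame(
          t = sort(runif(nt, gseg$t0[1], gseg$t0[1] + gseg$duration[1])),
          x = bx + err[, 1], y = by + err[, 2],
          popped = runif(nt) < tc$pop_p,
          force = pmax(0.05, rnorm(nt, tc$force, tc$force_sd)),
          traj_length = pmax(0.01, rnorm(nt, tc$traj_length, 0.05)),
          bubble_x = bx, bubble_y = by, stringsAsFactors = FALSE)
      }
    }
    if (is.null(touches))
      touches <- data.frame(t = numeric(), x = numeric(), y = numeric(),
                            popped = logical(), force = numeric(),
                            traj_length = numeric(), bubble_x = numeric(),
                            bubble_y = numeric())
    layout <- segs[, c("name", "class", "duration", "t0", "split_screen",
                       "social_half")]
    structure(list(frames = frames,
                   name_calls = nc[, c("onset", "offset", "respond", "delay")],
                   touches = touches, layout = layout,
                   meta = list(fps = fps, schema_version = "1.0",
                               speaker_turn = script$speaker_turn,
                               seed = seed)),
              class = "session_signals")
  })
}

# alternating speaker side during the conversation movie: -1 left, +1 right
speaker_side <- function(t_rel, turn) {
  ifelse(floor(t_rel / turn) %% 2 == 0, -1, 1)
}

#' Invalidate parts of a session (partial administration)
#'
#' Marks all frames of the named segments invalid without deleting them;
#' event logs stay consistent. Touch events of a dropped game segment are
#' removed (the game was not administered).
#'
#' @param signals A `session_signals` object.
#' @param drop_segments Character vector of segment names to invalidate.
#' @return The degraded `session_signals`.
#' @export
degrade_session <- function(signals, drop_segments = character()) {
  stopifnot(inherits(signals, "session_signals"))
  unknown <- setdiff(drop_segments, signals$layout$name)
  if (length(unknown))
    stop("unknown segment name(s): ", paste(unknown, collapse = ", "))
  if (length(drop_segments) == 0) return(signals)  # identity
  sel <- signals$frames$segment %in% drop_segments
  signals$frames$valid[sel] <- FALSE
  dropped_game <- signals$layout$name[signals$layout$class == "game"] %in%
    drop_segments
  if (any(dropped_game)) signals$touches <- signals$touches[0, ]
  dropped <- union(attr(signals, "dropped_segments"), drop_segments)
  attr(signals, "dropped_segments") <- dropped
  signals
}

#' Session JSON serialization
#'
#' One JSON document per child, schema `inst/extdata/session_schema.json`.
#'
#' @param signals A `session_signals` object.
#' @param path File path (`.json`).
#' @return `read_session_json` returns the `session_signals`.
#' @export
write_session_json <- function(signals, path) {
  stopifnot(inherits(signals, "session_signals"))
  doc <- list(schema_version = signals$meta$schema_version,
              meta = signals$meta, frames = signals$frames,
              name_calls = signals$name_calls, touches = signals$touches,
              layout = signals$layout,
              dropped_segments = attr(signals, "dropped_segments") %||%
                character())
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_session_json
#' @export
read_session_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sig <- structure(list(frames = as.data.frame(doc$frames),
                        name_calls = as.data.frame(doc$name_calls),
                        touches = as.data.frame(doc$touches),
                        layout = as.data.frame(doc$layout),
                        meta = doc$meta),
                   class = "session_signals")
  if (length(doc$dropped_segments))
    attr(sig, "dropped_segments") <- unlist(doc$dropped_segments)
  sig
}
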