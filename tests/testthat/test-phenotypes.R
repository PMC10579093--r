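# hand-constructed session with full control over every frame
make_signals <- function(frames, layout = NULL,
                         name_calls = data.frame(onset = numeric(),
                                                 offset = numeric()),
                         touches = NULL, fps = 30, speaker_turn = 3) {
  if (is.null(layout)) {
    segs <- unique(frames[, c("segment", "class")])
    layout <- data.frame(name = segs$segment, class = segs$class,
                         duration = NA_real_,
                         t0 = vapply(segs$segment, function(s)
                           min(frames$t[frames$segment == s]), numeric(1)),
                         split_screen = FALSE, social_half = NA,
                         stringsAsFactors = FALSE)
  }
  if (is.null(touches))
    touches <- data.frame(t = numeric(), x = numeric(), y = numeric(),
                          popped = logical(), force = numeric(),
                          traj_length = numeric(), bubble_x = numeric(),
                          bubble_y = numeric())
  structure(list(frames = frames, name_calls = name_calls,
                 touches = touches, layout = layout,
                 meta = list(fps = fps, schema_version = "1.0",
                             speaker_turn = speaker_turn, seed = 1L)),
            class = "session_signals")
}

flat_frames <- function(n, class = "social", segment = "seg1", fps = 30,
                        t0 = 0) {
  data.frame(t = t0 + (seq_len(n) - 1) / fps, segment = segment,
             class = class, valid = TRUE, gaze_x = 0.5, gaze_y = 0.5,
             yaw = 0, pitch = 0, roll = 0, eye_openness = 1,
             mouth_y = 0.7, brow_y = 0.3, stringsAsFactors = FALSE)
}

test_that("facing forward: degenerate filters give 0 and 100 percent", {
  fr <- flat_frames(300)
  sig <- make_signals(fr)
  expect_equal(facing_forward_fraction(sig, "social")$value, 100)
  fr$eye_openness <- 0
  expect_equal(facing_forward_fraction(make_signals(fr), "social")$value, 0)
  # no segments of the requested class -> missing with reason
  res <- facing_forward_fraction(sig, "nonsocial")
  expect_true(is.na(res$value))
  expect_equal(res$reason, "no_segments_of_class")
})

test_that("facing forward recovers the scripted probability", {
  segs <- default_segments()
  segs$facing_forward_p[segs$class == "social"] <- 0.6
  sig <- generate_session(session_script(segments = segs), seed = 31L)
  expect_equal(facing_forward_fraction(sig, "social")$value, 60,
               tolerance = 5 / 60)
})

test_that("gaze percent social recovers the scripted preference", {
  segs <- default_segments()
  segs$social_gaze_p[segs$split_screen] <- 0.7
  vals <- vapply(1:5, function(s)
    gaze_percent_social(generate_session(session_script(segments = segs),
                                         seed = 40L + s))$value,
    numeric(1))
  expect_equal(mean(vals), 70, tolerance = 3 / 70)
})

test_that("silhouette: separated clouds high, uniform scatter near zero, oracle match", {
  set.seed(1)
  tight <- rbind(cbind(rnorm(20, 0, 0.005), rnorm(20, 0, 0.005)),
                 cbind(rnorm(20, 1, 0.005), rnorm(20, 1, 0.005)))
  cl <- rep(1:2, each = 20)
  expect_gte(silhouette_mean(tight, cl), 0.9)
  # uniform scatter: an optimized 2-means partition of uniform points
  # scores ~0.39 (never near the tight-cluster regime); a *random*
  # 2-partition of the same points scores ~0
  scores_km <- vapply(1:50, function(s) {
    set.seed(s)
    pts <- cbind(runif(60), runif(60))
    km <- kmeans(pts, 2, nstart = 10)
    silhouette_mean(pts, km$cluster)
  }, numeric(1))
  expect_true(all(scores_km < 0.55))
  scores_rand <- vapply(1:50, function(s) {
    set.seed(100 + s)
    pts <- cbind(runif(60), runif(60))
    silhouette_mean(pts, sample(1:2, 60, replace = TRUE))
  }, numeric(1))
  expect_true(all(abs(scores_rand) <= 0.1))
  # printed toy instance equals the brute-force definition
  pts <- cbind(c(0, 0.1, 0.2, 1, 1.1, 0.9, 0.5, 0.45, 0.55, 0.05),
               c(0, 0.05, 0.1, 1, 0.95, 1.05, 0.5, 0.55, 0.48, 0.02))
  cl <- c(1, 1, 1, 2, 2, 2, 2, 1, 2, 1)
  expect_equal(silhouette_mean(pts, cl), bf_silhouette(pts, cl),
               tolerance = 1e-12)
})

test_that("gaze-speech correlation: exact follow/avoid and flip noise", {
  n <- 900
  t <- (seq_len(n) - 1) / 30
  spk <- ifelse(floor(t / 3) %% 2 == 0, -1, 1)
  fr <- flat_frames(n, class = "conversation", segment = "conv")
  fr$gaze_x <- 0.5 + spk * 0.25
  expect_equal(gaze_speech_correlation(make_signals(fr))$value, 1.0)
  fr$gaze_x <- 0.5 - spk * 0.25
  expect_equal(gaze_speech_correlation(make_signals(fr))$value, -1.0)
  # constant gaze side -> undefined
  fr$gaze_x <- 0.7
  res <- gaze_speech_correlation(make_signals(fr))
  expect_true(is.na(res$value))
  expect_equal(res$reason, "constant_series")
  # 10% flip noise -> correlation ~ 1 - 2 * 0.1
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    flip <- runif(n) < 0.1
    fr$gaze_x <- 0.5 + ifelse(flip, -spk, spk) * 0.25
    gaze_speech_correlation(make_signals(fr))$value
  }, numeric(1))
  expect_equal(mean(vals), 0.8, tolerance = 0.1 / 0.8)
})

test_that("multiscale entropy: constant series, toy oracle, noise vs sine", {
  expect_equal(multiscale_entropy(rep(3.7, 100)), 0)
  # 30-point toy series: every scale matches brute-force template counting
  set.seed(2)
  x <- round(rnorm(30), 2)
  r <- 0.2 * sd(x)
  expect_equal(sampen(x, 2L, r), bf_sampen(x, 2, r), tolerance = 1e-12)
  x2 <- cumsum(round(rnorm(40), 1))
  r2 <- 0.3 * sd(x2)
  expect_equal(sampen(x2, 2L, r2), bf_sampen(x2, 2, r2), tolerance = 1e-12)
  expect_equal(sampen(x2, 3L, r2), bf_sampen(x2, 3, r2), tolerance = 1e-12)
  # white noise is more entropic than a same-variance sine at scale 1
  wins <- vapply(1:100, function(s) {
    set.seed(s)
    noise <- rnorm(1000)
    sine <- sqrt(2) * sin(2 * pi * 5 * seq_len(1000) / 1000)
    sampen(noise, 2L, 0.2 * sd(noise)) > sampen(sine, 2L, 0.2 * sd(sine))
  }, logical(1))
  expect_gte(sum(wins), 95)
  # too-short series is missing
  expect_true(is.na(multiscale_entropy(rnorm(30), scales = 1:5)))
})

test_that("head movement: static, sinusoid closed form, linearity", {
  fr <- flat_frames(600)
  hs <- head_movement_stats(make_signals(fr), "social")
  expect_equal(hs$rate$value, 0)
  expect_equal(hs$acceleration$value, 0)
  # yaw = A sin(2 pi f t): mean |derivative| = 4 A f
  fps <- 30; A <- 10; f <- 0.5
  fr <- flat_frames(60 * fps)
  fr$yaw <- A * sin(2 * pi * f * fr$t)
  rate <- head_movement_stats(make_signals(fr), "social")$rate$value
  expect_equal(rate, 4 * A * f, tolerance = 0.02)
  fr2 <- fr
  fr2$yaw <- 2 * fr$yaw
  rate2 <- head_movement_stats(make_signals(fr2), "social")$rate$value
  expect_equal(rate2, 2 * rate, tolerance = 0.02)
})

test_that("response to name: scripted proportions, delays and edge rules", {
  nc <- data.frame(onset = c(75, 160, 250), duration = 1,
                   respond = c(TRUE, TRUE, FALSE), delay = c(0.8, 1.2, NA))
  sig <- generate_session(session_script(name_calls = nc), seed = 6L)
  rtn <- response_to_name(sig)
  expect_equal(rtn$proportion$value, 2 / 3)
  expect_equal(rtn$delay$value, 1.0, tolerance = 2 / 30)
  expect_equal(rtn$proportion$rho, 1)
  # no yaw change ever -> proportion 0, delay missing
  fr <- flat_frames(300 * 30, segment = "m1")
  nc0 <- data.frame(onset = c(20, 60, 100), offset = c(21, 61, 101))
  rtn0 <- response_to_name(make_signals(fr, name_calls = nc0))
  expect_equal(rtn0$proportion$value, 0)
  expect_true(is.na(rtn0$delay$value))
  # a turn that begins before the call offset is not a response
  fr2 <- flat_frames(300 * 30, segment = "m1")
  fr2$yaw[fr2$t >= 20.0] <- 40  # turn starts 1 s before offset (21)
  rtn2 <- response_to_name(make_signals(fr2, name_calls = nc0[1, ]))
  expect_equal(rtn2$proportion$value, 0)
  # invisible child during every window -> both missing, rho 0
  fr3 <- flat_frames(300 * 30, segment = "m1")
  fr3$valid <- FALSE
  rtn3 <- response_to_name(make_signals(fr3, name_calls = nc0))
  expect_true(is.na(rtn3$proportion$value))
  expect_equal(rtn3$proportion$rho, 0)
})

test_that("blink rate: constant openness, square-wave dips", {
  fr <- flat_frames(30 * 30)
  expect_equal(blink_rate(make_signals(fr), "social")$value, 0)
  # 10 dips in 30 s -> 20 blinks/min
  dip_starts <- seq(30, 30 * 30 - 30, length.out = 10)
  for (d in dip_starts) fr$eye_openness[d:(d + 3)] <- 0
  expect_equal(blink_rate(make_signals(fr), "social")$value, 20)
})

test_that("touch metrics: rates, error SD, force averages, equivariance", {
  tc <- data.frame(t = seq(1, 12), x = runif(12), y = runif(12),
                   popped = rep(c(TRUE, FALSE), c(9, 3)),
                   force = rep(2, 12), traj_length = rep(0.3, 12),
                   bubble_x = NA_real_, bubble_y = NA_real_)
  tc$bubble_x <- tc$x; tc$bubble_y <- tc$y  # exactly at centers
  fr <- flat_frames(60, class = "game", segment = "game")
  sig <- make_signals(fr, touches = tc)
  tm <- touch_metrics(sig)
  expect_equal(tm$touch_popping_rate$value, 0.75)
  expect_equal(tm$touch_error_sd$value, 0)
  expect_equal(tm$touch_average_applied_force$value, 2)
  # forces {1,2,3} -> mean 2
  tc3 <- tc[1:3, ]; tc3$force <- c(1, 2, 3)
  expect_equal(touch_metrics(make_signals(fr, touches = tc3))$
                 touch_average_applied_force$value, 2)
  # scale equivariance: coords * c leaves popping rate unchanged and
  # multiplies error SD and trajectory length by c
  set.seed(8)
  tc$x <- tc$bubble_x + rnorm(12, 0, 0.05)
  tc$y <- tc$bubble_y + rnorm(12, 0, 0.05)
  base <- touch_metrics(make_signals(fr, touches = tc))
  cc <- 3.5
  tcs <- tc
  for (col in c("x", "y", "bubble_x", "bubble_y", "traj_length"))
    tcs[[col]] <- tcs[[col]] * cc
  scaled <- touch_metrics(make_signals(fr, touches = tcs))
  expect_equal(scaled$touch_popping_rate$value,
               base$touch_popping_rate$value)
  expect_equal(scaled$touch_error_sd$value,
               cc * base$touch_error_sd$value, tolerance = 1e-12)
  expect_equal(scaled$touch_average_length$value,
               cc * base$touch_average_length$value, tolerance = 1e-12)
})

test_that("extract_all is total: full, game-only and empty sessions", {
  av <- extract_all(default_session())
  expect_named(av$values, app_variable_names())
  expect_true(all(!is.na(av$values)))
  expect_true(all(av$rho > 0 & av$rho <= 1))
  # game-only session: exactly the four touch variables present
  sig <- default_session()
  camera <- sig$layout$name[sig$layout$class != "game"]
  av2 <- extract_all(degrade_session(sig, camera))
  touch_vars <- c("touch_popping_rate", "touch_error_sd",
                  "touch_average_length", "touch_average_applied_force")
  expect_true(all(!is.na(av2$values[touch_vars])))
  expect_true(all(is.na(av2$values[setdiff(app_variable_names(),
                                           touch_vars)])))
  # bounded outputs
  expect_true(av$values["gaze_silhouette"] >= -1 &&
                av$values["gaze_silhouette"] <= 1)
  expect_true(av$values["gaze_speech_correlation"] >= -1 &&
                av$values["gaze_speech_correlation"] <= 1)
  expect_gte(av$values["rtn_delay"], 0)
})
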