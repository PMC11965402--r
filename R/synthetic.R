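#' Motion profile of a repeated exercise
#'
#' Describes the commanded joint-angle trajectory of one exercise bout:
#' each repetition holds at `theta_start` for `dwell` seconds, moves to
#' `theta_end`, holds there for `dwell` seconds, and moves back, all
#' within `rep_period` seconds. Default angle ranges per exercise place
#' the trajectory well inside the exercise's counting thresholds:
#' hip flexion 170 -> 10, hip external rotation 170 -> 20, knee
#' extension 90 -> 170 degrees.
#'
#' @param exercise `"hip_flexion"`, `"hip_external_rotation"` or
#'   `"knee_extension"`.
#' @param reps number of repetitions (>= 0).
#' @param theta_start,theta_end trajectory extremes in degrees;
#'   `theta_end` may be a vector of length `reps` for per-repetition
#'   amplitudes.
#' @param rep_period seconds per repetition (> 2 * dwell).
#' @param dwell seconds held at each extreme.
#' @param waveform `"smoothstep"` (default) or `"sinusoid"` easing.
#' @return An object of class `motion_profile`.
#' @export
motion_profile <- function(exercise = "hip_flexion", reps = 10L,
                           theta_start = NULL, theta_end = NULL,
                           rep_period = 3, dwell = 0.5,
                           waveform = c("smoothstep", "sinusoid")) {
  waveform <- match.arg(waveform)
  def <- switch(exercise,
                hip_flexion = c(170, 10),
                hip_external_rotation = c(170, 20),
                knee_extension = c(90, 170),
                stop_romtrack(sprintf("unknown exercise '%s'", exercise),
                              "romtrack_format_error"))
  if (is.null(theta_start)) theta_start <- def[1]
  if (is.null(theta_end)) theta_end <- def[2]
  reps <- as.integer(reps)
  if (reps < 0L) {
    stop_romtrack("reps must be >= 0", "romtrack_validation_error")
  }
  if (reps > 0L && !length(theta_end) %in% c(1L, reps)) {
    stop_romtrack("theta_end must have length 1 or reps",
                  "romtrack_validation_error")
  }
  if (any(theta_end == theta_start)) {
    stop_romtrack("theta_start and theta_end must differ",
                  "romtrack_validation_error")
  }
  if (rep_period <= 2 * dwell || dwell < 0) {
    stop_romtrack("need rep_period > 2 * dwell >= 0",
                  "romtrack_validation_error")
  }
  if (any(c(theta_start, theta_end) < 0 | c(theta_start, theta_end) > 180)) {
    stop_romtrack("trajectory extremes must lie in [0, 180]",
                  "romtrack_validation_error")
  }
  structure(list(exercise = exercise, reps = reps,
                 theta_start = theta_start, theta_end = theta_end,
                 rep_period = rep_period, dwell = dwell,
                 waveform = waveform),
            class = "motion_profile")
}

#' Planar body model for the landmark generator
#'
#' 2-D segment lengths in normalised image units and the fixed hip
#' anchor. The seated subject faces image-right: the thigh points from
#' the hip toward +x and the shank swings about the knee so that the
#' hip-knee-ankle angle equals the commanded trajectory angle.
#'
#' @param side exercising side, `"left"` or `"right"`.
#' @param hip_anchor (x, y) of the mid-hip point.
#' @param trunk,thigh,shank,foot segment lengths (> 0).
#' @return An object of class `body_model`.
#' @export
body_model <- function(side = c("left", "right"),
                       hip_anchor = c(0.50, 0.45), trunk = 0.22,
                       thigh = 0.20, shank = 0.20, foot = 0.06) {
  side <- match.arg(side)
  if (any(c(trunk, thigh, shank, foot) <= 0)) {
    stop_romtrack("segment lengths must be positive",
                  "romtrack_validation_error")
  }
  reach <- thigh + shank + foot
  if (hip_anchor[1] + reach > 1 || hip_anchor[2] + reach > 1 ||
      hip_anchor[2] - trunk - 0.15 < 0) {
    stop_romtrack("body would leave the unit image frame",
                  "romtrack_configuration_error")
  }
  structure(list(side = side, hip_anchor = as.numeric(hip_anchor),
                 trunk = trunk, thigh = thigh, shank = shank, foot = foot),
            class = "body_model")
}

#' Landmark noise model
#'
#' @param coord_sd Gaussian noise SD on x and y of every landmark
#'   (normalised units).
#' @param angle_sd Gaussian jitter SD on the commanded joint angle
#'   (degrees), applied before forward kinematics.
#' @param dropout_prob per-frame probability that one landmark of the
#'   exercising joint triple gets a sub-threshold visibility.
#' @param seed RNG seed; identical seed gives identical output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(coord_sd = 0, angle_sd = 0, dropout_prob = 0,
                        seed = 1L) {
  if (coord_sd < 0 || angle_sd < 0) {
    stop_romtrack("noise SDs must be >= 0", "romtrack_validation_error")
  }
  if (dropout_prob < 0 || dropout_prob > 1) {
    stop_romtrack("dropout_prob must lie in [0, 1]",
                  "romtrack_validation_error")
  }
  structure(list(coord_sd = coord_sd, angle_sd = angle_sd,
                 dropout_prob = dropout_prob, seed = as.integer(seed)),
            class = "noise_model")
}

# commanded angle at time t (vectorised); theta_end may be per-rep
profile_theta <- function(profile, t) {
  P <- profile$rep_period
  d <- profile$dwell
  mt <- (P - 2 * d) / 2
  wave <- switch(profile$waveform,
                 smoothstep = function(u) 3 * u^2 - 2 * u^3,
                 sinusoid = function(u) (1 - cos(pi * u)) / 2)
  ends <- rep_len(profile$theta_end, max(profile$reps, 1L))
  vapply(t, function(ti) {
    r <- floor(ti / P) + 1
    if (profile$reps == 0L || r > profile$reps) return(profile$theta_start)
    tau <- ti - (r - 1) * P
    s <- if (tau < d) 0
         else if (tau < d + mt) wave((tau - d) / mt)
         else if (tau < 2 * d + mt) 1
         else wave(1 - (tau - 2 * d - mt) / mt)
    profile$theta_start + (ends[r] - profile$theta_start) * s
  }, numeric(1))
}

# static landmark template around the body model; returns x, y vectors
# of length 33 (z = 0).  Legs are filled in per-frame.
body_template <- function(body) {
  x <- numeric(N_LANDMARKS); y <- numeric(N_LANDMARKS)
  set_lm <- function(name, p) {
    i <- landmark_index(name)
    x[i] <<- p[1]; y[i] <<- p[2]
  }
  hip <- body$hip_anchor
  sho <- hip - c(0, body$trunk)
  set_lm("left_hip", hip + c(-0.015, 0))
  set_lm("right_hip", hip + c(0.015, 0))
  set_lm("left_shoulder", sho + c(-0.015, 0))
  set_lm("right_shoulder", sho + c(0.015, 0))
  head <- sho - c(0, 0.10)
  set_lm("nose", head + c(0.03, 0))
  for (s in c("left", "right")) {
    off <- if (s == "left") -0.012 else 0.012
    set_lm(paste0(s, "_eye_inner"), head + c(0.02, -0.015 + off / 4))
    set_lm(paste0(s, "_eye"), head + c(0.015 + off, -0.02))
    set_lm(paste0(s, "_eye_outer"), head + c(0.01 + off, -0.02))
    set_lm(paste0(s, "_ear"), head + c(off * 2, -0.01))
    set_lm(paste0("mouth_", s), head + c(0.025, 0.01 + off / 3))
    sh <- sho + c(if (s == "left") -0.015 else 0.015, 0)
    set_lm(paste0(s, "_elbow"), sh + c(0.02, 0.10))
    set_lm(paste0(s, "_wrist"), sh + c(0.06, 0.16))
    set_lm(paste0(s, "_pinky"), sh + c(0.075, 0.175))
    set_lm(paste0(s, "_index"), sh + c(0.08, 0.17))
    set_lm(paste0(s, "_thumb"), sh + c(0.07, 0.165))
  }
  list(x = x, y = y)
}

# fill one side's leg landmarks for a given knee angle (degrees)
fill_leg <- function(x, y, body, side, theta_deg) {
  hip <- c(x[landmark_index(paste0(side, "_hip"))],
           y[landmark_index(paste0(side, "_hip"))])
  knee <- hip + c(body$thigh, 0)
  th <- theta_deg * pi / 180
  shank_dir <- c(-cos(th), sin(th))   # angle at knee w.r.t. hip ray
  ankle <- knee + body$shank * shank_dir
  perp <- c(sin(th), cos(th))
  set_at <- function(name, p) {
    i <- landmark_index(name)
    x[i] <<- p[1]; y[i] <<- p[2]
  }
  set_at(paste0(side, "_knee"), knee)
  set_at(paste0(side, "_ankle"), ankle)
  set_at(paste0(side, "_heel"), ankle - 0.3 * body$foot * perp)
  set_at(paste0(side, "_foot_index"), ankle + body$foot * perp)
  list(x = x, y = y)
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  force(code)
}

#' Generate one synthetic exercise session with ground truth
#'
#' Forward kinematics of the planar body model driven by the motion
#' profile: the exercising side's hip-knee-ankle angle follows the
#' commanded trajectory (plus optional angle jitter), all 33 landmarks
#' are emitted so files are schema-complete, and the returned ground
#' truth records the true repetition windows, ROM and count. Output is
#' deterministic for a fixed noise seed.
#'
#' @param profile a [motion_profile()].
#' @param body a [body_model()]; its `side` is the exercising side.
#' @param noise a [noise_model()].
#' @param fps frames per second.
#' @param subject subject id recorded in the sequence metadata.
#' @return list with `sequence` (a [landmark_sequence()]) and `truth`
#'   (list: `rep_count`, `rep_windows` data frame, `true_rom`, `theta`
#'   commanded angle per frame).
#' @export
generate_session <- function(profile, body = body_model(),
                             noise = noise_model(), fps = 30,
                             subject = "synthetic") {
  stopifnot(inherits(profile, "motion_profile"),
            inherits(body, "body_model"), inherits(noise, "noise_model"))
  with_preserved_rng({
    set.seed(noise$seed)
    total <- max(profile$reps, 1L) * profile$rep_period
    t <- seq(0, total, by = 1 / fps)
    n <- length(t)
    theta_true <- profile_theta(profile, t)
    theta_cmd <- theta_true
    if (noise$angle_sd > 0) {
      theta_cmd <- pmin(180, pmax(0, theta_cmd +
                                    stats::rnorm(n, 0, noise$angle_sd)))
    }
    tmpl <- body_template(body)
    other <- if (body$side == "left") "right" else "left"
    base <- fill_leg(tmpl$x, tmpl$y, body, other, 90)
    X <- matrix(NA_real_, n, N_LANDMARKS)
    Y <- matrix(NA_real_, n, N_LANDMARKS)
    for (i in seq_len(n)) {
      f <- fill_leg(base$x, base$y, body, body$side, theta_cmd[i])
      X[i, ] <- f$x; Y[i, ] <- f$y
    }
    if (noise$coord_sd > 0) {
      X <- X + matrix(stats::rnorm(n * N_LANDMARKS, 0, noise$coord_sd),
                      n, N_LANDMARKS)
      Y <- Y + matrix(stats::rnorm(n * N_LANDMARKS, 0, noise$coord_sd),
                      n, N_LANDMARKS)
    }
    V <- matrix(1, n, N_LANDMARKS)
    if (noise$dropout_prob > 0) {
      triple_cols <- landmark_index(paste0(body$side,
                                           c("_hip", "_knee", "_ankle")))
      drop <- stats::runif(n) < noise$dropout_prob
      for (i in which(drop)) {
        V[i, sample(triple_cols, 1L)] <- stats::runif(1, 0.3, 0.89)
      }
    }
    seqn <- landmark_sequence(
      frame_index = seq_len(n) - 1L, t = t, x = X, y = Y,
      z = matrix(0, n, N_LANDMARKS), v = V, fps = fps,
      subject = subject, exercise = profile$exercise, side = body$side)
    rep_windows <- if (profile$reps > 0L) {
      P <- profile$rep_period
      do.call(rbind, lapply(seq_len(profile$reps), function(r) {
        rows <- which(t >= (r - 1) * P & t <= r * P)
        data.frame(index = r, start_row = min(rows), end_row = max(rows),
                   start_frame = min(rows) - 1L, end_frame = max(rows) - 1L)
      }))
    } else {
      data.frame(index = integer(0), start_row = integer(0),
                 end_row = integer(0), start_frame = integer(0),
                 end_frame = integer(0))
    }
    ends <- rep_len(profile$theta_end, max(profile$reps, 1L))
    truth <- list(
      rep_count = profile$reps,
      rep_windows = rep_windows,
      true_rom = if (profile$reps > 0L)
        abs(profile$theta_start - ends[seq_len(profile$reps)]) else numeric(0),
      theta = theta_true)
    list(sequence = seqn, truth = truth)
  })
}

#' Generate a cohort of synthetic exercise sessions
#'
#' Emulates a study cohort: `n_subjects` subjects each perform
#' `reps_per_leg` repetitions with each leg. When `rom_mean` is given,
#' each subject draws a personal ROM from
#' `N(rom_mean, rom_between_sd^2)` (shared by both legs) and every
#' repetition jitters it by `N(0, rom_within_sd^2)`; otherwise all
#' sessions use the profile's default fixed amplitude. All per-session
#' seeds derive deterministically from `seed`.
#'
#' @param n_subjects,legs_per_subject,reps_per_leg cohort shape
#'   (defaults 30, 2, 10).
#' @param exercise exercise name.
#' @param rom_mean optional mean commanded ROM (degrees).
#' @param rom_between_sd,rom_within_sd between-subject and
#'   within-subject ROM standard deviations (degrees).
#' @param noise a [noise_model()]; its seed field is overridden by the
#'   derived per-session seeds.
#' @param fps frames per second.
#' @param rep_period,dwell,waveform forwarded to [motion_profile()].
#' @param seed master seed.
#' @return list with `sessions` (each: `sequence`, `truth`, `subject`,
#'   `side`) and `params`.
#' @export
generate_cohort <- function(n_subjects = 30L, legs_per_subject = 2L,
                            reps_per_leg = 10L, exercise = "hip_flexion",
                            rom_mean = NULL, rom_between_sd = 0,
                            rom_within_sd = 0, noise = noise_model(),
                            fps = 30, rep_period = 3, dwell = 0.5,
                            waveform = "smoothstep", seed = 42L) {
  if (n_subjects < 1L || legs_per_subject < 1L || reps_per_leg < 1L) {
    stop_romtrack("cohort shape must be >= 1 in every dimension",
                  "romtrack_validation_error")
  }
  base <- motion_profile(exercise, reps = reps_per_leg,
                         rep_period = rep_period, dwell = dwell,
                         waveform = waveform)
  sgn <- sign(base$theta_end[1] - base$theta_start)
  with_preserved_rng({
    set.seed(seed)
    sides <- c("left", "right")[seq_len(min(legs_per_subject, 2L))]
    sessions <- list()
    for (s in seq_len(n_subjects)) {
      subj_rom <- if (!is.null(rom_mean))
        stats::rnorm(1, rom_mean, rom_between_sd) else NA_real_
      for (leg in seq_len(legs_per_subject)) {
        side <- sides[(leg - 1L) %% 2L + 1L]
        if (!is.null(rom_mean)) {
          roms <- subj_rom + stats::rnorm(reps_per_leg, 0, rom_within_sd)
          roms <- pmin(pmax(roms, 1), 178)
          ends <- pmin(178, pmax(1, base$theta_start + sgn * roms))
          prof <- motion_profile(exercise, reps = reps_per_leg,
                                 theta_start = base$theta_start,
                                 theta_end = ends,
                                 rep_period = rep_period, dwell = dwell,
                                 waveform = waveform)
        } else {
          prof <- base
        }
        sess_noise <- noise_model(noise$coord_sd, noise$angle_sd,
                                  noise$dropout_prob,
                                  seed = sample.int(2147483646L, 1L))
        sess <- generate_session(prof, body_model(side = side),
                                 sess_noise, fps = fps,
                                 subject = sprintf("S%02d", s))
        sess$subject <- sprintf("S%02d", s)
        sess$side <- side
        sessions[[length(sessions) + 1L]] <- sess
      }
    }
    list(sessions = sessions,
         params = list(n_subjects = n_subjects,
                       legs_per_subject = legs_per_subject,
                       reps_per_leg = reps_per_leg, exercise = exercise,
                       rom_mean = rom_mean,
                       rom_between_sd = rom_between_sd,
                       rom_within_sd = rom_within_sd, seed = seed))
  })
}

#' Generate a labelled terminal-state pose dataset
#'
#' Samples frames at the two terminal states of an exercise ("down" at
#' the start angle, "up" at the target angle), jitters the joint angle
#' within each cluster, embeds every frame with [embed_pose()] and
#' splits into a training [pose_dataset()] and a held-out test set.
#'
#' @param exercise exercise name.
#' @param n_per_class training samples per terminal state.
#' @param cluster_separation angular distance between the two class
#'   means (degrees); default the exercise's full default excursion.
#' @param noise_sd within-class angular jitter SD (degrees).
#' @param n_test_per_class held-out samples per class.
#' @param k neighbour count stored in the dataset.
#' @param side exercising side.
#' @param seed RNG seed.
#' @return list with `train` (a [pose_dataset()]), `test_embeddings`,
#'   `test_labels`, `classes`.
#' @export
generate_pose_dataset <- function(exercise = "hip_flexion",
                                  n_per_class = 50L,
                                  cluster_separation = NULL,
                                  noise_sd = 2, n_test_per_class = 20L,
                                  k = 10L, side = "left", seed = 1L) {
  prof <- motion_profile(exercise, reps = 1L)
  down <- prof$theta_start
  sep <- if (is.null(cluster_separation))
    abs(prof$theta_end[1] - prof$theta_start) else cluster_separation
  up <- down + sign(prof$theta_end[1] - prof$theta_start) * sep
  body <- body_model(side = side)
  classes <- paste(exercise, c("down", "up"), sep = "_")
  with_preserved_rng({
    set.seed(seed)
    draw <- function(mu, m) {
      th <- pmin(179, pmax(1, stats::rnorm(m, mu, noise_sd)))
      tmpl <- body_template(body)
      other <- if (side == "left") "right" else "left"
      base <- fill_leg(tmpl$x, tmpl$y, body, other, 90)
      t(vapply(th, function(a) {
        f <- fill_leg(base$x, base$y, body, side, a)
        fr <- structure(list(
          frame_index = 0L, t = 0,
          landmarks = data.frame(name = blazepose_landmarks, x = f$x,
                                 y = f$y, z = 0, v = 1)),
          class = "landmark_frame")
        embed_pose(fr)
      }, numeric(2L * length(embedding_landmarks))))
    }
    ntr <- n_per_class; nte <- n_test_per_class
    Xd <- draw(down, ntr + nte); Xu <- draw(up, ntr + nte)
    train <- pose_dataset(rbind(Xd[seq_len(ntr), , drop = FALSE],
                                Xu[seq_len(ntr), , drop = FALSE]),
                          rep(classes, each = ntr), k = k)
    list(train = train,
         test_embeddings = rbind(Xd[ntr + seq_len(nte), , drop = FALSE],
                                 Xu[ntr + seq_len(nte), , drop = FALSE]),
         test_labels = rep(classes, each = nte), classes = classes)
  })
}
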