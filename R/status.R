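#' Ordered fuzzy status bands
#'
#' Five movement-quality categories, worst to best: starting position
#' (`ST`), `LOW`, `OKAY`, `GOOD`, `PERFECT`.
#' @export
status_bands <- c("ST", "LOW", "OKAY", "GOOD", "PERFECT")

# default band edges and rep thresholds per exercise.  Bands are stored
# as interior break points on [0, 180] plus the band label of each cell,
# listed from theta = 0 upward; intervals are (lower, upper] with the
# lowest closed at 0.
default_exercise_params <- function(name) {
  switch(name,
    hip_flexion = list(
      breaks = c(15, 60, 100, 130),
      labels = c("PERFECT", "GOOD", "OKAY", "LOW", "ST"),
      direction = "decreasing",
      rep_start_threshold = 160, rep_target_threshold = 15),
    hip_external_rotation = list(
      breaks = c(30, 60, 100, 130),
      labels = c("PERFECT", "GOOD", "OKAY", "LOW", "ST"),
      direction = "decreasing",
      rep_start_threshold = 150, rep_target_threshold = 30),
    knee_extension = list(
      # package default five-band scheme anchored at the exercise's two
      # trajectory thresholds (95 and 160); direction reversed because
      # the knee straightens toward 180
      breaks = c(95, 115, 140, 160),
      labels = c("ST", "LOW", "OKAY", "GOOD", "PERFECT"),
      direction = "increasing",
      rep_start_threshold = 95, rep_target_threshold = 160),
    stop_romtrack(sprintf("unknown exercise '%s'", name),
                  "romtrack_format_error")
  )
}

#' Exercise specification: joint, bands, repetition thresholds
#'
#' Bundles everything needed to score one exercise on one side: the
#' joint triple, the five status-band edges, the movement direction
#' (which way theta moves toward `PERFECT`), and the hysteresis
#' thresholds for repetition counting. Status bands and repetition
#' thresholds are deliberately separate parameters: the bands grade the
#' instantaneous angle, while a repetition is only counted when theta
#' crosses the start threshold, reaches the target threshold and returns.
#'
#' Defaults per exercise (degrees):
#' \describe{
#'   \item{hip_flexion}{decreasing; `PERFECT <= 15 < GOOD <= 60 < OKAY
#'     <= 100 < LOW <= 130 < ST`; rep start > 160, target < 15.}
#'   \item{hip_external_rotation}{decreasing; same bands with the
#'     `GOOD`/`PERFECT` edge at 30; rep start > 150, target < 30.}
#'   \item{knee_extension}{increasing; `ST <= 95 < LOW <= 115 < OKAY <=
#'     140 < GOOD <= 160 < PERFECT`; rep start < 95, target > 160. The
#'     five-band tiling between the two published trajectory thresholds
#'     is a package default and fully overridable.}
#' }
#'
#' @param name `"hip_flexion"`, `"hip_external_rotation"` or
#'   `"knee_extension"`.
#' @param side `"left"` or `"right"`; picks the default joint triple
#'   (hip-knee-ankle of that side, vertex at the knee).
#' @param triple optional [joint_triple()] override.
#' @param breaks optional numeric vector of 4 strictly increasing
#'   interior band edges in (0, 180).
#' @param labels optional character vector of 5 band labels (a
#'   permutation of [status_bands]) for the cells of `breaks`, listed
#'   from theta = 0 upward.
#' @param direction `"decreasing"` or `"increasing"`.
#' @param rep_start_threshold,rep_target_threshold hysteresis thresholds
#'   in degrees; for decreasing exercises start > target, reversed for
#'   increasing.
#' @param min_rep_frames debounce: excursions out of the start region
#'   shorter than this many frames are ignored (default 3 at 30 fps).
#' @return An object of class `exercise_spec`.
#' @export
exercise_spec <- function(name, side = c("left", "right"), triple = NULL,
                          breaks = NULL, labels = NULL, direction = NULL,
                          rep_start_threshold = NULL,
                          rep_target_threshold = NULL,
                          min_rep_frames = 3L) {
  side <- match.arg(side)
  def <- default_exercise_params(name)
  breaks <- if (is.null(breaks)) def$breaks else as.numeric(breaks)
  labels <- if (is.null(labels)) def$labels else as.character(labels)
  direction <- if (is.null(direction)) def$direction else
    match.arg(direction, c("decreasing", "increasing"))
  if (is.null(rep_start_threshold)) rep_start_threshold <- def$rep_start_threshold
  if (is.null(rep_target_threshold)) rep_target_threshold <- def$rep_target_threshold
  if (is.null(triple)) {
    triple <- joint_triple(paste0(side, "_hip"), paste0(side, "_knee"),
                           paste0(side, "_ankle"))
  }
  if (length(breaks) != 4L || any(diff(breaks) <= 0) ||
      breaks[1] <= 0 || breaks[4] >= 180) {
    stop_romtrack("breaks must be 4 strictly increasing edges in (0, 180)",
                  "romtrack_validation_error")
  }
  if (length(labels) != 5L || !setequal(labels, status_bands)) {
    stop_romtrack("labels must be a permutation of the five status bands",
                  "romtrack_validation_error")
  }
  for (th in c(rep_start_threshold, rep_target_threshold)) {
    if (th < 0 || th > 180) {
      stop_romtrack("repetition thresholds must lie in [0, 180]",
                    "romtrack_validation_error")
    }
  }
  if (direction == "decreasing" &&
      rep_start_threshold <= rep_target_threshold) {
    stop_romtrack("decreasing exercise needs start threshold > target",
                  "romtrack_validation_error")
  }
  if (direction == "increasing" &&
      rep_start_threshold >= rep_target_threshold) {
    stop_romtrack("increasing exercise needs start threshold < target",
                  "romtrack_validation_error")
  }
  structure(
    list(name = name, side = side, triple = triple, breaks = breaks,
         labels = labels, direction = direction,
         rep_start_threshold = rep_start_threshold,
         rep_target_threshold = rep_target_threshold,
         min_rep_frames = as.integer(min_rep_frames)),
    class = "exercise_spec")
}

#' @export
print.exercise_spec <- function(x, ...) {
  edges <- c(0, x$breaks, 180)
  cells <- paste(sprintf("(%g,%g]=%s", edges[-6], edges[-1], x$labels),
                 collapse = " ")
  cat(sprintf("<exercise_spec> %s (%s, %s)\n  bands: %s\n  reps: start %s%g°, target %s%g°, debounce %d frames\n",
              x$name, x$side, x$direction, cells,
              if (x$direction == "decreasing") ">" else "<",
              x$rep_start_threshold,
              if (x$direction == "decreasing") "<" else ">",
              x$rep_target_threshold, x$min_rep_frames))
  invisible(x)
}

#' Classify an instantaneous joint angle into a status band
#'
#' Band intervals are half-open `(lower, upper]` with the lowest band
#' closed at 0, so every angle in \[0, 180\] maps to exactly one band:
#' e.g. for hip flexion 130 degrees is `LOW` ("less than or equal" the
#' edge) while 130.0001 is `ST`.
#'
#' @param theta angle(s) in degrees, each in \[0, 180\].
#' @param spec an [exercise_spec()].
#' @return factor with the five ordered levels of [status_bands]
#'   (worst to best), same length as `theta`.
#' @export
#' @examples
#' sp <- exercise_spec("hip_flexion", "left")
#' classify_status(12.49, sp) # PERFECT
classify_status <- function(theta, spec) {
  stopifnot(inherits(spec, "exercise_spec"))
  if (any(!is.finite(theta)) || any(theta < 0 | theta > 180)) {
    stop_romtrack("theta must lie in [0, 180]", "romtrack_domain_error")
  }
  cell <- cut(theta, breaks = c(0, spec$breaks, 180),
              include.lowest = TRUE, right = TRUE, labels = FALSE)
  factor(spec$labels[cell], levels = status_bands, ordered = TRUE)
}

# start/target region membership (NA theta -> FALSE)
in_start_region <- function(theta, spec) {
  r <- if (spec$direction == "decreasing") theta > spec$rep_start_threshold
       else theta < spec$rep_start_threshold
  r & !is.na(theta)
}

in_target_region <- function(theta, spec) {
  r <- if (spec$direction == "decreasing") theta < spec$rep_target_threshold
       else theta > spec$rep_target_threshold
  r & !is.na(theta)
}

#' Count exercise repetitions by hysteresis
#'
#' A repetition is recorded each time the angle, starting in the start
#' region (e.g. theta > 160 for hip flexion), crosses into the target
#' region (theta < 15) and returns to the start region. The two
#' thresholds form a hysteresis band: jitter around a single threshold
#' cannot double-count. Excursions out of the start region shorter than
#' `min_rep_frames` are ignored, as are excursions that never reach the
#' target. A repetition's window opens at the first start-region frame
#' of its cycle (so the hold at the starting extreme is part of the
#' repetition) and closes at the frame of re-entry into the start
#' region; ROM is computed over that closed window.
#'
#' @param trace an [angle_trace()].
#' @param spec an [exercise_spec()].
#' @return data frame of repetitions with columns `index`, `start_frame`,
#'   `end_frame` (frame indices), `start_row`, `end_row` (1-based rows
#'   into the trace), `theta_min`, `theta_max`, `rom`, `best_band`.
#' @export
count_repetitions <- function(trace, spec) {
  stopifnot(inherits(trace, "angle_trace"), inherits(spec, "exercise_spec"))
  theta <- trace$theta_deg
  n <- length(theta)
  empty <- data.frame(index = integer(0), start_frame = integer(0),
                      end_frame = integer(0), start_row = integer(0),
                      end_row = integer(0), theta_min = numeric(0),
                      theta_max = numeric(0), rom = numeric(0),
                      best_band = character(0))
  if (n == 0L) return(empty)
  st <- in_start_region(theta, spec)
  tg <- in_target_region(theta, spec)
  if (!any(st)) {
    warn_romtrack("trace never enters the start region; no repetitions",
                  "romtrack_no_start_region")
    return(empty)
  }
  reps <- list()
  state <- "idle"   # idle -> armed (seen start) -> hit (seen target)
  window_open <- NA_integer_  # first start-region frame of this cycle
  last_start <- NA_integer_   # latest start-region frame seen
  for (i in seq_len(n)) {
    if (st[i]) {
      if (state == "idle") {
        window_open <- i
      }
      if (state == "hit") {
        # closing a candidate excursion; debounce on its length
        if (i - last_start - 1L >= spec$min_rep_frames) {
          th <- theta[window_open:i]
          reps[[length(reps) + 1L]] <- data.frame(
            start_row = window_open, end_row = i,
            theta_min = min(th, na.rm = TRUE),
            theta_max = max(th, na.rm = TRUE))
          window_open <- i  # re-entry frame starts the next cycle
        }
      }
      state <- "armed"
      last_start <- i
    } else if (state == "armed" && tg[i]) {
      state <- "hit"
    }
  }
  if (length(reps) == 0L) return(empty)
  out <- do.call(rbind, reps)
  out$index <- seq_len(nrow(out))
  out$start_frame <- trace$frame[out$start_row]
  out$end_frame <- trace$frame[out$end_row]
  out$rom <- out$theta_max - out$theta_min
  best <- vapply(seq_len(nrow(out)), function(r) {
    bands <- classify_status(
      stats::na.omit(trace$theta_deg[out$start_row[r]:out$end_row[r]]),
      spec)
    as.character(bands[which.max(as.integer(bands))])
  }, character(1))
  out$best_band <- best
  out[, c("index", "start_frame", "end_frame", "start_row", "end_row",
          "theta_min", "theta_max", "rom", "best_band")]
}

#' Range of motion of one repetition
#'
#' ROM is defined as `max(theta) - min(theta)` over the repetition's
#' closed frame window.
#'
#' @param rep one row of the data frame returned by
#'   [count_repetitions()] (or any list with `start_row` and `end_row`).
#' @param trace the [angle_trace()] the repetition was counted on.
#' @return ROM in degrees (>= 0).
#' @export
extract_rom <- function(rep, trace) {
  stopifnot(inherits(trace, "angle_trace"))
  th <- trace$theta_deg[rep$start_row:rep$end_row]
  max(th, na.rm = TRUE) - min(th, na.rm = TRUE)
}

#' Run a full tracking session
#'
#' End-to-end scoring of one landmark sequence against one exercise
#' specification: visibility filtering on the triple's landmarks, angle
#' trace, per-frame status bands, hysteresis repetition counting,
#' per-repetition ROM and summary statistics.
#'
#' @param seq a [landmark_sequence()].
#' @param spec an [exercise_spec()].
#' @param visibility_threshold passed to [filter_visibility()].
#' @param visibility_policy passed to [filter_visibility()].
#' @param smooth_window passed to [angle_trace()].
#' @return A `session_report`: list with `exercise`, `side`, `frames`
#'   (data frame `frame`, `t`, `theta_deg`, `band`), `repetitions`,
#'   `rep_count`, `rom_series`, `summary` (see [rom_summary()]), and the
#'   `spec` used.
#' @export
run_session <- function(seq, spec, visibility_threshold = 0.9,
                        visibility_policy = "hold_last",
                        smooth_window = 1L) {
  stopifnot(inherits(seq, "landmark_sequence"),
            inherits(spec, "exercise_spec"))
  idx0 <- c(spec$triple$start, spec$triple$vertex, spec$triple$end) - 1L
  filt <- filter_visibility(seq, indices = idx0,
                            threshold = visibility_threshold,
                            policy = visibility_policy)
  trace <- angle_trace(filt$sequence, spec$triple,
                       smooth_window = smooth_window)
  ok <- trace$flag == "ok" & !is.na(trace$theta_deg)
  band <- rep(NA_character_, nrow(trace))
  if (any(ok)) {
    band[ok] <- as.character(classify_status(trace$theta_deg[ok], spec))
  }
  reps <- if (nrow(trace) > 0 && any(in_start_region(trace$theta_deg, spec)))
    count_repetitions(trace, spec) else count_repetitions_quiet(trace, spec)
  roms <- reps$rom
  structure(
    list(exercise = spec$name, side = spec$side,
         frames = data.frame(frame = trace$frame, t = trace$t,
                             theta_deg = trace$theta_deg, band = band),
         repetitions = reps, rep_count = nrow(reps), rom_series = roms,
         summary = if (length(roms) > 0) rom_summary(roms) else NULL,
         spec = spec),
    class = "session_report")
}

# empty-trace path without the no-start-region warning noise
count_repetitions_quiet <- function(trace, spec) {
  suppressWarnings(count_repetitions(trace, spec))
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %s (%s): %d frames, %d repetitions\n",
              x$exercise, x$side, nrow(x$frames), x$rep_count))
  if (!is.null(x$summary)) {
    cat(sprintf("  ROM per rep: mean %.2f°, median %.2f°, sd %.2f°\n",
                x$summary$mean, x$summary$median, x$summary$sd))
  }
  invisible(x)
}

#' Write a session report to disk
#'
#' Emits `report.json` (counts, repetitions, ROM summary) and
#' `frames.csv` (per-frame angle and band) under `dir`.
#'
#' @param report a `session_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_report <- function(report, dir) {
  stopifnot(inherits(report, "session_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$frames, file.path(dir, "frames.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(exercise = report$exercise, side = report$side,
         rep_count = report$rep_count,
         repetitions = report$repetitions,
         rom_series = report$rom_series,
         summary = report$summary),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
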