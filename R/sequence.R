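#' Construct a landmark sequence
#'
#' The central container for a pose stream: per-frame coordinates and
#' visibilities of all 33 body landmarks, stored as frame-by-landmark
#' matrices, plus capture metadata. `x` and `y` are image-normalised
#' coordinates (origin top-left, `y` increasing downward), `z` is the
#' estimator's relative depth (hip-centred, negative toward the camera)
#' and `v` the per-landmark visibility confidence in \[0, 1\].
#'
#' @param frame_index integer vector, strictly increasing, >= 0.
#' @param t numeric vector of timestamps in seconds, non-decreasing; if
#'   `NULL`, synthesised as `frame_index / fps`.
#' @param x,y,z,v numeric matrices with one row per frame and 33 columns
#'   (in [blazepose_landmarks] order).
#' @param fps frames per second, > 0.
#' @param subject,exercise,side free-form capture metadata (`side` must be
#'   `"left"` or `"right"` when given).
#' @param tags named list of additional metadata.
#' @return An object of class `landmark_sequence`.
#' @export
landmark_sequence <- function(frame_index, t = NULL, x, y, z, v,
                              fps = 30, subject = NA_character_,
                              exercise = NA_character_,
                              side = NA_character_, tags = list()) {
  frame_index <- as.integer(frame_index)
  n <- length(frame_index)
  for (nm in c("x", "y", "z", "v")) {
    m <- get(nm)
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != N_LANDMARKS) {
      stop_romtrack(sprintf("'%s' must be a %d x 33 matrix", nm, n),
                    "romtrack_format_error")
    }
  }
  if (n > 0 && (any(is.na(frame_index)) || any(frame_index < 0L))) {
    stop_romtrack("frame_index must be non-negative integers",
                  "romtrack_format_error")
  }
  if (n > 1 && any(diff(frame_index) <= 0L)) {
    stop_romtrack("frame_index must be strictly increasing",
                  "romtrack_ordering_error")
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop_romtrack("fps must be a single positive number",
                  "romtrack_format_error")
  }
  if (is.null(t)) t <- frame_index / fps
  t <- as.numeric(t)
  if (length(t) != n) {
    stop_romtrack("t must have one timestamp per frame",
                  "romtrack_format_error")
  }
  if (n > 1 && any(diff(t) < 0)) {
    stop_romtrack("timestamps must be non-decreasing",
                  "romtrack_ordering_error")
  }
  if (n > 0) {
    if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))) {
      stop_romtrack("landmark coordinates must be finite",
                    "romtrack_format_error")
    }
    if (any(v < 0 | v > 1, na.rm = TRUE) || anyNA(v)) {
      stop_romtrack("visibility must lie in [0, 1]",
                    "romtrack_format_error")
    }
  }
  dimnames(x) <- dimnames(y) <- dimnames(z) <- dimnames(v) <-
    list(NULL, blazepose_landmarks)
  if (!is.na(side) && !side %in% c("left", "right")) {
    stop_romtrack("side must be 'left' or 'right'", "romtrack_format_error")
  }
  structure(
    list(frame_index = frame_index, t = t, x = x, y = y, z = z, v = v,
         fps = fps, subject = subject, exercise = exercise, side = side,
         tags = tags),
    class = "landmark_sequence"
  )
}

#' Number of frames in a landmark sequence
#' @param x a `landmark_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "landmark_sequence"))
  length(x$frame_index)
}

#' @export
print.landmark_sequence <- function(x, ...) {
  cat(sprintf(
    "<landmark_sequence> %d frames @ %g fps (33 landmarks)\n",
    n_frames(x), x$fps))
  if (!is.na(x$exercise) || !is.na(x$side)) {
    cat(sprintf("  exercise: %s  side: %s  subject: %s\n",
                x$exercise, x$side, x$subject))
  }
  invisible(x)
}

#' Extract one frame from a sequence
#'
#' @param seq a `landmark_sequence`.
#' @param i frame position (1-based row into the sequence).
#' @return A `landmark_frame`: list with `frame_index`, `t` and a
#'   33-row `landmarks` data frame (`name`, `x`, `y`, `z`, `v`).
#' @export
get_frame <- function(seq, i) {
  stopifnot(inherits(seq, "landmark_sequence"))
  if (i < 1L || i > n_frames(seq)) {
    stop_romtrack(sprintf("frame position %d out of range", i),
                  "romtrack_format_error")
  }
  structure(
    list(frame_index = seq$frame_index[i], t = seq$t[i],
         landmarks = data.frame(name = blazepose_landmarks,
                                x = seq$x[i, ], y = seq$y[i, ],
                                z = seq$z[i, ], v = seq$v[i, ],
                                row.names = NULL)),
    class = "landmark_frame"
  )
}

#' Keep a subset of frames (rows) of a sequence
#' @noRd
subset_frames <- function(seq, keep) {
  landmark_sequence(
    frame_index = seq$frame_index[keep], t = seq$t[keep],
    x = seq$x[keep, , drop = FALSE], y = seq$y[keep, , drop = FALSE],
    z = seq$z[keep, , drop = FALSE], v = seq$v[keep, , drop = FALSE],
    fps = seq$fps, subject = seq$subject, exercise = seq$exercise,
    side = seq$side, tags = seq$tags
  )
}
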