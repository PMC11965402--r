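#' Define a joint as a landmark triple
#'
#' A joint angle is measured at a vertex landmark between the rays to a
#' start and an end landmark — e.g. the knee angle at the vertex `knee`
#' between the `hip` and `ankle` rays. Angles are computed from 2-D
#' image coordinates by default; `dims = 3` includes the estimator's
#' relative depth.
#'
#' @param start,vertex,end landmark names or 0-based indices; must be
#'   three distinct landmarks.
#' @param dims 2 (x, y only; default) or 3 (include z).
#' @return An object of class `joint_triple`.
#' @export
#' @examples
#' joint_triple("left_hip", "left_knee", "left_ankle")
joint_triple <- function(start, vertex, end, dims = 2) {
  idx <- landmark_index(c(start, vertex, end))
  if (anyDuplicated(idx)) {
    stop_romtrack("start, vertex and end must be distinct landmarks",
                  "romtrack_format_error")
  }
  if (!dims %in% c(2, 3)) {
    stop_romtrack("dims must be 2 or 3", "romtrack_format_error")
  }
  structure(list(start = idx[1], vertex = idx[2], end = idx[3],
                 dims = as.integer(dims)),
            class = "joint_triple")
}

#' @export
print.joint_triple <- function(x, ...) {
  cat(sprintf("<joint_triple> %s -- [%s] -- %s (%dD)\n",
              blazepose_landmarks[x$start], blazepose_landmarks[x$vertex],
              blazepose_landmarks[x$end], x$dims))
  invisible(x)
}

# clamp a cosine into [-1, 1]; values beyond 1 + tol are a caller error
clamp_cosine <- function(ct, tol = 1e-9) {
  if (any(abs(ct) > 1 + tol, na.rm = TRUE)) {
    stop_romtrack("cosine argument exceeds [-1, 1] beyond tolerance",
                  "romtrack_domain_error")
  }
  pmin(1, pmax(-1, ct))
}

#' Angle between two vectors (dot-product rule)
#'
#' `theta = arccos((a . b) / (|a| |b|))`, in degrees in \[0, 180\]. The
#' cosine is clamped to \[-1, 1\] (tolerance 1e-9) before `acos` so that
#' round-off near parallel vectors cannot produce `NaN`.
#'
#' @param a,b numeric vectors of equal length (2-D or 3-D).
#' @return angle in degrees.
#' @export
#' @examples
#' vector_angle(c(1, 0), c(0, 1)) # 90
vector_angle <- function(a, b) {
  if (length(a) != length(b)) {
    stop_romtrack("vectors must have equal dimension",
                  "romtrack_format_error")
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop_romtrack("zero-length vector: angle undefined",
                  "romtrack_degenerate_geometry")
  }
  acos(clamp_cosine(sum(a * b) / (na * nb))) * 180 / pi
}

#' Angle from three side lengths (law of cosines)
#'
#' For a triangle with the measured joint at vertex A, `b = |AC|`,
#' `c = |AB|` and `a = |BC|`: `cos A = (b^2 + c^2 - a^2) / (2 b c)`.
#' Returns A in degrees in \[0, 180\].
#'
#' @param b,c the two side lengths adjacent to the vertex (> 0).
#' @param a the side length opposite the vertex.
#' @return angle at the vertex, degrees.
#' @export
#' @examples
#' cosine_rule_angle(b = 3, c = 4, a = 5) # 90
cosine_rule_angle <- function(b, c, a) {
  if (b <= 0 || c <= 0) {
    stop_romtrack("adjacent side lengths must be positive",
                  "romtrack_degenerate_geometry")
  }
  acos(clamp_cosine((b^2 + c^2 - a^2) / (2 * b * c))) * 180 / pi
}

#' Joint angle of a landmark triple in one frame
#'
#' Vector-rule angle between `start - vertex` and `end - vertex`; agrees
#' with the law-of-cosines form on the pairwise distances to numerical
#' precision.
#'
#' @param frame a `landmark_frame` (see [get_frame()]).
#' @param triple a [joint_triple()].
#' @param method `"vector"` (default) or `"cosine_rule"` — two
#'   algebraically equivalent routes, kept separate for cross-validation.
#' @return angle in degrees in \[0, 180\].
#' @export
triple_angle <- function(frame, triple, method = c("vector", "cosine_rule")) {
  stopifnot(inherits(frame, "landmark_frame"),
            inherits(triple, "joint_triple"))
  method <- match.arg(method)
  lm <- frame$landmarks
  cols <- if (triple$dims == 2L) c("x", "y") else c("x", "y", "z")
  P <- as.matrix(lm[c(triple$start, triple$vertex, triple$end), cols])
  if (method == "vector") {
    vector_angle(P[1, ] - P[2, ], P[3, ] - P[2, ])
  } else {
    cosine_rule_angle(b = sqrt(sum((P[1, ] - P[2, ])^2)),
                      c = sqrt(sum((P[3, ] - P[2, ])^2)),
                      a = sqrt(sum((P[1, ] - P[3, ])^2)))
  }
}

#' Per-frame joint-angle trace of a sequence
#'
#' Computes the triple's angle in every frame (vectorised), optionally
#' smoothed by a centred moving average. Frames with degenerate geometry
#' (a landmark coincident with the vertex) yield `NA` with
#' `flag = "degenerate"` rather than an error, so one bad frame does not
#' abort a session.
#'
#' @param seq a [landmark_sequence()].
#' @param triple a [joint_triple()].
#' @param smooth_window odd window width in frames for a centred moving
#'   average; 1 (default) disables smoothing.
#' @return An `angle_trace`: data frame with columns `frame`, `t`,
#'   `theta_deg`, `method`, `flag` (`"ok"` or `"degenerate"`); the
#'   sequence's fps is kept as attribute `fps`.
#' @export
angle_trace <- function(seq, triple, smooth_window = 1L) {
  stopifnot(inherits(seq, "landmark_sequence"),
            inherits(triple, "joint_triple"))
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    stop_romtrack("smooth_window must be a positive odd integer",
                  "romtrack_format_error")
  }
  n <- n_frames(seq)
  if (n == 0L) {
    out <- data.frame(frame = integer(0), t = numeric(0),
                      theta_deg = numeric(0), method = character(0),
                      flag = character(0))
    return(structure(out, class = c("angle_trace", "data.frame"),
                     fps = seq$fps))
  }
  s <- triple$start; vx <- triple$vertex; e <- triple$end
  ax <- seq$x[, s] - seq$x[, vx]; ay <- seq$y[, s] - seq$y[, vx]
  bx <- seq$x[, e] - seq$x[, vx]; by <- seq$y[, e] - seq$y[, vx]
  dot <- ax * bx + ay * by
  na2 <- ax^2 + ay^2; nb2 <- bx^2 + by^2
  if (triple$dims == 3L) {
    az <- seq$z[, s] - seq$z[, vx]; bz <- seq$z[, e] - seq$z[, vx]
    dot <- dot + az * bz
    na2 <- na2 + az^2; nb2 <- nb2 + bz^2
  }
  deg <- na2 == 0 | nb2 == 0
  theta <- rep(NA_real_, n)
  ok <- !deg
  theta[ok] <- acos(clamp_cosine(dot[ok] / sqrt(na2[ok] * nb2[ok]))) *
    180 / pi
  if (smooth_window > 1L && n > 1L) {
    theta <- moving_average(theta, smooth_window)
  }
  out <- data.frame(frame = seq$frame_index, t = seq$t, theta_deg = theta,
                    method = "vector",
                    flag = ifelse(deg, "degenerate", "ok"))
  structure(out, class = c("angle_trace", "data.frame"), fps = seq$fps)
}

# centred moving average with shrinking windows at the edges; NAs pass
# through untouched and do not contaminate neighbours
moving_average <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  out <- x
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- mean(x[lo:hi], na.rm = TRUE)
  }
  out
}

#' Write an angle trace to CSV
#' @param trace an `angle_trace`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_angle_trace <- function(trace, path) {
  stopifnot(inherits(trace, "angle_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
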