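#' Read a landmark stream from JSONL or CSV
#'
#' Two on-disk dialects are supported. JSONL holds one frame per line:
#' `{"frame": int, "t": float, "landmarks": [{"name", "x", "y", "z", "v"}
#' x 33]}`. CSV is long format with columns `frame,t,name,x,y,z,v` and 33
#' rows per frame. Every frame must carry all 33 landmarks of the
#' BlazePose topology; missing or surplus landmarks raise a format error
#' naming the offending frame.
#'
#' @param path file to read.
#' @param format `"jsonl"` or `"csv"`; default guessed from the file
#'   extension.
#' @param fps frames per second recorded in the returned sequence
#'   (timestamps in the file take precedence over `fps` if present).
#' @param ... further metadata passed to [landmark_sequence()]
#'   (`subject`, `exercise`, `side`, `tags`).
#' @return A validated [landmark_sequence()].
#' @export
read_landmarks <- function(path, format = c("auto", "jsonl", "csv"),
                           fps = 30, ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (!file.exists(path)) {
    stop_romtrack(sprintf("file not found: %s", path), "romtrack_io_error")
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    frames <- lapply(lines, jsonlite::fromJSON, simplifyDataFrame = TRUE)
    long <- do.call(rbind, lapply(frames, function(fr) {
      lm <- fr$landmarks
      data.frame(frame = fr$frame,
                 t = if (is.null(fr$t)) NA_real_ else fr$t,
                 name = lm$name, x = lm$x, y = lm$y, z = lm$z, v = lm$v)
    }))
  } else {
    long <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("frame", "t", "name", "x", "y", "z", "v")
    if (!all(need %in% names(long))) {
      stop_romtrack(sprintf("CSV must have columns %s",
                            paste(need, collapse = ",")),
                    "romtrack_format_error")
    }
  }
  long_to_sequence(long, fps = fps, ...)
}

# long data.frame (frame,t,name,x,y,z,v) -> landmark_sequence
long_to_sequence <- function(long, fps = 30, ...) {
  if (is.null(long) || nrow(long) == 0L) {
    empty <- matrix(numeric(0), nrow = 0, ncol = N_LANDMARKS)
    return(landmark_sequence(integer(0), numeric(0), empty, empty, empty,
                             empty, fps = fps, ...))
  }
  ord <- unique(long$frame)
  if (any(diff(ord) <= 0)) {
    stop_romtrack("frame indices are not strictly increasing",
                  "romtrack_ordering_error")
  }
  idx <- match(long$frame, ord)
  n <- length(ord)
  col <- match(long$name, blazepose_landmarks)
  if (anyNA(col)) {
    bad <- unique(long$name[is.na(col)])
    stop_romtrack(sprintf("unknown landmark name(s): %s",
                          paste(bad, collapse = ", ")),
                  "romtrack_format_error")
  }
  counts <- tabulate(idx, nbins = n)
  dup <- tapply(col, idx, function(z) anyDuplicated(z) > 0L)
  if (any(counts != N_LANDMARKS) || any(dup)) {
    bad <- ord[which(counts != N_LANDMARKS | dup)[1]]
    stop_romtrack(
      sprintf("frame %d does not carry exactly the 33 topology landmarks",
              bad),
      "romtrack_format_error")
  }
  mk <- function(vals) {
    m <- matrix(NA_real_, n, N_LANDMARKS)
    m[cbind(idx, col)] <- vals
    m
  }
  t_per_frame <- long$t[!duplicated(long$frame)]
  if (anyNA(t_per_frame)) t_per_frame <- NULL
  landmark_sequence(frame_index = ord, t = t_per_frame,
                    x = mk(long$x), y = mk(long$y), z = mk(long$z),
                    v = mk(long$v), fps = fps, ...)
}

sequence_to_long <- function(seq) {
  n <- n_frames(seq)
  data.frame(
    frame = rep(seq$frame_index, each = N_LANDMARKS),
    t = rep(seq$t, each = N_LANDMARKS),
    name = rep(blazepose_landmarks, times = n),
    x = as.vector(t(seq$x)), y = as.vector(t(seq$y)),
    z = as.vector(t(seq$z)), v = as.vector(t(seq$v))
  )
}

#' Write a landmark sequence to JSONL or CSV
#'
#' Inverse of [read_landmarks()]: the written file reads back to a
#' sequence with identical coordinates (up to float formatting; 12
#' significant digits are emitted).
#'
#' @param seq a [landmark_sequence()].
#' @param path destination file.
#' @param format `"jsonl"` or `"csv"`; default guessed from extension.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(seq, path, format = c("auto", "jsonl", "csv")) {
  stopifnot(inherits(seq, "landmark_sequence"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "jsonl") {
    n <- n_frames(seq)
    lines <- vapply(seq_len(n), function(i) {
      fr <- list(
        frame = seq$frame_index[i], t = seq$t[i],
        landmarks = data.frame(name = blazepose_landmarks,
                               x = seq$x[i, ], y = seq$y[i, ],
                               z = seq$z[i, ], v = seq$v[i, ]))
      jsonlite::toJSON(fr, auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path)
  } else {
    long <- sequence_to_long(seq)
    utils::write.csv(format(long, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Handle low-visibility landmarks in a sequence
#'
#' Frames where any of the requested landmarks falls strictly below the
#' visibility threshold are treated per `policy`:
#' \describe{
#'   \item{drop}{remove the affected frames;}
#'   \item{hold_last}{replace the affected landmarks' coordinates with
#'     their value in the nearest preceding confident frame (the first
#'     confident frame back-fills any leading gap);}
#'   \item{interpolate}{linearly interpolate each affected coordinate
#'     between the neighbouring confident frames.}
#' }
#' The default threshold 0.9 is the upstream estimator's "high
#' confidence" cut.
#'
#' @param seq a [landmark_sequence()].
#' @param indices landmarks to police: names or 0-based indices; default
#'   all 33.
#' @param threshold visibility cut in \[0, 1\]; a landmark is unreliable
#'   when `v < threshold` (strict).
#' @param policy `"hold_last"` (default), `"drop"` or `"interpolate"`.
#' @return list with `sequence` (the filtered [landmark_sequence()]) and
#'   `mask` (logical, one element per input frame, `TRUE` where the frame
#'   was affected).
#' @export
filter_visibility <- function(seq, indices = blazepose_landmarks,
                              threshold = 0.9,
                              policy = c("hold_last", "drop",
                                         "interpolate")) {
  stopifnot(inherits(seq, "landmark_sequence"))
  policy <- match.arg(policy)
  if (threshold < 0 || threshold > 1) {
    stop_romtrack("threshold must lie in [0, 1]", "romtrack_format_error")
  }
  cols <- landmark_index(indices)
  n <- n_frames(seq)
  low <- seq$v[, cols, drop = FALSE] < threshold
  mask <- if (n > 0) apply(low, 1, any) else logical(0)
  if (!any(mask)) {
    return(list(sequence = seq, mask = mask))
  }
  if (policy == "drop") {
    return(list(sequence = subset_frames(seq, !mask), mask = mask))
  }
  if (policy == "interpolate" && sum(!mask) < 2L) {
    warn_romtrack(
      "fewer than 2 fully-visible frames; falling back to hold_last",
      "romtrack_interp_fallback")
    policy <- "hold_last"
  }
  out <- seq
  for (jj in seq_along(cols)) {
    j <- cols[jj]
    bad <- low[, jj]
    if (!any(bad)) next
    good <- which(!bad)
    if (length(good) == 0L) {
      warn_romtrack(sprintf(
        "landmark '%s' never reaches visibility %.3g; left untouched",
        blazepose_landmarks[j], threshold), "romtrack_all_low_visibility")
      next
    }
    for (field in c("x", "y", "z")) {
      vals <- out[[field]][, j]
      if (policy == "hold_last") {
        # nearest preceding good frame; first good frame back-fills
        src <- findInterval(seq_len(n), good)
        src[src == 0L] <- 1L
        out[[field]][bad, j] <- vals[good[src[bad]]]
      } else {
        out[[field]][bad, j] <- stats::approx(
          x = good, y = vals[good], xout = which(bad), rule = 2)$y
      }
    }
  }
  list(sequence = out, mask = mask)
}
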