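#' The 33-landmark BlazePose body topology
#'
#' Fixed index-to-name mapping for the 33 body keypoints emitted by the
#' upstream pose estimator. Index 0 is the nose; lower-limb landmarks of
#' interest are 23/24 (hips), 25/26 (knees), 27/28 (ankles), 29/30 (heels)
#' and 31/32 (foot index). All sequence containers in this package pin
#' their landmark order to this vector; unknown landmark names or indices
#' are rejected rather than passed through.
#'
#' @format A character vector of length 33; element `i` names landmark
#'   index `i - 1` (the topology is conventionally 0-based).
#' @export
blazepose_landmarks <- c(
  "nose",
  "left_eye_inner", "left_eye", "left_eye_outer",
  "right_eye_inner", "right_eye", "right_eye_outer",
  "left_ear", "right_ear",
  "mouth_left", "mouth_right",
  "left_shoulder", "right_shoulder",
  "left_elbow", "right_elbow",
  "left_wrist", "right_wrist",
  "left_pinky", "right_pinky",
  "left_index", "right_index",
  "left_thumb", "right_thumb",
  "left_hip", "right_hip",
  "left_knee", "right_knee",
  "left_ankle", "right_ankle",
  "left_heel", "right_heel",
  "left_foot_index", "right_foot_index"
)

N_LANDMARKS <- 33L

#' Resolve landmark names or 0-based indices to 1-based column positions
#'
#' @param x character vector of landmark names, or numeric vector of
#'   0-based landmark indices (the topology's native indexing).
#' @return integer vector of 1-based positions into [blazepose_landmarks].
#' @export
#' @examples
#' landmark_index("left_knee")   # 26 (0-based index 25)
#' landmark_index(c(23, 25, 27)) # left hip, knee, ankle
landmark_index <- function(x) {
  if (is.character(x)) {
    pos <- match(x, blazepose_landmarks)
    if (anyNA(pos)) {
      stop_romtrack(sprintf("unknown landmark name(s): %s",
                            paste(x[is.na(pos)], collapse = ", ")),
                    "romtrack_bad_landmark")
    }
    return(pos)
  }
  idx <- as.integer(x)
  if (any(is.na(idx)) || any(idx < 0L) || any(idx >= N_LANDMARKS)) {
    stop_romtrack("landmark indices must lie in 0..32", "romtrack_bad_landmark")
  }
  idx + 1L
}

# classed conditions so callers can distinguish degenerate geometry,
# format errors etc. from ordinary failures
stop_romtrack <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "romtrack_error"),
                      call = call))
}

warn_romtrack <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "romtrack_warning")))
}
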