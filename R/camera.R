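#' Camera extrinsics (rigid transform)
#'
#' A rotation `R` and translation `T` mapping keypoint coordinates into
#' the camera frame as `R p + T`. `R` must be a proper rotation:
#' orthonormal with determinant +1, checked to 1e-9.
#'
#' @param R 3x3 rotation matrix.
#' @param T length-3 translation vector (scene units).
#' @return An object of class `camera_extrinsics`.
#' @export
camera_extrinsics <- function(R = diag(3), T = c(0, 0, 0)) {
  R <- as.matrix(R)
  T <- as.numeric(T)
  if (!all(dim(R) == c(3L, 3L)) || length(T) != 3L) {
    stop_romtrack("R must be 3x3 and T length 3", "romtrack_format_error")
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    stop_romtrack("R is not a proper rotation (orthonormal, det +1)",
                  "romtrack_validation_error")
  }
  structure(list(R = R, T = T), class = "camera_extrinsics")
}

#' Camera intrinsics (pinhole model)
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx = 0, cy = 0) {
  if (fx <= 0 || fy <= 0) {
    stop_romtrack("focal lengths must be positive",
                  "romtrack_validation_error")
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy),
            class = "camera_intrinsics")
}

#' Rigidly transform a 3D point into the camera frame
#'
#' Computes `R p + T`.
#'
#' @param p length-3 numeric vector, or an n x 3 matrix of points.
#' @param ext a [camera_extrinsics()].
#' @return transformed point(s), same shape as `p`.
#' @export
#' @examples
#' ext <- camera_extrinsics(diag(3), c(1, 0, 0))
#' transform_point(c(0, 0, 0), ext) # (1, 0, 0)
transform_point <- function(p, ext) {
  stopifnot(inherits(ext, "camera_extrinsics"))
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    return(sweep(p %*% t(ext$R), 2, ext$T, "+"))
  }
  stopifnot(length(p) == 3L)
  as.numeric(ext$R %*% p + ext$T)
}

#' Project a camera-frame 3D point to pixel coordinates
#'
#' Pinhole projection `u = (x/z) fx + cx`, `v = (y/z) fy + cy`.
#'
#' @param p length-3 numeric vector with nonzero depth `z`.
#' @param intr a [camera_intrinsics()].
#' @return named numeric vector `c(u =, v =)`.
#' @export
project_point <- function(p, intr) {
  stopifnot(inherits(intr, "camera_intrinsics"), length(p) == 3L)
  if (p[3] == 0) {
    stop_romtrack("cannot project a point with zero depth",
                  "romtrack_domain_error")
  }
  c(u = p[1] / p[3] * intr$fx + intr$cx,
    v = p[2] / p[3] * intr$fy + intr$cy)
}
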