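# Shared fixture builders and independent oracles, all generated in code.

# A landmark frame with every point at (0.5, 0.5, 0) except explicit
# overrides: coords = named list of c(x, y) or c(x, y, z).
make_frame <- function(coords = list(), v = rep(1, 33)) {
  x <- rep(0.5, 33); y <- rep(0.5, 33); z <- rep(0, 33)
  for (nm in names(coords)) {
    i <- landmark_index(nm)
    p <- coords[[nm]]
    x[i] <- p[1]; y[i] <- p[2]
    if (length(p) > 2) z[i] <- p[3]
  }
  structure(list(frame_index = 0L, t = 0,
                 landmarks = data.frame(name = blazepose_landmarks,
                                        x = x, y = y, z = z, v = v)),
            class = "landmark_frame")
}

# A sequence whose left hip-knee-ankle angle equals `thetas` frame by
# frame (exact planar geometry); shoulders placed so embeddings work.
make_theta_sequence <- function(thetas, fps = 30, v = NULL, side = "left") {
  n <- length(thetas)
  X <- matrix(0.5, n, 33); Y <- matrix(0.5, n, 33); Z <- matrix(0, n, 33)
  hip <- c(0.5, 0.45); thigh <- 0.2; shank <- 0.2
  set_col <- function(nm, px, py) {
    i <- landmark_index(nm)
    X[, i] <<- px; Y[, i] <<- py
  }
  set_col("left_hip", hip[1] - 0.015, hip[2])
  set_col("right_hip", hip[1] + 0.015, hip[2])
  set_col("left_shoulder", hip[1] - 0.015, hip[2] - 0.22)
  set_col("right_shoulder", hip[1] + 0.015, hip[2] - 0.22)
  hx <- if (side == "left") hip[1] - 0.015 else hip[1] + 0.015
  knee <- c(hx + thigh, hip[2])
  th <- thetas * pi / 180
  set_col(paste0(side, "_knee"), knee[1], knee[2])
  set_col(paste0(side, "_ankle"), knee[1] - shank * cos(th),
          knee[2] + shank * sin(th))
  V <- if (is.null(v)) matrix(1, n, 33) else v
  landmark_sequence(frame_index = seq_len(n) - 1L, x = X, y = Y, z = Z,
                    v = V, fps = fps, side = side)
}

# Independent repetition-count oracle: compress the per-frame region
# labels (S = start region, T = target region, o = neither) with rle and
# count S ... T ... S patterns on the label string — a different route
# from the package's state machine.  No debounce, so use it on traces
# built with min_rep_frames = 0.
oracle_rep_count <- function(theta, start_thr, target_thr,
                             decreasing = TRUE) {
  lab <- ifelse(if (decreasing) theta > start_thr else theta < start_thr,
                "S",
                ifelse(if (decreasing) theta < target_thr
                       else theta > target_thr, "T", "o"))
  s <- paste(rle(lab)$values, collapse = "")
  m <- gregexpr("S[^S]*T[^S]*(?=S)", s, perl = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

# Independent brute-force k-NN: repeatedly extract the closest remaining
# sample (selection rather than a single sort), then majority vote with
# the package's documented tie-breaks.
oracle_knn <- function(query, X, labels, k) {
  d <- apply(X, 1, function(r) sqrt(sum((r - query)^2)))
  remaining <- seq_along(d)
  nn <- integer(0)
  for (j in seq_len(k)) {
    best <- remaining[which.min(d[remaining])]
    # which.min takes the first minimum -> insertion-order tie-break
    nn <- c(nn, best)
    remaining <- setdiff(remaining, best)
  }
  votes <- table(factor(labels[nn], levels = sort(unique(labels))))
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    meand <- sapply(top, function(cl) mean(d[nn][labels[nn] == cl]))
    top <- top[order(meand, top)]
  }
  list(votes = votes, predicted = top[1])
}

# random proper rotation (QR of a Gaussian matrix, det corrected to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

table4_path <- function() {
  system.file("extdata", "table4_angles.csv", package = "romtrack")
}
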