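#' Default embedding landmarks: torso + lower limb
#'
#' The 12 landmarks used by the default pose embedding: shoulders, hips,
#' knees, ankles, heels and foot-index points.
#' @export
embedding_landmarks <- c(
  "left_shoulder", "right_shoulder", "left_hip", "right_hip",
  "left_knee", "right_knee", "left_ankle", "right_ankle",
  "left_heel", "right_heel", "left_foot_index", "right_foot_index")

#' Embed a pose frame as a normalised feature vector
#'
#' Coordinates of the selected landmarks are translated so the mid-hip
#' point is the origin and scaled so the mid-hip to mid-shoulder (torso)
#' distance is 1, then flattened in fixed landmark order. The embedding
#' is therefore invariant to image translation and uniform scale — the
#' properties a terminal-state classifier needs to generalise across
#' camera placements and body sizes.
#'
#' @param frame a `landmark_frame` (see [get_frame()]).
#' @param landmark_subset landmarks to include (names or 0-based
#'   indices); default [embedding_landmarks].
#' @param dims 2 (default) or 3.
#' @return numeric vector of length `dims * length(landmark_subset)`,
#'   named `<landmark>.<coord>`.
#' @export
embed_pose <- function(frame, landmark_subset = embedding_landmarks,
                       dims = 2) {
  stopifnot(inherits(frame, "landmark_frame"))
  if (!dims %in% c(2, 3)) {
    stop_romtrack("dims must be 2 or 3", "romtrack_format_error")
  }
  lm <- frame$landmarks
  cols <- if (dims == 2) c("x", "y") else c("x", "y", "z")
  idx <- landmark_index(landmark_subset)
  hip <- colMeans(lm[landmark_index(c("left_hip", "right_hip")), cols])
  sho <- colMeans(lm[landmark_index(c("left_shoulder", "right_shoulder")),
                     cols])
  torso <- sqrt(sum((sho - hip)^2))
  if (torso < 1e-12) {
    stop_romtrack("mid-hip coincides with mid-shoulder: degenerate pose",
                  "romtrack_degenerate_pose")
  }
  P <- sweep(as.matrix(lm[idx, cols]), 2, hip) / torso
  out <- as.numeric(t(P))
  names(out) <- paste(rep(blazepose_landmarks[idx], each = dims), cols,
                      sep = ".")
  out
}

#' Euclidean distance between two embeddings
#'
#' @param x,x2 numeric vectors of equal length.
#' @return non-negative distance.
#' @export
euclidean_distance <- function(x, x2) {
  if (length(x) != length(x2)) {
    stop_romtrack("embedding dimensions differ", "romtrack_format_error")
  }
  sqrt(sum((x - x2)^2))
}

#' Build a labelled pose dataset for k-NN
#'
#' @param embeddings numeric matrix, one embedded pose per row.
#' @param labels character vector of terminal-state class labels, one
#'   per row (e.g. `"hip_flexion_up"`).
#' @param k neighbour count; default 10, which also makes the per-frame
#'   confidence a 0..10 vote count.
#' @return An object of class `pose_dataset`.
#' @export
pose_dataset <- function(embeddings, labels, k = 10L) {
  embeddings <- as.matrix(embeddings)
  labels <- as.character(labels)
  k <- as.integer(k)
  if (nrow(embeddings) != length(labels)) {
    stop_romtrack("one label per embedding row is required",
                  "romtrack_format_error")
  }
  if (!all(is.finite(embeddings))) {
    stop_romtrack("embeddings must be finite", "romtrack_format_error")
  }
  if (nrow(embeddings) < k) {
    stop_romtrack("dataset must contain at least k samples",
                  "romtrack_validation_error")
  }
  if (length(unique(labels)) < 2L) {
    stop_romtrack("dataset must contain at least 2 classes",
                  "romtrack_validation_error")
  }
  structure(list(X = embeddings, labels = labels,
                 class_set = sort(unique(labels)), k = k),
            class = "pose_dataset")
}

#' @export
print.pose_dataset <- function(x, ...) {
  cat(sprintf("<pose_dataset> %d samples x %d features, k = %d\n",
              nrow(x$X), ncol(x$X), x$k))
  print(table(x$labels))
  invisible(x)
}

#' Classify one embedded pose by k nearest neighbours
#'
#' The k training samples nearest to the query (Euclidean distance, ties
#' at the k-th neighbour broken by insertion order) vote for their
#' labels; the class probability is votes / k and the prediction is the
#' modal class. Vote ties are broken by the smaller mean distance to the
#' query among tied classes, then lexicographic class name — all
#' deterministic, so predictions never depend on dataset ordering.
#'
#' @param query numeric embedding vector.
#' @param data a [pose_dataset()].
#' @return list with `votes` (named integer, sums to k), `probabilities`
#'   (named, sums to 1), `predicted` (class name).
#' @export
knn_classify <- function(query, data) {
  stopifnot(inherits(data, "pose_dataset"))
  if (length(query) != ncol(data$X)) {
    stop_romtrack("query dimension does not match dataset",
                  "romtrack_format_error")
  }
  d <- sqrt(colSums((t(data$X) - query)^2))
  ord <- order(d, seq_along(d))
  nn <- ord[seq_len(data$k)]
  votes <- table(factor(data$labels[nn], levels = data$class_set))
  votes <- stats::setNames(as.integer(votes), data$class_set)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    meand <- vapply(top, function(cl) mean(d[nn][data$labels[nn] == cl]),
                    numeric(1))
    top <- top[order(meand, top)]
  }
  list(votes = votes, probabilities = votes / data$k, predicted = top[1])
}

#' Classify every frame of a sequence, with confidence smoothing
#'
#' Per-frame k-NN vote counts (the 0..k confidence trace) are smoothed
#' with an exponential moving average (`alpha` = weight of the current
#' frame; `alpha = 1` disables smoothing) and the predicted class is
#' re-derived from the smoothed votes.
#'
#' @param seq a [landmark_sequence()].
#' @param data a [pose_dataset()].
#' @param smoothing_alpha EMA weight in (0, 1\]; default 0.2.
#' @param landmark_subset,dims forwarded to [embed_pose()].
#' @return A `classification_trace`: list with `frame`, `votes` and
#'   `smoothed` (frame x class matrices on the 0..k scale),
#'   `probabilities`, `predicted` (character per frame), and `k`.
#' @export
classify_sequence <- function(seq, data, smoothing_alpha = 0.2,
                              landmark_subset = embedding_landmarks,
                              dims = 2) {
  stopifnot(inherits(seq, "landmark_sequence"),
            inherits(data, "pose_dataset"))
  if (smoothing_alpha <= 0 || smoothing_alpha > 1) {
    stop_romtrack("smoothing_alpha must lie in (0, 1]",
                  "romtrack_format_error")
  }
  n <- n_frames(seq)
  cls <- data$class_set
  votes <- matrix(0L, n, length(cls), dimnames = list(NULL, cls))
  predicted_raw <- character(n)
  for (i in seq_len(n)) {
    res <- knn_classify(embed_pose(get_frame(seq, i), landmark_subset,
                                   dims), data)
    votes[i, ] <- res$votes
    predicted_raw[i] <- res$predicted
  }
  smoothed <- votes * 1.0
  if (n > 1L) {
    for (i in 2:n) {
      smoothed[i, ] <- smoothing_alpha * votes[i, ] +
        (1 - smoothing_alpha) * smoothed[i - 1L, ]
    }
  }
  predicted <- if (n > 0) cls[max.col(smoothed, ties.method = "first")]
               else character(0)
  structure(
    list(frame = seq$frame_index, votes = votes,
         probabilities = votes / data$k, smoothed = smoothed,
         predicted = predicted, predicted_raw = predicted_raw, k = data$k),
    class = "classification_trace")
}

#' @export
print.classification_trace <- function(x, ...) {
  cat(sprintf("<classification_trace> %d frames, classes: %s (k = %d)\n",
              length(x$frame), paste(colnames(x$votes), collapse = ", "),
              x$k))
  invisible(x)
}

#' Count exercises from a classification trace
#'
#' One count each time the target class's smoothed confidence rises to
#' at least `enter_threshold` after having been at or below
#' `exit_threshold` — hysteresis on the 0..k confidence scale, the
#' classification-route analogue of angle-threshold repetition counting.
#'
#' @param trace a `classification_trace`.
#' @param target_class class whose visits are counted.
#' @param enter_threshold,exit_threshold confidence thresholds on the
#'   0..k scale, `enter_threshold > exit_threshold`.
#' @return integer count.
#' @export
count_by_classification <- function(trace, target_class,
                                    enter_threshold = 8,
                                    exit_threshold = 2) {
  stopifnot(inherits(trace, "classification_trace"))
  if (enter_threshold <= exit_threshold) {
    stop_romtrack("enter_threshold must exceed exit_threshold",
                  "romtrack_validation_error")
  }
  if (!target_class %in% colnames(trace$smoothed)) {
    stop_romtrack(sprintf("unknown class '%s'", target_class),
                  "romtrack_format_error")
  }
  conf <- trace$smoothed[, target_class]
  count <- 0L
  armed <- TRUE   # start counts if confidence is already high at frame 1
  for (ci in conf) {
    if (armed && ci >= enter_threshold) {
      count <- count + 1L
      armed <- FALSE
    } else if (!armed && ci <= exit_threshold) {
      armed <- TRUE
    }
  }
  count
}

#' Evaluate a k-NN pose classifier on a held-out test set
#'
#' @param data a [pose_dataset()] (the training set).
#' @param test_embeddings matrix of test embeddings (one per row).
#' @param test_labels true labels of the test rows.
#' @return list with `accuracy`, `confusion` (true x predicted table)
#'   and `per_class` data frame (`class`, `precision`, `recall`).
#' @export
evaluate_classifier <- function(data, test_embeddings, test_labels) {
  stopifnot(inherits(data, "pose_dataset"))
  test_embeddings <- as.matrix(test_embeddings)
  if (nrow(test_embeddings) == 0L) {
    stop_romtrack("empty test set", "romtrack_validation_error")
  }
  pred <- vapply(seq_len(nrow(test_embeddings)), function(i) {
    knn_classify(test_embeddings[i, ], data)$predicted
  }, character(1))
  lev <- sort(unique(c(data$class_set, test_labels)))
  confusion <- table(true = factor(test_labels, lev),
                     predicted = factor(pred, lev))
  per_class <- data.frame(
    class = lev,
    precision = vapply(lev, function(cl) {
      p <- sum(confusion[, cl])
      if (p == 0) NA_real_ else confusion[cl, cl] / p
    }, numeric(1)),
    recall = vapply(lev, function(cl) {
      a <- sum(confusion[cl, ])
      if (a == 0) NA_real_ else confusion[cl, cl] / a
    }, numeric(1)),
    row.names = NULL)
  list(accuracy = mean(pred == test_labels), confusion = confusion,
       per_class = per_class)
}

#' Read / write a pose dataset as CSV
#'
#' The CSV carries one embedding per row, feature columns first, then a
#' `label` column; `k` is stored in a header comment.
#'
#' @param data a [pose_dataset()].
#' @param path CSV file.
#' @return `write_pose_dataset` returns `path` invisibly;
#'   `read_pose_dataset` returns a [pose_dataset()].
#' @export
write_pose_dataset <- function(data, path) {
  stopifnot(inherits(data, "pose_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d", data$k), con)
  df <- as.data.frame(data$X)
  df$label <- data$labels
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_dataset
#' @export
read_pose_dataset <- function(path) {
  first <- readLines(path, n = 1L)
  k <- if (grepl("^# k=", first)) as.integer(sub("^# k=", "", first)) else 10L
  df <- utils::read.csv(path, comment.char = "#")
  pose_dataset(as.matrix(df[, setdiff(names(df), "label")]), df$label,
               k = k)
}
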