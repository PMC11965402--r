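test_that("pose embedding is translation- and scale-invariant", {
  base <- list(left_hip = c(0.45, 0.5), right_hip = c(0.55, 0.5),
               left_shoulder = c(0.45, 0.3), right_shoulder = c(0.55, 0.3),
               left_knee = c(0.6, 0.55), left_ankle = c(0.62, 0.7),
               right_knee = c(0.65, 0.5), right_ankle = c(0.66, 0.68),
               left_heel = c(0.60, 0.72), right_heel = c(0.64, 0.70),
               left_foot_index = c(0.67, 0.71),
               right_foot_index = c(0.70, 0.69))
  e0 <- embed_pose(make_frame(base))
  shifted <- lapply(base, function(p) p + c(0.3, 0.1))
  expect_equal(embed_pose(make_frame(shifted)), e0, tolerance = 1e-9)
  scaled <- lapply(base, function(p) c(0.2, 0.1) + 2 * p)
  expect_equal(embed_pose(make_frame(scaled)), e0, tolerance = 1e-9)
  # mid-hip == mid-shoulder is degenerate
  flat <- list(left_hip = c(0.45, 0.5), right_hip = c(0.55, 0.5),
               left_shoulder = c(0.45, 0.5), right_shoulder = c(0.55, 0.5))
  expect_error(embed_pose(make_frame(flat)),
               class = "romtrack_degenerate_pose")
})

test_that("euclidean distance behaves like a metric", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_error(euclidean_distance(c(1, 2), c(1, 2, 3)),
               class = "romtrack_format_error")
  set.seed(8)
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(6); z <- rnorm(6)
    expect_equal(euclidean_distance(x, y), euclidean_distance(y, x))
    expect_lte(euclidean_distance(x, z),
               euclidean_distance(x, y) + euclidean_distance(y, z) + 1e-12)
  }
})

test_that("knn_classify votes and probabilities follow the vote rule", {
  set.seed(9)
  X <- rbind(matrix(rnorm(14, 0), 7), matrix(rnorm(6, 10), 3))
  data <- pose_dataset(X, c(rep("up", 7), rep("down", 3)), k = 10)
  res <- knn_classify(c(0, 0), data)
  expect_equal(sum(res$votes), 10L)
  expect_equal(res$probabilities[["up"]], 0.7)
  expect_equal(sum(res$probabilities), 1)
  expect_equal(res$predicted, "up")
  # one-class neighbourhood has probability 1
  near <- knn_classify(c(0, 0), pose_dataset(
    rbind(matrix(rnorm(18, 0, 0.01), 9), matrix(10, 1, 2)),
    c(rep("a", 9), "b"), k = 5))
  expect_equal(near$probabilities[["a"]], 1)
  expect_error(pose_dataset(X[1:5, ], rep(c("a", "b"), c(3, 2)), k = 10),
               class = "romtrack_validation_error")
})

test_that("knn matches the exhaustive selection oracle on random data", {
  set.seed(10)
  for (trial in 1:30) {
    n <- sample(10:50, 1)
    d <- sample(2:6, 1)
    k <- sample(3:min(9, n - 1), 1)
    X <- matrix(rnorm(n * d), n)
    labels <- sample(c("up", "down", "rest"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    data <- pose_dataset(X, labels, k = k)
    for (q in 1:3) {
      query <- rnorm(d)
      got <- knn_classify(query, data)
      want <- oracle_knn(query, X, labels, k)
      expect_equal(as.integer(got$votes[names(want$votes)]),
                   as.integer(want$votes))
      expect_equal(got$predicted, want$predicted)
      expect_equal(sum(got$votes), k)
    }
  }
})

test_that("predictions agree with an independent k-NN implementation", {
  skip_if_not_installed("class")
  set.seed(12)
  X <- matrix(rnorm(80), 40)
  labels <- rep(c("up", "down"), each = 20)
  data <- pose_dataset(X, labels, k = 5)   # odd k, 2 classes: no vote ties
  Q <- matrix(rnorm(30), 15)
  mine <- vapply(seq_len(nrow(Q)),
                 function(i) knn_classify(Q[i, ], data)$predicted,
                 character(1))
  ref <- as.character(class::knn(X, Q, factor(labels), k = 5))
  expect_equal(mine, ref)
})

test_that("predictions are invariant to dataset permutation", {
  set.seed(13)
  X <- matrix(rnorm(60), 30)
  labels <- sample(c("up", "down"), 30, replace = TRUE)
  data <- pose_dataset(X, labels, k = 7)
  perm <- sample(30)
  data_p <- pose_dataset(X[perm, ], labels[perm], k = 7)
  for (q in 1:10) {
    query <- rnorm(2)
    expect_equal(knn_classify(query, data)$predicted,
                 knn_classify(query, data_p)$predicted)
  }
})

test_that("sequence classification traces and hysteresis counting work", {
  pd <- generate_pose_dataset("hip_flexion", n_per_class = 30,
                              noise_sd = 1, seed = 21)
  # constant pose at a training extreme: full confidence every frame
  sess <- generate_session(motion_profile("hip_flexion", reps = 0),
                           body_model("left"), noise_model(seed = 3))
  tr <- classify_sequence(sess$sequence, pd$train, smoothing_alpha = 1)
  expect_true(all(tr$predicted == "hip_flexion_down"))
  expect_true(all(tr$smoothed[, "hip_flexion_down"] == 10))
  expect_true(all(rowSums(tr$votes) == 10))
  # alpha = 1 leaves votes unsmoothed
  expect_equal(tr$smoothed, tr$votes * 1.0)
  # constant full confidence counts exactly once
  expect_equal(count_by_classification(tr, "hip_flexion_down"), 1L)
  expect_equal(count_by_classification(tr, "hip_flexion_up"), 0L)
  # a 10-rep session alternates classes 10 times
  sess10 <- generate_session(motion_profile("hip_flexion", reps = 10),
                             body_model("left"), noise_model(seed = 4))
  tr10 <- classify_sequence(sess10$sequence, pd$train)
  expect_equal(count_by_classification(tr10, "hip_flexion_up"), 10L)
  runs <- rle(tr10$predicted)$values
  expect_equal(sum(runs == "hip_flexion_up"), 10L)
})

test_that("classifier evaluation reports accuracy, precision and recall", {
  pd <- generate_pose_dataset("hip_flexion", n_per_class = 100,
                              noise_sd = 2, n_test_per_class = 50,
                              seed = 22)
  ev <- evaluate_classifier(pd$train, pd$test_embeddings, pd$test_labels)
  expect_gte(ev$accuracy, 0.99)
  expect_true(all(ev$per_class$precision >= 0.98))
  # train == test with k = 1 is perfect
  d1 <- pose_dataset(pd$train$X, pd$train$labels, k = 1)
  ev1 <- evaluate_classifier(d1, pd$train$X, pd$train$labels)
  expect_equal(ev1$accuracy, 1)
  # overlapping classes are at chance
  set.seed(23)
  Xnull <- matrix(rnorm(400), 200)
  lnull <- rep(c("a", "b"), 100)
  dnull <- pose_dataset(Xnull[1:100, ], lnull[1:100], k = 9)
  evn <- evaluate_classifier(dnull, Xnull[101:200, ], lnull[101:200])
  expect_gt(evn$accuracy, 0.3); expect_lt(evn$accuracy, 0.7)
})

test_that("pose datasets round-trip through CSV", {
  pd <- generate_pose_dataset("knee_extension", n_per_class = 15,
                              seed = 24, k = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_dataset(pd$train, path)
  back <- read_pose_dataset(path)
  expect_equal(back$k, 7L)
  expect_equal(back$labels, pd$train$labels)
  expect_equal(unname(back$X), unname(pd$train$X), tolerance = 1e-9)
})
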