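hf <- exercise_spec("hip_flexion", "left")
her <- exercise_spec("hip_external_rotation", "left")
ke <- exercise_spec("knee_extension", "left")

test_that("status bands reproduce the rule edges, boundaries included", {
  expect_equal(as.character(classify_status(12.49, hf)), "PERFECT")
  expect_equal(as.character(classify_status(3.51, hf)), "PERFECT")
  expect_equal(as.character(classify_status(45, her)), "GOOD")
  expect_equal(as.character(classify_status(130, hf)), "LOW")
  expect_equal(as.character(classify_status(130.0001, hf)), "ST")
  expect_equal(as.character(classify_status(100, hf)), "OKAY")
  expect_equal(as.character(classify_status(c(15, 60), hf)),
               c("PERFECT", "GOOD"))
  expect_equal(as.character(classify_status(30, her)), "PERFECT")
  expect_equal(as.character(classify_status(c(95, 160, 160.5), ke)),
               c("ST", "GOOD", "PERFECT"))
  expect_error(classify_status(180.5, hf), class = "romtrack_domain_error")
  expect_error(classify_status(-1, hf), class = "romtrack_domain_error")
})

test_that("every angle maps to exactly one band and ordering is monotone", {
  grid <- seq(0, 180, by = 0.01)
  for (spec in list(hf, her, ke)) {
    bands <- classify_status(grid, spec)
    expect_false(anyNA(bands))
    # for decreasing exercises lower theta never maps to a worse band
    ranks <- as.integer(bands)
    if (spec$direction == "decreasing") {
      expect_true(all(diff(ranks) <= 0))
    } else {
      expect_true(all(diff(ranks) >= 0))
    }
  }
})

test_that("repetition counting matches the excursion oracle", {
  tri <- function(n_reps, lo, hi, len = 40) {
    rep(c(seq(hi, lo, length.out = len), seq(lo, hi, length.out = len)),
        n_reps)
  }
  spec0 <- exercise_spec("hip_flexion", "left", min_rep_frames = 0L)
  cases <- list(
    tri(10, 10, 170),                      # 10 clean reps
    tri(3, 20, 170),                       # never below 15: 0 reps
    c(tri(2, 10, 170), seq(170, 100, length.out = 30)),  # trailing partial
    seq(170, 10, length.out = 50),         # no return: 0 reps
    rep(170, 20),                          # never leaves start: 0 reps
    c(tri(1, 10, 170), rep(120, 25), tri(1, 5, 175))     # pause between
  )
  for (theta in cases) {
    trace <- angle_trace(make_theta_sequence(theta), spec0$triple)
    got <- nrow(count_repetitions(trace, spec0))
    want <- oracle_rep_count(theta, 160, 15, decreasing = TRUE)
    expect_equal(got, want)
  }
  # increasing direction (knee extension thresholds)
  ke0 <- exercise_spec("knee_extension", "left", min_rep_frames = 0L)
  theta_up <- rep(c(seq(90, 170, length.out = 40),
                    seq(170, 90, length.out = 40)), 4)
  trace_up <- angle_trace(make_theta_sequence(theta_up), ke0$triple)
  expect_equal(nrow(count_repetitions(trace_up, ke0)),
               oracle_rep_count(theta_up, 95, 160, decreasing = FALSE))
})

test_that("debounce ignores short spikes and windows stay disjoint", {
  # a 1-frame dip into target must not count with min_rep_frames = 3
  theta <- c(rep(170, 5), 10, rep(170, 5),
             rep(c(seq(170, 10, length.out = 20),
                   seq(10, 170, length.out = 20)), 2))
  spec3 <- exercise_spec("hip_flexion", "left", min_rep_frames = 3L)
  trace <- angle_trace(make_theta_sequence(theta), spec3$triple)
  reps <- count_repetitions(trace, spec3)
  expect_equal(nrow(reps), 2L)
  expect_true(all(reps$start_row < reps$end_row))
  if (nrow(reps) > 1) {
    expect_true(all(diff(as.vector(rbind(reps$start_row,
                                         reps$end_row))) >= 0))
  }
  # never entering the start region warns and returns nothing
  low <- angle_trace(make_theta_sequence(rep(100, 10)), spec3$triple)
  expect_warning(out <- count_repetitions(low, spec3),
                 class = "romtrack_no_start_region")
  expect_equal(nrow(out), 0L)
})

test_that("ROM is max minus min over the repetition window", {
  theta <- c(rep(170, 3), seq(170, 15, length.out = 20),
             seq(15, 170, length.out = 20), rep(170, 3))
  spec0 <- exercise_spec("hip_flexion", "left", min_rep_frames = 0L)
  trace <- angle_trace(make_theta_sequence(theta), spec0$triple)
  reps <- count_repetitions(trace, spec0)
  expect_equal(nrow(reps), 1L)
  expect_equal(reps$rom, 155, tolerance = 1e-6)
  expect_equal(extract_rom(reps[1, ], trace), 155, tolerance = 1e-6)
  expect_true(all(reps$rom >= 0 & reps$rom <= 180))
  # constant window
  flat <- angle_trace(make_theta_sequence(rep(170, 4)), spec0$triple)
  expect_equal(extract_rom(list(start_row = 1, end_row = 4), flat), 0)
})

test_that("run_session assembles a consistent report", {
  sess <- generate_session(motion_profile("hip_flexion", reps = 10),
                           body_model("left"), noise_model(seed = 5))
  rep <- run_session(sess$sequence, hf)
  expect_s3_class(rep, "session_report")
  expect_equal(rep$rep_count, 10L)
  expect_equal(rep$rep_count, nrow(rep$repetitions))
  expect_equal(length(rep$rom_series), rep$rep_count)
  expect_true(all(rep$repetitions$best_band == "PERFECT"))
  # per-frame band equals classify_status of the per-frame angle
  ok <- !is.na(rep$frames$theta_deg)
  expect_equal(rep$frames$band[ok],
               as.character(classify_status(rep$frames$theta_deg[ok], hf)))
  # empty sequence -> empty report
  empty <- matrix(numeric(0), 0, 33)
  seq_e <- landmark_sequence(integer(0), x = empty, y = empty, z = empty,
                             v = empty)
  rep_e <- run_session(seq_e, hf)
  expect_equal(rep_e$rep_count, 0L)
  # session that stays in ST counts nothing
  still <- make_theta_sequence(rep(170, 30))
  rep_s <- run_session(still, hf)
  expect_equal(rep_s$rep_count, 0L)
  expect_true(all(rep_s$frames$band == "ST"))
})

test_that("reports serialize to JSON and CSV", {
  sess <- generate_session(motion_profile("hip_flexion", reps = 2),
                           body_model("left"), noise_model(seed = 5))
  rep <- run_session(sess$sequence, hf)
  dir <- withr::local_tempdir()
  write_session_report(rep, dir)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$rep_count, 2L)
  frames <- read.csv(file.path(dir, "frames.csv"))
  expect_equal(nrow(frames), nrow(rep$frames))
})

test_that("spec validation rejects inconsistent thresholds and bands", {
  expect_error(exercise_spec("hip_flexion", "left",
                             rep_start_threshold = 10,
                             rep_target_threshold = 100),
               class = "romtrack_validation_error")
  expect_error(exercise_spec("hip_flexion", "left",
                             breaks = c(60, 15, 100, 130)),
               class = "romtrack_validation_error")
  expect_error(exercise_spec("hip_flexion", "left",
                             labels = rep("ST", 5)),
               class = "romtrack_validation_error")
  expect_error(exercise_spec("squat", "left"),
               class = "romtrack_format_error")
})
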