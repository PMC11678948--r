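test_that("classification generator honours its contract", {
  d0 <- make_classification_data(seed = 1)
  d1 <- make_classification_data(seed = 1)
  expect_identical(d0$x, d1$x)
  expect_identical(d0$y, d1$y)
  expect_identical(sum(d0$informative), 3L)
  expect_error(make_classification_data(n_features = 5, n_informative = 6))

  # zero effect: chance-level error on the informative mask
  set.seed(10)
  errs <- replicate(30, {
    d <- make_classification_data(n_samples = 80, n_features = 5,
                                  effect_size = 0)
    cv_error(d$x, d$y, d$informative, fitness_spec())
  })
  expect_gt(mean(errs), 0.35)
  expect_lt(mean(errs), 0.65)

  # huge effect: separable construction
  d_big <- make_classification_data(n_samples = 80, effect_size = 8, seed = 2)
  expect_lt(cv_error(d_big$x, d_big$y, d_big$informative, fitness_spec(),
                     seed = 1), 0.05)

  # redundant columns correlate with the informative block
  d_red <- make_classification_data(n_redundant = 2, seed = 3)
  cors <- abs(cor(d_red$x[, 4], d_red$x[, 1:3]))
  expect_gt(max(cors), 0.3)
})

test_that("IMU recordings have the stated shape, ranges and determinism", {
  acts <- imu_activities()
  expect_identical(nrow(acts), 14L)
  expect_identical(sum(acts$category == "Fall"), 6L)
  for (a in acts$activity) {
    rec <- make_imu_recording(a, seed = 20)
    expect_identical(dim(unclass(rec)), c(200L, 9L))
    expect_identical(attr(rec, "sample_rate"), 20)
    expect_true(all(abs(rec[, 1:3]) <= 16))
    expect_true(all(abs(rec[, 4:6]) <= 2000))
    expect_true(all(abs(rec[, "angle_pitch"]) <= 90))
    expect_true(all(abs(rec[, c("angle_yaw", "angle_roll")]) <= 180))
  }
  r1 <- make_imu_recording("jogging", seed = 8)
  r2 <- make_imu_recording("jogging", seed = 8)
  expect_identical(unclass(r1), unclass(r2))
  expect_error(make_imu_recording("moonwalk"))
})

test_that("falls show larger sustained pitch deviation than slow walking", {
  dev <- function(rec) max(abs(rec[, "angle_pitch"] - rec[1, "angle_pitch"]))
  cmp <- vapply(1:30, function(s) {
    dev(make_imu_recording("fall_forward_walking", seed = s)) >
      dev(make_imu_recording("walking_slowly", seed = s))
  }, logical(1))
  expect_true(all(cmp))
})

test_that("feature extraction yields 243 named, finite, channel-covariant values", {
  rec <- make_imu_recording("squat", seed = 4)
  fv <- extract_features(rec)
  expect_length(fv, 243)
  expect_true(all(is.finite(fv)))
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_identical(sum(grepl("^acc_y_", names(fv))), 27L)

  # permuting channels permutes feature blocks accordingly
  perm <- c(2, 1, 3:9)
  rec_p <- rec[, perm]
  attributes(rec_p) <- c(attributes(rec_p),
                         attributes(rec)[c("activity", "category",
                                           "sample_rate", "class")])
  fv_p <- extract_features(rec_p)
  expect_equal(unname(fv_p[1:27]), unname(fv[28:54]))

  # constant channel degenerates cleanly
  flat <- rec
  flat[, "gyro_z"] <- 5
  fz <- extract_features(flat)
  expect_equal(unname(fz["gyro_z_sd"]), 0)
  expect_equal(unname(fz["gyro_z_range"]), 0)
  expect_equal(unname(fz["gyro_z_zcr"]), 0)
  expect_equal(unname(fz["gyro_z_energy"]), 0)

  # pure 2 Hz sinusoid: dominant frequency lands on the 2 Hz bin
  sine <- rec
  sine[, "acc_x"] <- sin(2 * pi * 2 * (0:199) / 20)
  fs <- extract_features(sine)
  expect_equal(unname(fs["acc_x_dom_freq"]), 2)

  # wavelet energies per channel sum to one
  expect_equal(unname(sum(fv[sprintf("acc_y_wpt%d", 1:8)])), 1,
               tolerance = 1e-9)
  expect_error(extract_features(matrix(0, 10, 9)))
})

test_that("recording IO round-trips through plain CSV", {
  rec <- make_imu_recording("lying_down", seed = 6)
  path <- tempfile(fileext = ".csv")
  write_imu_recording(rec, path)
  back <- read_imu_recording(path)
  expect_equal(unclass(back), unclass(rec), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(attr(back, "activity"), "lying_down")
  expect_identical(attr(back, "category"), "ADL")
})

test_that("F1 and confusion counts follow their definitions", {
  expect_equal(f1_score(12, 0, 0), 1)
  expect_equal(f1_score(12, 2, 2), 24 / 28)
  expect_equal(f1_score(0, 3, 0), 0)
  expect_equal(f1_score(0, 0, 0), 1)
  truth <- factor(c("Fall", "Fall", "ADL", "ADL", "ADL"))
  pred <- factor(c("Fall", "ADL", "Fall", "ADL", "ADL"))
  cc <- confusion_counts(truth, pred)
  expect_identical(cc, c(tp = 1L, fn = 1L, fp = 1L, tn = 2L))
  # margins: tp + fn = true falls, fp + tn = true ADLs
  expect_identical(cc[["tp"]] + cc[["fn"]], sum(truth == "Fall"))
  expect_identical(cc[["fp"]] + cc[["tn"]], sum(truth == "ADL"))
})

test_that("fall pipeline reports coherent confusion margins and accuracy", {
  ds <- make_imu_dataset(n_fall = 8, n_adl = 8, seed = 11)
  out <- fall_pipeline(ds$recordings, n_agents = 6, max_iter = 5, seed = 12)
  cc <- out$confusion
  n_test <- length(out$fs_result$test_idx)
  expect_identical(sum(cc), n_test)
  expect_equal(out$accuracy,
               100 * (cc[["tp"]] + cc[["tn"]]) / n_test)
  expect_equal(out$f1, f1_score(cc[["tp"]], cc[["fn"]], cc[["fp"]]))
  expect_error(fall_pipeline(ds$recordings[1:3]))
})

test_that("fall pipeline separates falls from ADLs across seeds", {
  # 30 fall / 30 ADL recordings as in the emulated collection protocol;
  # optimizer budget reduced (6 agents, 10 iterations) to keep the suite fast
  f1s <- vapply(1:10, function(s) {
    ds <- make_imu_dataset(n_fall = 30, n_adl = 30, seed = 1000 + s)
    fall_pipeline(ds$recordings, n_agents = 6, max_iter = 10, seed = s)$f1
  }, numeric(1))
  expect_gte(sum(f1s >= 0.9), 8)
})
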