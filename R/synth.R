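#' Synthetic classification data with known informative features
#'
#' Emulates the wrapper-feature-selection benchmark regime: a handful of
#' informative columns (class-conditionally shifted Gaussians, the two class
#' means `effect_size` standard deviations apart per column), optional
#' redundant columns (noisy linear combinations of the informative ones), and
#' class-independent standard-normal noise columns. The ground-truth
#' informative mask is returned so recovery can be scored.
#'
#' @param n_samples number of samples (default 150).
#' @param n_features total feature count (default 30).
#' @param n_informative number of informative columns, placed first
#'   (default 3).
#' @param n_redundant number of redundant columns following the informative
#'   block (default 0).
#' @param effect_size between-class mean shift per informative column, in
#'   within-class standard deviations. The default, 2.4, is calibrated so the
#'   informative subset is near-separating (roughly 97-98% attainable
#'   accuracy, the regime of the benchmarks the generator emulates) while
#'   every informative column remains individually necessary: dropping one
#'   roughly doubles the attainable error, whereas adding noise columns can
#'   only help by fold-level luck. Much smaller values make noise columns
#'   genuinely useful to a k-NN (the ground-truth mask is no longer the
#'   fitness optimum); much larger values let a strict subset of the
#'   informative columns already separate the classes.
#' @param class_balance proportion of samples in the first class
#'   (default 0.5).
#' @param seed optional integer seed.
#' @return List with `x` (matrix with named columns), `y` (factor `"A"/"B"`),
#'   and `informative` (logical ground-truth mask).
#' @export
make_classification_data <- function(n_samples = 150, n_features = 30,
                                     n_informative = 3, n_redundant = 0,
                                     effect_size = 2.4, class_balance = 0.5,
                                     seed = NULL) {
  if (n_informative + n_redundant > n_features)
    stop("informative + redundant columns exceed 'n_features'")
  if (n_informative < 1) stop("need at least one informative feature")
  if (!is.null(seed)) set.seed(seed)

  n_a <- round(class_balance * n_samples)
  y <- factor(rep(c("A", "B"), c(n_a, n_samples - n_a)), levels = c("A", "B"))
  shift <- ifelse(y == "A", -effect_size / 2, effect_size / 2)

  x <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
  for (j in seq_len(n_informative)) x[, j] <- x[, j] + shift
  if (n_redundant > 0) {
    for (j in n_informative + seq_len(n_redundant)) {
      wts <- stats::runif(n_informative, -1, 1)
      x[, j] <- x[, seq_len(n_informative), drop = FALSE] %*% wts +
        stats::rnorm(n_samples, sd = 0.3)
    }
  }
  colnames(x) <- sprintf("f%02d", seq_len(n_features))
  informative <- seq_len(n_features) <= n_informative
  list(x = x, y = y, informative = informative)
}

IMU_CHANNELS <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z",
                  "angle_pitch", "angle_yaw", "angle_roll")
IMU_RATE <- 20     # Hz
IMU_SAMPLES <- 200 # 10 s at 20 Hz

#' Activity catalogue of the synthetic fall-detection dataset
#'
#' Fourteen activity types: eight activities of daily living (ADL) and six
#' fall modes, mirroring a waist-worn IMU data-collection protocol.
#'
#' @return `data.frame` with columns `activity`, `category`
#'   (`"ADL"`/`"Fall"`) and `description`.
#' @export
imu_activities <- function() {
  data.frame(
    activity = c("walking_slowly", "jogging", "sit_stand", "bending",
                 "squat", "lying_down", "stairs", "adl_mix",
                 "fall_forward_walking", "fall_backward_walking",
                 "fall_left_walking", "fall_right_walking",
                 "fall_vertical_walking", "fall_jogging"),
    category = rep(c("ADL", "Fall"), c(8L, 6L)),
    description = c(
      "Walking slowly", "Jogging", "Slowly sit down and stand up again",
      "Bending slowly from standing and stand straight again",
      "Slowly squat and then stand up", "Lie down slowly and then stand up",
      "Walking upstairs and downstairs slowly", "Mix of daily activities",
      "Fall forward while walking", "Fall backward while walking",
      "Fall left while walking", "Fall right while walking",
      "Vertical fall while walking", "Fall while jogging"),
    stringsAsFactors = FALSE)
}

# Gaussian bump and smooth step, both on the 10 s time axis.
imu_bump <- function(t, center, width) exp(-((t - center) / width)^2)
imu_step <- function(t, t0, width) stats::plogis((t - t0) / width)

# Baseline locomotion template (walking/jogging family). Vertical axis = y.
imu_gait <- function(t, f, amp, phase) {
  s1 <- sin(2 * pi * f * t + phase)
  s2 <- sin(4 * pi * f * t + 2 * phase)
  list(acc_x = 0.15 * amp * sin(2 * pi * f * t + phase + 1.1),
       acc_y = 1 + amp * s1 + 0.4 * amp * s2,
       acc_z = 0.12 * amp * sin(2 * pi * f * t + phase + 2.3),
       gyro_x = 25 * amp * sin(2 * pi * f * t + phase + 0.4),
       gyro_y = 60 * amp * s1,
       gyro_z = 20 * amp * sin(2 * pi * f * t + phase + 1.9),
       angle_pitch = 4 * amp * s1,
       angle_yaw = 8 * sin(2 * pi * 0.1 * t + phase),
       angle_roll = 3 * amp * sin(2 * pi * f * t + phase + 0.7))
}

# Quiet posture-transition template: angle trajectories are prescribed and
# the gyroscope follows as their numerical time derivative.
imu_transition <- function(t, pitch, roll = 0 * t, acc_y = NULL,
                           acc_z = NULL) {
  fs <- IMU_RATE
  deriv <- function(v) c(0, diff(v)) * fs
  if (is.null(acc_y)) acc_y <- 1 + 0 * t
  if (is.null(acc_z)) acc_z <- 0 * t
  list(acc_x = 0 * t, acc_y = acc_y, acc_z = acc_z,
       gyro_x = deriv(roll), gyro_y = 0 * t, gyro_z = deriv(pitch),
       angle_pitch = pitch, angle_yaw = 0 * t, angle_roll = roll)
}

#' Generate one synthetic IMU recording
#'
#' Parametric 9-channel, 10-second recording at 20 Hz (200 samples per
#' channel): triaxial acceleration in g, triaxial angular velocity in deg/s,
#' and pitch/yaw/roll in degrees, for one of the 14 activities in
#' [imu_activities()]. ADLs are band-limited periodic or slow-transition
#' templates around 1 g vertical acceleration; falls are a locomotion prefix
#' followed by a high-magnitude acceleration/angular-velocity transient at a
#' random impact time (4-6 s) and a sustained post-impact orientation change.
#' Channels respect the sensor ranges (acc within 16 g, gyro within
#' 2000 deg/s, pitch within 90 deg, yaw/roll within 180 deg). Generation is
#' deterministic given `(activity, seed)`.
#'
#' @param activity an activity id from [imu_activities()].
#' @param seed optional integer seed.
#' @return An `"imu_recording"`: a 200 x 9 numeric matrix with named channel
#'   columns and attributes `activity`, `category`, `sample_rate`.
#' @export
make_imu_recording <- function(activity, seed = NULL) {
  acts <- imu_activities()
  row <- match(activity, acts$activity)
  if (is.na(row)) stop("unknown activity: ", activity)
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(IMU_SAMPLES) - 1L) / IMU_RATE

  phase <- stats::runif(1, 0, 2 * pi)
  jit <- function(x, rel = 0.12) x * stats::runif(1, 1 - rel, 1 + rel)

  ch <- switch(activity,
    walking_slowly = imu_gait(t, jit(1.0), jit(0.3), phase),
    jogging = imu_gait(t, jit(2.5), jit(0.8), phase),
    stairs = imu_gait(t, jit(1.2), jit(0.35), phase),
    sit_stand = imu_transition(
      t, pitch = jit(18) * (imu_bump(t, 3, 0.8) + imu_bump(t, 7, 0.8)),
      acc_y = 1 - 0.2 * (imu_bump(t, 3, 0.5) + imu_bump(t, 7, 0.5))),
    bending = imu_transition(t, pitch = jit(50) * imu_bump(t, 5, 1.5)),
    squat = imu_transition(
      t, pitch = jit(15) * imu_bump(t, 5, 1.2),
      acc_y = 1 - 0.3 * imu_bump(t, 5, 0.8)),
    lying_down = {
      win <- imu_step(t, 4, 0.3) - imu_step(t, 8, 0.3)
      imu_transition(t, pitch = jit(75) * win,
                     acc_y = 1 - 0.8 * win, acc_z = 0.85 * win)
    },
    adl_mix = {
      g <- imu_gait(t, jit(1.0), jit(0.3), phase)
      half <- t < 5
      tr <- imu_transition(t, pitch = jit(15) * imu_bump(t, 7, 1.0),
                           acc_y = 1 - 0.3 * imu_bump(t, 7, 0.8))
      stats::setNames(lapply(IMU_CHANNELS, function(nm)
        ifelse(half, g[[nm]], tr[[nm]])), IMU_CHANNELS)
    },
    # fall modes share a construction
    imu_fall(t, activity, phase, jit))

  noise_sd <- c(rep(0.02, 3), rep(1.5, 3), rep(0.4, 3))
  lim_lo <- c(rep(-16, 3), rep(-2000, 3), -90, -180, -180)
  lim_hi <- c(rep(16, 3), rep(2000, 3), 90, 180, 180)
  rec <- vapply(seq_along(IMU_CHANNELS), function(j) {
    v <- ch[[IMU_CHANNELS[j]]] + stats::rnorm(IMU_SAMPLES, sd = noise_sd[j])
    pmin(pmax(v, lim_lo[j]), lim_hi[j])
  }, numeric(IMU_SAMPLES))
  colnames(rec) <- IMU_CHANNELS
  structure(rec, activity = activity, category = acts$category[row],
            sample_rate = IMU_RATE, class = c("imu_recording", "matrix"))
}

# Fall template: gait prefix, impact transient, sustained orientation change.
imu_fall <- function(t, activity, phase, jit) {
  jog <- activity == "fall_jogging"
  g <- imu_gait(t, jit(if (jog) 2.5 else 1.0), jit(if (jog) 0.8 else 0.3),
                phase)
  t_imp <- stats::runif(1, 4, 6)
  mag <- stats::runif(1, if (jog) 6 else 4, if (jog) 10 else 8)
  pre <- 1 - imu_step(t, t_imp, 0.1)   # locomotion dies at impact
  post <- imu_step(t, t_imp, 0.15)     # lying phase
  spike <- imu_bump(t, t_imp, 0.12)
  gspike <- stats::runif(1, 300, 700)

  dir <- switch(activity,
    fall_forward_walking = , fall_jogging =
      list(pitch = jit(70), roll = 0, rest_y = 0.15, rest_x = 0, rest_z = 0.9),
    fall_backward_walking =
      list(pitch = -jit(70), roll = 0, rest_y = 0.2, rest_x = 0, rest_z = -0.9),
    fall_left_walking =
      list(pitch = 0, roll = -jit(70), rest_y = 0.2, rest_x = -0.9, rest_z = 0),
    fall_right_walking =
      list(pitch = 0, roll = jit(70), rest_y = 0.2, rest_x = 0.9, rest_z = 0),
    fall_vertical_walking =
      list(pitch = jit(30), roll = 0, rest_y = 0.3, rest_x = 0, rest_z = 0.3))

  axis_gyro <- if (dir$roll != 0) "gyro_x" else "gyro_z"
  out <- list(
    acc_x = g$acc_x * pre + dir$rest_x * post +
      0.5 * mag * spike * sign(dir$rest_x + 0.1),
    acc_y = g$acc_y * pre + dir$rest_y * post + mag * spike,
    acc_z = g$acc_z * pre + dir$rest_z * post +
      0.5 * mag * spike * sign(dir$rest_z + 0.1),
    gyro_x = g$gyro_x * pre, gyro_y = g$gyro_y * pre, gyro_z = g$gyro_z * pre,
    angle_pitch = g$angle_pitch * pre + dir$pitch * post,
    angle_yaw = g$angle_yaw * pre,
    angle_roll = g$angle_roll * pre + dir$roll * post)
  out[[axis_gyro]] <- out[[axis_gyro]] + gspike * spike *
    sign(if (dir$roll != 0) dir$roll else dir$pitch)
  out
}

#' Generate a labelled synthetic fall-detection dataset
#'
#' Draws recordings round-robin over the six fall and eight ADL activity
#' types, with an independent seed per recording derived from `seed`.
#'
#' @param n_fall,n_adl number of fall and ADL recordings (defaults 30/30).
#' @param seed optional integer seed.
#' @return List with `recordings` (list of [make_imu_recording()] outputs)
#'   and `labels` (`data.frame` of `activity`, `category`).
#' @export
make_imu_dataset <- function(n_fall = 30, n_adl = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  acts <- imu_activities()
  plan <- c(rep_len(acts$activity[acts$category == "Fall"], n_fall),
            rep_len(acts$activity[acts$category == "ADL"], n_adl))
  seeds <- sample.int(.Machine$integer.max, length(plan))
  recordings <- Map(make_imu_recording, plan, seeds)
  labels <- data.frame(activity = plan,
                       category = acts$category[match(plan, acts$activity)],
                       stringsAsFactors = FALSE)
  list(recordings = recordings, labels = labels)
}

#' Write / read an IMU recording as plain CSV
#'
#' The file carries two comment lines (`# activity:`, `# sample_rate:`)
#' followed by a 200-row, 9-column CSV with the channel names as header.
#'
#' @param recording an `"imu_recording"`.
#' @param path file path.
#' @return `write_imu_recording` invisibly returns `path`;
#'   `read_imu_recording` returns the reconstructed `"imu_recording"`.
#' @export
write_imu_recording <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# activity: ", attr(recording, "activity")),
               paste0("# sample_rate: ", attr(recording, "sample_rate"))),
             con)
  utils::write.csv(as.data.frame(unclass(recording)), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_recording
#' @export
read_imu_recording <- function(path) {
  head2 <- readLines(path, n = 2L)
  activity <- sub("^# activity: *", "", head2[1L])
  df <- utils::read.csv(path, skip = 2L)
  rec <- as.matrix(df[, IMU_CHANNELS])
  acts <- imu_activities()
  structure(rec, activity = activity,
            category = acts$category[match(activity, acts$activity)],
            sample_rate = as.numeric(sub("^# sample_rate: *", "", head2[2L])),
            class = c("imu_recording", "matrix"))
}
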