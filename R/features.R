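# Per-channel feature lists. The counts (13 time-domain, 6 frequency-domain,
# 8 time-frequency) are fixed by the extraction protocol; the concrete
# statistics are package configuration, documented here and in the vignette.
TIME_FEATURES <- c("mean", "sd", "var", "rms", "min", "max", "range",
                   "median", "iqr", "skewness", "kurtosis", "mad", "zcr")
FREQ_FEATURES <- c("energy", "dom_freq", "centroid", "bandwidth",
                   "entropy", "mean_freq")
WPT_FEATURES <- sprintf("wpt%d", 1:8)

time_domain_features <- function(x) {
  n <- length(x)
  mu <- mean(x)
  s <- stats::sd(x)
  xc <- x - mu
  zcr <- sum(xc[-n] * xc[-1] < 0) / (n - 1)
  skew <- if (s > 0) mean(xc^3) / (stats::sd(x) * sqrt((n - 1) / n))^3 else 0
  kurt <- if (s > 0) mean(xc^4) / (mean(xc^2))^2 - 3 else 0
  c(mean = mu, sd = s, var = stats::var(x), rms = sqrt(mean(x^2)),
    min = min(x), max = max(x), range = max(x) - min(x),
    median = stats::median(x), iqr = stats::IQR(x),
    skewness = skew, kurtosis = kurt, mad = mean(abs(xc)), zcr = zcr)
}

freq_domain_features <- function(x, fs) {
  n <- length(x)
  half <- n %/% 2
  mag <- Mod(stats::fft(x))[2:(half + 1)]  # DC excluded, Nyquist included
  freq <- (1:half) * fs / n
  pw <- mag^2
  tot_m <- sum(mag)
  tot_p <- sum(pw)
  if (tot_p <= 0)
    return(c(energy = 0, dom_freq = 0, centroid = 0, bandwidth = 0,
             entropy = 0, mean_freq = 0))
  centroid <- sum(freq * mag) / tot_m
  p <- pw / tot_p
  c(energy = tot_p,
    dom_freq = freq[which.max(mag)],
    centroid = centroid,
    bandwidth = sqrt(sum(mag * (freq - centroid)^2) / tot_m),
    entropy = -sum(ifelse(p > 0, p * log(p), 0)) / log(half),
    mean_freq = sum(freq * pw) / tot_p)
}

#' Extract the 243-feature vector from an IMU recording
#'
#' Per channel, 27 features: 13 time-domain statistics (mean, standard
#' deviation, variance, RMS, min, max, range, median, interquartile range,
#' skewness, excess kurtosis, mean absolute deviation, zero-crossing rate of
#' the mean-centred signal), 6 frequency-domain statistics of the magnitude
#' spectrum with DC excluded (total spectral power, dominant frequency,
#' spectral centroid, spectral bandwidth, normalized spectral entropy, mean
#' frequency), and the 8 relative sub-band energies of a 3-level Daubechies-4
#' wavelet packet decomposition ([wpt_band_energies()]). Features are
#' concatenated channel-major over the 9 channels, giving 243 named values.
#' Degenerate (constant) channels yield zero spread, zero crossing rate and
#' zero spectral statistics.
#'
#' @param recording an `"imu_recording"` (200 x 9 matrix; see
#'   [make_imu_recording()]).
#' @return Named numeric vector of length 243.
#' @export
extract_features <- function(recording) {
  rec <- unclass(recording)
  if (!is.matrix(rec) || nrow(rec) != IMU_SAMPLES ||
      ncol(rec) != length(IMU_CHANNELS))
    stop("recording must be a 200 x 9 channel matrix")
  fs <- attr(recording, "sample_rate")
  if (is.null(fs)) fs <- IMU_RATE
  chan_names <- colnames(rec)
  if (is.null(chan_names)) chan_names <- IMU_CHANNELS

  out <- lapply(seq_len(ncol(rec)), function(j) {
    x <- rec[, j]
    v <- c(time_domain_features(x), freq_domain_features(x, fs),
           stats::setNames(wpt_band_energies(x), WPT_FEATURES))
    names(v) <- paste(chan_names[j], names(v), sep = "_")
    v
  })
  unlist(out)
}

#' Confusion counts and F1 score with falls as the positive class
#'
#' `f1_score` computes `2*TP / (2*TP + FP + FN)`; when there are no
#' positives at all (all three terms zero) it is defined as 1.
#'
#' @param truth,pred factors of true and predicted labels.
#' @param positive the positive-class label.
#' @return `confusion_counts`: named vector `tp, fn, fp, tn`.
#' @export
confusion_counts <- function(truth, pred, positive = "Fall") {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' @rdname confusion_counts
#' @param tp,fn,fp true-positive, false-negative and false-positive counts.
#' @export
f1_score <- function(tp, fn, fp) {
  den <- 2 * tp + fp + fn
  if (den == 0) return(1)
  2 * tp / den
}

#' Fall-detection demonstration pipeline
#'
#' Extracts the 243-feature vector from every recording, runs the
#' whale-optimization feature-selection wrapper with an SVM-error fitness on
#' the stratified 80% training split, refits the SVM on the selected
#' features, and scores the held-out 20%: confusion counts (falls positive),
#' F1 and accuracy.
#'
#' @param recordings list of `"imu_recording"` objects (at least two falls
#'   and two ADLs).
#' @param algorithm `"mswoa"` or `"woa"`.
#' @param n_agents,max_iter optimizer budget.
#' @param seed integer seed (split, folds, optimizer).
#' @param spec a [fitness_spec()]; the classifier should be `"svm"`.
#' @return List with `confusion` (tp/fn/fp/tn), `f1`, `accuracy` (percent on
#'   the test split) and `fs_result` (the underlying [select_features()]
#'   record).
#' @export
fall_pipeline <- function(recordings, algorithm = c("mswoa", "woa"),
                          n_agents = 10, max_iter = 100, seed = NULL,
                          spec = fitness_spec(classifier = "svm")) {
  algorithm <- match.arg(algorithm)
  y <- factor(vapply(recordings, attr, character(1), which = "category"),
              levels = c("ADL", "Fall"))
  if (sum(y == "Fall") < 2 || sum(y == "ADL") < 2)
    stop("need at least two fall and two ADL recordings")
  x <- t(vapply(recordings, extract_features, numeric(243)))

  res <- select_features(x, y, algorithm = algorithm, spec = spec,
                         n_agents = n_agents, max_iter = max_iter,
                         seed = seed)
  sc <- scale_minmax(x[res$train_idx, res$mask, drop = FALSE],
                     x[res$test_idx, res$mask, drop = FALSE])
  fit <- svm_train(sc$train, y[res$train_idx])
  pred <- predict(fit, sc$test)
  truth <- y[res$test_idx]
  cc <- confusion_counts(truth, pred, positive = "Fall")
  list(confusion = cc,
       f1 = f1_score(cc[["tp"]], cc[["fn"]], cc[["fp"]]),
       accuracy = 100 * mean(pred == truth),
       fs_result = res)
}
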