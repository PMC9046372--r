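# Three-level aggregation statistics: per-recording baselines and filtering
# (sample level), circularity-binned confidence-weighted means with top-bin
# normalization (subject level), and mean/std across recordings (population
# level). Boundary conventions: confidence rule inclusive (>= threshold),
# outlier rule strict (> tolerance removed, = tolerance kept), circularity
# bins half-open [0, 0.1), ..., [0.8, 0.9), with the final bin closed
# [0.9, 1.0].

#' Per-recording baseline pupil size
#'
#' Median of the pupil-size measure over all sweep-period samples with
#' confidence at least the threshold. For simulated recordings every frame
#' belongs to the sweep period, so this is the run median.
#'
#' @param values Numeric vector of per-frame pupil-size values.
#' @param confidence Per-frame detection confidence in `[0, 1]`.
#' @param threshold Inclusive confidence threshold.
#' @return The baseline (scalar).
#' @export
compute_baseline <- function(values, confidence = rep(1, length(values)),
                             threshold = 0.6) {
  keep <- confidence >= threshold
  if (!any(keep)) stop("no samples with confidence >= ", threshold)
  stats::median(values[keep])
}

#' Remove frames whose major axis deviates too far from baseline
#'
#' Frames with `|major - baseline| / baseline > tolerance` are dropped
#' (strictly greater; a frame exactly at the tolerance is kept). The same
#' frames are removed for all methods' records.
#'
#' @param frames Data frame with a `major_px` column.
#' @param baseline_major Baseline major axis in px (> 0).
#' @param tolerance Relative tolerance (default 0.2, i.e. 20 %).
#' @return `frames` filtered, with attribute `removed_fraction`.
#' @export
filter_outliers <- function(frames, baseline_major, tolerance = 0.2) {
  stopifnot(baseline_major > 0)
  dev <- abs(frames$major_px - baseline_major) / baseline_major
  keep <- dev <= tolerance
  out <- frames[keep, , drop = FALSE]
  attr(out, "removed_fraction") <- mean(!keep)
  out
}

#' Circularity bin edges and labels
#'
#' Ten equal-width bins spanning the theoretical circularity range `[0, 1]`.
#' @return Data frame with `bin`, `low`, `high`.
#' @export
circularity_bins <- function() {
  data.frame(bin = 1:10, low = seq(0, 0.9, by = 0.1),
             high = seq(0.1, 1, by = 0.1))
}

bin_index <- function(C) {
  b <- findInterval(C, seq(0, 1, by = 0.1), rightmost.closed = TRUE)
  b[b < 1 | b > 10] <- NA_integer_
  b
}

#' Confidence-weighted circularity-binned means of relative pupil size
#'
#' @param relative Per-frame relative pupil size (value / baseline).
#' @param circ Per-frame circularity in `[0, 1]`.
#' @param weights Per-frame weights (detection confidence).
#' @return A `binned_profile` data frame: `bin`, `low`, `high`, `n`,
#'   `weight_sum`, `weighted_mean` (NA for empty bins).
#' @export
bin_by_circularity <- function(relative, circ, weights = rep(1, length(relative))) {
  if (length(relative) == 0) stop("empty series")
  b <- bin_index(circ)
  prof <- circularity_bins()
  prof$n <- 0L; prof$weight_sum <- 0; prof$weighted_mean <- NA_real_
  for (k in 1:10) {
    sel <- which(b == k & weights > 0)
    if (length(sel) == 0) next
    prof$n[k] <- length(sel)
    prof$weight_sum[k] <- sum(weights[sel])
    prof$weighted_mean[k] <- sum(weights[sel] * relative[sel]) / sum(weights[sel])
  }
  if (all(prof$weight_sum == 0)) stop("zero total weight in all bins")
  class(prof) <- c("binned_profile", "data.frame")
  prof
}

#' Normalize a binned profile by its top-circularity bin
#'
#' Divides every bin mean by the mean of the highest-circularity bin
#' (C in [0.9, 1.0]), which therefore becomes exactly 1.
#'
#' @param profile A `binned_profile`.
#' @return The profile with a `normalized_mean` column.
#' @export
normalize_profile <- function(profile) {
  top <- profile$weighted_mean[profile$bin == 10]
  if (is.na(top)) stop("empty top-circularity bin: profile cannot be normalized")
  profile$normalized_mean <- profile$weighted_mean / top
  profile
}

#' Per-bin mean and standard deviation across profiles
#'
#' @param profiles List of normalized `binned_profile`s (or a long data frame
#'   with columns `bin` and `normalized_mean`).
#' @return Data frame `bin`, `low`, `high`, `n_profiles`, `mean`, `sd`
#'   (sample, n-1, standard deviation; NA where fewer than 2 profiles
#'   populate the bin).
#' @export
population_stats <- function(profiles) {
  if (is.data.frame(profiles)) {
    long <- profiles
  } else {
    if (length(profiles) < 2) stop("need at least 2 profiles")
    long <- do.call(rbind, profiles)
  }
  out <- circularity_bins()
  out$n_profiles <- 0L; out$mean <- NA_real_; out$sd <- NA_real_
  for (k in 1:10) {
    v <- long$normalized_mean[long$bin == k & !is.na(long$normalized_mean)]
    out$n_profiles[k] <- length(v)
    if (length(v) >= 1) out$mean[k] <- mean(v)
    if (length(v) >= 2) out$sd[k] <- stats::sd(v)
  }
  out
}

#' Aggregate per-frame measurements into subject-level profiles
#'
#' Runs the full subject-level pipeline per recording and method: baseline,
#' 20 % major-axis outlier filter (shared across methods), relative pupil
#' sizes, circularity binning with confidence weights, top-bin normalization.
#'
#' @param measurements Long data frame with columns `run_id`, `frame`,
#'   `method`, `value`, `major_px`, `circularity`, `confidence`.
#' @param confidence_threshold Baseline confidence threshold.
#' @param outlier_tolerance Major-axis filter tolerance.
#' @return List with `profiles` (long data frame of normalized profiles per
#'   run and method), `population` (per-method [population_stats()]), and
#'   `failed` (run/method combinations whose profile was unusable).
#' @export
aggregate_measurements <- function(measurements, confidence_threshold = 0.6,
                                   outlier_tolerance = 0.2) {
  profs <- list(); failed <- list()
  for (rid in unique(measurements$run_id)) {
    rec <- measurements[measurements$run_id == rid, , drop = FALSE]
    maj <- rec[rec$method == "2D-0p", , drop = FALSE]
    base_major <- tryCatch(
      compute_baseline(maj$value, maj$confidence, confidence_threshold),
      error = function(e) NA_real_)
    if (is.na(base_major)) {
      failed[[length(failed) + 1]] <- data.frame(run_id = rid, method = "all",
                                                 reason = "no confident baseline")
      next
    }
    keep_frames <- maj$frame[abs(maj$value - base_major) / base_major <=
                               outlier_tolerance]
    for (m in unique(rec$method)) {
      ser <- rec[rec$method == m & rec$frame %in% keep_frames &
                   !is.na(rec$value), , drop = FALSE]
      res <- tryCatch({
        base <- compute_baseline(ser$value, ser$confidence, confidence_threshold)
        prof <- bin_by_circularity(ser$value / base, ser$circularity,
                                   ser$confidence)
        prof <- normalize_profile(prof)
        prof$run_id <- rid; prof$method <- m
        prof
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        failed[[length(failed) + 1]] <- data.frame(run_id = rid, method = m,
                                                   reason = res)
      } else {
        profs[[length(profs) + 1]] <- res
      }
    }
  }
  if (length(profs) == 0) stop("no usable profiles")
  long <- do.call(rbind, profs)
  pop <- lapply(split(long, long$method), population_stats)
  list(profiles = long, population = pop,
       failed = if (length(failed)) do.call(rbind, failed) else NULL)
}

#' Read a generic per-frame pupil time series CSV
#'
#' Accepts any CSV with columns `run_id`, `frame`, `method`, `value`,
#' `major_px`, `circularity`, `confidence` for use with
#' [aggregate_measurements()].
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_pupil_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("run_id", "frame", "method", "value", "major_px", "circularity",
            "confidence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df
}
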