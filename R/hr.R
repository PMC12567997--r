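#' Band-pass preprocessing for heart-rate estimation
#'
#' Zero-phase 4th-order Butterworth band-pass, 0.5-8 Hz: removes
#' low-frequency baseline drift and high-frequency noise while keeping the
#' pulse fundamental and early harmonics. Requires fs > 16 Hz so the 8 Hz
#' corner sits below Nyquist.
#'
#' @param record a \code{\link{ppg_record}} or numeric vector
#' @param fs sampling rate, required when \code{record} is a bare vector
#' @param band corner frequencies, Hz
#' @param order Butterworth design order
#' @return filtered numeric vector
#' @export
preprocess_hr <- function(record, fs = NULL, band = c(0.5, 8), order = 4) {
  if (inherits(record, "ppg_record")) {
    x <- record$samples; fs <- record$fs
  } else {
    x <- record
    if (is.null(fs)) stop("fs required for a bare numeric vector")
  }
  if (fs <= 2 * band[2]) stop("fs must exceed twice the upper band edge (",
                              2 * band[2], " Hz)")
  bp_filter(x, fs, band[1], band[2], order)
}

#' Detect systolic peaks with an adaptive threshold
#'
#' Candidate peaks are strict local maxima of the filtered series that
#' exceed an adaptive threshold: \code{thresh_frac} times a rolling
#' \code{window_s}-second 90th-percentile amplitude envelope (so the
#' threshold tracks slow amplitude changes, e.g. alternating-strength
#' beats or perfusion drift). Peaks closer than the refractory period keep
#' only the taller one. Inter-beat intervals (IBIs) come from consecutive
#' peak times and the heart rate is 60 divided by the mean IBI.
#'
#' @param x filtered PPG series (from \code{\link{preprocess_hr}})
#' @param fs sampling rate, Hz
#' @param window_s rolling envelope window, seconds
#' @param envelope_q envelope quantile (0.9 = 90th percentile)
#' @param thresh_frac threshold as a fraction of the envelope
#' @param refractory_s minimum peak spacing, seconds
#' @return object of class \code{peak_train}: \code{peak_indices} (1-based
#'   sample positions), \code{ibis} (s), \code{hr_bpm} (NA with
#'   \code{flag = "no_hr"} when fewer than 2 peaks are found)
#' @export
detect_systolic_peaks <- function(x, fs, window_s = 3, envelope_q = 0.9,
                                  thresh_frac = 0.5, refractory_s = 0.25) {
  if (length(x) < 3 * fs) stop("need at least 3 s of signal")
  w <- max(3, round(window_s * fs))
  env <- zoo::rollapply(zoo::zoo(x), width = w, align = "center",
                        partial = TRUE,
                        FUN = function(v) stats::quantile(v, envelope_q,
                                                          names = FALSE))
  env <- as.numeric(env)
  thr <- thresh_frac * env
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  cand <- cand[x[cand] > thr[cand] & x[cand] > 0]
  # refractory thinning, taller peak wins
  if (length(cand) > 1) {
    refr <- round(refractory_s * fs)
    ord <- order(-x[cand])
    taken <- integer(0)
    sel <- logical(length(cand))
    for (k in ord) {
      if (all(abs(cand[k] - taken) >= refr)) {
        sel[k] <- TRUE
        taken <- c(taken, cand[k])
      }
    }
    cand <- sort(cand[sel])
  }
  if (length(cand) < 2) {
    return(structure(list(peak_indices = cand, ibis = numeric(0),
                          hr_bpm = NA_real_, flag = "no_hr"),
                     class = "peak_train"))
  }
  ibis <- diff(cand) / fs
  hr <- 60 / mean(ibis)
  flag <- if (hr <= 20 || hr >= 300) "implausible_hr" else "ok"
  structure(list(peak_indices = cand, ibis = ibis, hr_bpm = hr, flag = flag),
            class = "peak_train")
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("peak_train: %d peaks, HR %.2f bpm (%s)\n",
              length(x$peak_indices), x$hr_bpm, x$flag))
  invisible(x)
}

#' Estimate heart rate from a PPG record
#'
#' Convenience wrapper: 0.5-8 Hz zero-phase preprocessing, adaptive
#' threshold systolic peak detection, HR = 60 / mean inter-beat interval.
#'
#' @param record a \code{\link{ppg_record}}
#' @param ... passed to \code{\link{detect_systolic_peaks}}
#' @return a \code{peak_train}
#' @export
estimate_hr <- function(record, ...) {
  y <- preprocess_hr(record)
  detect_systolic_peaks(y, record$fs, ...)
}

#' Windowed heart-rate time series
#'
#' Runs the estimation pipeline on sliding windows (default 10 s windows
#' with a 5 s hop) and reports one HR value per window (NA where no HR
#' could be derived).
#'
#' @param record a \code{\link{ppg_record}}
#' @param window_s window length, s
#' @param hop_s hop between window starts, s
#' @param ... passed to \code{\link{detect_systolic_peaks}}
#' @return data.frame: \code{t_start} (s), \code{hr_bpm}
#' @export
hr_series <- function(record, window_s = 10, hop_s = 5, ...) {
  y <- preprocess_hr(record)
  fs <- record$fs
  n <- length(y)
  starts <- seq(1, n - round(window_s * fs) + 1, by = round(hop_s * fs))
  hr <- vapply(starts, function(s) {
    seg <- y[s:(s + round(window_s * fs) - 1)]
    pt <- detect_systolic_peaks(seg, fs, ...)
    if (identical(pt$flag, "ok")) pt$hr_bpm else NA_real_
  }, numeric(1))
  data.frame(t_start = (starts - 1) / fs, hr_bpm = hr)
}

#' Score estimated heart rates against a reference
#'
#' Mean absolute error (bpm) and the percentage of aligned windows within
#' 3 bpm of the reference.
#'
#' @param estimates,reference aligned numeric HR series (bpm), same length
#' @param na.rm drop pairs where either value is NA
#' @return list: \code{mae_bpm}, \code{pct_within_3bpm}, \code{n}
#' @export
score_against_reference <- function(estimates, reference, na.rm = TRUE) {
  if (length(estimates) != length(reference))
    stop("estimate and reference series must have the same length")
  if (na.rm) {
    ok <- is.finite(estimates) & is.finite(reference)
    estimates <- estimates[ok]; reference <- reference[ok]
  }
  err <- abs(estimates - reference)
  list(mae_bpm = mean(err),
       pct_within_3bpm = 100 * mean(err <= 3),
       n = length(err))
}
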