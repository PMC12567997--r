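#' Generate synthetic PPG with known ground truth
#'
#' Seeded generator for testing the signal path without recorded data.
#' Each beat is a two-Gaussian surrogate: a systolic lobe plus a delayed
#' dicrotic lobe (relative amplitude 0.35, delay 0.35 of the beat
#' interval, widths 0.09 and 0.12 of the interval -- fixed, documented
#' shape constants). Beat onsets follow the target rate with Gaussian
#' jitter (\code{hrv_pct} percent of the mean interval). The pulsatile
#' component is rescaled so its peak-to-trough excursion is exactly
#' \code{ac_amplitude}; the signal is then
#' \code{dc_level + pulses + respiratory drift + white noise + artifact
#' bursts}. Additive noise power is set relative to the pulsatile (AC)
#' power, so \code{noise_snr_db} orders clean vs noisy variants
#' unambiguously.
#'
#' @param fs sampling rate, Hz (> 16)
#' @param duration record length, s (>= 6)
#' @param hr_bpm target heart rate, 30-240 bpm
#' @param hrv_pct beat-interval jitter SD as percent of the mean interval
#' @param dc_level static baseline level (ADC units)
#' @param ac_amplitude pulsatile peak-to-trough amplitude (ADC units);
#'   ac_amplitude / dc_level is the designed perfusion ratio
#' @param drift_amplitude baseline (respiratory) drift amplitude
#' @param drift_freq drift frequency, Hz
#' @param noise_snr_db additive white-noise level relative to AC power;
#'   \code{Inf} disables noise
#' @param artifact_rate motion-artifact bursts per minute (0 disables)
#' @param dicrotic_amp,dicrotic_delay,sys_width,dic_width beat shape
#'   constants (fractions of the beat interval, except \code{dicrotic_amp}
#'   which is relative to the systolic lobe)
#' @param seed RNG seed (the global RNG state is restored on exit)
#' @return list of class \code{synth_ppg}: \code{record} (a
#'   \code{\link{ppg_record}}) and \code{truth} with \code{peak_times} (s,
#'   local maxima of the noiseless signal), \code{peak_indices},
#'   \code{hr_bpm} (60 / mean annotated IBI), \code{ibis_s}, \code{ac},
#'   \code{dc} (mean of the noiseless signal), \code{ac_dc},
#'   \code{noiseless} samples
#' @export
synth_ppg <- function(fs = 100, duration = 60, hr_bpm = 72, hrv_pct = 2,
                      dc_level = 100, ac_amplitude = 2,
                      drift_amplitude = 0.5, drift_freq = 0.25,
                      noise_snr_db = Inf, artifact_rate = 0,
                      dicrotic_amp = 0.35, dicrotic_delay = 0.35,
                      sys_width = 0.09, dic_width = 0.12, seed = 1) {
  if (fs <= 16) stop("fs must exceed 16 Hz")
  if (duration < 6) stop("duration must be at least 6 s")
  if (hr_bpm < 30 || hr_bpm > 240) stop("hr_bpm must lie in [30, 240]")
  if (ac_amplitude < 0) stop("ac_amplitude must be >= 0")

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  ibi0 <- 60 / hr_bpm

  # beat centers (systolic lobe centers), jittered intervals
  centers <- c()
  tc <- 0.5 * ibi0
  while (tc < duration + ibi0) {
    centers <- c(centers, tc)
    gap <- ibi0 * (1 + stats::rnorm(1, 0, hrv_pct / 100))
    tc <- tc + max(gap, 0.3 * ibi0)
  }

  pulse <- numeric(n)
  for (k in seq_along(centers)) {
    ib <- if (k < length(centers)) centers[k + 1] - centers[k] else
      centers[k] - centers[max(k - 1, 1)]
    if (ib <= 0) ib <- ibi0
    cs <- centers[k]
    cd <- cs + dicrotic_delay * ib
    ss <- sys_width * ib
    sd_ <- dic_width * ib
    lo <- max(1, floor((cs - 5 * ss) * fs))
    hi <- min(n, ceiling((cd + 5 * sd_) * fs) + 1)
    if (lo > n || hi < 1) next
    idx <- lo:hi
    pulse[idx] <- pulse[idx] +
      exp(-(t[idx] - cs)^2 / (2 * ss^2)) +
      dicrotic_amp * exp(-(t[idx] - cd)^2 / (2 * sd_^2))
  }
  # rescale: pulsatile peak-to-trough exactly ac_amplitude
  rng <- range(pulse)
  if (rng[2] > rng[1] && ac_amplitude > 0) {
    pulse <- ac_amplitude * (pulse - rng[1]) / (rng[2] - rng[1])
  } else {
    pulse <- pulse * 0
  }

  drift <- if (drift_amplitude > 0)
    drift_amplitude * sin(2 * pi * drift_freq * t) else numeric(n)

  noiseless <- dc_level + pulse + drift

  noise <- numeric(n)
  if (is.finite(noise_snr_db)) {
    ac_power <- mean((pulse - mean(pulse))^2)
    noise_sd <- sqrt(ac_power * 10^(-noise_snr_db / 10))
    noise <- stats::rnorm(n, 0, noise_sd)
  }

  artifacts <- numeric(n)
  if (artifact_rate > 0) {
    n_burst <- stats::rpois(1, artifact_rate * duration / 60)
    burst_len <- round(0.5 * fs)
    if (n_burst > 0) {
      for (b in seq_len(n_burst)) {
        s0 <- sample.int(max(1, n - burst_len), 1)
        idx <- s0:(s0 + burst_len - 1)
        win <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
        artifacts[idx] <- artifacts[idx] +
          5 * ac_amplitude * win * stats::rnorm(length(idx))
      }
    }
  }

  samples <- noiseless + noise + artifacts

  # annotate true peaks: refine each systolic center to the local maximum of
  # the noiseless signal (drift can shift the apex slightly)
  keep <- centers >= 0 & centers < duration
  peak_idx <- vapply(centers[keep], function(cs) {
    half <- max(2, round(0.2 * ibi0 * fs))
    i0 <- max(1, round(cs * fs) + 1 - half)
    i1 <- min(n, round(cs * fs) + 1 + half)
    i0 + which.max(noiseless[i0:i1]) - 1
  }, numeric(1))
  peak_idx <- unique(as.integer(peak_idx))
  peak_times <- t[peak_idx]
  ibis <- diff(peak_times)
  truth_hr <- if (length(ibis) >= 1) 60 / mean(ibis) else NA_real_

  list(record = ppg_record(samples, fs, channel = "synthetic"),
       truth = list(peak_times = peak_times, peak_indices = peak_idx,
                    hr_bpm = truth_hr, ibis_s = ibis,
                    ac = ac_amplitude, dc = mean(noiseless),
                    ac_dc = if (mean(noiseless) != 0)
                      ac_amplitude / mean(noiseless) else NaN,
                    noiseless = noiseless),
       spec = list(fs = fs, duration = duration, hr_bpm = hr_bpm,
                   hrv_pct = hrv_pct, dc_level = dc_level,
                   ac_amplitude = ac_amplitude,
                   drift_amplitude = drift_amplitude,
                   drift_freq = drift_freq, noise_snr_db = noise_snr_db,
                   artifact_rate = artifact_rate, seed = seed)) ->
    out
  class(out) <- "synth_ppg"
  out
}

#' @export
print.synth_ppg <- function(x, ...) {
  cat(sprintf(
    "synth_ppg: %g s @ %g Hz, target %g bpm (annotated %.2f bpm), %d beats\n",
    x$spec$duration, x$spec$fs, x$spec$hr_bpm, x$truth$hr_bpm,
    length(x$truth$peak_times)))
  invisible(x)
}
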