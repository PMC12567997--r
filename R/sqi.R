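#' PPG record container
#'
#' A single-channel PPG time series with its sampling rate. Amplitudes are
#' arbitrary linear ADC units.
#'
#' @param samples numeric amplitude vector
#' @param fs sampling rate, Hz
#' @param channel channel label
#' @return object of class \code{ppg_record}
#' @export
ppg_record <- function(samples, fs, channel = "ch1") {
  stopifnot(is.numeric(samples), fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs, channel = channel),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("ppg_record '%s': %d samples @ %g Hz (%.1f s)\n",
              x$channel, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

# zero-phase Butterworth helpers (forward-backward filtering, so the
# effective magnitude response is the squared design response and phase is
# exactly zero; chosen to preserve pulse morphology). The mean is removed
# and the signal reflection-padded before filtering: both are in the
# stop band of the high/band-pass designs but otherwise excite large edge
# transients in the forward-backward pass.
zp_filter <- function(x, bf, keep_mean = FALSE) {
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  npad <- min(n - 1, max(6 * (length(bf$a) - 1), round(n / 2)))
  pad_head <- 2 * xc[1] - xc[(npad + 1):2]
  pad_tail <- 2 * xc[n] - xc[(n - 1):(n - npad)]
  xp <- c(pad_head, xc, pad_tail)
  # forward-backward pass with the start-up transients absorbed by the
  # reflection padding on both sides
  yf <- as.numeric(signal::filter(bf, xp))
  yb <- rev(as.numeric(signal::filter(bf, rev(yf))))
  y <- yb[(npad + 1):(npad + n)]
  if (keep_mean) y + mu else y - mean(y)
}
bp_filter <- function(x, fs, lo, hi, order = 4) {
  zp_filter(x, signal::butter(order, c(lo, hi) / (fs / 2), type = "pass"))
}
hp_filter <- function(x, fs, fc, order = 4) {
  zp_filter(x, signal::butter(order, fc / (fs / 2), type = "high"))
}
lp_filter <- function(x, fs, fc, order = 4) {
  zp_filter(x, signal::butter(order, fc / (fs / 2), type = "low"),
            keep_mean = TRUE)
}

#' Segment a PPG record and band-pass filter each segment
#'
#' Splits the record into N = floor(length / (6 fs)) non-overlapping
#' segments of exactly 6 seconds (the remainder is discarded) and filters
#' each with a zero-phase 4th-order Butterworth band-pass, 0.5-5 Hz by
#' default. Each segment keeps both its raw samples (for the DC and SNR
#' computations) and the filtered series.
#'
#' @param record a \code{\link{ppg_record}}
#' @param band band-pass corner frequencies, Hz
#' @param order Butterworth design order
#' @return list of \code{ppg_segment} objects (fields \code{raw},
#'   \code{filtered}, \code{fs}, \code{index})
#' @export
segment_and_filter <- function(record, band = c(0.5, 5), order = 4) {
  stopifnot(inherits(record, "ppg_record"))
  seg_len <- round(6 * record$fs)
  n_seg <- floor(length(record$samples) / seg_len)
  if (n_seg < 1)
    stop("record shorter than one 6-s segment (", length(record$samples),
         " samples at ", record$fs, " Hz)")
  lapply(seq_len(n_seg), function(i) {
    raw <- record$samples[((i - 1) * seg_len + 1):(i * seg_len)]
    structure(list(raw = raw,
                   filtered = bp_filter(raw, record$fs, band[1], band[2], order),
                   fs = record$fs, index = i),
              class = "ppg_segment")
  })
}

#' Pulse wave amplitude (AC) of a segment
#'
#' The filtered segment is divided into L non-overlapping one-second
#' windows; AC is the mean over windows of the local (max - min) amplitude.
#'
#' @param segment a \code{ppg_segment}
#' @return AC value (input units)
#' @export
compute_ac <- function(segment) {
  y <- segment$filtered
  w <- round(segment$fs)
  L <- floor(length(y) / w)
  mean(vapply(seq_len(L), function(l) {
    win <- y[((l - 1) * w + 1):(l * w)]
    max(win) - min(win)
  }, numeric(1)))
}

#' Static level (DC) of a segment
#'
#' Arithmetic mean of the raw (unfiltered) segment.
#'
#' @param segment a \code{ppg_segment}
#' @return DC value (input units)
#' @export
compute_dc <- function(segment) mean(segment$raw)

#' Perfusion index
#'
#' Ratio of pulsatile to static amplitude, PI = AC / DC. Undefined when
#' DC = 0 (returns NaN; such segments are flagged and excluded from the
#' figure of merit).
#'
#' @param ac,dc pulse amplitude and static level
#' @return PI (dimensionless)
#' @export
compute_pi <- function(ac, dc) {
  if (dc == 0) return(NaN)
  ac / dc
}

#' Segment signal-to-noise ratio
#'
#' SNR (dB) defined as the in-band signal power of the filtered segment
#' over the residual powers of the raw segment's out-of-band components:
#' \code{10 log10( sum(y^2) / (sum((y - xhigh)^2) - sum((y - xlow)^2)) )},
#' where \code{xhigh} is the raw segment high-passed at 0.5 Hz and
#' \code{xlow} low-passed at 5 Hz (zero-phase 4th-order Butterworth). The
#' difference in the denominator can be non-positive for some noise
#' mixtures; the SNR is then NaN (a defined degenerate outcome, not an
#' error). SNR is reported alongside the other indices but does not enter
#' the figure of merit.
#'
#' @param segment a \code{ppg_segment}
#' @return list: \code{xhigh}, \code{xlow}, \code{snr_db}
#' @export
compute_snr <- function(segment) {
  y <- segment$filtered
  xhigh <- hp_filter(segment$raw, segment$fs, 0.5)
  xlow <- lp_filter(segment$raw, segment$fs, 5)
  num <- sum(y^2)
  den <- sum((y - xhigh)^2) - sum((y - xlow)^2)
  snr <- if (den <= 0 || num <= 0) NaN else 10 * log10(num / den)
  list(xhigh = xhigh, xlow = xlow, snr_db = snr)
}

#' Standardized moments of a power spectrum
#'
#' Given one-sided power values f[nf], computes their mean and standard
#' deviation and the raw standardized third- and fourth-moment sums
#' \code{SPSD = sum(((f - fmean)/fstd)^3)} and
#' \code{KPSD = sum(((f - fmean)/fstd)^4)}. No 1/NF factor is applied (the
#' session-level min-max normalization of the figure of merit absorbs
#' scale). A flat spectrum (fstd = 0) leaves both undefined (NaN).
#'
#' @param f non-negative power values
#' @return list: \code{f}, \code{fmean}, \code{fstd}, \code{NF},
#'   \code{spsd}, \code{kpsd}
#' @export
psd_moments_from_power <- function(f) {
  fmean <- mean(f)
  fstd <- stats::sd(f)
  if (!is.finite(fstd) || fstd == 0)
    return(list(f = f, fmean = fmean, fstd = fstd, NF = length(f),
                spsd = NaN, kpsd = NaN))
  z <- (f - fmean) / fstd
  list(f = f, fmean = fmean, fstd = fstd, NF = length(f),
       spsd = sum(z^3), kpsd = sum(z^4))
}

#' Power-spectrum skewness and kurtosis of a segment
#'
#' FFT power values of the filtered segment over the one-sided components
#' (NF = T/2 + 1 for even segment length T), passed to
#' \code{\link{psd_moments_from_power}}.
#'
#' @param segment a \code{ppg_segment}
#' @return see \code{\link{psd_moments_from_power}}
#' @export
compute_psd_moments <- function(segment) {
  y <- segment$filtered
  T_ <- length(y)
  nf <- floor(T_ / 2) + 1
  f <- Mod(stats::fft(y))[seq_len(nf)]^2
  psd_moments_from_power(f)
}

#' One-sided normalized autocorrelation profile of a segment
#'
#' Computes the unbiased one-sided autocorrelation of the filtered segment,
#' \code{R[k] = sum(y[t+k] y[t]) / (T - k)}, normalized by R[0], for lags up
#' to \code{max_lag} (default T/2: the unbiased estimate is too noisy beyond
#' half the window). Peaks of the profile are local maxima with topographic
#' prominence of at least \code{min_prominence} (fraction of R[0] = 1) and
#' at least \code{min_spacing_s} apart. The periodicity quality indices are
#' the standard deviations of the peak heights (STDpeaks) and of the
#' peak-to-peak lag intervals (STDperiods); both are exactly 0 for a
#' strictly periodic segment and undefined (NA) when fewer than two peaks /
#' two intervals exist.
#'
#' @param segment a \code{ppg_segment}
#' @param min_prominence peak prominence threshold as a fraction of R[0]
#' @param min_spacing_s minimum lag spacing between peaks, seconds
#' @param max_lag maximum lag in samples (default half the segment)
#' @return list: \code{R} (lags 0..max_lag), \code{peak_lags} (samples),
#'   \code{peak_heights}, \code{rppi_s} (intervals, s), \code{std_periods},
#'   \code{std_peaks}
#' @export
compute_autocorr_profile <- function(segment, min_prominence = 0.1,
                                     min_spacing_s = 0.25, max_lag = NULL) {
  y <- segment$filtered
  T_ <- length(y)
  if (is.null(max_lag)) max_lag <- floor(T_ / 2)
  lags <- 0:max_lag
  R <- vapply(lags, function(k)
    sum(y[(1 + k):T_] * y[1:(T_ - k)]) / (T_ - k), numeric(1))
  if (R[1] <= 0) {
    return(list(R = R, peak_lags = integer(0), peak_heights = numeric(0),
                rppi_s = numeric(0), std_periods = NA_real_,
                std_peaks = NA_real_))
  }
  R <- R / R[1]
  pk <- find_peaks(R, min_prominence = min_prominence,
                   min_distance = round(min_spacing_s * segment$fs))
  # drop the trivial lag-0 endpoint if it surfaced as a peak
  keep <- pk$index > 1
  peak_lags <- pk$index[keep] - 1
  peak_heights <- pk$height[keep]
  rppi <- diff(peak_lags) / segment$fs
  std_periods <- if (length(rppi) >= 2) stats::sd(rppi) else NA_real_
  std_peaks <- if (length(peak_heights) >= 2) stats::sd(peak_heights) else NA_real_
  list(R = R, peak_lags = peak_lags, peak_heights = peak_heights,
       rppi_s = rppi, std_periods = std_periods, std_peaks = std_peaks)
}

#' Local maxima with prominence and spacing constraints
#'
#' Strict local maxima of \code{x} whose topographic prominence (height
#' above the higher of the two saddle minima separating the peak from
#' higher ground) reaches \code{min_prominence}, thinned so that accepted
#' peaks are at least \code{min_distance} samples apart (taller peaks win).
#'
#' @param x numeric vector
#' @param min_prominence prominence threshold (same units as x)
#' @param min_distance minimum index spacing between accepted peaks
#' @return list: \code{index}, \code{height}, \code{prominence}
#' @export
find_peaks <- function(x, min_prominence = 0, min_distance = 1) {
  n <- length(x)
  if (n < 3) return(list(index = integer(0), height = numeric(0),
                         prominence = numeric(0)))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (length(cand) == 0)
    return(list(index = integer(0), height = numeric(0), prominence = numeric(0)))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    # walk left until higher ground, tracking the lowest saddle
    lmin <- h
    j <- i - 1
    while (j >= 1 && x[j] <= h) { if (x[j] < lmin) lmin <- x[j]; j <- j - 1 }
    rmin <- h
    j <- i + 1
    while (j <= n && x[j] <= h) { if (x[j] < rmin) rmin <- x[j]; j <- j + 1 }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) > 1 && min_distance > 1) {
    ord <- order(-x[cand])
    sel <- logical(length(cand))
    taken <- integer(0)
    for (k in ord) {
      if (all(abs(cand[k] - taken) >= min_distance)) {
        sel[k] <- TRUE
        taken <- c(taken, cand[k])
      }
    }
    cand <- cand[sel]; prom <- prom[sel]
    o <- order(cand)
    cand <- cand[o]; prom <- prom[o]
  }
  list(index = cand, height = x[cand], prominence = prom)
}

#' All signal-quality indices of one segment
#'
#' Computes the eight indices (AC, DC, PI, SNR, spectral skewness SPSD,
#' spectral kurtosis KPSD, STDperiods, STDpeaks) and a degeneracy flag.
#' A segment is flagged (and later excluded from the figure of merit) when
#' DC = 0, the spectrum is flat, fewer than the required autocorrelation
#' peaks exist, or either periodicity SD is exactly 0 (a strictly periodic
#' segment makes the figure-of-merit denominator degenerate).
#'
#' @param segment a \code{ppg_segment}
#' @param ... passed to \code{\link{compute_autocorr_profile}}
#' @return one-row data.frame of indices plus \code{flagged}, \code{flag_reason}
#' @export
compute_sqi <- function(segment, ...) {
  ac <- compute_ac(segment)
  dc <- compute_dc(segment)
  pi_ <- compute_pi(ac, dc)
  snr <- compute_snr(segment)$snr_db
  ps <- compute_psd_moments(segment)
  acf_ <- compute_autocorr_profile(segment, ...)
  reasons <- c()
  if (dc == 0) reasons <- c(reasons, "dc_zero")
  if (!is.finite(ps$spsd)) reasons <- c(reasons, "flat_spectrum")
  if (!is.finite(acf_$std_periods) || !is.finite(acf_$std_peaks))
    reasons <- c(reasons, "too_few_autocorr_peaks")
  else if (acf_$std_periods == 0 || acf_$std_peaks == 0)
    reasons <- c(reasons, "degenerate_periodicity")
  data.frame(segment = segment$index, ac = ac, dc = dc, pi = pi_,
             snr_db = snr, spsd = ps$spsd, kpsd = ps$kpsd,
             std_periods = acf_$std_periods, std_peaks = acf_$std_peaks,
             flagged = length(reasons) > 0,
             flag_reason = paste(reasons, collapse = ";"))
}

#' Per-segment signal-quality table for a whole record
#'
#' Segments and filters the record, then computes all indices per segment.
#'
#' @param record a \code{\link{ppg_record}}
#' @param band band-pass corners for \code{\link{segment_and_filter}}
#' @param ... passed to \code{\link{compute_sqi}}
#' @return data.frame, one row per segment
#' @export
sqi_session <- function(record, band = c(0.5, 5), ...) {
  segs <- segment_and_filter(record, band = band)
  do.call(rbind, lapply(segs, compute_sqi, ...))
}

#' Combine normalized indices into the figure of merit
#'
#' The composite quality score on (already normalized) indices:
#' \code{(PI * AC * SPSD * KPSD) / (STDperiods * STDpeaks)}. Amplitude and
#' spectral-shape quality multiply in the numerator; periodicity
#' instability divides.
#'
#' @param pi_,ac,spsd,kpsd,std_periods,std_peaks normalized index values
#' @return figure of merit value(s)
#' @export
fom_combine <- function(pi_, ac, spsd, kpsd, std_periods, std_peaks) {
  (pi_ * ac * spsd * kpsd) / (std_periods * std_peaks)
}

#' Figure of merit over a session of segments
#'
#' Each of the six contributing indices (PI, AC, SPSD, KPSD, STDperiods,
#' STDpeaks) is min-max normalized to [eps, 1] across the session's
#' unflagged segments (an index that is constant across the session
#' normalizes to 1). The per-segment figure of merit is then
#' \code{FoM = (PI * AC * SPSD * KPSD) / (STDperiods * STDpeaks)} on the
#' normalized values; the session summary is the mean and SD over segments.
#' SNR is carried through for reporting but does not enter the FoM.
#'
#' @param sqi data.frame from \code{\link{sqi_session}} (or rbind of
#'   \code{\link{compute_sqi}} rows)
#' @param eps normalization floor; keeps products positive and the
#'   denominator away from 0
#' @return list: \code{per_segment} (segment, fom, normalized indices),
#'   \code{mean_fom}, \code{sd_fom}, \code{n_used}, \code{n_flagged}
#' @export
compute_fom <- function(sqi, eps = 1e-6) {
  ok <- sqi[!sqi$flagged, , drop = FALSE]
  if (nrow(ok) == 0) stop("all segments flagged; figure of merit undefined")
  norm01 <- function(x) {
    rng <- range(x)
    if (rng[2] - rng[1] < .Machine$double.eps * max(1, abs(rng[2])))
      return(rep(1, length(x)))
    eps + (1 - eps) * (x - rng[1]) / (rng[2] - rng[1])
  }
  nz <- data.frame(pi = norm01(ok$pi), ac = norm01(ok$ac),
                   spsd = norm01(ok$spsd), kpsd = norm01(ok$kpsd),
                   std_periods = norm01(ok$std_periods),
                   std_peaks = norm01(ok$std_peaks))
  fom <- fom_combine(nz$pi, nz$ac, nz$spsd, nz$kpsd,
                     nz$std_periods, nz$std_peaks)
  list(per_segment = cbind(data.frame(segment = ok$segment, fom = fom), nz),
       mean_fom = mean(fom),
       sd_fom = if (length(fom) > 1) stats::sd(fom) else 0,
       n_used = nrow(ok), n_flagged = sum(sqi$flagged))
}
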