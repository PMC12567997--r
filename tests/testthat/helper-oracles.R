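# Independent brute-force transcriptions of the signal-quality formulas and
# small model builders used across the test files. These deliberately avoid
# the package's own code paths (plain loops, DFT-matrix transforms,
# convolution-theorem autocorrelation) so they can serve as oracles.

oracle_ac <- function(seg) {
  y <- seg$filtered
  w <- round(seg$fs)
  L <- floor(length(y) / w)
  tot <- 0
  for (l in 0:(L - 1)) {
    win <- y[(l * w + 1):((l + 1) * w)]
    wmax <- win[1]; wmin <- win[1]
    for (v in win) { if (v > wmax) wmax <- v; if (v < wmin) wmin <- v }
    tot <- tot + (wmax - wmin)
  }
  tot / L
}

oracle_dc <- function(seg) {
  s <- 0
  for (v in seg$raw) s <- s + v
  s / length(seg$raw)
}

# literal transcription of the SNR formula given the decomposition series
oracle_snr_db <- function(y, xhigh, xlow) {
  num <- 0; d1 <- 0; d2 <- 0
  for (t in seq_along(y)) {
    num <- num + y[t]^2
    d1 <- d1 + (y[t] - xhigh[t])^2
    d2 <- d2 + (y[t] - xlow[t])^2
  }
  den <- d1 - d2
  if (den <= 0 || num <= 0) NaN else 10 * log10(num / den)
}

# one-sided power spectrum via an explicit DFT matrix (independent of fft)
oracle_power_spectrum <- function(y) {
  T_ <- length(y)
  nf <- floor(T_ / 2) + 1
  k <- 0:(nf - 1)
  t <- 0:(T_ - 1)
  W <- exp(-2i * pi * outer(k, t) / T_)
  Mod(as.vector(W %*% y))^2
}

oracle_psd_moments <- function(f) {
  n <- length(f)
  m <- sum(f) / n
  s <- sqrt(sum((f - m)^2) / (n - 1))
  if (s == 0) return(list(spsd = NaN, kpsd = NaN))
  sp <- 0; kp <- 0
  for (v in f) {
    z <- (v - m) / s
    sp <- sp + z^3
    kp <- kp + z^4
  }
  list(spsd = sp, kpsd = kp)
}

# unbiased one-sided autocorrelation through the convolution theorem
# (normalized by R[0]), independent of the package's shifted-sum route
oracle_autocorr_fft <- function(y, max_lag) {
  T_ <- length(y)
  n2 <- 2^ceiling(log2(2 * T_))
  Y <- stats::fft(c(y, rep(0, n2 - T_)))
  r <- Re(stats::fft(Y * Conj(Y), inverse = TRUE)) / n2
  r <- r[1:(max_lag + 1)] / (T_ - 0:max_lag)
  r / r[1]
}

# plain O(T^2) double-loop autocorrelation (slow; use on few fixtures)
oracle_autocorr_loop <- function(y, max_lag) {
  T_ <- length(y)
  R <- numeric(max_lag + 1)
  for (k in 0:max_lag) {
    s <- 0
    for (t in 1:(T_ - k)) s <- s + y[t + k] * y[t]
    R[k + 1] <- s / (T_ - k)
  }
  R / R[1]
}

# homogeneous cylinder model filling the whole finger cross-section
rod_model <- function(mu_a, mu_s = 0, g = 0.5, n = 1.0, wavelength = 550,
                      label = "microcirculation") {
  op <- optical_properties(mu_a, mu_s, g, n)
  reg <- finger_region(label, "annulus", r_in = 0, r_out = 9.6,
                       props = stats::setNames(list(op), wavelength))
  finger_model(list(reg), outer_radius = 9.6, axial_length = 20,
               wavelengths = as.numeric(wavelength))
}

# weakly scattering two-layer toy model (fast sweeps)
toy_model <- function(wavelength = 550) {
  mk <- function(mu_a, mu_s, g) stats::setNames(
    list(optical_properties(mu_a, mu_s, g, 1.0)), wavelength)
  regions <- list(
    finger_region("dermis", "annulus", r_in = 7, r_out = 9.6,
                  props = mk(0.02, 1.0, 0.5)),
    finger_region("microcirculation", "annulus", r_in = 0, r_out = 7,
                  props = mk(0.02, 0.5, 0.5)))
  finger_model(regions, outer_radius = 9.6, axial_length = 20,
               wavelengths = as.numeric(wavelength))
}

# seeded fixture segments at fs = 50 (one 6-s segment each): a mix of
# pulse-like records and coloured/white noise records
fixture_segments <- function(n, fs = 50) {
  lapply(seq_len(n), function(i) {
    if (i %% 2 == 0) {
      g <- synth_ppg(fs = fs, duration = 6, hr_bpm = 45 + (i %% 9) * 15,
                     hrv_pct = 3, noise_snr_db = 20 - (i %% 5) * 10,
                     seed = 9000 + i)
      segment_and_filter(g$record)[[1]]
    } else {
      set.seed(9000 + i)
      segment_and_filter(ppg_record(100 + stats::rnorm(6 * fs), fs))[[1]]
    }
  })
}

# smoothed binomial SE for a traversal fraction estimated from n detections
smoothed_fraction_se <- function(f, n) {
  ft <- (f * n + 0.5) / (n + 1)
  sqrt(ft * (1 - ft) / n)
}
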