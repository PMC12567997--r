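mk_segment <- function(filtered, raw = filtered, fs = 100, index = 1) {
  structure(list(raw = raw, filtered = filtered, fs = fs, index = index),
            class = "ppg_segment")
}

test_that("segmentation yields 6-s segments and rejects short records", {
  g <- synth_ppg(fs = 100, duration = 60, seed = 1)
  segs <- segment_and_filter(g$record)
  expect_length(segs, 10)
  expect_length(segs[[1]]$raw, 600)
  expect_length(segs[[1]]$filtered, 600)
  short <- ppg_record(stats::rnorm(500), 100)
  expect_error(segment_and_filter(short), "shorter")
  # 61.5 s -> remainder discarded
  g2 <- ppg_record(stats::rnorm(6150), 100)
  expect_length(segment_and_filter(g2), 10)
})

test_that("the band-pass passes a 1 Hz tone within 2 percent and removes DC", {
  fs <- 100
  t <- (0:1199) / fs
  rec <- ppg_record(100 + sin(2 * pi * 1 * t), fs)
  segs <- segment_and_filter(rec)
  y <- segs[[2]]$filtered
  trim <- 100:500
  expect_lt(abs(max(abs(y[trim])) - 1), 0.02)
  expect_lt(abs(mean(y)), 1e-3)
})

test_that("AC of a unit 1 Hz sinusoid is exactly 2 and of a constant 0", {
  fs <- 100
  t <- (0:599) / fs
  seg <- mk_segment(sin(2 * pi * t), fs = fs)
  expect_equal(compute_ac(seg), 2, tolerance = 1e-12)
  expect_equal(compute_ac(mk_segment(rep(3, 600))), 0)
  # brute-force oracle on random segments
  set.seed(41)
  for (i in 1:5) {
    s <- mk_segment(stats::rnorm(600), fs = 100)
    expect_equal(compute_ac(s), oracle_ac(s), tolerance = 1e-12)
  }
})

test_that("DC is the raw-segment mean", {
  expect_equal(compute_dc(mk_segment(rep(0, 600), raw = rep(512, 600))), 512)
  t <- (0:599) / 100
  seg <- mk_segment(rep(0, 600), raw = 100 + sin(2 * pi * t))
  expect_equal(compute_dc(seg), 100, tolerance = 1e-12)
  set.seed(42)
  s <- mk_segment(stats::rnorm(600), raw = stats::rnorm(600, 50))
  expect_equal(compute_dc(s), oracle_dc(s), tolerance = 1e-12)
})

test_that("perfusion index is AC/DC with the DC=0 degenerate case flagged", {
  expect_equal(compute_pi(2, 10), 0.2)
  expect_equal(compute_pi(0, 10), 0)
  expect_true(is.nan(compute_pi(2, 0)))
  # generator-designed perfusion ratio recovered within 5 percent over the session
  g <- synth_ppg(seed = 8, noise_snr_db = Inf)
  q <- sqi_session(g$record)
  expect_lt(abs(mean(q$pi) - g$truth$ac_dc) / g$truth$ac_dc, 0.05)
})

test_that("SNR is the literal formula: degenerate on zero signal, monotone in noise", {
  z <- mk_segment(rep(0, 600))
  expect_true(is.nan(compute_snr(z)$snr_db))
  # pure in-band tone + white noise at two levels: computed SNR must order
  # them; the tone is Tukey-windowed per segment so no in-band content sits
  # on the segment edges (the narrow 0.5 Hz corner makes edge transients
  # intrinsic, and the two decomposition filters disagree there)
  fs <- 100
  t <- (0:1199) / fs
  win <- rep(0.5 * (1 - cos(2 * pi * (0:599) / 599)), 2)
  tone <- sin(2 * pi * 1.2 * t) * win
  set.seed(43)
  noise <- stats::rnorm(length(t))
  snr_at <- function(sdn) {
    rec <- ppg_record(tone + sdn * noise, fs)
    segs <- segment_and_filter(rec)
    mean(vapply(segs, function(s) compute_snr(s)$snr_db, numeric(1)))
  }
  hi <- snr_at(0.1)   # generator-side 20 dB
  lo <- snr_at(1.0)   # generator-side 0 dB
  expect_true(is.finite(hi) && is.finite(lo))
  expect_gt(hi, lo)
})

test_that("spectral moment sums match closed forms on a constructed spectrum", {
  m <- 5; d <- 2; k <- 8
  f <- c(m + d, m - d, rep(m, k))
  ps <- psd_moments_from_power(f)
  expect_equal(ps$spsd, 0, tolerance = 1e-12)  # odd-moment symmetry
  s <- stats::sd(f)
  expect_equal(ps$kpsd, 2 * (d / s)^4, tolerance = 1e-12)
  # flat spectrum is undefined
  expect_true(is.nan(psd_moments_from_power(rep(1, 10))$spsd))
})

test_that("autocorrelation of an exactly periodic segment has zero-SD peaks and is flagged", {
  fs <- 50
  t <- (0:299) / fs
  seg <- mk_segment(sin(2 * pi * 2 * t), fs = fs)
  a <- compute_autocorr_profile(seg)
  expect_equal(a$R[1], 1)
  expect_equal(a$peak_lags, c(25, 50, 75, 100, 125))
  expect_equal(a$std_periods, 0, tolerance = 1e-12)
  expect_equal(a$std_peaks, 0, tolerance = 1e-9)
  q <- compute_sqi(mk_segment(sin(2 * pi * 2 * t), raw = 100 + sin(2 * pi * 2 * t),
                              fs = fs))
  expect_true(q$flagged)
  expect_match(q$flag_reason, "degenerate_periodicity")
})

test_that("white-noise autocorrelation is near zero beyond lag 0", {
  set.seed(44)
  small <- 0
  for (i in 1:20) {
    seg <- mk_segment(stats::rnorm(600), fs = 100)
    a <- compute_autocorr_profile(seg)
    expect_equal(a$R[1], 1)
    if (mean(abs(a$R[-1])) < 0.1 &&
        (length(a$peak_heights) == 0 || max(a$peak_heights) < 0.5))
      small <- small + 1
  }
  expect_equal(small, 20)
})

test_that("autocorrelation matches the O(T^2) loop transcription", {
  set.seed(45)
  for (i in 1:3) {
    y <- stats::rnorm(300)
    seg <- mk_segment(y, fs = 50)
    a <- compute_autocorr_profile(seg)
    expect_equal(a$R, oracle_autocorr_loop(y, 150), tolerance = 1e-9)
  }
})

test_that("amplitude and offset invariances hold for the index set", {
  g <- synth_ppg(seed = 14, noise_snr_db = 20)
  q1 <- sqi_session(g$record)
  # scaling the whole record leaves PI and the standardized spectral sums fixed
  rec_scaled <- ppg_record(3.7 * g$record$samples, g$record$fs)
  q2 <- sqi_session(rec_scaled)
  expect_equal(q2$pi, q1$pi, tolerance = 1e-6)
  expect_equal(q2$ac, 3.7 * q1$ac, tolerance = 1e-6)
  expect_equal(q2$dc, 3.7 * q1$dc, tolerance = 1e-6)
  expect_equal(q2$spsd, q1$spsd, tolerance = 1e-6)
  expect_equal(q2$kpsd, q1$kpsd, tolerance = 1e-6)
  # adding a constant shifts DC but not AC (the filter removes it)
  rec_off <- ppg_record(g$record$samples + 250, g$record$fs)
  q3 <- sqi_session(rec_off)
  expect_equal(q3$ac, q1$ac, tolerance = 1e-6)
  expect_equal(q3$dc, q1$dc + 250, tolerance = 1e-6)
})

test_that("the figure-of-merit combination follows the index ratio arithmetic", {
  expect_equal(fom_combine(1, 1, 1, 1, 1, 1), 1)
  expect_equal(fom_combine(1, 1, 1, 1, 0.5, 0.5), 4)
  expect_equal(fom_combine(0.5, 0.5, 1, 1, 1, 1), 0.25)
})

test_that("session FoM normalizes per index, excludes flagged segments, errors when empty", {
  g <- synth_ppg(seed = 3)
  q <- sqi_session(g$record)
  f <- compute_fom(q)
  expect_equal(f$n_used + f$n_flagged, nrow(q))
  expect_true(all(is.finite(f$per_segment$fom)))
  nz <- f$per_segment[, c("pi", "ac", "spsd", "kpsd", "std_periods", "std_peaks")]
  expect_true(all(nz >= 1e-6 - 1e-12 & nz <= 1))
  # a single unflagged segment normalizes to all ones -> FoM 1
  one <- q[!q$flagged, ][1, ]
  f1 <- compute_fom(one)
  expect_equal(f1$per_segment$fom, 1)
  allflag <- q
  allflag$flagged <- TRUE
  expect_error(compute_fom(allflag), "flagged")
})

test_that("clean sessions outscore heavily corrupted sessions in joint FoM", {
  # corruption at 0 dB in-band (broadband -10 dB): periodicity clearly degraded
  for (s in 1:3) {
    qa <- sqi_session(synth_ppg(seed = s)$record)
    qb <- sqi_session(synth_ppg(seed = s, noise_snr_db = -10)$record)
    qb$segment <- qb$segment + 10
    f <- compute_fom(rbind(qa, qb))
    ps <- f$per_segment
    expect_gt(mean(ps$fom[ps$segment <= 10]), mean(ps$fom[ps$segment > 10]))
  }
})
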