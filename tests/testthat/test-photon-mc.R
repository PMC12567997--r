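test_that("free-path sampling is exponential with mean 1/mu_t", {
  expect_equal(sample_free_path(1.0, exp(-1)), 1.0)
  expect_equal(sample_free_path(2.0, exp(-1)), 0.5)
  expect_equal(sample_free_path(0, c(0.3, 0.7)), c(Inf, Inf))
  set.seed(11)
  s <- sample_free_path(1.0, stats::runif(1e6))
  se <- stats::sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - 1.0), 3 * se)
})

test_that("Henyey-Greenstein sampling has first moment g and valid range", {
  expect_equal(scatter_hg(0, 0.5)$cost, 0)
  set.seed(12)
  for (g in c(0, 0.5, 0.9)) {
    u <- stats::runif(1e6)
    cost <- scatter_hg(g, u, stats::runif(1e6))$cost
    expect_true(all(cost >= -1 & cost <= 1))
    se <- stats::sd(cost) / sqrt(length(cost))
    expect_lt(abs(mean(cost) - g), 3 * se)
  }
})

test_that("Fresnel reflectance matches the sine/tangent-form equations on a 1-degree grid", {
  expect_equal(fresnel_reflectance(1.0, 1.5, 0), ((1 - 1.5) / (1 + 1.5))^2)
  expect_equal(fresnel_reflectance(1.4, 1.4, 0.7), 0)
  n1 <- 1.4; n2 <- 1.0
  crit <- asin(n2 / n1)
  th <- (0:89) * pi / 180
  got <- fresnel_reflectance(n1, n2, th)
  # independent transcription via the sin/tan forms
  expected <- vapply(th, function(ti) {
    st <- n1 / n2 * sin(ti)
    if (st >= 1) return(1)
    tt <- asin(st)
    if (ti == 0) return(((n1 - n2) / (n1 + n2))^2)
    rs <- sin(ti - tt) / sin(ti + tt)
    rp <- tan(ti - tt) / tan(ti + tt)
    0.5 * (rs^2 + rp^2)
  }, numeric(1))
  expect_equal(got, expected, tolerance = 1e-12)
  expect_true(all(got[th > crit] == 1))  # total internal reflection
})

test_that("non-scattering transmission follows Beer-Lambert with exact weight conservation", {
  pl <- ring_placement(0, 180, led_aperture = 1, pd_aperture = 20,
                       axial_extent = 6)
  for (mu_a in c(0.05, 0.1)) {
    m <- rod_model(mu_a, mu_s = 0, n = 1.0)
    cfg <- transport_config(n_photons = 1e5, seed = 31, launch = "collimated")
    r <- run_simulation(m, pl, 550, cfg)
    p <- exp(-mu_a * 19.2)
    se <- sqrt(p * (1 - p) / cfg$n_photons)
    expect_lt(abs(r$detected_weight / r$launched_weight - p), 3 * se)
    resid <- abs(r$launched_weight - r$absorbed_weight - r$escaped_weight -
                   r$detected_weight) / r$launched_weight
    expect_lt(resid, 1e-6)
  }
})

test_that("boundary Fresnel reflection reduces straight-through detection by (1 - R)", {
  # index 1.5 rod: normal-incidence exit reflectance 0.04 at the PD side
  m <- rod_model(0.1, mu_s = 0, n = 1.5)
  pl <- ring_placement(0, 180, led_aperture = 1, pd_aperture = 20,
                       axial_extent = 6)
  cfg <- transport_config(n_photons = 4e4, seed = 32, launch = "collimated")
  r <- run_simulation(m, pl, 550, cfg)
  p <- exp(-0.1 * 19.2) * (1 - 0.04)
  se <- sqrt(p * (1 - p) / cfg$n_photons)
  expect_lt(abs(r$detected_weight / r$launched_weight - p), 3 * se + 1e-3)
})

test_that("a microcirculation region spanning the interior gives micro_fraction 1", {
  m <- rod_model(0.05, mu_s = 1, g = 0.5, n = 1.0)
  pl <- ring_placement(0, 180, pd_aperture = 60, axial_extent = 10)
  r <- run_simulation(m, pl, 550, transport_config(n_photons = 5e3, seed = 33))
  expect_gt(r$detected_count, 0)
  expect_equal(r$micro_fraction, 1)
})

test_that("identical seeds give bit-identical results; zero detection gives NaN", {
  m <- toy_model()
  pl <- ring_placement(0, 90)
  cfg <- transport_config(n_photons = 3e3, seed = 77)
  r1 <- run_simulation(m, pl, 550, cfg)
  r2 <- run_simulation(m, pl, 550, cfg)
  fields <- c("launched_weight", "absorbed_weight", "escaped_weight",
              "detected_weight", "detected_weight_through_microcirculation",
              "detected_count", "micro_fraction")
  expect_identical(r1[fields], r2[fields])
  r3 <- run_simulation(m, pl, 550, transport_config(n_photons = 3e3, seed = 78))
  expect_false(identical(r1[fields], r3[fields]))
  # opaque rod: nothing reaches the PD -> NaN fraction, not an error
  mo <- rod_model(5, mu_s = 0, n = 1.0)
  ro <- run_simulation(mo, ring_placement(0, 180, led_aperture = 1),
                       550, transport_config(n_photons = 500, seed = 1,
                                             launch = "collimated"))
  expect_equal(ro$detected_weight, 0)
  expect_true(is.nan(ro$micro_fraction))
})

test_that("traversal tallies and fractions respect their bounds on a scattering run", {
  m <- build_default_finger(940)
  r <- run_simulation(m, ring_placement(0, 90), 940,
                      transport_config(n_photons = 2e4, seed = 5))
  expect_lte(r$detected_weight_through_microcirculation, r$detected_weight)
  expect_lte(r$detected_weight_through_artery, r$detected_weight)
  expect_true(is.nan(r$micro_fraction) ||
                (r$micro_fraction >= 0 && r$micro_fraction <= 1))
  resid <- abs(r$launched_weight - r$absorbed_weight - r$escaped_weight -
                 r$detected_weight) / r$launched_weight
  expect_lt(resid, 1e-6)
  expect_equal(r$n_step_capped, 0)
})

test_that("count-ratio mode reports detected photon-count fractions", {
  m <- build_default_finger(940)
  cfgw <- transport_config(n_photons = 1e4, seed = 9)
  cfgc <- transport_config(n_photons = 1e4, seed = 9, count_ratio = TRUE)
  rw <- run_simulation(m, ring_placement(0, 90), 940, cfgw)
  rc <- run_simulation(m, ring_placement(0, 90), 940, cfgc)
  expect_equal(rc$micro_fraction,
               rc$detected_micro_count / rc$detected_count)
  expect_equal(rw$detected_count, rc$detected_count)  # same transport, same seed
})
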