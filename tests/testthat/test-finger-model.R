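test_that("default finger geometry matches the anatomical reference dimensions", {
  m <- build_default_finger(550)
  expect_s3_class(m, "finger_model")
  expect_equal(m$outer_radius, 9.6)
  labs <- vapply(m$regions, function(r) r$label, character(1))
  micro <- m$regions[[which(labs == "microcirculation")]]
  expect_equal(2 * micro$r_out, 16)          # microcirculation diameter
  epi <- m$regions[[which(labs == "epidermis")]]
  expect_equal(epi$r_out - epi$r_in, 0.6)    # epidermis thickness
  der <- m$regions[[which(labs == "dermis")]]
  expect_equal(der$r_out - der$r_in, 1.0)    # dermis thickness
  expect_equal(epi$r_out - micro$r_out, 1.6) # skin thickness above microcirculation
  expect_equal(sum(labs %in% c("artery", "vein")), 4)
  expect_equal(sum(labs == "bone"), 1)
})

test_that("every region covers every declared wavelength; unknown wavelengths error", {
  m <- build_default_finger(c(550, 628, 940))
  for (r in m$regions)
    expect_setequal(names(r$props), c("550", "628", "940"))
  expect_error(build_default_finger(700), "700")
  expect_equal(attr(m, "optics_source"), "literature defaults")
})

test_that("optical property invariants are enforced", {
  expect_error(optical_properties(-1, 10, 0.9, 1.4), "mu_a")
  expect_error(optical_properties(1, -1, 0.9, 1.4), "mu_s")
  expect_error(optical_properties(1, 10, 1, 1.4), "g")
  expect_error(optical_properties(1, 10, 0.9, 0.5), "refractive")
})

test_that("locate_region classifies canonical points", {
  m <- build_default_finger(550)
  z <- m$axial_length / 2
  expect_equal(locate_region(m, c(9.3, 0, z)), "epidermis")
  expect_equal(locate_region(m, c(20, 0, z)), "ambient")
  expect_equal(locate_region(m, c(8.5, 0, z)), "dermis")
  expect_equal(locate_region(m, c(0, 0, z)), "bone")
  expect_equal(locate_region(m, c(0, 5.5, z)), "microcirculation")
  a30 <- 6.5 * c(cos(pi / 6), sin(pi / 6))
  expect_equal(locate_region(m, c(a30, z)), "artery")
  a150 <- 6.5 * c(cos(5 * pi / 6), sin(5 * pi / 6))
  expect_equal(locate_region(m, c(a150, z)), "vein")
  expect_equal(locate_region(m, c(5, 0, -1)), "ambient")  # outside axial extent
})

test_that("locate_region agrees with a brute-force containment oracle on random points", {
  m <- build_default_finger(550)
  set.seed(101)
  n <- 1e4
  pts <- cbind(stats::runif(n, -12, 12), stats::runif(n, -12, 12),
               stats::runif(n, -2, 22))
  got <- locate_region(m, pts)
  # independent oracle: explicit precedence walk over the default geometry
  vessels <- list(artery = 30, artery = -30, vein = 150, vein = 210)
  expected <- character(n)
  for (i in seq_len(n)) {
    x <- pts[i, 1]; y <- pts[i, 2]; z <- pts[i, 3]
    r <- sqrt(x^2 + y^2)
    lab <- "ambient"
    if (z >= 0 && z <= 20 && r <= 9.6) {
      hit <- NA_character_
      for (k in seq_along(vessels)) {
        cx <- 6.5 * cos(vessels[[k]] * pi / 180)
        cy <- 6.5 * sin(vessels[[k]] * pi / 180)
        if ((x - cx)^2 + (y - cy)^2 < 0.6^2) { hit <- names(vessels)[k]; break }
      }
      if (is.na(hit) && x^2 + y^2 < 9) hit <- "bone"
      if (is.na(hit)) {
        hit <- if (r < 8) "microcirculation" else if (r < 9) "dermis" else "epidermis"
      }
      lab <- hit
    }
    expected[i] <- lab
  }
  expect_identical(got, expected)
})

test_that("cross-section areas are the analytic annulus/disk values", {
  m <- build_default_finger(550)
  a <- region_areas(m)
  expect_equal(a[["epidermis"]], pi * (9.6^2 - 9.0^2), tolerance = 1e-12)
  expect_equal(a[["dermis"]], pi * (9.0^2 - 8.0^2), tolerance = 1e-12)
  expect_equal(a[["microcirculation"]], pi * 64, tolerance = 1e-12)
  expect_equal(sum(a[names(a) %in% c("artery", "vein")]), 4 * pi * 0.36,
               tolerance = 1e-12)
})

test_that("overlapping annuli are rejected", {
  op <- list("550" = optical_properties(0.1, 1, 0.5, 1.4))
  r1 <- finger_region("dermis", "annulus", r_in = 0, r_out = 9, props = op)
  r2 <- finger_region("epidermis", "annulus", r_in = 8, r_out = 9.6, props = op)
  expect_error(finger_model(list(r1, r2), 9.6, wavelengths = 550), "overlap")
})

test_that("enumerate_layouts produces the full angular grid", {
  expect_length(enumerate_layouts(30), 144)   # 12 x 12 design grid
  expect_length(enumerate_layouts(90), 16)
  for (g in c(30, 45, 90, 120))
    expect_length(enumerate_layouts(g), (360 / g)^2)
  # exactly 12 placements share the 60-degree LED-PD angle on the 30 grid
  deltas <- vapply(enumerate_layouts(30), function(p) p$delta, numeric(1))
  expect_equal(sum(deltas == 60), 12)
  expect_error(enumerate_layouts(0), "positive")
  expect_error(enumerate_layouts(-30), "positive")
  expect_error(enumerate_layouts(7), "divide")
})

test_that("ring placement normalizes angles modulo 360", {
  p <- ring_placement(-30, 390)
  expect_equal(p$led_angle, 330)
  expect_equal(p$pd_angle, 30)
  expect_equal(p$delta, 60)
})

test_that("a JSON finger config round-trips through read_finger_config", {
  path <- system.file("extdata", "default_optics.json", package = "ringppg")
  opt <- jsonlite::read_json(path)
  cfg <- list(outer_radius = 9.6, axial_length = 20, source = "test config",
              regions = list(
                list(label = "epidermis", type = "annulus", r_in = 9, r_out = 9.6),
                list(label = "microcirculation", type = "annulus", r_in = 0, r_out = 9),
                list(label = "artery", type = "cylinder", center = c(5, 0),
                     radius = 0.6, optics = "vessel")),
              optics = opt$optics)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  m <- read_finger_config(tmp, wavelengths = c(550, 940))
  expect_s3_class(m, "finger_model")
  expect_equal(locate_region(m, c(5, 0, 10)), "artery")
  expect_equal(m$regions[[3]]$props[["940"]]$mu_s,
               opt$optics$vessel[["940"]]$mu_s)
})
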