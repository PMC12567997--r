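#' Transport configuration
#'
#' Controls for the weighted Monte Carlo kernel. Implicit-capture weighting
#' is used: at each interaction a photon deposits \code{mu_a/mu_t} of its
#' weight and scatters with the remainder; Russian roulette terminates
#' low-weight photons unbiasedly.
#'
#' @param n_photons photons to launch (>= 1)
#' @param seed RNG seed; each photon gets an independent counter-derived
#'   substream, so runs are reproducible under any execution order
#' @param roulette_threshold weight below which roulette triggers
#' @param roulette_survival survival probability in (0, 1)
#' @param max_steps per-photon step cap; capped photons are tallied as
#'   absorbed and counted (their fraction should be negligible in default runs)
#' @param launch "lambertian" (cosine-weighted into the tissue, the default)
#'   or "collimated" (along the inward surface normal; useful for
#'   closed-form transmission checks)
#' @param count_ratio if TRUE, traversal fractions are reported as detected
#'   photon-count ratios instead of weight ratios
#' @param n_ambient refractive index of the surrounding medium
#' @return object of class \code{transport_config}
#' @export
transport_config <- function(n_photons = 1e5, seed = 1,
                             roulette_threshold = 1e-4,
                             roulette_survival = 0.1,
                             max_steps = 1e5,
                             launch = c("lambertian", "collimated"),
                             count_ratio = FALSE, n_ambient = 1.0) {
  launch <- match.arg(launch)
  stopifnot(n_photons >= 1, roulette_threshold > 0,
            roulette_survival > 0, roulette_survival < 1, max_steps >= 1)
  structure(list(n_photons = as.integer(n_photons), seed = seed,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 max_steps = as.integer(max_steps), launch = launch,
                 count_ratio = count_ratio, n_ambient = n_ambient),
            class = "transport_config")
}

#' Sample a photon free path
#'
#' Exponential free-path sampling: \code{-log(u)/mu_t} for total attenuation
#' \code{mu_t} (1/mm) and a uniform draw in (0, 1). A non-positive
#' \code{mu_t} means free flight to the next boundary (infinite path).
#'
#' @param mu_t total attenuation coefficient, 1/mm
#' @param u uniform draw(s) in (0, 1)
#' @return path length(s), mm
#' @export
sample_free_path <- function(mu_t, u) {
  if (mu_t <= 0) return(rep(Inf, length(u)))
  -log(u) / mu_t
}

#' Sample a Henyey-Greenstein deflection
#'
#' Inverse-CDF sampling of the scattering polar angle cosine for the
#' Henyey-Greenstein phase function with anisotropy \code{g}; the azimuth is
#' uniform on [0, 2*pi). \code{g = 0} reduces to isotropic
#' \code{cos(theta) = 2u - 1}. The first moment of the sampled cosine
#' equals g.
#'
#' @param g anisotropy, strictly in (-1, 1)
#' @param u1 uniform draw(s) for the polar cosine
#' @param u2 uniform draw(s) for the azimuth
#' @return list with \code{cost} (cosine of deflection) and \code{phi}
#' @export
scatter_hg <- function(g, u1, u2 = stats::runif(length(u1))) {
  stopifnot(g > -1, g < 1)
  if (abs(g) < 1e-8) {
    cost <- 2 * u1 - 1
  } else {
    f <- (1 - g^2) / (1 + g - 2 * g * u1)
    cost <- (1 + g^2 - f^2) / (2 * g)
    cost <- pmin(1, pmax(-1, cost))
  }
  list(cost = cost, phi = 2 * pi * u2)
}

#' Unpolarized Fresnel reflectance
#'
#' Reflectance for an unpolarized ray crossing from index \code{n1} into
#' \code{n2} at incidence angle \code{theta_i} (radians from the surface
#' normal). Returns 1 beyond the critical angle (total internal
#' reflection).
#'
#' @param n1,n2 refractive indices on the incident and far side
#' @param theta_i incidence angle(s), radians
#' @return reflectance in [0, 1]
#' @export
fresnel_reflectance <- function(n1, n2, theta_i) {
  ci <- cos(theta_i)
  si2 <- 1 - ci^2
  sin2t <- (n1 / n2)^2 * si2
  ct <- sqrt(pmax(0, 1 - sin2t))
  rs <- (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct)
  rp <- (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci)
  r <- 0.5 * (rs^2 + rp^2)
  r[sin2t >= 1] <- 1
  r
}

# Flatten a finger_model into the kernel's matrix representation.
# Returns annuli / cylinders / props matrices plus logical flags.
model_to_kernel <- function(model, wavelength) {
  wl <- as.character(wavelength)
  regs <- model$regions
  K <- length(regs)
  props <- matrix(0, K, 4)
  is_micro <- logical(K)
  is_artery <- logical(K)
  ann <- NULL; cyl <- NULL
  for (i in seq_len(K)) {
    p <- regs[[i]]$props[[wl]]
    if (is.null(p))
      stop("model has no optical properties at ", wavelength, " nm")
    props[i, ] <- c(p$mu_a, p$mu_s, p$g, p$n)
    is_micro[i] <- regs[[i]]$label == "microcirculation"
    is_artery[i] <- regs[[i]]$label == "artery"
    if (regs[[i]]$type == "annulus")
      ann <- rbind(ann, c(regs[[i]]$r_in, regs[[i]]$r_out, i - 1))
    else
      cyl <- rbind(cyl, c(regs[[i]]$center[1], regs[[i]]$center[2],
                          regs[[i]]$radius, i - 1))
  }
  if (is.null(ann)) ann <- matrix(0, 0, 3)
  if (is.null(cyl)) cyl <- matrix(0, 0, 4)
  # kernel checks annuli in row order after cylinders: sort inner to outer
  if (nrow(ann) > 1) ann <- ann[order(ann[, 2]), , drop = FALSE]
  list(annuli = ann, cylinders = cyl, props = props,
       is_micro = is_micro, is_artery = is_artery)
}

#' Run a Monte Carlo transport simulation
#'
#' Launches \code{cfg$n_photons} weighted photons from the LED patch,
#' propagates them through the finger model with exponential step sampling,
#' Henyey-Greenstein scattering, implicit-capture absorption and Russian
#' roulette, tags every region a photon visits, and tallies photons that
#' exit the outer boundary within the PD patch as detected. The headline
#' quantity is \code{micro_fraction}: the share of detected light (by
#' weight, or by count with \code{count_ratio = TRUE}) that traversed the
#' microcirculation layer at least once. Zero detected weight yields
#' \code{micro_fraction = NaN} rather than an error, mirroring layouts where
#' no light reaches the detector.
#'
#' Weight is conserved per run:
#' launched = absorbed + escaped + detected to floating-point rounding
#' (roulette survival boosts are debited from the absorbed tally, which
#' makes it the balancing unbiased estimator).
#'
#' @param model a \code{\link{finger_model}}
#' @param placement a \code{\link{ring_placement}}
#' @param wavelength nm; must be covered by the model
#' @param cfg a \code{\link{transport_config}}
#' @return object of class \code{mc_result}: launched/absorbed/escaped/
#'   detected weights, microcirculation and artery splits of the detected
#'   weight, detected counts, \code{micro_fraction}, \code{artery_fraction},
#'   an approximate binomial standard error \code{micro_fraction_se}, and a
#'   config echo
#' @export
run_simulation <- function(model, placement, wavelength, cfg = transport_config()) {
  stopifnot(inherits(model, "finger_model"),
            inherits(placement, "ring_placement"),
            inherits(cfg, "transport_config"))
  km <- model_to_kernel(model, wavelength)
  res <- mc_transport(km$annuli, km$cylinders, km$props,
                      km$is_micro, km$is_artery,
                      model$outer_radius, model$axial_length,
                      placement$led_angle, placement$led_aperture,
                      placement$pd_angle, placement$pd_aperture,
                      placement$axial_extent,
                      cfg$n_photons, cfg$seed,
                      cfg$roulette_threshold, cfg$roulette_survival,
                      cfg$max_steps, cfg$launch == "collimated",
                      cfg$n_ambient)
  det_w <- res$detected_weight
  if (cfg$count_ratio) {
    micro_fraction <- if (res$detected_count > 0)
      res$detected_micro_count / res$detected_count else NaN
    artery_fraction <- if (res$detected_count > 0)
      res$detected_artery_count / res$detected_count else NaN
  } else {
    micro_fraction <- if (det_w > 0)
      res$detected_weight_through_microcirculation / det_w else NaN
    artery_fraction <- if (det_w > 0)
      res$detected_weight_through_artery / det_w else NaN
  }
  se <- if (res$detected_count > 1 && is.finite(micro_fraction)) {
    f <- min(max(micro_fraction, 0), 1)
    sqrt(f * (1 - f) / res$detected_count)
  } else NA_real_
  structure(c(res, list(micro_fraction = micro_fraction,
                        artery_fraction = artery_fraction,
                        micro_fraction_se = se,
                        wavelength = wavelength,
                        placement = placement, config = cfg)),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("mc_result: %d nm, LED %g deg -> PD %g deg (delta %g)\n",
              as.integer(x$wavelength), x$placement$led_angle,
              x$placement$pd_angle, x$placement$delta))
  cat(sprintf("  launched %.0f | detected %.4g (n=%d) | absorbed %.4g | escaped %.4g\n",
              x$launched_weight, x$detected_weight, as.integer(x$detected_count),
              x$absorbed_weight, x$escaped_weight))
  cat(sprintf("  micro_fraction %.4f (SE %.4f), artery_fraction %.4f\n",
              x$micro_fraction, x$micro_fraction_se, x$artery_fraction))
  invisible(x)
}
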