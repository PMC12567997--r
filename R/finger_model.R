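#' Optical properties of a tissue region
#'
#' Bundle of the four coefficients that drive photon transport in a turbid
#' medium: absorption \code{mu_a} (1/mm), scattering \code{mu_s} (1/mm),
#' Henyey-Greenstein anisotropy \code{g} (dimensionless, -1 < g < 1) and
#' refractive index \code{n} (>= 1).
#'
#' @param mu_a absorption coefficient, 1/mm
#' @param mu_s scattering coefficient, 1/mm
#' @param g scattering anisotropy (Henyey-Greenstein parameter)
#' @param n refractive index
#' @return an object of class \code{optical_properties}
#' @export
optical_properties <- function(mu_a, mu_s, g, n) {
  stopifnot(is.numeric(mu_a), is.numeric(mu_s), is.numeric(g), is.numeric(n))
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s < 0) stop("mu_s must be >= 0")
  if (g <= -1 || g >= 1) stop("g must lie strictly in (-1, 1)")
  if (n < 1) stop("refractive index must be >= 1")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, n = n),
            class = "optical_properties")
}

#' Finger tissue region
#'
#' A region is either a concentric annulus about the finger axis
#' (\code{type = "annulus"}, with inner/outer radii in mm; a disk has
#' \code{r_in = 0}) or an embedded axis-parallel cylinder
#' (\code{type = "cylinder"}, with a cross-sectional center offset and
#' radius in mm). \code{props} maps wavelength (nm, as character keys) to
#' \code{\link{optical_properties}}.
#'
#' @param label one of "epidermis", "dermis", "microcirculation", "artery",
#'   "vein", "bone"
#' @param type "annulus" or "cylinder"
#' @param r_in,r_out annulus radii (mm), for \code{type = "annulus"}
#' @param center length-2 cross-sectional center (mm), for cylinders
#' @param radius cylinder radius (mm)
#' @param props named list: wavelength (nm) -> optical_properties
#' @return an object of class \code{finger_region}
#' @export
finger_region <- function(label, type = c("annulus", "cylinder"),
                          r_in = NULL, r_out = NULL,
                          center = NULL, radius = NULL, props = list()) {
  type <- match.arg(type)
  labels <- c("epidermis", "dermis", "microcirculation", "artery", "vein", "bone")
  if (!label %in% labels)
    stop("unknown region label: ", label)
  if (type == "annulus") {
    stopifnot(is.numeric(r_in), is.numeric(r_out), r_in >= 0, r_out > r_in)
  } else {
    stopifnot(length(center) == 2, is.numeric(radius), radius > 0)
  }
  structure(list(label = label, type = type, r_in = r_in, r_out = r_out,
                 center = center, radius = radius, props = props),
            class = "finger_region")
}

#' Multilayer cylindrical finger model
#'
#' Assembles ordered regions into a simulation domain: a cylinder of
#' \code{outer_radius} (mm) and \code{axial_length} (mm) along z, with
#' absorbing end caps. Region precedence for point classification is
#' innermost-first: embedded cylinders shadow the annulus that contains
#' them. Every region must carry optical properties for every declared
#' wavelength.
#'
#' @param regions list of \code{\link{finger_region}}
#' @param outer_radius outer skin radius, mm
#' @param axial_length simulation domain length along the finger axis, mm
#' @param wavelengths numeric vector of wavelengths (nm)
#' @return object of class \code{finger_model}
#' @export
finger_model <- function(regions, outer_radius, axial_length = 20,
                         wavelengths = c(550, 628, 940)) {
  stopifnot(outer_radius > 0, axial_length > 0, length(regions) >= 1)
  ann <- Filter(function(r) r$type == "annulus", regions)
  if (length(ann) > 1) {
    ord <- order(vapply(ann, function(r) r$r_out, numeric(1)))
    ann <- ann[ord]
    for (i in seq_len(length(ann) - 1)) {
      if (ann[[i]]$r_out - ann[[i + 1]]$r_in > 1e-9)
        stop("annuli overlap: ", ann[[i]]$label, " / ", ann[[i + 1]]$label)
    }
  }
  for (reg in regions) {
    for (wl in wavelengths) {
      if (is.null(reg$props[[as.character(wl)]]))
        stop("region '", reg$label, "' has no optical properties at ",
             wl, " nm; supply a property table covering this wavelength")
    }
  }
  structure(list(regions = regions, outer_radius = outer_radius,
                 axial_length = axial_length, wavelengths = wavelengths),
            class = "finger_model")
}

#' @export
print.finger_model <- function(x, ...) {
  cat("finger_model: outer radius", x$outer_radius, "mm, axial length",
      x$axial_length, "mm\n")
  cat("wavelengths (nm):", paste(x$wavelengths, collapse = ", "), "\n")
  for (r in x$regions) {
    if (r$type == "annulus")
      cat(sprintf("  %-16s annulus %.2f-%.2f mm\n", r$label, r$r_in, r$r_out))
    else
      cat(sprintf("  %-16s cylinder r=%.2f mm at (%.2f, %.2f)\n",
                  r$label, r$radius, r$center[1], r$center[2]))
  }
  if (!is.null(attr(x, "optics_source")))
    cat("optics:", attr(x, "optics_source"), "\n")
  invisible(x)
}

#' Load the packaged default optical-property table
#'
#' Returns the per-region, per-wavelength absorption/scattering/anisotropy/
#' index table shipped with the package. These are literature defaults
#' assembled from standard skin-optics compendium values at 550, 628 and
#' 940 nm; they are placeholders intended to be replaced with a
#' measurement-specific table via \code{\link{read_finger_config}} when
#' quantitative agreement with a particular study is required.
#'
#' @return nested list: region label -> wavelength (nm, character) ->
#'   \code{optical_properties}; carries attribute \code{source =
#'   "literature defaults"}
#' @export
default_optics_table <- function() {
  path <- system.file("extdata", "default_optics.json", package = "ringppg")
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw$optics, function(wls) {
    lapply(wls, function(p)
      optical_properties(p$mu_a, p$mu_s, p$g, p$n))
  })
  attr(out, "source") <- raw$source
  out
}

#' Build the default finger model
#'
#' Default geometry: 19.2 mm total finger diameter with a 0.6 mm epidermis
#' (annulus 9.0-9.6 mm), a 1 mm dermis (8.0-9.0 mm) and a 16 mm diameter
#' microcirculation disk (radius 8.0 mm). Inside the microcirculation sit
#' four blood vessels of radius 0.6 mm -- two volar arteries at +/-30 deg
#' from the volar midline (0 deg) and two dorsal veins at +/-30 deg from the
#' dorsal midline (180 deg), each centered at 6.5 mm from the axis -- and a
#' central bone cylinder of radius 3 mm. Vessel and bone placement are
#' anatomical assumptions (digital arteries run along the sides of the
#' finger); all positions and radii can be overridden via a config file.
#'
#' Optical properties come from the packaged literature-defaults table
#' unless \code{optics} is supplied.
#'
#' @param wavelengths nm; must be covered by the optics table (the packaged
#'   table covers 550, 628, 940)
#' @param optics optional optics table in the format of
#'   \code{\link{default_optics_table}}
#' @param axial_length simulation domain length (mm)
#' @return a \code{\link{finger_model}}; attribute \code{optics_source}
#'   records the provenance of the property table
#' @export
build_default_finger <- function(wavelengths = c(550, 628, 940),
                                 optics = NULL, axial_length = 20) {
  if (is.null(optics)) optics <- default_optics_table()
  for (wl in wavelengths) {
    cov <- vapply(optics, function(o) !is.null(o[[as.character(wl)]]), logical(1))
    if (!all(cov))
      stop("no optical properties at ", wl,
           " nm for region(s): ", paste(names(optics)[!cov], collapse = ", "),
           "; supply a property table covering this wavelength")
  }
  pick <- function(lbl) optics[[lbl]][as.character(wavelengths)]
  vessel_r <- 0.6
  vessel_c <- 6.5
  ang <- function(a) vessel_c * c(cos(a * pi / 180), sin(a * pi / 180))
  regions <- list(
    finger_region("epidermis", "annulus", r_in = 9.0, r_out = 9.6,
                  props = pick("epidermis")),
    finger_region("dermis", "annulus", r_in = 8.0, r_out = 9.0,
                  props = pick("dermis")),
    finger_region("microcirculation", "annulus", r_in = 0, r_out = 8.0,
                  props = pick("microcirculation")),
    finger_region("artery", "cylinder", center = ang(30), radius = vessel_r,
                  props = pick("vessel")),
    finger_region("artery", "cylinder", center = ang(-30), radius = vessel_r,
                  props = pick("vessel")),
    finger_region("vein", "cylinder", center = ang(150), radius = vessel_r,
                  props = pick("vessel")),
    finger_region("vein", "cylinder", center = ang(210), radius = vessel_r,
                  props = pick("vessel")),
    finger_region("bone", "cylinder", center = c(0, 0), radius = 3,
                  props = pick("bone"))
  )
  m <- finger_model(regions, outer_radius = 9.6, axial_length = axial_length,
                    wavelengths = wavelengths)
  attr(m, "optics_source") <- attr(optics, "source", exact = TRUE)
  if (is.null(attr(m, "optics_source"))) attr(m, "optics_source") <- "user supplied"
  m
}

#' Read a finger model from a JSON config file
#'
#' The config carries \code{regions} (label, geometry) and \code{optics}
#' (per label, per wavelength: mu_a, mu_s, g, n). Regions reference optics
#' entries by their \code{optics} key (so several regions can share one
#' property set, e.g. arteries and veins sharing "vessel").
#'
#' @param path JSON file path
#' @param wavelengths wavelengths (nm) the model must cover
#' @return a \code{\link{finger_model}}
#' @export
read_finger_config <- function(path, wavelengths = c(550, 628, 940)) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  optics <- lapply(cfg$optics, function(wls)
    lapply(wls, function(p) optical_properties(p$mu_a, p$mu_s, p$g, p$n)))
  regions <- lapply(cfg$regions, function(r) {
    key <- if (!is.null(r$optics)) r$optics else r$label
    props <- optics[[key]][as.character(wavelengths)]
    if (identical(r$type, "annulus"))
      finger_region(r$label, "annulus", r_in = r$r_in, r_out = r$r_out,
                    props = props)
    else
      finger_region(r$label, "cylinder", center = unlist(r$center),
                    radius = r$radius, props = props)
  })
  m <- finger_model(regions, outer_radius = cfg$outer_radius,
                    axial_length = if (!is.null(cfg$axial_length))
                      cfg$axial_length else 20,
                    wavelengths = wavelengths)
  attr(m, "optics_source") <- if (!is.null(cfg$source)) cfg$source else path
  m
}

#' Classify points by finger region
#'
#' Returns the innermost region containing each point (embedded vessels and
#' bone shadow the microcirculation disk; annuli are checked inner to
#' outer). Points with radial distance beyond the outer radius, or outside
#' the axial extent, are "ambient".
#'
#' @param model a \code{\link{finger_model}}
#' @param points numeric matrix n x 3 (x, y, z in mm) or length-3 vector
#' @return character vector of region labels
#' @export
locate_region <- function(model, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  cyl <- Filter(function(r) r$type == "cylinder", model$regions)
  ann <- Filter(function(r) r$type == "annulus", model$regions)
  ann <- ann[order(vapply(ann, function(r) r$r_out, numeric(1)))]
  r2 <- points[, 1]^2 + points[, 2]^2
  out <- rep("ambient", nrow(points))
  inside <- r2 <= model$outer_radius^2 &
    points[, 3] >= 0 & points[, 3] <= model$axial_length
  for (i in which(inside)) {
    lab <- NA_character_
    for (cc in cyl) {
      dx <- points[i, 1] - cc$center[1]
      dy <- points[i, 2] - cc$center[2]
      if (dx * dx + dy * dy < cc$radius^2) { lab <- cc$label; break }
    }
    if (is.na(lab)) {
      ri <- sqrt(r2[i])
      for (aa in ann) {
        if (ri >= aa$r_in && (ri < aa$r_out ||
            (abs(aa$r_out - model$outer_radius) < 1e-12 && ri <= aa$r_out))) {
          lab <- aa$label; break
        }
      }
    }
    if (!is.na(lab)) out[i] <- lab
  }
  out
}

#' Cross-sectional areas of the model's annular regions
#'
#' Analytic pi*(r_out^2 - r_in^2) areas (mm^2), named by region label.
#' Embedded cylinders report pi*r^2. Useful for geometry sanity checks.
#'
#' @param model a \code{\link{finger_model}}
#' @return named numeric vector of areas (mm^2)
#' @export
region_areas <- function(model) {
  vapply(model$regions, function(r) {
    if (r$type == "annulus") pi * (r$r_out^2 - r$r_in^2) else pi * r$radius^2
  }, numeric(1)) -> a
  names(a) <- vapply(model$regions, function(r) r$label, character(1))
  a
}

#' LED / photodiode placement on the ring surface
#'
#' Angles are degrees on the outer circumference, measured counter-clockwise
#' in the cross-sectional plane with 0 at the volar midline, taken modulo
#' 360. The LED-PD angle is \code{(pd_angle - led_angle) mod 360}. Apertures
#' are the angular widths of the emitting/detecting patches; both patches
#' are flush on the outer epidermis boundary and span \code{axial_extent}
#' mm along the finger axis.
#'
#' @param led_angle,pd_angle degrees
#' @param led_aperture,pd_aperture angular patch widths, degrees
#' @param axial_extent axial patch extent, mm
#' @return object of class \code{ring_placement}
#' @export
ring_placement <- function(led_angle, pd_angle, led_aperture = 10,
                           pd_aperture = 10, axial_extent = 2) {
  structure(list(led_angle = led_angle %% 360, pd_angle = pd_angle %% 360,
                 led_aperture = led_aperture, pd_aperture = pd_aperture,
                 axial_extent = axial_extent,
                 delta = (pd_angle - led_angle) %% 360),
            class = "ring_placement")
}

#' Enumerate all LED-PD placements on an angular grid
#'
#' All (led_angle, pd_angle) pairs on a grid of step \code{grid_step}
#' degrees: (360/grid_step)^2 placements, e.g. 144 for the 30-degree design
#' grid (12 LED-PD angles x 12 ring positions per angle).
#'
#' @param grid_step grid resolution in degrees; must divide 360
#' @param ... passed to \code{\link{ring_placement}} (apertures, axial extent)
#' @return list of \code{ring_placement}
#' @export
enumerate_layouts <- function(grid_step = 30, ...) {
  if (!is.numeric(grid_step) || grid_step <= 0)
    stop("grid_step must be positive")
  if (360 %% grid_step != 0)
    stop("grid_step must divide 360")
  angles <- seq(0, 360 - grid_step, by = grid_step)
  out <- vector("list", length(angles)^2)
  k <- 1
  for (led in angles) for (pd in angles) {
    out[[k]] <- ring_placement(led, pd, ...)
    k <- k + 1
  }
  out
}
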