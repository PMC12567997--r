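#' Sweep all LED-PD placements on an angular grid
#'
#' Runs one transport simulation per (led_angle, pd_angle) cell and collects
#' the microcirculation traversal fraction into a square grid (rows = LED
#' angle, columns = PD angle). Cells where no light reaches the detector are
#' NaN. Each cell uses an independent derived seed
#' (\code{base_seed * 1000 + cell_index}), so the sweep is deterministic and
#' restartable cell by cell.
#'
#' @param model a \code{\link{finger_model}}
#' @param wavelength nm
#' @param cfg a \code{\link{transport_config}}; \code{cfg$seed} is the base
#'   seed of the per-cell schedule
#' @param grid_step angular resolution in degrees (must divide 360); the
#'   design-study resolution is 30 (12 x 12 combinations)
#' @param ... passed to \code{\link{ring_placement}}
#' @return object of class \code{sweep_table}: \code{fractions} matrix with
#'   angle dimnames, matching \code{detected_counts} matrix, wavelength,
#'   grid step and base seed
#' @export
sweep_layouts <- function(model, wavelength, cfg = transport_config(),
                          grid_step = 30, ...) {
  if (360 %% grid_step != 0) stop("grid_step must divide 360")
  angles <- seq(0, 360 - grid_step, by = grid_step)
  n <- length(angles)
  fr <- matrix(NaN, n, n, dimnames = list(led = angles, pd = angles))
  dc <- matrix(0, n, n, dimnames = list(led = angles, pd = angles))
  cell <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ccfg <- cfg
      ccfg$seed <- cfg$seed * 1000 + cell
      pl <- ring_placement(angles[i], angles[j], ...)
      r <- run_simulation(model, pl, wavelength, ccfg)
      fr[i, j] <- r$micro_fraction
      dc[i, j] <- r$detected_count
      cell <- cell + 1L
    }
  }
  structure(list(fractions = fr, detected_counts = dc,
                 wavelength = wavelength, grid_step = grid_step,
                 n_photons = cfg$n_photons, seed = cfg$seed),
            class = "sweep_table")
}

#' @export
print.sweep_table <- function(x, ...) {
  cat(sprintf("sweep_table: %g nm, %g deg grid, %d photons/cell, seed %g\n",
              x$wavelength, x$grid_step, x$n_photons, x$seed))
  print(round(x$fractions, 3))
  invisible(x)
}

#' Aggregate a sweep by LED-PD angle
#'
#' Ring rotation maps a fixed LED-PD angle onto different absolute
#' positions, so layout robustness is judged per angle: all cells sharing
#' the same \code{delta = (pd - led) mod 360} are pooled and the mean and
#' standard deviation of their traversal fractions computed over non-NaN
#' positions. An angle whose positions are all NaN aggregates to NaN.
#'
#' @param table a \code{\link{sweep_layouts}} result, or a bare numeric
#'   matrix with angle dimnames (rows = LED, cols = PD)
#' @return data.frame with columns \code{delta}, \code{mean_fraction},
#'   \code{dispersion} (SD over positions), \code{n_valid}
#' @export
aggregate_by_angle <- function(table) {
  fr <- if (inherits(table, "sweep_table")) table$fractions else table
  led <- as.numeric(rownames(fr))
  pd <- as.numeric(colnames(fr))
  deltas <- sort(unique(as.vector(outer(led, pd, function(l, p) (p - l) %% 360))))
  out <- data.frame(delta = deltas, mean_fraction = NaN,
                    dispersion = NaN, n_valid = 0L)
  for (k in seq_along(deltas)) {
    vals <- c()
    for (i in seq_along(led)) for (j in seq_along(pd)) {
      if ((pd[j] - led[i]) %% 360 == deltas[k]) vals <- c(vals, fr[i, j])
    }
    ok <- vals[!is.na(vals)]
    out$n_valid[k] <- length(ok)
    if (length(ok) > 0) {
      out$mean_fraction[k] <- mean(ok)
      out$dispersion[k] <- if (length(ok) > 1) stats::sd(ok) else 0
    }
  }
  out
}

#' Rank LED-PD angles by microcirculation traversal
#'
#' Orders angles by mean traversal fraction (descending); ties break toward
#' lower dispersion across ring positions, then toward the smaller angle.
#' Angles with no detectable layout (all-NaN) are dropped; if none remain,
#' an error is raised.
#'
#' @param aggregates data.frame from \code{\link{aggregate_by_angle}}
#' @return the input rows reordered best-first
#' @export
rank_angles <- function(aggregates) {
  ok <- aggregates[!is.na(aggregates$mean_fraction), , drop = FALSE]
  if (nrow(ok) == 0) stop("no detectable layouts: all angles are NaN")
  ord <- order(-ok$mean_fraction, ok$dispersion, ok$delta)
  ok[ord, , drop = FALSE]
}

#' Published reference table of angle-aggregated traversal fractions
#'
#' The bundled reference simulation summary: mean microcirculation-traversal
#' proportion of detected photons at each LED-PD angle (30-degree grid) for
#' 550, 628 and 940 nm, as reported in the ring-PPG simulation literature
#' for a 5e7-photon run on an anatomical finger model. NaN marks angles
#' where no photons reached the detector (green light at 150-210 degrees).
#' Used as a validation fixture for the ranking machinery; reproducing these
#' absolute values requires the original study's (unpublished) tissue
#' optical-coefficient table.
#'
#' @return data.frame: \code{wavelength_nm}, then one column per angle
#'   (\code{deg_0} ... \code{deg_330})
#' @export
reference_angle_table <- function() {
  path <- system.file("extdata", "angle_reference.csv", package = "ringppg")
  utils::read.csv(path, check.names = FALSE)
}

#' Reference table rows as angle aggregates
#'
#' Reshapes one wavelength row of \code{\link{reference_angle_table}} into
#' the \code{\link{aggregate_by_angle}} format so it can be ranked.
#'
#' @param wavelength 550, 628 or 940
#' @return data.frame with \code{delta} and \code{mean_fraction} columns
#'   (\code{dispersion} NA, \code{n_valid} NA: the reference reports means only)
#' @export
reference_aggregates <- function(wavelength) {
  tab <- reference_angle_table()
  row <- tab[tab$wavelength_nm == wavelength, , drop = FALSE]
  if (nrow(row) != 1) stop("no reference row for ", wavelength, " nm")
  vals <- as.numeric(row[, -1])
  deltas <- as.numeric(sub("^deg_", "", colnames(tab)[-1]))
  data.frame(delta = deltas, mean_fraction = vals,
             dispersion = NA_real_, n_valid = NA_integer_)
}
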