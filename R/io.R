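#' Read PPG channels from a CSV signal file
#'
#' Expects a header row; the first column is either time in seconds or a
#' sample index, and every remaining column is one PPG channel. The
#' sampling rate is inferred from the time column (median spacing) when it
#' looks like time; an explicit \code{fs} always wins for an index column
#' and is cross-checked against an inferred rate (mismatch above 1 percent
#' is an error).
#'
#' @param path CSV file
#' @param fs sampling rate, Hz; required when the first column is a bare
#'   sample index
#' @return list of \code{\link{ppg_record}}, one per channel
#' @export
read_signal_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("need a time/index column plus at least one channel")
  for (j in seq_len(ncol(df))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[j]]))))
    if (length(bad) > 0)
      stop("non-numeric value in column '", colnames(df)[j],
           "', row ", bad[1])
    df[[j]] <- as.numeric(df[[j]])
  }
  tcol <- df[[1]]
  dt <- diff(tcol)
  if (any(dt <= 0)) stop("non-monotonic time/index column at row ",
                         which(dt <= 0)[1] + 1)
  # a unit-spaced integer column is a sample index, anything else is time
  is_index <- all(abs(dt - 1) < 1e-9) && all(abs(tcol - round(tcol)) < 1e-9)
  if (is_index) {
    if (is.null(fs))
      stop("first column is a sample index; supply fs")
    fs_use <- fs
  } else {
    fs_inferred <- 1 / stats::median(dt)
    if (!is.null(fs)) {
      if (abs(fs_inferred - fs) / fs > 0.01)
        stop(sprintf("inferred rate %.4g Hz disagrees with fs = %g Hz by more than 1%%",
                     fs_inferred, fs))
      fs_use <- fs
    } else {
      fs_use <- fs_inferred
    }
  }
  chans <- colnames(df)[-1]
  lapply(seq_along(chans), function(k)
    ppg_record(df[[k + 1]], fs_use, channel = chans[k]))
}

#' Write a PPG record (plus optional extra channels) to CSV
#'
#' Writes a time column (seconds) followed by one column per channel.
#' Round-trips through \code{\link{read_signal_csv}}.
#'
#' @param records a \code{\link{ppg_record}} or list of records sharing fs
#' @param path output CSV path
#' @export
write_signal_csv <- function(records, path) {
  if (inherits(records, "ppg_record")) records <- list(records)
  fs <- records[[1]]$fs
  n <- length(records[[1]]$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / fs)
  for (r in records) {
    stopifnot(identical(r$fs, fs), length(r$samples) == n)
    df[[r$channel]] <- r$samples
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis result to disk
#'
#' Grid-like results (sweep tables) go to CSV; everything else is
#' serialized as JSON with a config/seed echo for provenance. Dispatch is
#' by class.
#'
#' @param result object to write
#' @param path output path
#' @param ... unused
#' @return \code{path}, invisibly
#' @export
write_report <- function(result, path, ...) UseMethod("write_report")

#' @export
write_report.sweep_table <- function(result, path, ...) {
  fr <- result$fractions
  df <- data.frame(led_angle = as.numeric(rownames(fr)), fr,
                   check.names = FALSE)
  colnames(df) <- c("led_angle", paste0("pd_", colnames(fr)))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(wavelength = result$wavelength, grid_step = result$grid_step,
               n_photons = result$n_photons, seed = result$seed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
write_report.mc_result <- function(result, path, ...) {
  out <- result[c("launched_weight", "absorbed_weight", "escaped_weight",
                  "detected_weight",
                  "detected_weight_through_microcirculation",
                  "detected_weight_through_artery", "detected_count",
                  "micro_fraction", "artery_fraction", "wavelength")]
  out$placement <- unclass(result$placement)
  out$config <- unclass(result$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @export
write_report.data.frame <- function(result, path, ...) {
  utils::write.csv(result, path, row.names = FALSE)
  invisible(path)
}

#' @export
write_report.default <- function(result, path, ...) {
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}

#' Read back a sweep table written by \code{write_report}
#'
#' @param path CSV path previously written for a \code{sweep_table}
#' @return numeric matrix with angle dimnames (rows = LED, cols = PD)
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$led_angle
  colnames(m) <- sub("^pd_", "", colnames(m))
  names(dimnames(m)) <- c("led", "pd")
  m
}
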