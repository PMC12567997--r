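#' LED duty cycle
#'
#' Fraction of time one LED is ON: \code{led_on_us * 1e-6 * fire_rate_hz}.
#' A 70 us ON time fired at the 100 Hz system sampling rate gives 0.007
#' (0.7 percent).
#'
#' @param led_on_us LED ON time per firing, microseconds
#' @param fire_rate_hz per-LED firings per second
#' @return duty cycle as a fraction
#' @export
duty_cycle <- function(led_on_us, fire_rate_hz) {
  stopifnot(led_on_us >= 0, fire_rate_hz >= 0)
  led_on_us * 1e-6 * fire_rate_hz
}

#' LED ON-time budget
#'
#' The LED must stay ON long enough to cover the ADC sampling window, the
#' transimpedance-amplifier settling minimum, the LED+PD setup delay and a
#' damping margin; the ON time is their sum. The reference design uses
#' 30 + 20 + 10 + 10 = 70 us.
#'
#' @param t_samp_us ADC sampling window, us
#' @param t_tiasu_us TIA settling minimum, us
#' @param t_ledsu_pdsu_us combined LED + PD setup allowance, us
#' @param margin_us ON/OFF damping margin, us
#' @return LED ON time, us
#' @export
led_on_budget <- function(t_samp_us, t_tiasu_us, t_ledsu_pdsu_us, margin_us) {
  stopifnot(t_samp_us >= 0, t_tiasu_us >= 0, t_ledsu_pdsu_us >= 0,
            margin_us >= 0)
  t_samp_us + t_tiasu_us + t_ledsu_pdsu_us + margin_us
}

#' Minimum TIA settling time
#'
#' Settling requirement as a multiple of the feedback time constant
#' \code{r_f * c_f}: an 8x multiple of the 1 MOhm x 2.5 pF = 2.5 us
#' constant gives the reference 20 us minimum.
#'
#' @param r_f feedback resistance, Ohm
#' @param c_f feedback capacitance, F
#' @param multiple settling multiple of the time constant
#' @return settling time, seconds
#' @export
tia_settling_min <- function(r_f, c_f, multiple = 8) {
  stopifnot(r_f > 0, c_f > 0, multiple > 0)
  multiple * r_f * c_f
}

#' TIA frequency-compensation capacitance
#'
#' Two evaluation modes for the compensation capacitor that keeps the
#' transimpedance amplifier stable without overcompensation:
#' \itemize{
#'   \item \code{"stability"} (default): \code{sqrt(Ci / (2 pi RF UGB))},
#'     the dimensionally consistent standard pole-matching form; for
#'     Ci = 20 pF, UGB = 1 MHz it gives about 1.78 pF at RF = 1 MOhm and
#'     about 17.8 pF at RF = 10 kOhm, bracketing the practical 2.5-20 pF
#'     adjustment range.
#'   \item \code{"literal"}: \code{Ci / (2 pi RF UGB)} exactly as sometimes
#'     quoted; this expression has units of seconds-squared-per-ohm rather
#'     than farads and yields ~3.2e-24 at the same operating point. It is
#'     provided for fidelity and flagged with a message; no silent
#'     correction is made.
#' }
#'
#' @param c_i total TIA input capacitance, F
#' @param r_f feedback resistance, Ohm
#' @param ugb amplifier unity-gain bandwidth, Hz
#' @param mode "stability" or "literal"
#' @param quiet suppress the mode message
#' @return compensation capacitance, F (in "literal" mode the raw quotient)
#' @export
tia_comp_cap <- function(c_i, r_f, ugb, mode = c("stability", "literal"),
                         quiet = FALSE) {
  mode <- match.arg(mode)
  stopifnot(c_i > 0, r_f > 0, ugb > 0)
  q <- c_i / (2 * pi * r_f * ugb)
  if (mode == "literal") {
    if (!quiet)
      message("tia_comp_cap: literal quotient Ci/(2*pi*RF*UGB) is not ",
              "dimensionally a capacitance; see mode = \"stability\"")
    return(q)
  }
  if (!quiet)
    message("tia_comp_cap: using stability form sqrt(Ci/(2*pi*RF*UGB))")
  sqrt(q)
}

#' Effective signal-chain bandwidth
#'
#' \code{f_rc * f_sp_adc * t_samp}: the low-pass corner times the ADC
#' sample rate times the sampling window. The reference design pairs a
#' 100 Hz corner with the 2.5 kHz ADC rate and a 30 us window for 7.5 Hz --
#' a 25 percent margin above the 6 Hz needed to avoid non-linear phase
#' distortion of the pulse waveform.
#'
#' @param f_rc low-pass corner frequency, Hz
#' @param f_sp_adc ADC sample frequency, Hz (distinct from the 100 Hz
#'   system output rate)
#' @param t_samp_s ADC sampling window, seconds
#' @return effective bandwidth, Hz
#' @export
effective_bandwidth <- function(f_rc, f_sp_adc, t_samp_s) {
  stopifnot(f_rc >= 0, f_sp_adc >= 0, t_samp_s >= 0)
  f_rc * f_sp_adc * t_samp_s
}

#' Module current budget and battery life
#'
#' Sums named module currents (uA) and converts a battery capacity (mAh)
#' into a continuous-acquisition lifetime: \code{battery_mah / (total_uA /
#' 1000)} hours.
#'
#' @param modules named numeric vector of module currents, uA
#' @param battery_mah battery capacity, mAh
#' @return object of class \code{current_budget}: \code{modules},
#'   \code{total_ua}, \code{total_ma}, \code{battery_mah}, \code{lifetime_h}
#' @export
current_budget <- function(modules, battery_mah = 22) {
  stopifnot(is.numeric(modules), all(modules >= 0), battery_mah > 0)
  total <- sum(modules)
  structure(list(modules = modules, total_ua = total,
                 total_ma = total / 1000, battery_mah = battery_mah,
                 lifetime_h = battery_mah / (total / 1000)),
            class = "current_budget")
}

#' @export
print.current_budget <- function(x, ...) {
  cat("current_budget:\n")
  for (nm in names(x$modules))
    cat(sprintf("  %-24s %8.1f uA\n", nm, x$modules[[nm]]))
  cat(sprintf("  %-24s %8.1f uA (%.4g mA)\n", "total", x$total_ua, x$total_ma))
  cat(sprintf("  battery %g mAh -> lifetime %.1f h\n",
              x$battery_mah, x$lifetime_h))
  invisible(x)
}

#' Reference smart-ring module currents
#'
#' The packaged reference current budget of the ring design: wireless
#' transmission, 4-channel PPG readout at 100 Hz, LED drive averaged over
#' the duty-cycled firing scheme, 3-axis accelerometer at 25 Hz, 4-channel
#' temperature sensing, and miscellaneous. The LED average is an empirical
#' input (it is not the bare product of duty cycle and drive current, which
#' underestimates the effective ON window).
#'
#' @return named numeric vector, uA
#' @export
default_current_modules <- function() {
  c(wireless_transmission = 201, ppg_readout_4ch = 157, led_drive = 179,
    accelerometer_3axis = 21, temperature_4ch = 1.5, others = 35)
}

#' Reference analog front-end timing budget
#'
#' The packaged reference timings: 30 us ADC sampling window, 20 us TIA
#' settling (8x the 1 MOhm x 2.5 pF time constant), under 10 us combined
#' LED/PD setup, 10 us damping margin -> 70 us LED ON at a 100 Hz per-LED
#' firing rate (0.7 percent duty cycle); 2.5 kHz ADC sample rate and a
#' 100 Hz low-pass corner giving a 7.5 Hz effective bandwidth.
#'
#' @return object of class \code{timing_budget}
#' @export
default_timing_budget <- function() {
  t_samp <- 30; t_tiasu <- 20; t_setup <- 10; margin <- 10
  led_on <- led_on_budget(t_samp, t_tiasu, t_setup, margin)
  structure(list(
    t_samp_us = t_samp, t_tiasu_us = t_tiasu, t_ledsu_pdsu_us = t_setup,
    margin_us = margin, led_on_us = led_on, fire_rate_hz = 100,
    duty_cycle = duty_cycle(led_on, 100),
    f_rc_hz = 100, f_sp_adc_hz = 2500, f_sp_sys_hz = 100,
    f_sig_eff_hz = effective_bandwidth(100, 2500, t_samp * 1e-6)),
    class = "timing_budget")
}

#' @export
print.timing_budget <- function(x, ...) {
  cat(sprintf(
    "timing_budget: LED ON %g us (= %g + %g + %g + %g), duty %.3g%% @ %g Hz\n",
    x$led_on_us, x$t_samp_us, x$t_tiasu_us, x$t_ledsu_pdsu_us, x$margin_us,
    100 * x$duty_cycle, x$fire_rate_hz))
  cat(sprintf("  fSIGEFF %.3g Hz = fRC %g Hz x fSP(ADC) %g Hz x TSAMP %g us\n",
              x$f_sig_eff_hz, x$f_rc_hz, x$f_sp_adc_hz, x$t_samp_us))
  invisible(x)
}
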