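#' Strain-gauge Wheatstone bridge specification
#'
#' Electrical model of a single strain-gauge load cell: four gauges of
#' nominal resistance `R` wired in a Wheatstone bridge and excited with
#' `V_in`. Deformation of the cell body changes each gauge's resistance by
#' `delta_r[i]`; the bridge converts these changes into a differential
#' output voltage.
#'
#' @param nominal_resistance Nominal gauge resistance R in ohms (> 0).
#' @param delta_r Numeric vector of four resistance changes in ohms,
#'   one per gauge.
#' @param excitation Excitation voltage V_in in volts (> 0).
#'
#' @return An object of class `bridge_spec`.
#' @details A warning is issued when any `|delta_r|/R` exceeds 0.05, i.e.
#'   outside the small-deformation regime where the linear approximation
#'   holds; `|delta_r| >= R` is an error.
#' @examples
#' bridge_spec(350, c(-0.35, 0.35, 0.35, -0.35), 5)
#' @export
bridge_spec <- function(nominal_resistance, delta_r = rep(0, 4), excitation = 5) {
  if (!is.numeric(nominal_resistance) || length(nominal_resistance) != 1L ||
      !is.finite(nominal_resistance) || nominal_resistance <= 0) {
    stop("`nominal_resistance` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(excitation) || length(excitation) != 1L ||
      !is.finite(excitation) || excitation <= 0) {
    stop("`excitation` must be a single positive number", call. = FALSE)
  }
  delta_r <- as.numeric(delta_r)
  if (length(delta_r) != 4L || any(!is.finite(delta_r))) {
    stop("`delta_r` must be four finite resistance changes", call. = FALSE)
  }
  if (any(abs(delta_r) >= nominal_resistance)) {
    stop("|delta_r| must be smaller than the nominal resistance", call. = FALSE)
  }
  if (any(abs(delta_r) / nominal_resistance > 0.05)) {
    warning("|delta_r|/R > 0.05: outside the small-deformation regime",
            call. = FALSE)
  }
  structure(
    list(nominal_resistance = nominal_resistance,
         delta_r = delta_r,
         excitation = excitation),
    class = "bridge_spec"
  )
}

#' @export
print.bridge_spec <- function(x, ...) {
  cat(sprintf("<bridge_spec> R = %g ohm, V_in = %g V\n",
              x$nominal_resistance, x$excitation))
  cat(sprintf("  delta_r = [%s] ohm\n", paste(format(x$delta_r), collapse = ", ")))
  invisible(x)
}

#' Exact Wheatstone bridge output voltage
#'
#' Full quotient form of the bridge equation:
#' \deqn{V_{out} = \left(\frac{R+\Delta R_2}{(R+\Delta R_1)+(R+\Delta R_2)} -
#'   \frac{R+\Delta R_4}{(R+\Delta R_3)+(R+\Delta R_4)}\right) V_{in}.}
#' A balanced bridge (all `delta_r` zero) outputs exactly 0 V.
#'
#' @param spec A [bridge_spec()].
#' @return Output voltage in volts.
#' @examples
#' bridge_output_exact(bridge_spec(350, c(-0.35, 0.35, 0.35, -0.35), 5)) # 5 mV
#' @seealso [bridge_output_linear()] for the small-signal approximation.
#' @export
bridge_output_exact <- function(spec) {
  stopifnot(inherits(spec, "bridge_spec"))
  R <- spec$nominal_resistance
  d <- spec$delta_r
  v <- (R + d[2]) / ((R + d[1]) + (R + d[2])) -
       (R + d[4]) / ((R + d[3]) + (R + d[4]))
  v * spec$excitation
}

#' Linearised Wheatstone bridge output voltage
#'
#' Small-signal approximation valid for a symmetric gauge configuration
#' (`delta_r[2] == delta_r[3] == dR`, `delta_r[1] == delta_r[4] == -dR`):
#' \eqn{V_{out} \approx (\Delta R / R)\, V_{in}}. For symmetric specs both
#' half-bridge denominators equal 2R, so this equals the exact quotient
#' form to machine precision.
#'
#' @param spec A [bridge_spec()]. `dR` is taken from `delta_r[2]`.
#' @return Output voltage in volts.
#' @export
bridge_output_linear <- function(spec) {
  stopifnot(inherits(spec, "bridge_spec"))
  spec$delta_r[2] / spec$nominal_resistance * spec$excitation
}
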