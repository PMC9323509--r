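# Pointwise reaction kinetics. These are the scalar forms of the source/sink
# terms used by the finite-volume solver; exposed for testing and for
# inspecting the local metabolic state. All vectorised over c, s, n.

.check_nonneg <- function(...) {
  args <- list(...)
  for (nm in names(args))
    if (any(args[[nm]] < 0, na.rm = TRUE))
      stop("negative ", nm, " supplied to a kinetic rate")
}

#' Volumetric oxygen consumption rate
#'
#' Michaelis-Menten oxygen uptake by the viable cell population:
#' `M_c * n * c / (c + c_half)`.
#'
#' @param c oxygen concentration, kg/m3
#' @param n viable cell density, cell/m3
#' @param p a [parameter_set()]
#' @return consumption rate, kg m-3 s-1 (nonnegative)
#' @export
oxygen_sink <- function(c, n, p) {
  .check_nonneg(oxygen = c, `cell density` = n)
  p[["M_c"]] * n * c / (c + p[["c_half"]])
}

#' Volumetric glucose consumption rate
#'
#' Michaelis-Menten glucose uptake with a multiplicative anaerobic enhancement
#' that rises from 1 (oxygen-replete) to `1 + A` (anoxic) on the oxygen
#' half-saturation scale:
#' `M_s * n * s/(s + s_half) * (1 + A * c_half/(c + c_half))`.
#'
#' @param c oxygen concentration, kg/m3
#' @param s glucose concentration, kg/m3
#' @inheritParams oxygen_sink
#' @return consumption rate, kg m-3 s-1 (nonnegative)
#' @export
glucose_sink <- function(c, s, n, p) {
  .check_nonneg(oxygen = c, glucose = s, `cell density` = n)
  p[["M_s"]] * n * s / (s + p[["s_half"]]) *
    (1 + p[["A"]] * p[["c_half"]] / (c + p[["c_half"]]))
}

#' Volumetric VEGF secretion rate
#'
#' Per-cell secretion with an oxygen-proportional baseline term and a
#' hypoxia-gated term, saturated in cell density by the crowding factor:
#' `n * (alpha*c + beta*exp(-c/c_tau)) / (1 + n/n_tau)`.
#'
#' @inheritParams oxygen_sink
#' @return secretion rate, kg m-3 s-1 (nonnegative; zero iff `n == 0`)
#' @export
vegf_source <- function(c, n, p) {
  .check_nonneg(oxygen = c, `cell density` = n)
  n * (p[["alpha"]] * c + p[["beta"]] * exp(-c / p[["c_tau"]])) /
    (1 + n / p[["n_tau"]])
}

#' Viable cell density rate of change
#'
#' Death-only dynamics: a baseline rate plus hypoxic and glucose-deprivation
#' components that each switch on below the corresponding half-saturation
#' scale: `-n * (delta_0 + delta_c*c_half/(c+c_half) + delta_s*s_half/(s+s_half))`.
#'
#' @inheritParams glucose_sink
#' @return rate of change of viable density, cell m-3 s-1 (nonpositive)
#' @export
death_rate <- function(c, s, n, p) {
  .check_nonneg(oxygen = c, glucose = s, `cell density` = n)
  -n * (p[["delta_0"]] +
          p[["delta_c"]] * p[["c_half"]] / (c + p[["c_half"]]) +
          p[["delta_s"]] * p[["s_half"]] / (s + p[["s_half"]]))
}
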