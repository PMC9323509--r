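# The 19 free constants of the cell-solute model, in modeling units
# (kg/m3, cell/m3, m, s). n_max is carried as metadata only: with the
# proliferation rate fixed at zero it enters no governing equation.

.free_params <- c(
  "D_c_gel", "D_c_med", "M_c", "c_half",
  "D_s_gel", "D_s_med", "M_s", "s_half", "A",
  "D_v_gel", "D_v_med", "K_v", "alpha", "beta", "c_tau", "n_tau",
  "delta_0", "delta_c", "delta_s"
)

#' Construct a parameter set for the cell-solute model
#'
#' Bundles the 19 free constants of the reaction-diffusion model (diffusivities
#' in gel and medium for oxygen, glucose and VEGF; Michaelis-Menten consumption
#' constants; anaerobic enhancement; VEGF secretion, gating, crowding and
#' degradation constants; and the three death-rate constants) together with the
#' maximal cell density `n_max`, which is metadata only. All values are in
#' modeling units: kg/m3 for solute concentrations, cell/m3 for densities,
#' m2/s for diffusivities, 1/s for rates.
#'
#' @param ... named numeric values for all 19 free constants
#' @param n_max maximal cell density, cell/m3 (metadata; not in the dynamics)
#' @return a named numeric vector of class `"parameter_set"`
#' @seealso [default_parameters()], [parameter_bounds()], [validate_parameters()]
#' @export
parameter_set <- function(..., n_max = 6.0e13) {
  vals <- c(...)
  missing <- setdiff(.free_params, names(vals))
  if (length(missing)) stop("missing parameters: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(vals), .free_params)
  if (length(extra)) stop("unknown parameters: ", paste(extra, collapse = ", "))
  vals <- vals[.free_params]
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all parameters must be finite and nonnegative")
  pos <- c("D_c_gel", "D_c_med", "c_half", "D_s_gel", "D_s_med", "s_half",
           "D_v_gel", "D_v_med", "c_tau", "n_tau")
  if (any(vals[pos] <= 0))
    stop("diffusivities, half-saturations and gating constants must be strictly positive")
  structure(vals, n_max = n_max, class = "parameter_set")
}

#' Names of the free model constants
#'
#' @return character vector of length 19, in canonical order
#' @export
free_parameter_names <- function() .free_params

#' Published best-fit parameter values
#'
#' The calibrated constants of the model in modeling units, as shipped in the
#' packaged key-value fixture file (`system.file("extdata",
#' "final_parameters.conf", package = "cellsolute")`). Note that four of these
#' values fall outside the literature intervals returned by
#' [parameter_bounds()]; [validate_parameters()] reports them.
#'
#' @return a `parameter_set`
#' @export
default_parameters <- function() {
  parameter_set(
    D_c_gel = 4.98e-10, D_c_med = 2e-9, M_c = 5.88e-20, c_half = 5.13e-4,
    D_s_gel = 2.67e-10, D_s_med = 9e-11, M_s = 1.75e-18, s_half = 1.39,
    A = 4.6,
    D_v_gel = 4.16e-11, D_v_med = 1.32e-10, K_v = 8.37e-5,
    alpha = 2.92e-21, beta = 2.86e-22, c_tau = 4.49e-4, n_tau = 2.32e13,
    delta_0 = 3.18e-6, delta_c = 2.53e-6, delta_s = 5.6e-7,
    n_max = 6.0e13
  )
}

#' Literature intervals for the free model constants
#'
#' Lower/upper bounds per parameter in modeling units. Where the literature
#' gives ranges in practical units they are converted (cm2/s to m2/s;
#' mol/cell/s to kg/cell/s via the species molar mass; mM to kg/m3; %O2 to
#' kg/m3 through the module solubility constant; cell/mL to cell/m3). The
#' anaerobic enhancement `A` and the VEGF secretion coefficients `alpha` and
#' `beta` have no literature interval; the defaults here span about three
#' decades around plausible magnitudes.
#'
#' @return a 19 x 2 matrix with rownames [free_parameter_names()] and columns
#'   `lower`, `upper`
#' @export
parameter_bounds <- function() {
  b <- rbind(
    D_c_gel = c(1e-10, 4e-10),
    D_c_med = c(1e-9, 4e-9),
    M_c     = c(1e-18, 7.7e-16) * .o2_molar_kg,
    c_half  = c(6.66e-9, 4e-8) * 1e6 * .o2_molar_kg,
    D_s_gel = c(2.3e-11, 1.51e-10),
    D_s_med = c(5.65e-10, 1.09e-9),
    M_s     = c(5e-17, 2.2e-16) * .glucose_molar_kg,
    s_half  = c(2, 10) * .glucose_molar_kg,
    A       = c(0.1, 10),
    D_v_gel = c(2.9e-11, 1.13e-10),
    D_v_med = c(1.3e-10, 2e-10),
    K_v     = c(2.67e-6, 1.28e-4),
    alpha   = c(1e-22, 1e-19),
    beta    = c(1e-23, 1e-20),
    c_tau   = c(0.1, 2) * .o2_kgm3_per_pct,
    n_tau   = c(1e6, 60e6) * 1e6,
    delta_0 = c(3.3e-7, 1.1334e-5),
    delta_c = c(1.7e-8, 4e-6),
    delta_s = c(1.7e-8, 4e-6)
  )
  colnames(b) <- c("lower", "upper")
  b[.free_params, , drop = FALSE]
}

#' Default search intervals for calibration
#'
#' The literature intervals of [parameter_bounds()] enlarged, where necessary,
#' to cover the published best-fit values (four of which lie outside the
#' literature ranges): each interval is extended to include one third to three
#' times the packaged final value.
#'
#' @return a 19 x 2 matrix like [parameter_bounds()]
#' @export
calibration_bounds <- function() {
  b <- parameter_bounds()
  p <- default_parameters()
  b[, "lower"] <- pmin(b[, "lower"], as.numeric(p) / 3)
  b[, "upper"] <- pmax(b[, "upper"], as.numeric(p) * 3)
  b
}

#' Check a parameter set against bounds
#'
#' @param p a `parameter_set`
#' @param bounds a bounds matrix as from [parameter_bounds()]
#' @return data frame of violations (zero rows if none) with columns
#'   `parameter`, `value`, `lower`, `upper`
#' @export
validate_parameters <- function(p, bounds = parameter_bounds()) {
  stopifnot(inherits(p, "parameter_set"))
  v <- as.numeric(p)[match(rownames(bounds), names(p))]
  bad <- which(v < bounds[, "lower"] | v > bounds[, "upper"])
  data.frame(parameter = rownames(bounds)[bad], value = v[bad],
             lower = bounds[bad, "lower"], upper = bounds[bad, "upper"],
             row.names = NULL)
}

#' Read / write a parameter set as a flat key-value file
#'
#' One `key = value` line per constant (SI / modeling units), plus `n_max`.
#' Lines starting with `#` are comments.
#'
#' @param path file path
#' @return `read_parameters()` returns a `parameter_set`;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed line in ", path)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  if (anyNA(vals)) stop("non-numeric value in ", path)
  names(vals) <- keys
  n_max <- if ("n_max" %in% keys) vals[["n_max"]] else 6.0e13
  do.call(parameter_set, c(as.list(vals[setdiff(keys, "n_max")]),
                           list(n_max = n_max)))
}

#' @rdname read_parameters
#' @param p a `parameter_set`
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "parameter_set"))
  lines <- c("# cell-solute model constants, modeling units (kg/m3, cell/m3, m, s)",
             sprintf("%s = %.17g", names(p), as.numeric(p)),
             sprintf("n_max = %.17g", attr(p, "n_max")))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("Cell-solute model parameters (modeling units)\n")
  print(setNames(as.numeric(x), names(x)))
  cat("n_max (metadata):", attr(x, "n_max"), "cell/m3\n")
  invisible(x)
}
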