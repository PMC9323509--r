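# R-level interface to the finite-volume integrator.

#' Construct a field state
#'
#' Concentration fields on every mesh cell (oxygen `c`, glucose `s`, VEGF `v`,
#' kg/m3) and viable cell density `n` (cell/m3, nonzero only on gel cells) at
#' time `t` (s).
#'
#' @param t time, s
#' @param c,s,v,n numeric vectors, one value per mesh cell
#' @param mesh the [axial_mesh()] the fields live on
#' @return an object of class `"field_state"`
#' @export
field_state <- function(t, c, s, v, n, mesh) {
  N <- length(mesh$widths)
  stopifnot(length(c) == N, length(s) == N, length(v) == N, length(n) == N)
  if (any(c(c, s, v, n) < 0)) stop("field values must be nonnegative")
  if (any(n[mesh$domain == "medium"] != 0)) stop("n must be zero in the medium")
  structure(list(t = t, c = c, s = s, v = v, n = n, mesh = mesh),
            class = "field_state")
}

.par_vector <- function(p) {
  stopifnot(inherits(p, "parameter_set"))
  setNames(as.numeric(p), names(p))
}

#' Advance the coupled fields by one time step
#'
#' Backward-Euler diffusion (unconditionally stable) with reactions linearised
#' about the state at the start of the step: consumption and degradation enter
#' the implicit diagonal (preserving positivity), the VEGF source is explicit,
#' and the death ODE is solved pointwise semi-implicitly. Oxygen is held at
#' the ambient Dirichlet value at the medium-air interface (unless
#' `bc$oxygen_top = "noflux"`); glucose and VEGF see zero-flux outer
#' boundaries; the gel-medium interface flux uses the harmonic mean of the
#' half-cell diffusive resistances.
#'
#' @param state a [field_state()]
#' @param dt time step, s
#' @param p a [parameter_set()]
#' @param bc boundary configuration: list with `oxygen_top`
#'   (`"dirichlet"` or `"noflux"`) and `ambient` (kg/m3, required for
#'   Dirichlet)
#' @return the advanced `field_state`
#' @export
fv_step <- function(state, dt, p, bc = list(oxygen_top = "dirichlet", ambient = NULL)) {
  stopifnot(inherits(state, "field_state"), dt > 0)
  mesh <- state$mesh
  dirich <- identical(bc$oxygen_top, "dirichlet")
  if (dirich && is.null(bc$ambient)) stop("Dirichlet oxygen top requires bc$ambient")
  out <- fv_core(mesh$widths, mesh$n_gel, state$c, state$s, state$v, state$n,
                 .par_vector(p), if (dirich) bc$ambient else 0, dirich,
                 dt, dt, 1L)
  k <- nrow(out$c)
  field_state(state$t + dt, out$c[k, ], out$s[k, ], out$v[k, ], out$n[k, ], mesh)
}

#' Volume-weighted gel average of a field
#'
#' The model's principal observable: the mean of a species over the gel
#' domain, weighting each cell by its volume.
#'
#' @param state a [field_state()]
#' @param species one of `"oxygen"`, `"glucose"`, `"vegf"`, `"cells"`
#' @return scalar, kg/m3 (or cell/m3 for `"cells"`)
#' @export
gel_average <- function(state, species = c("oxygen", "glucose", "vegf", "cells")) {
  species <- match.arg(species)
  mesh <- state$mesh
  x <- switch(species, oxygen = state$c, glucose = state$s,
              vegf = state$v, cells = state$n)
  gel <- mesh$domain == "gel"
  sum(x[gel] * mesh$widths[gel]) / sum(mesh$widths[gel])
}

.domain_average <- function(mat, widths, sel) {
  as.numeric(mat[, sel, drop = FALSE] %*% widths[sel]) / sum(widths[sel])
}

#' Simulate the well over the culture period
#'
#' Integrates the coupled oxygen/glucose/VEGF/cell system from the standard
#' initial condition: gel oxygen at the 12% preconditioning level, medium
#' oxygen at ambient, glucose 25 mM in the medium and 1.25 mM in the gel,
#' no VEGF, and a uniform viable density `n0` in the gel.
#'
#' @param p a [parameter_set()]
#' @param geom a [well_geometry()]; defaults to the standard well at the
#'   requested density
#' @param mesh an [axial_mesh()]; defaults to 100 cells, 20% in the gel
#' @param ambient_o2 ambient oxygen, % (0 < ambient <= 21)
#' @param n0 post-stabilisation viable density, cells/mL (0 allowed for
#'   acellular runs)
#' @param t_end final time, s (default 24 h)
#' @param output_every output cadence, s (default 0.5 h)
#' @param dt time step, s (default 100 s); if `t_end` is not a multiple of
#'   `dt` the last step is shortened and a message is emitted
#' @return an object of class `"well_sim"` with elements `times` (s),
#'   `centre_oxygen` (kg/m3 at the axial midpoint of the gel), `gel_avg` and
#'   `medium_avg` (data frames of per-species domain averages over time),
#'   `viable_fraction` (final gel-average viable density / n0),
#'   `zone_viability` (final viable density in the bottom/middle/top thirds
#'   of the gel, cell/m3), `final_state`, and the run configuration
#' @export
simulate_well <- function(p, geom = NULL, mesh = NULL, ambient_o2 = 1,
                          n0 = 60e6, t_end = 86400, output_every = 1800,
                          dt = 100) {
  stopifnot(ambient_o2 > 0, ambient_o2 <= 21, n0 >= 0, t_end > 0, dt > 0)
  if (is.null(geom)) geom <- well_geometry(max(n0, 1) / 40)
  if (is.null(mesh)) mesh <- axial_mesh(geom)
  N <- length(mesh$widths)
  gel <- mesh$domain == "gel"
  amb <- convert_oxygen(ambient_o2, "percent", "kg/m3")
  c0 <- ifelse(gel, convert_oxygen(12, "percent", "kg/m3"), amb)
  s0 <- ifelse(gel, convert_glucose(1.25), convert_glucose(25))
  v0 <- rep(0, N)
  n0_m3 <- n0 * 1e6
  nn0 <- ifelse(gel, n0_m3, 0)
  if (abs(t_end / dt - round(t_end / dt)) > 1e-9)
    message("t_end is not a multiple of dt; shortening the last step")
  save_every <- max(1L, as.integer(round(output_every / dt)))
  out <- fv_core(mesh$widths, mesh$n_gel, c0, s0, v0, nn0, .par_vector(p),
                 amb, TRUE, dt, t_end, save_every)
  times <- out$times
  # gel-centre oxygen: linear interpolation of cell-centre values at z = H/2
  zc <- geom$gel_height / 2
  centre <- apply(out$c, 1, function(row)
    approx(mesh$centres, row, xout = zc, rule = 2)$y)
  gel_avg <- data.frame(
    time = times,
    oxygen = .domain_average(out$c, mesh$widths, gel),
    glucose = .domain_average(out$s, mesh$widths, gel),
    vegf = .domain_average(out$v, mesh$widths, gel),
    cells = .domain_average(out$n, mesh$widths, gel)
  )
  medium_avg <- data.frame(
    time = times,
    oxygen = .domain_average(out$c, mesh$widths, !gel),
    glucose = .domain_average(out$s, mesh$widths, !gel),
    vegf = .domain_average(out$v, mesh$widths, !gel)
  )
  nfin <- out$n[nrow(out$n), ]
  zw <- .zone_weights(mesh)
  zone <- as.numeric(zw %*% nfin[seq_len(mesh$n_gel)]) / rowSums(zw)
  names(zone) <- rownames(zw)
  k <- nrow(out$c)
  final <- field_state(times[k], out$c[k, ], out$s[k, ], out$v[k, ], nfin, mesh)
  structure(list(
    times = times, centre_oxygen = centre, gel_avg = gel_avg,
    medium_avg = medium_avg,
    viable_fraction = if (n0 > 0) gel_avg$cells[k] / n0_m3 else NA_real_,
    zone_viability = zone, final_state = final,
    config = list(ambient_o2 = ambient_o2, n0 = n0, t_end = t_end,
                  output_every = output_every, dt = dt,
                  n_cells = N, n_gel = mesh$n_gel, geom = geom)
  ), class = "well_sim")
}

#' @export
print.well_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Well simulation: ambient %.3g%% O2, n0 = %.3g cells/mL, %g h\n",
              cfg$ambient_o2, cfg$n0, cfg$t_end / 3600))
  cat(sprintf("  mesh: %d cells (%d gel), dt = %g s\n",
              cfg$n_cells, cfg$n_gel, cfg$dt))
  k <- length(x$times)
  cat(sprintf("  24-h gel averages: O2 %.3e kg/m3 (%.2f mmHg), glucose %.3g mM\n",
              x$gel_avg$oxygen[k],
              convert_oxygen(x$gel_avg$oxygen[k], "kg/m3", "mmHg"),
              convert_glucose(x$gel_avg$glucose[k], "kg/m3", "mM")))
  if (!is.na(x$viable_fraction))
    cat(sprintf("  viable fraction: %.3f\n", x$viable_fraction))
  cat(sprintf("  medium VEGF: %.3g pg/mL\n",
              convert_vegf(x$medium_avg$vegf[k], "kg/m3", "pg/mL")))
  invisible(x)
}
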