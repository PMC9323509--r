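# Pseudo-experimental datasets with the structure, design and noise character
# of the four measurement blocks: gel-centre oxygen traces (probe, mmHg),
# 24-h medium glucose (mM), 24-h gel viable fraction, and 24-h medium VEGF
# (pg/mL).

#' Experimental design matrix
#'
#' The default culture conditions: oxygen traces at ambient 1/3/7% O2 for the
#' highest density only (48 half-hourly samples each, 144 observations), and
#' endpoint glucose / viability / VEGF for 4 ambient levels x 3 densities
#' (12 observations each). The "normoxic" ambient level is labelled 19%.
#'
#' @param trace_ambients ambient levels with an oxygen trace, %
#' @param endpoint_ambients ambient levels for the endpoint blocks, %
#' @param densities post-stabilisation densities, cells/mL
#' @param trace_density density at which the probe trace is recorded
#' @param trace_times_h sampling times of the oxygen trace, h
#' @return list of class `"experiment_design"`
#' @export
experiment_design <- function(trace_ambients = c(1, 3, 7),
                              endpoint_ambients = c(1, 3, 7, 19),
                              densities = c(20e6, 31e6, 60e6),
                              trace_density = 60e6,
                              trace_times_h = seq(0.5, 24, by = 0.5)) {
  stopifnot(all(trace_ambients > 0), all(endpoint_ambients <= 21),
            all(densities > 0))
  structure(list(trace_ambients = trace_ambients,
                 endpoint_ambients = endpoint_ambients,
                 densities = densities, trace_density = trace_density,
                 trace_times_h = trace_times_h),
            class = "experiment_design")
}

#' Noise specification
#'
#' Multiplicative Gaussian noise, truncated at zero, with a per-block
#' coefficient of variation.
#'
#' @param oxygen,glucose,viability,vegf CV per block (>= 0)
#' @return list of class `"noise_spec"`
#' @export
noise_spec <- function(oxygen = 0.05, glucose = 0.05, viability = 0.08,
                       vegf = 0.08) {
  cv <- c(oxygen = oxygen, glucose = glucose, viability = viability,
          vegf = vegf)
  if (any(cv < 0)) stop("CV must be nonnegative")
  structure(as.list(cv), class = "noise_spec")
}

.apply_noise <- function(x, cv) {
  if (cv == 0) return(x)
  pmax(0, x * rnorm(length(x), 1, cv))
}

# sim_args may carry well_geometry / axial_mesh objects; provenance stores
# their defining scalars instead so a manifest survives a JSON round trip.
.serialize_sim_args <- function(sim_args) {
  out <- sim_args
  if (!is.null(out$mesh)) {
    out$mesh_spec <- list(n_cells = length(out$mesh$widths),
                          n_gel = out$mesh$n_gel)
    out$mesh <- NULL
  }
  if (!is.null(out$geom)) {
    g <- out$geom
    out$geom_spec <- list(radius = g$radius, gel_height = g$gel_height,
                          medium_height = g$medium_height,
                          density_post = g$density_post,
                          compression_factor = g$compression_factor)
    out$geom <- NULL
  }
  out
}

.restore_sim_args <- function(lst) {
  lst <- as.list(lst)
  if (!is.null(lst$geom_spec)) {
    gs <- lst$geom_spec
    area <- pi * gs$radius^2
    # rebuilt field-by-field (not via well_geometry()) so the restored
    # object is bit-identical to the serialized one
    geom <- structure(list(
      radius = gs$radius, area = area,
      gel_height = gs$gel_height, medium_height = gs$medium_height,
      gel_volume = gs$gel_height * area,
      medium_volume = gs$medium_height * area,
      density_post = gs$density_post,
      compression_factor = gs$compression_factor
    ), class = "well_geometry")
    lst$geom <- geom
    lst$geom_spec <- NULL
  }
  if (!is.null(lst$mesh_spec)) {
    if (is.null(lst$geom)) stop("mesh specification without geometry")
    ms <- lst$mesh_spec
    lst$mesh <- axial_mesh(lst$geom, n_cells = ms$n_cells,
                           gel_fraction = ms$n_gel / ms$n_cells)
    lst$mesh_spec <- NULL
  }
  lst
}

#' Assemble an experimental dataset
#'
#' Container for the four observation blocks; also the return type of
#' [generate_dataset()]. Each block is a data frame with condition labels:
#' `oxygen(ambient, n0, time_h, po2_mmHg)`, `glucose(ambient, n0,
#' glucose_mM)`, `viability(ambient, n0, viable_fraction)`, `vegf(ambient,
#' n0, vegf_pg_ml)`.
#'
#' @param oxygen,glucose,viability,vegf the observation blocks
#' @param provenance optional list recording how the data were produced
#' @return list of class `"experiment_dataset"`
#' @export
experiment_dataset <- function(oxygen, glucose, viability, vegf,
                               provenance = NULL) {
  need <- list(oxygen = c("ambient", "n0", "time_h", "po2_mmHg"),
               glucose = c("ambient", "n0", "glucose_mM"),
               viability = c("ambient", "n0", "viable_fraction"),
               vegf = c("ambient", "n0", "vegf_pg_ml"))
  blocks <- list(oxygen = oxygen, glucose = glucose, viability = viability,
                 vegf = vegf)
  for (b in names(blocks)) {
    if (!all(need[[b]] %in% names(blocks[[b]])))
      stop("block '", b, "' must have columns ",
           paste(need[[b]], collapse = ", "))
    vcol <- setdiff(need[[b]], c("ambient", "n0", "time_h"))
    if (any(blocks[[b]][[vcol]] < 0)) stop("negative values in block '", b, "'")
  }
  if (nrow(viability) && any(viability$viable_fraction > 1))
    stop("viable fractions must lie in [0, 1]")
  structure(c(blocks, list(provenance = provenance)),
            class = "experiment_dataset")
}

#' Generate a synthetic pseudo-experiment
#'
#' Runs the forward model at every design condition under `true_params`,
#' extracts the four observable blocks at the experimental cadences, applies
#' multiplicative truncated-Gaussian noise, and records full provenance
#' (true parameters, design, noise spec, seed) so the dataset can be
#' regenerated bit-identically.
#'
#' @param true_params generating [parameter_set()]
#' @param design an [experiment_design()]
#' @param noise a [noise_spec()]; use CVs of 0 for noise-free data
#' @param seed RNG seed for the noise draws
#' @param sim_args list of extra arguments for [simulate_well()]
#' @return an [experiment_dataset()]
#' @export
generate_dataset <- function(true_params = default_parameters(),
                             design = experiment_design(),
                             noise = noise_spec(), seed = NULL,
                             sim_args = list()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(noise, "noise_spec"))
  conds <- unique(rbind(
    data.frame(ambient = design$trace_ambients, n0 = design$trace_density),
    expand.grid(ambient = design$endpoint_ambients, n0 = design$densities)
  ))
  sims <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    sims[[i]] <- try(do.call(simulate_well,
                             c(list(p = true_params,
                                    ambient_o2 = conds$ambient[i],
                                    n0 = conds$n0[i]), sim_args)),
                     silent = TRUE)
    if (inherits(sims[[i]], "try-error"))
      stop(sprintf("forward solve failed at ambient %g%%, n0 %g cells/mL",
                   conds$ambient[i], conds$n0[i]))
  }
  key <- function(a, n) paste(signif(a, 10), signif(n, 10))
  names(sims) <- key(conds$ambient, conds$n0)

  oxy <- do.call(rbind, lapply(design$trace_ambients, function(a) {
    sim <- sims[[key(a, design$trace_density)]]
    val <- approx(sim$times, sim$centre_oxygen,
                  xout = design$trace_times_h * 3600)$y
    data.frame(ambient = a, n0 = design$trace_density,
               time_h = design$trace_times_h,
               po2_mmHg = convert_oxygen(val, "kg/m3", "mmHg"))
  }))
  ep <- expand.grid(ambient = design$endpoint_ambients,
                    n0 = design$densities)
  endpoint <- function(extract) vapply(seq_len(nrow(ep)), function(i)
    extract(sims[[key(ep$ambient[i], ep$n0[i])]]), 0)
  glu <- data.frame(ep, glucose_mM = endpoint(function(s)
    convert_glucose(s$medium_avg$glucose[length(s$times)], "kg/m3", "mM")))
  via <- data.frame(ep, viable_fraction = endpoint(function(s)
    s$viable_fraction))
  veg <- data.frame(ep, vegf_pg_ml = endpoint(function(s)
    convert_vegf(s$medium_avg$vegf[length(s$times)], "kg/m3", "pg/mL")))

  if (!is.null(seed)) set.seed(seed)
  oxy$po2_mmHg <- .apply_noise(oxy$po2_mmHg, noise$oxygen)
  glu$glucose_mM <- .apply_noise(glu$glucose_mM, noise$glucose)
  via$viable_fraction <- pmin(1, .apply_noise(via$viable_fraction,
                                              noise$viability))
  veg$vegf_pg_ml <- .apply_noise(veg$vegf_pg_ml, noise$vegf)

  experiment_dataset(oxy, glu, via, veg, provenance = list(
    true_params = as.list(setNames(as.numeric(true_params),
                                   names(true_params))),
    n_max = attr(true_params, "n_max"),
    design = unclass(design), noise = unclass(noise), seed = seed,
    sim_args = .serialize_sim_args(sim_args),
    package_version = as.character(packageVersion("cellsolute"))
  ))
}

#' Acellular oxygen equilibration trace
#'
#' Simulates a cell-free construct (`n0 = 0`) and returns the gel-centre
#' oxygen trace, used to characterise pure diffusive equilibration of the
#' initially 12%-preconditioned gel toward the ambient level.
#'
#' @param ambient ambient oxygen, %
#' @param geom optional [well_geometry()]
#' @param params a [parameter_set()] (only diffusivities matter)
#' @param ... passed to [simulate_well()]
#' @return data frame with `time_h` and `po2_mmHg`
#' @export
generate_acellular_trace <- function(ambient = 1, geom = NULL,
                                     params = default_parameters(), ...) {
  stopifnot(ambient > 0)
  sim <- simulate_well(params, geom = geom, ambient_o2 = ambient, n0 = 0, ...)
  data.frame(time_h = sim$times / 3600,
             po2_mmHg = convert_oxygen(sim$centre_oxygen, "kg/m3", "mmHg"))
}

#' Write / read a dataset as CSV files plus a JSON provenance manifest
#'
#' Four CSV files (`oxygen.csv`, `glucose.csv`, `viability.csv`, `vegf.csv`)
#' and `manifest.json` in `dir`. The reader validates block shapes and can
#' regenerate a synthetic dataset from its manifest.
#'
#' @param dataset an [experiment_dataset()]
#' @param dir output directory (created if needed)
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()` an
#'   `experiment_dataset`
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "experiment_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(dataset$oxygen, file.path(dir, "oxygen.csv"), row.names = FALSE)
  write.csv(dataset$glucose, file.path(dir, "glucose.csv"), row.names = FALSE)
  write.csv(dataset$viability, file.path(dir, "viability.csv"),
            row.names = FALSE)
  write.csv(dataset$vegf, file.path(dir, "vegf.csv"), row.names = FALSE)
  jsonlite::write_json(dataset$provenance, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  prov <- if (file.exists(man_path)) jsonlite::read_json(man_path,
                                                         simplifyVector = TRUE)
  experiment_dataset(
    oxygen = read.csv(file.path(dir, "oxygen.csv")),
    glucose = read.csv(file.path(dir, "glucose.csv")),
    viability = read.csv(file.path(dir, "viability.csv")),
    vegf = read.csv(file.path(dir, "vegf.csv")),
    provenance = prov
  )
}

#' Regenerate a synthetic dataset from its provenance manifest
#'
#' @param provenance the `provenance` element of a synthetic
#'   [experiment_dataset()] (or a manifest read back from JSON)
#' @return an [experiment_dataset()] identical to the original
#' @export
regenerate_dataset <- function(provenance) {
  p <- do.call(parameter_set, c(provenance$true_params,
                                list(n_max = provenance$n_max)))
  design <- do.call(experiment_design, provenance$design[
    c("trace_ambients", "endpoint_ambients", "densities", "trace_density",
      "trace_times_h")])
  noise <- do.call(noise_spec, provenance$noise[
    c("oxygen", "glucose", "viability", "vegf")])
  sim_args <- provenance$sim_args
  if (is.null(sim_args)) sim_args <- list()
  generate_dataset(p, design, noise, seed = provenance$seed,
                   sim_args = .restore_sim_args(sim_args))
}
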