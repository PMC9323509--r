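# Tidy result writers and run manifests.

#' Write simulation results as tidy CSV
#'
#' One row per (time, species, domain, statistic): gel and medium averages
#' for every species plus the gel-centre oxygen trace, in modeling units.
#'
#' @param sim a `well_sim` from [simulate_well()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_simulation_csv <- function(sim, path) {
  stopifnot(inherits(sim, "well_sim"))
  long <- function(df, domain) {
    sp <- setdiff(names(df), "time")
    do.call(rbind, lapply(sp, function(s)
      data.frame(time = df$time, species = s, domain = domain,
                 statistic = "average", value = df[[s]])))
  }
  rows <- rbind(
    long(sim$gel_avg, "gel"),
    long(sim$medium_avg, "medium"),
    data.frame(time = sim$times, species = "oxygen", domain = "gel",
               statistic = "centre", value = sim$centre_oxygen)
  )
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulation run manifest
#'
#' JSON capture of geometry, mesh, parameters and run configuration,
#' sufficient to reproduce the run.
#'
#' @param sim a `well_sim`
#' @param p the [parameter_set()] used
#' @param path output JSON path
#' @param seed optional seed to record
#' @return `path`, invisibly
#' @export
write_run_manifest <- function(sim, p, path, seed = NULL) {
  stopifnot(inherits(sim, "well_sim"))
  cfg <- sim$config
  manifest <- list(
    parameters = as.list(setNames(as.numeric(p), names(p))),
    n_max = attr(p, "n_max"),
    geometry = cfg$geom[c("radius", "gel_height", "medium_height",
                          "gel_volume", "medium_volume",
                          "compression_factor")],
    run = cfg[c("ambient_o2", "n0", "t_end", "output_every", "dt",
                "n_cells", "n_gel")],
    seed = seed,
    package_version = as.character(packageVersion("cellsolute"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Re-run a simulation from its manifest
#'
#' @param path manifest JSON path
#' @return a `well_sim`
#' @export
run_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- do.call(parameter_set, c(m$parameters, list(n_max = m$n_max)))
  geom <- well_geometry(
    seeded_density = m$run$n0 / m$geometry$compression_factor,
    gel_volume_prestab = m$geometry$gel_volume * m$geometry$compression_factor * 1e9,
    medium_volume = m$geometry$medium_volume * 1e9,
    compression_factor = m$geometry$compression_factor,
    radius = m$geometry$radius
  )
  mesh <- axial_mesh(geom, n_cells = m$run$n_cells,
                     gel_fraction = m$run$n_gel / m$run$n_cells)
  simulate_well(p, geom = geom, mesh = mesh, ambient_o2 = m$run$ambient_o2,
                n0 = m$run$n0, t_end = m$run$t_end,
                output_every = m$run$output_every, dt = m$run$dt)
}
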