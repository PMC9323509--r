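# L1 calibration cost against the four observation blocks, and the two-step
# particle-swarm calibration (step 1: oxygen/glucose/viability parameters;
# step 2: VEGF parameters, holding step 1 fixed).

.step1_params <- c("delta_0", "delta_c", "delta_s", "D_c_gel", "c_half",
                   "M_c", "D_s_gel", "s_half", "M_s", "A")
.step2_params <- c("D_v_gel", "K_v", "c_tau", "n_tau", "alpha", "beta")
.fixed_params <- c("D_c_med", "D_s_med", "D_v_med")

# run the forward model once per unique (ambient, n0) condition in the
# dataset and return the predictions matched to each observation block.
# Predictions are normalised like the observations (see calibration_cost).
.forward_predictions <- function(p, dataset, species, sim_args = list()) {
  conds <- unique(rbind(
    if ("oxygen" %in% species && nrow(dataset$oxygen))
      unique(dataset$oxygen[, c("ambient", "n0")]),
    if ("glucose" %in% species && nrow(dataset$glucose))
      unique(dataset$glucose[, c("ambient", "n0")]),
    if ("cells" %in% species && nrow(dataset$viability))
      unique(dataset$viability[, c("ambient", "n0")]),
    if ("vegf" %in% species && nrow(dataset$vegf))
      unique(dataset$vegf[, c("ambient", "n0")])
  ))
  sims <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds)))
    sims[[i]] <- do.call(simulate_well,
                         c(list(p = p, ambient_o2 = conds$ambient[i],
                                n0 = conds$n0[i]), sim_args))
  key <- function(a, n) paste(signif(a, 10), signif(n, 10))
  names(sims) <- key(conds$ambient, conds$n0)
  pred <- list()
  if ("oxygen" %in% species && nrow(dataset$oxygen)) {
    ob <- dataset$oxygen
    pred$oxygen <- vapply(seq_len(nrow(ob)), function(i) {
      sim <- sims[[key(ob$ambient[i], ob$n0[i])]]
      approx(sim$times, sim$centre_oxygen, xout = ob$time_h[i] * 3600)$y /
        convert_oxygen(ob$ambient[i], "percent", "kg/m3")
    }, 0)
  }
  if ("glucose" %in% species && nrow(dataset$glucose)) {
    ob <- dataset$glucose
    pred$glucose <- vapply(seq_len(nrow(ob)), function(i) {
      sim <- sims[[key(ob$ambient[i], ob$n0[i])]]
      k <- length(sim$times)
      sim$medium_avg$glucose[k] / convert_glucose(25)
    }, 0)
  }
  if ("cells" %in% species && nrow(dataset$viability)) {
    ob <- dataset$viability
    pred$cells <- vapply(seq_len(nrow(ob)), function(i)
      sims[[key(ob$ambient[i], ob$n0[i])]]$viable_fraction, 0)
  }
  if ("vegf" %in% species && nrow(dataset$vegf)) {
    ob <- dataset$vegf
    pred$vegf <- vapply(seq_len(nrow(ob)), function(i) {
      sim <- sims[[key(ob$ambient[i], ob$n0[i])]]
      k <- length(sim$times)
      convert_vegf(sim$medium_avg$vegf[k], "kg/m3", "pg/mL")
    }, 0)
  }
  pred
}

# observations on the same normalised scale as .forward_predictions
.normalised_observations <- function(dataset, species) {
  obs <- list()
  if ("oxygen" %in% species && nrow(dataset$oxygen))
    obs$oxygen <- dataset$oxygen$po2_mmHg /
      convert_oxygen(dataset$oxygen$ambient, "percent", "mmHg")
  if ("glucose" %in% species && nrow(dataset$glucose))
    obs$glucose <- dataset$glucose$glucose_mM / 25
  if ("cells" %in% species && nrow(dataset$viability))
    obs$cells <- dataset$viability$viable_fraction
  if ("vegf" %in% species && nrow(dataset$vegf))
    obs$vegf <- dataset$vegf$vegf_pg_ml
  obs
}

#' L1 calibration cost
#'
#' The average absolute difference between model predictions and observations,
#' summed over species: `J = sum_X (1/Omega_X) sum |F_X - Y_X|` on
#' nondimensionalised values. Oxygen traces are normalised by the condition's
#' ambient concentration, glucose by the initial 25 mM, cell density by the
#' initial density (i.e. compared as viable fractions), and VEGF -- whose
#' initial concentration is zero -- by the maximum observed value of the
#' block. One forward run is performed per unique (ambient, n0) condition.
#'
#' @param theta named numeric vector of parameter values to overlay on
#'   `fixed`
#' @param dataset an [experiment_dataset()]
#' @param fixed a full [parameter_set()] supplying every constant not in
#'   `theta`
#' @param species subset of `c("oxygen", "glucose", "cells", "vegf")`
#' @param sim_args list of extra arguments for [simulate_well()]
#' @return scalar cost; `+Inf` (with a warning) if the forward model fails
#' @export
calibration_cost <- function(theta, dataset, fixed = default_parameters(),
                             species = c("oxygen", "glucose", "cells", "vegf"),
                             sim_args = list()) {
  stopifnot(inherits(dataset, "experiment_dataset"))
  species <- match.arg(species, several.ok = TRUE)
  vals <- setNames(as.numeric(fixed), names(fixed))
  if (length(theta)) {
    bad <- setdiff(names(theta), names(vals))
    if (length(bad)) stop("unknown parameters in theta: ",
                          paste(bad, collapse = ", "))
    vals[names(theta)] <- theta
  }
  p <- try(do.call(parameter_set, as.list(vals)), silent = TRUE)
  if (inherits(p, "try-error")) return(Inf)
  pred <- try(.forward_predictions(p, dataset, species, sim_args),
              silent = TRUE)
  if (inherits(pred, "try-error")) {
    warning("forward model failed; returning Inf cost")
    return(Inf)
  }
  obs <- .normalised_observations(dataset, species)
  total <- 0
  for (sp in names(obs)) {
    o <- obs[[sp]]
    f <- pred[[sp]]
    if (sp == "vegf") {
      scale <- max(o)
      if (scale <= 0) scale <- 1
      o <- o / scale
      f <- f / scale
    }
    total <- total + mean(abs(f - o))
  }
  total
}

#' Two-step particle-swarm calibration
#'
#' Step 1 fits the ten oxygen/glucose/cell-density constants
#' (`delta_0, delta_c, delta_s, D_c_gel, c_half, M_c, D_s_gel, s_half, M_s, A`)
#' against the oxygen-trace, glucose and viability blocks with the step-1
#' swarm settings (`c1 = 2, c2 = 0.2, w = 0.6`). Step 2 then fits the six
#' VEGF constants (`D_v_gel, K_v, c_tau, n_tau, alpha, beta`) against the
#' VEGF block with `w = 0.7`, holding the step-1 result fixed. The medium
#' diffusivities (`D_c_med, D_s_med, D_v_med`) and `n_max` stay at their
#' values in `init`.
#'
#' @param dataset an [experiment_dataset()] with the four observation blocks
#' @param bounds search intervals (default [calibration_bounds()])
#' @param init a full `parameter_set` providing the fixed constants (and the
#'   non-VEGF constants if step 1 is skipped)
#' @param config1,config2 [swarm_config()]s for the two steps (defaults:
#'   the published step settings, c1 = 2, c2 = 0.2 with w = 0.6 and 0.7)
#' @param sim_args list of extra arguments for [simulate_well()]
#' @return list of class `"two_step_calibration"`: `params` (calibrated
#'   `parameter_set`), `step1`, `step2` (each a `calibration_result`, or
#'   `NULL` if skipped)
#' @export
calibrate_two_step <- function(dataset, bounds = calibration_bounds(),
                               init = default_parameters(),
                               config1 = swarm_config(c1 = 2, c2 = 0.2, w = 0.6),
                               config2 = swarm_config(c1 = 2, c2 = 0.2, w = 0.7),
                               sim_args = list()) {
  stopifnot(inherits(dataset, "experiment_dataset"))
  have1 <- nrow(dataset$oxygen) + nrow(dataset$glucose) +
    nrow(dataset$viability) > 0
  have2 <- nrow(dataset$vegf) > 0
  vals <- setNames(as.numeric(init), names(init))
  step1 <- step2 <- NULL
  if (have1) {
    step1 <- pso_minimize(
      function(th) calibration_cost(th, dataset, init,
                                    species = c("oxygen", "glucose", "cells"),
                                    sim_args = sim_args),
      bounds[.step1_params, , drop = FALSE], config1)
    vals[.step1_params] <- step1$par[.step1_params]
  } else {
    if (!have2) stop("dataset contains no observations")
    warning("no oxygen/glucose/viability observations: step 1 skipped, ",
            "using the supplied non-VEGF parameters")
  }
  p1 <- do.call(parameter_set, c(as.list(vals),
                                 list(n_max = attr(init, "n_max"))))
  if (have2) {
    step2 <- pso_minimize(
      function(th) calibration_cost(th, dataset, p1, species = "vegf",
                                    sim_args = sim_args),
      bounds[.step2_params, , drop = FALSE], config2)
    vals[.step2_params] <- step2$par[.step2_params]
  }
  params <- do.call(parameter_set, c(as.list(vals),
                                     list(n_max = attr(init, "n_max"))))
  structure(list(params = params, step1 = step1, step2 = step2),
            class = "two_step_calibration")
}

#' Multi-seed calibration spread
#'
#' Repeats a calibration under several seeds and reports the per-parameter
#' spread of the recovered values, quantifying how reproducible the swarm
#' optimum is.
#'
#' @param dataset an [experiment_dataset()]
#' @param seeds integer vector of seeds
#' @param ... passed to [calibrate_two_step()]; the configs' seeds are
#'   overridden per repeat
#' @param config1,config2 baseline [swarm_config()]s
#' @return list with `fits` (one `two_step_calibration` per seed) and
#'   `spread` (data frame of min/median/max per parameter)
#' @export
calibration_spread <- function(dataset, seeds = 1:10,
                               config1 = swarm_config(c1 = 2, c2 = 0.2, w = 0.6),
                               config2 = swarm_config(c1 = 2, c2 = 0.2, w = 0.7), ...) {
  fits <- lapply(seeds, function(s) {
    c1 <- config1; c1$seed <- s
    c2 <- config2; c2$seed <- s + 1e6
    calibrate_two_step(dataset, config1 = c1, config2 = c2, ...)
  })
  mat <- vapply(fits, function(f) as.numeric(f$params),
                numeric(length(free_parameter_names())))
  rownames(mat) <- free_parameter_names()
  spread <- data.frame(parameter = rownames(mat),
                       min = apply(mat, 1, min),
                       median = apply(mat, 1, median),
                       max = apply(mat, 1, max), row.names = NULL)
  list(fits = fits, spread = spread)
}

#' Write a calibration report as JSON
#'
#' Best parameters (modeling and practical units), per-species cost
#' decomposition, evaluation counts, seeds and convergence reasons.
#'
#' @param fit a `two_step_calibration`
#' @param dataset the dataset it was fitted to
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_calibration_report <- function(fit, dataset, path) {
  p <- fit$params
  decomp <- sapply(c("oxygen", "glucose", "cells", "vegf"), function(sp)
    calibration_cost(numeric(0), dataset, p, species = sp))
  report <- list(
    parameters_modeling_units = as.list(setNames(as.numeric(p), names(p))),
    parameters_practical_units = list(
      c_half_molml = convert_oxygen(p[["c_half"]], "kg/m3", "mol/mL"),
      c_tau_percent = convert_oxygen(p[["c_tau"]], "kg/m3", "percent"),
      s_half_mM = convert_glucose(p[["s_half"]], "kg/m3", "mM"),
      n_tau_cells_per_ml = p[["n_tau"]] / 1e6
    ),
    cost_per_species = as.list(decomp),
    step1 = if (!is.null(fit$step1))
      list(value = fit$step1$value, evals = fit$step1$evals,
           converged = fit$step1$converged, seed = fit$step1$config$seed),
    step2 = if (!is.null(fit$step2))
      list(value = fit$step2$value, evals = fit$step2$evals,
           converged = fit$step2$converged, seed = fit$step2$config$seed)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
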