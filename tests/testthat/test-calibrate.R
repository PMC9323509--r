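# Calibration cost and two-step swarm fitting on synthetic data.

noisefree_dataset <- function() {
  if (is.null(.cal_cache$ds))
    .cal_cache$ds <- generate_dataset(noise = noise_spec(0, 0, 0, 0),
                                      sim_args = fast_sim_args())
  .cal_cache$ds
}
.cal_cache <- new.env()

test_that("the cost vanishes at the generating parameters", {
  ds <- noisefree_dataset()
  J <- calibration_cost(numeric(0), ds, default_parameters(),
                        sim_args = fast_sim_args())
  expect_equal(J, 0, tolerance = 1e-12)
})

test_that("the cost averages absolute residuals per species", {
  ds <- noisefree_dataset()
  # perturb two glucose observations by known normalized amounts
  ds2 <- ds
  ds2$glucose$glucose_mM[1] <- ds$glucose$glucose_mM[1] + 0.1 * 25
  ds2$glucose$glucose_mM[2] <- ds$glucose$glucose_mM[2] - 0.3 * 25
  J <- calibration_cost(numeric(0), ds2, default_parameters(),
                        species = "glucose", sim_args = fast_sim_args())
  expect_equal(J, (0.1 + 0.3) / 12, tolerance = 1e-9)
  # two species sum independently (brute-force summation oracle)
  ds2$viability$viable_fraction[3] <-
    max(0, ds$viability$viable_fraction[3] - 0.25)
  d_v <- abs(ds2$viability$viable_fraction[3] -
               ds$viability$viable_fraction[3])
  J2 <- calibration_cost(numeric(0), ds2, default_parameters(),
                         species = c("glucose", "cells"),
                         sim_args = fast_sim_args())
  expect_equal(J2, (0.1 + 0.3) / 12 + d_v / 12, tolerance = 1e-9)
})

test_that("the cost is invariant to observation order within a species", {
  ds <- generate_dataset(noise = noise_spec(), seed = 5,
                         sim_args = fast_sim_args())
  perm <- sample(nrow(ds$oxygen))
  ds2 <- ds
  ds2$oxygen <- ds$oxygen[perm, ]
  th <- c(M_c = 4e-20)
  expect_equal(
    calibration_cost(th, ds, sim_args = fast_sim_args()),
    calibration_cost(th, ds2, sim_args = fast_sim_args())
  )
})

test_that("invalid parameter vectors cost +Inf, unknown names error", {
  ds <- noisefree_dataset()
  expect_error(calibration_cost(c(nonsense = 1), ds), "unknown")
  expect_equal(calibration_cost(c(c_half = 0), ds,
                                sim_args = fast_sim_args()), Inf)
})

test_that("a VEGF-only dataset skips step 1 with a warning", {
  ds <- noisefree_dataset()
  empty_o <- ds$oxygen[0, ]
  empty_g <- ds$glucose[0, ]
  empty_v <- ds$viability[0, ]
  vegf_only <- experiment_dataset(empty_o, empty_g, empty_v, ds$vegf)
  expect_warning(
    fit <- calibrate_two_step(
      vegf_only, init = default_parameters(),
      config2 = swarm_config(4, 3, w = 0.7, seed = 1),
      sim_args = fast_sim_args()),
    "step 1 skipped")
  expect_null(fit$step1)
  expect_s3_class(fit$params, "parameter_set")
  # non-VEGF parameters passed through untouched
  expect_equal(fit$params[["M_c"]], default_parameters()[["M_c"]])
  # an entirely empty dataset is refused
  empty_all <- experiment_dataset(empty_o, empty_g, empty_v, ds$vegf[0, ])
  expect_error(calibrate_two_step(empty_all), "no observations")
})

test_that("the optimizer beats random bound-respecting vectors on clean data", {
  ds <- noisefree_dataset()
  b <- calibration_bounds()
  fit <- calibrate_two_step(
    ds, init = default_parameters(),
    config1 = swarm_config(6, 8, w = 0.6, seed = 2),
    config2 = swarm_config(6, 8, w = 0.7, seed = 3),
    sim_args = fast_sim_args())
  expect_true(all(diff(fit$step1$trace) <= 0))
  set.seed(10)
  step1 <- cellsolute:::.step1_params
  rand_cost <- replicate(3, {
    th <- setNames(runif(length(step1), b[step1, "lower"],
                         b[step1, "upper"]), step1)
    calibration_cost(th, ds, default_parameters(),
                     species = c("oxygen", "glucose", "cells"),
                     sim_args = fast_sim_args())
  })
  expect_lte(fit$step1$value, min(rand_cost))
})
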