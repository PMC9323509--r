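test_that("the default design reproduces the experimental block sizes", {
  d <- experiment_design()
  expect_length(d$trace_ambients, 3)
  expect_length(d$trace_times_h, 48)
  expect_equal(length(d$endpoint_ambients) * length(d$densities), 12)
})

test_that("noise-free synthetic data equal the forward predictions", {
  ds <- generate_dataset(noise = noise_spec(0, 0, 0, 0),
                         sim_args = fast_sim_args())
  expect_s3_class(ds, "experiment_dataset")
  expect_equal(nrow(ds$oxygen), 144)
  expect_equal(nrow(ds$glucose), 12)
  expect_equal(nrow(ds$viability), 12)
  expect_equal(nrow(ds$vegf), 12)
  # direct forward check for one condition
  sim <- do.call(simulate_well,
                 c(list(p = default_parameters(), ambient_o2 = 1, n0 = 60e6),
                   fast_sim_args()))
  k <- length(sim$times)
  sub <- ds$glucose[ds$glucose$ambient == 1 & ds$glucose$n0 == 60e6, ]
  expect_equal(sub$glucose_mM,
               convert_glucose(sim$medium_avg$glucose[k], "kg/m3", "mM"))
  sub_o <- ds$oxygen[ds$oxygen$ambient == 1 & ds$oxygen$time_h == 24, ]
  expect_equal(sub_o$po2_mmHg,
               convert_oxygen(sim$centre_oxygen[k], "kg/m3", "mmHg"))
})

test_that("the multiplicative noise honours its coefficient of variation", {
  base <- c(7.6, 22.8, 53.2, 4, 80)
  set.seed(1234)
  draws <- replicate(2000, cellsolute:::.apply_noise(base, 0.05))
  cv <- apply(draws, 1, sd) / apply(draws, 1, mean)
  expect_true(all(cv > 0.04 & cv < 0.06))
  # CV = 0 leaves the data untouched
  expect_identical(cellsolute:::.apply_noise(base, 0), base)
  # truncation keeps values nonnegative even at absurd CV
  set.seed(1)
  expect_true(all(cellsolute:::.apply_noise(base, 2) >= 0))
})

test_that("a synthetic dataset regenerates bit-identically from provenance", {
  ds <- generate_dataset(noise = noise_spec(), seed = 420,
                         sim_args = fast_sim_args())
  ds2 <- regenerate_dataset(ds$provenance)
  expect_equal(ds$oxygen, ds2$oxygen, tolerance = 0)
  expect_equal(ds$vegf, ds2$vegf, tolerance = 0)
  # and survives a round trip through disk
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$glucose$glucose_mM, ds$glucose$glucose_mM)
  ds3 <- regenerate_dataset(back$provenance)
  expect_equal(ds3$viability$viable_fraction, ds$viability$viable_fraction)
})

test_that("synthetic data reproduce the qualitative ambient-oxygen trends", {
  ds <- generate_dataset(noise = noise_spec(0, 0, 0, 0),
                         sim_args = fast_sim_args())
  # 24-h medium glucose decreases as ambient oxygen decreases
  glu <- aggregate(glucose_mM ~ ambient, ds$glucose, mean)
  glu <- glu[order(glu$ambient), ]
  expect_true(all(diff(glu$glucose_mM) > 0))
  # viable fraction decreases with decreasing ambient oxygen
  via <- aggregate(viable_fraction ~ ambient, ds$viability, mean)
  via <- via[order(via$ambient), ]
  expect_true(all(diff(via$viable_fraction) > 0))
})

test_that("acellular constructs equilibrate to ambient by diffusion alone", {
  tr <- generate_acellular_trace(1)
  amb <- 7.6
  offset0 <- convert_oxygen(12, "percent", "mmHg") - amb
  # monotone decay toward ambient
  expect_true(all(diff(tr$po2_mmHg) <= 1e-9))
  # within 5% of the initial offset in at most 5 h
  at5 <- tr$po2_mmHg[tr$time_h == 5]
  expect_lt(at5 - amb, 0.05 * offset0)
  # long-time limit: ambient within 0.1%
  expect_lt(abs(tr$po2_mmHg[tr$time_h == 24] - amb) / amb, 1e-3)
})

test_that("viable fractions above one are rejected, negatives refused", {
  ds <- generate_dataset(noise = noise_spec(0, 0, 0, 0),
                         sim_args = fast_sim_args())
  bad <- ds$viability
  bad$viable_fraction[1] <- 1.2
  expect_error(experiment_dataset(ds$oxygen, ds$glucose, bad, ds$vegf),
               "viable")
  bad2 <- ds$glucose
  bad2$glucose_mM[1] <- -5
  expect_error(experiment_dataset(ds$oxygen, bad2, ds$viability, ds$vegf),
               "negative")
})
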