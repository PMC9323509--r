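unit_bounds <- function(k) {
  b <- cbind(lower = rep(0, k), upper = rep(1, k))
  rownames(b) <- paste0("x", seq_len(k))
  b
}

test_that("trajectories step one coordinate at a time on the four-level grid", {
  d <- morris_design(unit_bounds(2), r = 2, levels = 4, candidate_pool = 10,
                     seed = 1)
  expect_equal(d$delta, 2 / 3)
  for (B in d$trajectories) {
    expect_equal(dim(B), c(3, 2))
    expect_true(all(B >= 0 & B <= 1))
    for (i in 1:2) {
      step <- B[i + 1, ] - B[i, ]
      expect_equal(sum(step != 0), 1)
      expect_equal(abs(step[step != 0]), 2 / 3, ignore_attr = TRUE)
    }
    # grid levels only
    expect_true(all(round(B * 3) %in% 0:3))
  }
})

test_that("designs are reproducible under a seed", {
  b <- unit_bounds(5)
  d1 <- morris_design(b, r = 4, candidate_pool = 30, seed = 99)
  d2 <- morris_design(b, r = 4, candidate_pool = 30, seed = 99)
  expect_identical(d1$trajectories, d2$trajectories)
})

test_that("the selected subset is more spread than random subsets", {
  set.seed(7)
  b <- unit_bounds(4)
  d <- morris_design(b, r = 6, candidate_pool = 80, seed = 11)
  # recreate the candidate pool to compare against random subsets
  set.seed(11)
  delta <- 2 / 3
  cand <- replicate(80, cellsolute:::.one_trajectory(4, 4, delta),
                    simplify = FALSE)
  spread <- function(trajs) {
    s <- 0
    for (i in seq_along(trajs)[-1]) for (j in seq_len(i - 1))
      s <- s + cellsolute:::.traj_distance(trajs[[i]], trajs[[j]])^2
    s
  }
  sel_spread <- spread(d$trajectories)
  rand <- replicate(100, spread(cand[sample.int(80, 6)]))
  expect_gte(sel_spread, max(rand) * 0.999)
  expect_error(morris_design(b, r = 10, candidate_pool = 5), "at least r")
})

test_that("elementary effects are exact for linear models", {
  k <- 5
  a <- c(3, -2, 0.5, 0, 10)
  b <- unit_bounds(k)
  d <- morris_design(b, r = 6, candidate_pool = 40, seed = 3)
  ee <- elementary_effects(function(x) sum(a * x), d)
  expect_equal(dim(ee), c(6, k))
  for (i in seq_len(k)) expect_equal(unname(ee[, i]), rep(a[i], 6))
  st <- morris_statistics(ee)
  expect_equal(st$mu_star, abs(a), tolerance = 1e-12)
  expect_equal(st$sigma, rep(0, k), tolerance = 1e-12)
  # mu* ranking equals |coefficient| ranking
  expect_equal(order(st$mu_star), order(abs(a)))
})

test_that("interaction terms produce nonzero sigma", {
  b <- unit_bounds(2)
  d <- morris_design(b, r = 8, candidate_pool = 60, seed = 5)
  ee <- elementary_effects(function(x) x[1] * x[2], d)
  st <- morris_statistics(ee)
  expect_gt(st$sigma[1], 0)
  # constant model: all effects vanish
  ee0 <- elementary_effects(function(x) 42, d)
  expect_true(all(ee0 == 0))
})

test_that("screening statistics match an independent two-pass computation", {
  set.seed(21)
  ee <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("p", 1:6)))
  st <- morris_statistics(ee)
  for (i in 1:6) {
    expect_equal(st$mu_star[i], sum(abs(ee[, i])) / 10)
    mbar <- sum(ee[, i]) / 10
    expect_equal(st$sigma[i], sqrt(sum((ee[, i] - mbar)^2) / 10))
  }
  expect_error(morris_statistics(ee[1, , drop = FALSE]), "at least 2")
})

test_that("output scaling scales mu_star and sigma linearly", {
  b <- unit_bounds(3)
  d <- morris_design(b, r = 5, candidate_pool = 30, seed = 8)
  f <- function(x) x[1]^2 + sin(x[2] * 3) + x[3]
  s1 <- morris_statistics(elementary_effects(f, d))
  s5 <- morris_statistics(elementary_effects(function(x) 5 * f(x), d))
  expect_equal(s5$mu_star, 5 * s1$mu_star)
  expect_equal(s5$sigma, 5 * s1$sigma)
})

test_that("failing model evaluations drop the trajectory with a warning", {
  b <- unit_bounds(2)
  d <- morris_design(b, r = 4, candidate_pool = 20, seed = 13)
  hit <- 0
  f <- function(x) {
    hit <<- hit + 1
    if (hit == 1) stop("boom") else sum(x)
  }
  expect_warning(ee <- elementary_effects(f, d), "dropped")
  expect_equal(nrow(ee), 3)
})

test_that("wide parameter ranges are sampled in log space", {
  b <- rbind(narrow = c(1, 2), wide = c(1e-18, 1e-15))
  colnames(b) <- c("lower", "upper")
  expect_equal(unname(cellsolute:::.log_scaled(b)), c(FALSE, TRUE))
  x <- cellsolute:::.map_unit(c(0.5, 0.5), b, cellsolute:::.log_scaled(b))
  expect_equal(unname(x), c(1.5, 10^(-16.5)))
})
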