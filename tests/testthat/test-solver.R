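test_that("a uniform ambient state with no cells is a fixed point", {
  g <- std_geometry()
  m <- axial_mesh(g, 40, 0.2)
  amb <- convert_oxygen(1, "percent", "kg/m3")
  st <- uniform_state(m, c = amb, s = 2, v = 0, n0 = 0)
  p <- inert_parameters()
  out <- fv_step(st, 100, p, bc = list(oxygen_top = "dirichlet", ambient = amb))
  expect_equal(out$c, st$c, tolerance = 1e-14)
  expect_equal(out$s, st$s, tolerance = 1e-14)
  expect_equal(out$v, st$v)
})

test_that("total solute mass is conserved under zero flux with no reactions", {
  g <- std_geometry()
  m <- axial_mesh(g, 60, 0.2)
  p <- inert_parameters()
  # a deliberately nonuniform initial profile
  N <- length(m$widths)
  st <- field_state(0, c = 1 + sin(seq_len(N) / 5), s = exp(-seq_len(N) / 20),
                    v = rep(0.5, N), n = rep(0, N), mesh = m)
  mass <- function(x) sum(x * m$widths)
  m0 <- c(mass(st$c), mass(st$s), mass(st$v))
  for (i in 1:25) {
    st <- fv_step(st, 500, p, bc = list(oxygen_top = "noflux"))
    mt <- c(mass(st$c), mass(st$s), mass(st$v))
    expect_equal(mt, m0, tolerance = 1e-10)
  }
})

test_that("pure diffusion toward a fixed surface matches the Fourier series", {
  # uniform-diffusivity column, Dirichlet top for oxygen, no cells
  D <- 5e-10
  p <- inert_parameters(D = D)
  g <- std_geometry()
  m <- axial_mesh(g, 120, 0.2)
  h <- g$gel_height + g$medium_height
  c0 <- 1; c_top <- 0.2
  st <- uniform_state(m, c = c0, s = 1, v = 0)
  t_final <- h^2 / D # one diffusion time
  dt <- t_final / 4000
  for (i in 1:4000)
    st <- fv_step(st, dt, p, bc = list(oxygen_top = "dirichlet",
                                       ambient = c_top))
  exact <- slab_series(m$centres, t_final, h, D, c0, c_top)
  expect_lt(max(abs(st$c - exact)) / (c0 - c_top), 0.01)
})

test_that("viable density is pointwise nonincreasing and decays in closed form", {
  p <- default_parameters()
  vals <- as.list(setNames(as.numeric(p), names(p)))
  vals$M_c <- 0; vals$delta_c <- 0; vals$delta_s <- 0
  p0 <- do.call(parameter_set, vals)
  sim <- simulate_well(p0, ambient_o2 = 7, n0 = 60e6)
  k <- length(sim$times)
  # closed-form survival under a constant baseline death rate
  expect_equal(sim$viable_fraction, exp(-p[["delta_0"]] * 86400),
               tolerance = 5e-4)
  expect_true(all(diff(sim$gel_avg$cells) <= 0))
  # nonincrease holds for the full model too
  sim2 <- simulate_well(default_parameters(), ambient_o2 = 1, n0 = 60e6)
  expect_true(all(diff(sim2$gel_avg$cells) <= 0))
})

test_that("gel averages are volume-weighted means over the gel only", {
  g <- std_geometry()
  m <- axial_mesh(g, 40, 0.2)
  st <- uniform_state(m, c = 0.37, s = 1.1, v = 2)
  expect_equal(gel_average(st, "oxygen"), 0.37)
  expect_equal(gel_average(st, "glucose"), 1.1)
  # medium values must not leak into the gel average
  st$c[m$domain == "medium"] <- 99
  expect_equal(gel_average(st, "oxygen"), 0.37)
  # brute-force weighted mean oracle on a nonuniform field
  st$c[m$domain == "gel"] <- runif(m$n_gel)
  gel <- m$domain == "gel"
  oracle <- sum(st$c[gel] * m$widths[gel]) / sum(m$widths[gel])
  expect_equal(gel_average(st, "oxygen"), oracle)
  expect_error(gel_average(st, "ATP"), "arg")
})

test_that("raising ambient oxygen never lowers 24-h viability", {
  p <- default_parameters()
  args <- fast_sim_args()
  vf <- vapply(c(1, 3, 7, 19), function(a)
    do.call(simulate_well, c(list(p = p, ambient_o2 = a, n0 = 60e6),
                             args))$viable_fraction, 0)
  expect_true(all(diff(vf) >= 0))
})

test_that("viable cells are densest at the top of the gel after 24 h", {
  sim <- simulate_well(default_parameters(), ambient_o2 = 1, n0 = 60e6)
  z <- sim$zone_viability
  expect_gte(z[["top"]], z[["bottom"]])
})

test_that("observables converge monotonically under refinement", {
  p <- default_parameters()
  g <- std_geometry()
  res <- vapply(c(1, 2, 4), function(f) {
    sim <- simulate_well(p, geom = g, mesh = axial_mesh(g, 50 * f, 0.2),
                         ambient_o2 = 1, n0 = 60e6, dt = 200 / f)
    sim$gel_avg$oxygen[length(sim$times)]
  }, 0)
  # successive changes shrink and keep direction
  d <- diff(res)
  expect_lt(abs(d[2]), abs(d[1]))
  expect_gte(d[1] * d[2], 0)
})

test_that("field states reject negative values and misplaced cells", {
  g <- std_geometry()
  m <- axial_mesh(g, 20, 0.2)
  N <- length(m$widths)
  expect_error(field_state(0, rep(-1, N), rep(0, N), rep(0, N), rep(0, N), m),
               "nonnegative")
  n_bad <- rep(1e12, N)
  expect_error(field_state(0, rep(1, N), rep(0, N), rep(0, N), n_bad, m),
               "medium")
})
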