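# Shared fixtures: small geometries, a fast solver configuration, and the
# analytic single-slab diffusion oracle.

std_geometry <- function(n0 = 60e6) well_geometry(n0 / 40)

# reduced-resolution solver arguments for tests that run many simulations
fast_sim_args <- function() {
  geom <- std_geometry()
  list(geom = geom, mesh = axial_mesh(geom, n_cells = 50, gel_fraction = 0.2),
       dt = 300)
}

# Analytic solution for diffusion in a slab of height h with zero flux at
# z = 0, fixed concentration c_top at z = h, and uniform initial value c0:
# separation of variables / Fourier cosine series.
slab_series <- function(z, t, h, D, c0, c_top, nterms = 200) {
  m <- seq_len(nterms) - 1
  lam <- (2 * m + 1) * pi / (2 * h)
  coef <- 4 / pi * (-1)^m / (2 * m + 1)
  dev <- vapply(z, function(zz)
    sum(coef * cos(lam * zz) * exp(-D * lam^2 * t)), 0)
  c_top + (c0 - c_top) * dev
}

# a parameter set with all reactions switched off (pure transport)
inert_parameters <- function(D = 1e-9) {
  parameter_set(
    D_c_gel = D, D_c_med = D, M_c = 0, c_half = 5.13e-4,
    D_s_gel = D, D_s_med = D, M_s = 0, s_half = 1.39, A = 0,
    D_v_gel = D, D_v_med = D, K_v = 0, alpha = 0, beta = 0,
    c_tau = 4.49e-4, n_tau = 2.32e13,
    delta_0 = 0, delta_c = 0, delta_s = 0
  )
}

uniform_state <- function(mesh, c = 1, s = 1, v = 0, n0 = 0) {
  N <- length(mesh$widths)
  field_state(0, rep(c, N), rep(s, N), rep(v, N),
              ifelse(mesh$domain == "gel", n0, 0), mesh)
}
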