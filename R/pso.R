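# Global-best particle swarm minimisation with inertia and
# cognitive/social acceleration, bound handling by clipping with velocity
# zeroing, and optional log10-space search for wide-ranged coordinates.

#' Swarm configuration
#'
#' @param n_particles swarm size (>= 2)
#' @param n_iters iterations; every iteration evaluates each particle once,
#'   so the forward-evaluation budget is exactly `n_particles * n_iters`
#' @param c1,c2 cognitive (individual) and social (collective) acceleration
#'   coefficients; the defaults are the canonical constriction-equivalent
#'   values for a general-purpose swarm. The two-step calibration passes its
#'   own published step settings (c1 = 2, c2 = 0.2) instead.
#' @param w inertia coefficient
#' @param seed RNG seed
#' @param stall_iters,stall_tol optional early stop: quit when the global
#'   best improves by less than `stall_tol` (relative) over `stall_iters`
#'   consecutive iterations; `NULL` (default) disables it so the evaluation
#'   budget is exact
#' @return list of class `"swarm_config"`
#' @export
swarm_config <- function(n_particles = 20, n_iters = 1250, c1 = 1.49445,
                         c2 = 1.49445, w = 0.72984, seed = NULL, stall_iters = NULL,
                         stall_tol = 1e-6) {
  stopifnot(n_particles >= 2, n_iters >= 1, c1 > 0, c2 > 0, w > 0)
  structure(list(n_particles = n_particles, n_iters = n_iters, c1 = c1,
                 c2 = c2, w = w, seed = seed, stall_iters = stall_iters,
                 stall_tol = stall_tol), class = "swarm_config")
}

#' Particle-swarm minimisation
#'
#' Standard global-best swarm: each particle keeps its personal best, the
#' swarm shares one global best, and velocities follow
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with fresh uniform
#' `r1, r2` per coordinate. Particles start at rest, velocities are clamped
#' to half the search range, positions are clipped to the bounds and the
#' velocity component of a clipped coordinate is zeroed. Coordinates whose
#' bounds span at least two decades are searched in log10 space.
#'
#' @param cost_fn function of a named parameter vector returning a scalar
#'   cost; non-finite returns are treated as +Inf
#' @param bounds matrix with columns `lower`, `upper` (rownames name the
#'   coordinates)
#' @param config a [swarm_config()]
#' @param log_scale logical vector per coordinate, or `NULL` for the
#'   two-decade rule
#' @return list of class `"calibration_result"`: `par` (best vector, natural
#'   units), `value`, `trace` (global-best cost per iteration, nonincreasing),
#'   `evals`, `converged` reason
#' @export
pso_minimize <- function(cost_fn, bounds, config = swarm_config(),
                         log_scale = NULL) {
  stopifnot(all(is.finite(bounds)), all(bounds[, "upper"] >= bounds[, "lower"]))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- nrow(bounds)
  if (is.null(log_scale)) log_scale <- .log_scaled(bounds)
  lo <- ifelse(log_scale, log10(bounds[, "lower"]), bounds[, "lower"])
  hi <- ifelse(log_scale, log10(bounds[, "upper"]), bounds[, "upper"])
  back <- function(x) setNames(ifelse(log_scale, 10^x, x), rownames(bounds))
  np <- config$n_particles
  # stratified (Latin hypercube) start: one particle per stratum and axis
  U <- vapply(seq_len(k), function(i)
    (sample.int(np) - runif(np)) / np, numeric(np))
  X <- t(rep(lo, each = np) + U * rep(hi - lo, each = np)) # column = particle
  V <- matrix(0, k, np)                     # start at rest
  vmax <- 0.5 * (hi - lo)                   # standard velocity clamp
  pbest_x <- X
  pbest_f <- rep(Inf, np)
  gbest_x <- X[, 1]
  gbest_f <- Inf
  trace <- numeric(0)
  evals <- 0L
  stall <- 0L
  reason <- "max_iterations"
  for (it in seq_len(config$n_iters)) {
    f_prev <- gbest_f
    for (m in seq_len(np)) {
      f <- cost_fn(back(X[, m]))
      evals <- evals + 1L
      if (!is.finite(f)) f <- Inf
      if (f < pbest_f[m]) {
        pbest_f[m] <- f
        pbest_x[, m] <- X[, m]
      }
      if (f < gbest_f) {
        gbest_f <- f
        gbest_x <- X[, m]
      }
    }
    if (it == 1 && !is.finite(gbest_f))
      stop("cost is non-finite at every initial particle")
    trace <- c(trace, gbest_f)
    if (!is.null(config$stall_iters)) {
      improved <- is.finite(f_prev) &&
        (f_prev - gbest_f) > config$stall_tol * max(abs(f_prev), 1e-300)
      stall <- if (improved || !is.finite(f_prev)) 0L else stall + 1L
      if (stall >= config$stall_iters) {
        reason <- "stalled"
        break
      }
    }
    r1 <- matrix(runif(np * k), k, np)
    r2 <- matrix(runif(np * k), k, np)
    V <- config$w * V + config$c1 * r1 * (pbest_x - X) +
      config$c2 * r2 * (gbest_x - X)
    V <- pmin(pmax(V, -vmax), vmax)
    X <- X + V
    clip_lo <- X < lo
    clip_hi <- X > hi
    X[clip_lo] <- matrix(lo, k, np)[clip_lo]
    X[clip_hi] <- matrix(hi, k, np)[clip_hi]
    V[clip_lo | clip_hi] <- 0
  }
  structure(list(par = back(gbest_x), value = gbest_f, trace = trace,
                 evals = evals, converged = reason, config = config),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("PSO result: best cost %.6g after %d evaluations (%s)\n",
              x$value, x$evals, x$converged))
  print(x$par)
  invisible(x)
}
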