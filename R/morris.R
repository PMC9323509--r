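# Morris elementary-effects screening with Campolongo-style trajectory
# selection. Designs live in the unit hypercube; an affine (or log-affine)
# map takes them to the parameter bounds.

.log_scaled <- function(bounds) {
  # sample in log10 space when an interval spans >= 2 decades
  bounds[, "lower"] > 0 & bounds[, "upper"] / bounds[, "lower"] >= 100
}

.map_unit <- function(u, bounds, log_scale) {
  lo <- bounds[, "lower"]; hi <- bounds[, "upper"]
  x <- ifelse(log_scale,
              10^(log10(lo) + u * (log10(hi) - log10(lo))),
              lo + u * (hi - lo))
  setNames(x, rownames(bounds))
}

# one random Morris trajectory: (k+1) x k matrix in the unit cube,
# consecutive rows differ in exactly one coordinate by +/- delta
.one_trajectory <- function(k, levels, delta) {
  base_levels <- seq(0, 1 - delta, by = 1 / (levels - 1))
  x_base <- sample(base_levels, k, replace = TRUE)
  dirs <- sample(c(-1, 1), k, replace = TRUE)
  # shift the base so that the +/- step stays inside [0,1]
  x_base <- ifelse(dirs < 0, x_base + delta, x_base)
  ord <- sample.int(k)
  B <- matrix(rep(x_base, each = k + 1), k + 1, k)
  for (j in seq_len(k)) B[(which(ord == j) + 1):(k + 1), j] <-
      x_base[j] + dirs[j] * delta
  B
}

# Campolongo spread: sum over point pairs of Euclidean distances
.traj_distance <- function(t1, t2) {
  d <- 0
  for (i in seq_len(nrow(t1))) d <- d + sum(sqrt(colSums((t(t2) - t1[i, ])^2)))
  d
}

#' Sample an optimised Morris screening design
#'
#' Generates `candidate_pool` random Morris trajectories on a `levels`-level
#' grid in the unit hypercube and greedily selects the `r` most mutually
#' spread ones (maximising the summed pairwise trajectory distance, after
#' Campolongo's maximin criterion).
#'
#' @param bounds a bounds matrix as from [parameter_bounds()]
#' @param r number of trajectories to keep (>= 2)
#' @param levels number of grid levels (even; default 4)
#' @param candidate_pool number of random candidates (default 500)
#' @param seed RNG seed for reproducibility
#' @return an object of class `"morris_design"`: list of unit-cube
#'   trajectories, `delta`, bounds, log-scaling flags
#' @export
morris_design <- function(bounds, r = 40, levels = 4, candidate_pool = 500,
                          seed = NULL) {
  k <- nrow(bounds)
  if (levels %% 2 != 0) stop("levels must be even")
  if (r < 2) stop("r must be at least 2")
  if (candidate_pool < r) stop("candidate_pool must be at least r")
  if (!is.null(seed)) set.seed(seed)
  delta <- levels / (2 * (levels - 1))
  cand <- replicate(candidate_pool, .one_trajectory(k, levels, delta),
                    simplify = FALSE)
  if (candidate_pool == r) {
    sel <- seq_len(r)
  } else {
    D <- matrix(0, candidate_pool, candidate_pool)
    for (i in seq_len(candidate_pool - 1)) for (j in (i + 1):candidate_pool)
      D[i, j] <- D[j, i] <- .traj_distance(cand[[i]], cand[[j]])
    # greedy maximin: seed with the most distant pair, then add the candidate
    # with the largest summed squared distance to the selected set
    sel <- as.integer(arrayInd(which.max(D), dim(D)))
    while (length(sel) < r) {
      rest <- setdiff(seq_len(candidate_pool), sel)
      score <- colSums(D[sel, rest, drop = FALSE]^2)
      sel <- c(sel, rest[which.max(score)])
    }
  }
  structure(list(trajectories = cand[sel], delta = delta, levels = levels,
                 bounds = bounds, log_scale = .log_scaled(bounds),
                 r = r, k = k),
            class = "morris_design")
}

#' Elementary effects of a model over a Morris design
#'
#' Evaluates `model_fn` at every trajectory point and forms one elementary
#' effect per parameter per trajectory:
#' `EE_i = (Y(X + delta e_i) - Y(X)) / delta`, oriented so that the
#' numerator difference is taken toward increasing coordinate `i`.
#'
#' @param model_fn function of a named parameter vector (natural units)
#'   returning a scalar or a named numeric vector of outputs
#' @param design a [morris_design()]
#' @return for scalar outputs an (r x k) matrix of elementary effects; for
#'   vector outputs a named list of such matrices. Trajectories on which
#'   `model_fn` fails are dropped with a warning.
#' @export
elementary_effects <- function(model_fn, design) {
  stopifnot(inherits(design, "morris_design"))
  k <- design$k
  ee_list <- vector("list", length(design$trajectories))
  ok <- rep(TRUE, length(ee_list))
  for (j in seq_along(design$trajectories)) {
    B <- design$trajectories[[j]]
    Y <- try(lapply(seq_len(k + 1), function(i)
      model_fn(.map_unit(B[i, ], design$bounds, design$log_scale))),
      silent = TRUE)
    if (inherits(Y, "try-error") ||
        any(!vapply(Y, function(y) all(is.finite(y)), TRUE))) {
      ok[j] <- FALSE
      next
    }
    Y <- do.call(rbind, lapply(Y, rbind))
    ee <- matrix(NA_real_, k, ncol(Y))
    for (i in seq_len(k)) {
      dif <- B[i + 1, ] - B[i, ]
      coord <- which(dif != 0)
      ee[coord, ] <- (Y[i + 1, ] - Y[i, ]) / dif[coord]
    }
    ee_list[[j]] <- ee
  }
  if (any(!ok))
    warning(sum(!ok), " trajectory(ies) dropped: model evaluation failed")
  ee_list <- ee_list[ok]
  if (length(ee_list) == 0) stop("no valid trajectories")
  n_out <- ncol(ee_list[[1]])
  out_names <- names(model_fn(.map_unit(design$trajectories[[1]][1, ],
                                        design$bounds, design$log_scale)))
  res <- lapply(seq_len(n_out), function(m)
    t(vapply(ee_list, function(e) e[, m], numeric(k))) |>
      `colnames<-`(rownames(design$bounds)))
  if (n_out == 1) res[[1]] else setNames(res, out_names)
}

#' Morris screening statistics
#'
#' Per-parameter mean absolute elementary effect `mu_star` (overall
#' influence), signed mean `mu`, and the elementary-effect standard deviation
#' `sigma` (nonlinearity / interaction), computed with divisor `r` as in the
#' screening literature. Where `mu_star > 0` the ratio `sigma/mu_star` is
#' reported with the usual qualitative classification.
#'
#' @param ee an (r x k) elementary-effect matrix from [elementary_effects()]
#' @return a data frame with one row per parameter, class `"morris_result"`
#' @export
morris_statistics <- function(ee) {
  if (nrow(ee) < 2) stop("at least 2 trajectories are needed for sigma")
  r <- nrow(ee)
  mu <- colMeans(ee)
  mu_star <- colMeans(abs(ee))
  sigma <- sqrt(colMeans(sweep(ee, 2, mu)^2))
  ratio <- ifelse(mu_star > 0, sigma / mu_star, NA_real_)
  cls <- cut(ratio, c(-Inf, 0.1, 0.5, 1, Inf),
             labels = c("linear", "monotonic", "almost monotonic",
                        "nonlinear/interacting"))
  structure(data.frame(parameter = colnames(ee), mu = mu, mu_star = mu_star,
                       sigma = sigma, sigma_mu_star = ratio,
                       class = cls, row.names = NULL),
            class = c("morris_result", "data.frame"))
}

#' Screen the full well model
#'
#' Runs Morris screening of all 19 constants against the four 24-h gel-average
#' outputs (oxygen, glucose, VEGF, viable cell density) under a reference
#' culture condition.
#'
#' @param bounds parameter bounds (default [parameter_bounds()])
#' @param r trajectories (default 40)
#' @param ambient_o2 reference ambient oxygen, % (default 1)
#' @param n0 reference post-stabilisation density, cells/mL (default 60e6)
#' @param seed RNG seed
#' @param candidate_pool,levels passed to [morris_design()]
#' @param ... passed to [simulate_well()] (e.g. `dt`, `mesh`)
#' @return list with the design and one `morris_result` per output
#' @export
morris_screen <- function(bounds = parameter_bounds(), r = 40,
                          ambient_o2 = 1, n0 = 60e6, seed = NULL,
                          candidate_pool = 500, levels = 4, ...) {
  design <- morris_design(bounds, r = r, levels = levels,
                          candidate_pool = candidate_pool, seed = seed)
  fn <- function(theta) {
    p <- do.call(parameter_set, as.list(theta))
    sim <- simulate_well(p, ambient_o2 = ambient_o2, n0 = n0,
                         output_every = 86400, ...)
    k <- length(sim$times)
    c(oxygen = sim$gel_avg$oxygen[k], glucose = sim$gel_avg$glucose[k],
      vegf = sim$gel_avg$vegf[k], cells = sim$gel_avg$cells[k])
  }
  ee <- elementary_effects(fn, design)
  list(design = design, statistics = lapply(ee, morris_statistics), ee = ee)
}

#' Write Morris statistics to CSV
#'
#' One row per (output, parameter) with `mu_star`, `sigma`, `sigma/mu_star`.
#'
#' @param screen result of [morris_screen()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_morris_csv <- function(screen, path) {
  rows <- do.call(rbind, lapply(names(screen$statistics), function(out) {
    st <- screen$statistics[[out]]
    data.frame(output = out, st)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
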