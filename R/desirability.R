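#' Desirability goal for one response
#'
#' Derringer-style one-sided ramp: for a maximized response d rises from 0 at
#' the lower limit to 1 at the upper limit; for a minimized response the ramp
#' is reversed. The weight raises the ramp to a power (w = 1 is linear).
#'
#' @param response response name the goal refers to.
#' @param direction `"maximize"` or `"minimize"`.
#' @param low,high ramp limits in response units (`low < high`). Typically
#'   the observed extremes of the response over the experiment; see
#'   [ramp_limits()].
#' @param weight positive ramp exponent (default 1).
#' @return Object of class `desirability_goal`.
#' @export
goal <- function(response, direction = c("maximize", "minimize"),
                 low, high, weight = 1) {
  direction <- match.arg(direction)
  if (!(low < high)) stop("need low < high ramp limits")
  if (weight <= 0) stop("weight must be positive")
  structure(list(response = response, direction = direction,
                 low = low, high = high, weight = weight),
            class = "desirability_goal")
}

#' Individual desirability of a predicted response value
#'
#' @param y predicted response value(s).
#' @param goal a [goal()].
#' @return d in [0, 1], same length as `y`.
#' @export
individual_desirability <- function(y, goal) {
  r <- (y - goal$low) / (goal$high - goal$low)
  if (goal$direction == "minimize") r <- 1 - r
  pmin(pmax(r, 0), 1)^goal$weight
}

#' Overall desirability (geometric mean)
#'
#' @param ds numeric vector of individual desirabilities in [0, 1].
#' @return Geometric mean; 0 whenever any component is 0 (the veto property).
#' @export
overall_desirability <- function(ds) {
  if (length(ds) == 0) stop("no individual desirabilities")
  if (any(ds < 0 | ds > 1)) stop("individual desirabilities must lie in [0, 1]")
  if (any(ds == 0)) return(0)
  exp(mean(log(ds)))
}

#' Ramp limits reconstructed from response summaries
#'
#' The published form of a response is usually per-formulation means and SDs.
#' Ramp limits for desirability are taken as the extremes of the plausible
#' replicate-level range: min over formulations of mean - sd sqrt((n-1)/n)
#' and max of mean + sd sqrt((n-1)/n) (`method = "reconstructed"`), or simply
#' the extremes of the means (`method = "mean_extremes"`). With replicate
#' data, the observed min/max are used directly.
#'
#' @param response a `response_set`.
#' @param method limit convention for summary-level data.
#' @param default_n replicate count assumed when `n` is unknown.
#' @return Numeric `c(low, high)`.
#' @export
ramp_limits <- function(response, method = c("reconstructed", "mean_extremes"),
                        default_n = 3) {
  method <- match.arg(method)
  if (response$level == "replicate") {
    return(range(response$data$value))
  }
  d <- response$data
  if (method == "mean_extremes") return(range(d$mean))
  n <- ifelse(is.na(d$n), default_n, d$n)
  c <- sqrt((n - 1) / n)
  c(min(d$mean - c * d$sd), max(d$mean + c * d$sd))
}

#' Multi-response desirability optimization over a mixture region
#'
#' Maximizes the geometric-mean desirability of several Scheffe-model
#' predictions over the constrained mixture region. The equality constraint
#' is kept exact by optimizing the first two components and setting the third
#' to total minus their sum. A dense grid screen is followed by Nelder-Mead
#' polish from the grid optimum and from seeded random feasible starts;
#' infeasible proposals are rejected by penalty. Deterministic given `seed`.
#'
#' @param models list of `scheffe_model`/`scheffe_fit` objects, one per goal.
#' @param goals list of [goal()] objects, same order as `models`.
#' @param region the `mixture_region` (three components).
#' @param n_starts number of random polish starts (default 8).
#' @param seed integer seed.
#' @param grid_step grid spacing in dose units (default 0.01).
#' @return List with `composition` (named doses), `D`, `predictions`,
#'   `desirabilities`, `trace` (starts and convergence), `all_zero` flag.
#' @export
optimize_desirability <- function(models, goals, region, n_starts = 8L,
                                  seed = 1L, grid_step = 0.01) {
  stopifnot(length(models) == length(goals), length(models) >= 1)
  comps <- region$components
  if (length(comps) != 3) stop("optimizer supports three-component regions")
  total <- region$total
  lo <- region$lower
  hi <- region$upper
  D_at <- function(x12) {
    x3 <- total - sum(x12)
    x <- c(x12, x3)
    if (any(x < lo - 1e-12) || any(x > hi + 1e-12)) return(-1)
    ds <- vapply(seq_along(models), function(i) {
      individual_desirability(
        predict(models[[i]], x, warn_outside = FALSE), goals[[i]])
    }, numeric(1))
    if (any(ds == 0)) 0 else exp(mean(log(ds)))
  }
  # grid screen on the two free coordinates, vectorized over the lattice
  g1 <- seq(lo[1], hi[1], by = grid_step)
  g2 <- seq(lo[2], hi[2], by = grid_step)
  grid <- expand.grid(a = g1, b = g2)
  grid$c3 <- total - grid$a - grid$b
  grid <- grid[grid$c3 >= lo[3] - 1e-12 & grid$c3 <= hi[3] + 1e-12, ]
  if (nrow(grid) == 0) stop("empty region grid; reduce grid_step")
  dmat <- vapply(seq_along(models), function(i) {
    individual_desirability(
      predict(models[[i]], as.matrix(grid), warn_outside = FALSE), goals[[i]])
  }, numeric(nrow(grid)))
  dmat <- matrix(dmat, nrow = nrow(grid))
  Dvec <- exp(rowMeans(log(pmax(dmat, 1e-300))))
  Dvec[apply(dmat == 0, 1, any)] <- 0
  ibest <- which.max(Dvec)
  best <- c(grid$a[ibest], grid$b[ibest])
  best_D <- Dvec[ibest]
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  starts <- list(best)
  for (s in seq_len(n_starts)) {
    repeat {
      cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
      if (D_at(cand) >= 0) break
    }
    starts[[length(starts) + 1L]] <- cand
  }
  converged <- logical(0)
  for (st in starts) {
    opt <- stats::optim(st, function(z) -D_at(z), method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
    converged <- c(converged, opt$convergence == 0)
    if (-opt$value > best_D) {
      best_D <- -opt$value
      best <- opt$par
    }
  }
  x <- c(best, total - sum(best))
  names(x) <- comps
  preds <- vapply(models, function(m) predict(m, x, warn_outside = FALSE),
                  numeric(1))
  ds <- vapply(seq_along(models), function(i) {
    individual_desirability(preds[i], goals[[i]])
  }, numeric(1))
  names(preds) <- names(ds) <- vapply(goals, `[[`, character(1), "response")
  list(composition = x, D = max(best_D, 0), predictions = preds,
       desirabilities = ds,
       trace = list(n_starts = length(starts), converged = converged),
       all_zero = best_D <= 0)
}

#' Prediction grid over the coded simplex for ternary surface plots
#'
#' Triangular lattice of the given resolution on the coded simplex, clipped
#' to the mixture region, with model predictions at each node. The full
#' simplex at resolution m has choose(m + 2, 2) nodes for three components.
#'
#' @param model a `scheffe_model`/`scheffe_fit`.
#' @param region the `mixture_region`.
#' @param resolution number of lattice steps along each edge.
#' @param clip drop nodes outside the region bounds (default `TRUE`).
#' @return Data frame of actual doses, coded fractions and `prediction`.
#' @export
surface_grid <- function(model, region, resolution = 50, clip = TRUE) {
  comps <- region$components
  if (length(comps) != 3) stop("surface grids support three components")
  idx <- expand.grid(i = 0:resolution, j = 0:resolution)
  idx <- idx[idx$i + idx$j <= resolution, ]
  coded <- cbind(idx$i, idx$j, resolution - idx$i - idx$j) / resolution
  colnames(coded) <- comps
  actual <- coded * region$total
  if (clip) {
    ok <- region_contains(region, actual, tol = 1e-9)
    coded <- coded[ok, , drop = FALSE]
    actual <- actual[ok, , drop = FALSE]
  }
  out <- as.data.frame(actual)
  cc <- as.data.frame(coded)
  names(cc) <- paste0(comps, "_coded")
  out <- cbind(out, cc)
  out$prediction <- if (nrow(out)) {
    predict(model, actual, warn_outside = FALSE)
  } else {
    numeric(0)
  }
  rownames(out) <- NULL
  out
}
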