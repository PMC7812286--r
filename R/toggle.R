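#' Mutual-repression (toggle switch) model
#'
#' Dimensionless two-gene toggle for a pair of mutually repressing
#' transcripts (in the fibrosis application, Tgfb3 as `x` and Mmp13 as
#' `y`):
#' \deqn{dx/dt = \alpha_1 / (1 + y^{\beta_1}) - x}
#' \deqn{dy/dt = \alpha_2 / (1 + x^{\beta_2}) - y}
#' `alpha1`, `alpha2` are effective synthesis rates and `beta1`, `beta2`
#' cooperativity exponents. Mutual repression is a positive feedback loop;
#' for sufficient synthesis rate and cooperativity > 1 the system is
#' bistable: two stable nodes separated by a saddle, with the tipping point
#' of the biological transition corresponding to crossing the saddle's
#' separatrix.
#'
#' @param alpha1,alpha2 synthesis rates (> 0). Default 3, well inside the
#'   bistable regime at the default cooperativity.
#' @param beta1,beta2 cooperativity exponents (>= 0, finite). Default 2.
#' @return object of class `toggle_model`.
#' @examples
#' m <- toggle_model()
#' fixed_points(m)
#' @export
toggle_model <- function(alpha1 = 3, alpha2 = 3, beta1 = 2, beta2 = 2) {
  if (!(alpha1 > 0 && alpha2 > 0)) stop("alpha1, alpha2 must be > 0")
  if (beta1 < 0 || beta2 < 0 || !is.finite(beta1) || !is.finite(beta2))
    stop("beta1, beta2 must be finite and >= 0")
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 beta1 = beta1, beta2 = beta2),
            class = "toggle_model")
}

#' @export
print.toggle_model <- function(x, ...) {
  cat(sprintf("toggle_model: alpha = (%g, %g), beta = (%g, %g)\n",
              x$alpha1, x$alpha2, x$beta1, x$beta2))
  fp <- fixed_points(x)
  cat(sprintf("  %d fixed point(s): %s\n", nrow(fp),
              paste(sprintf("(%.4g, %.4g) %s", fp$x, fp$y, fp$class),
                    collapse = ", ")))
  cat(sprintf("  bistable: %s\n", is_bistable(x)))
  invisible(x)
}

#' Right-hand side of the toggle model
#' @param state numeric `c(x, y)`, non-negative.
#' @param model a [toggle_model()].
#' @return numeric `c(dx, dy)`.
#' @export
toggle_rates <- function(state, model) {
  x <- state[[1]]; y <- state[[2]]
  c(model$alpha1 / (1 + y^model$beta1) - x,
    model$alpha2 / (1 + x^model$beta2) - y)
}

toggle_jacobian <- function(state, model) {
  x <- state[[1]]; y <- state[[2]]
  dy_term <- if (model$beta1 == 0) 0 else
    -model$alpha1 * model$beta1 * y^(model$beta1 - 1) / (1 + y^model$beta1)^2
  dx_term <- if (model$beta2 == 0) 0 else
    -model$alpha2 * model$beta2 * x^(model$beta2 - 1) / (1 + x^model$beta2)^2
  matrix(c(-1, dx_term, dy_term, -1), 2, 2)
}

#' Fixed points of the toggle model, with stability
#'
#' Reduces the equilibrium problem to one dimension — any fixed point has
#' `y = alpha2 / (1 + x^beta2)` and residual
#' `r(x) = x - alpha1 / (1 + y(x)^beta1)` — scans `x` densely (log-spaced
#' over `(0, alpha1]`, a valid bracket because any fixed point satisfies
#' `x <= alpha1`), and refines every sign change by bisection to 1e-12.
#' Each root's Jacobian eigenvalues classify it as `stable_node`, `saddle`,
#' or `other` (degenerate). Generic parameter values yield 1 or 3 fixed
#' points.
#'
#' @param model a [toggle_model()].
#' @param n_scan number of scan points (default 2000).
#' @return data.frame with columns `x`, `y`, `eigen1`, `eigen2`, `class`.
#' @export
fixed_points <- function(model, n_scan = 2000) {
  a1 <- model$alpha1
  yfun <- function(x) model$alpha2 / (1 + x^model$beta2)
  resid <- function(x) x - a1 / (1 + yfun(x)^model$beta1)
  xs <- exp(seq(log(a1 * 1e-9), log(a1), length.out = n_scan))
  rv <- resid(xs)
  roots <- xs[rv == 0]
  idx <- which(rv[-1] * rv[-n_scan] < 0)
  for (i in idx) {
    lo <- xs[i]; hi <- xs[i + 1]
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (resid(lo) * resid(mid) <= 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-13) break
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  roots <- sort(unique(roots))
  if (!length(roots))
    return(data.frame(x = numeric(), y = numeric(), eigen1 = numeric(),
                      eigen2 = numeric(), class = character()))
  rows <- lapply(roots, function(x) {
    y <- yfun(x)
    ev <- sort(Re(eigen(toggle_jacobian(c(x, y), model),
                        only.values = TRUE)$values))
    cls <- if (all(ev < 0)) "stable_node"
           else if (ev[1] < 0 && ev[2] > 0) "saddle"
           else "other"
    data.frame(x = x, y = y, eigen1 = ev[1], eigen2 = ev[2], class = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Is the toggle bistable?
#'
#' `TRUE` when the model has exactly two stable nodes.
#'
#' @param model a [toggle_model()].
#' @return logical.
#' @export
is_bistable <- function(model) {
  sum(fixed_points(model)$class == "stable_node") == 2L
}

#' Locate the critical synthesis rate of the symmetric toggle
#'
#' For the symmetric model (`alpha1 = alpha2 = alpha`,
#' `beta1 = beta2 = beta`), scans `alpha` over a grid, checks the
#' fixed-point count is monotone along the grid, and bisects the
#' monostable-to-bistable transition to the requested tolerance.
#'
#' @param beta common cooperativity exponent.
#' @param alpha_grid scan grid (default 40 points over `(0.05, 100]`).
#' @param tol bisection tolerance on alpha (default 1e-4).
#' @return the critical alpha, or `NA` if the system is monostable over
#'   the whole grid.
#' @export
bifurcation_scan <- function(beta, alpha_grid = seq(0.05, 100, length.out = 40),
                             tol = 1e-4) {
  n_stable <- function(a)
    sum(fixed_points(toggle_model(a, a, beta, beta))$class == "stable_node")
  counts <- vapply(alpha_grid, n_stable, numeric(1))
  if (is.unsorted(counts))
    stop("non-monotone fixed-point count along alpha_grid; increase resolution")
  if (all(counts < 2)) return(NA_real_)
  if (counts[1] >= 2)
    stop("alpha_grid starts inside the bistable regime; extend it downward")
  i <- which(counts >= 2)[1]
  lo <- alpha_grid[i - 1]; hi <- alpha_grid[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (n_stable(mid) >= 2) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Integrate the toggle model deterministically
#'
#' Adaptive integration (lsoda) from a non-negative start. Convergence to a
#' fixed point is declared when the rate norm at the end time falls below
#' `conv_tol`; non-convergence is reported via the `converged` flag and a
#' warning, never silently truncated.
#'
#' @param model a [toggle_model()].
#' @param init numeric `c(x, y)` start, non-negative.
#' @param t_end end time (default 100).
#' @param dt_out output time step (default 0.1).
#' @param conv_tol rate-norm convergence tolerance (default 1e-8).
#' @return data.frame of class `toggle_trajectory` with columns `time`,
#'   `x`, `y`; attributes `converged` (logical) and `final` (c(x, y)).
#' @export
toggle_trajectory <- function(model, init, t_end = 100, dt_out = 0.1,
                              conv_tol = 1e-8) {
  if (any(init < 0)) stop("initial state must be non-negative")
  rhs <- function(t, state, parms) list(toggle_rates(state, model))
  out <- deSolve::ode(y = c(x = init[[1]], y = init[[2]]),
                      times = seq(0, t_end, by = dt_out), func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  df <- as.data.frame(out)
  final <- c(df$x[nrow(df)], df$y[nrow(df)])
  converged <- sqrt(sum(toggle_rates(final, model)^2)) < conv_tol
  if (!converged)
    warning("trajectory did not converge to a fixed point within t_end = ",
            t_end)
  structure(df, converged = converged, final = final,
            class = c("toggle_trajectory", "data.frame"))
}

#' Basin-of-attraction map
#'
#' Integrates the model from every grid start and labels it with the index
#' (row of [fixed_points()]' stable nodes) of the stable node it converges
#' to, within a distance tolerance. Unresolved starts get `NA`.
#'
#' @param model a [toggle_model()].
#' @param grid_x,grid_y numeric vectors of start coordinates (defaults: 21
#'   points over `[0, alpha]` on each axis).
#' @param t_end integration horizon per start.
#' @param match_tol distance tolerance for assigning a node (default 1e-4).
#' @return data.frame with `x0`, `y0`, `basin` (integer or `NA`); the
#'   stable-node table is attached as `attr(, "nodes")`.
#' @export
phase_map <- function(model, grid_x = NULL, grid_y = NULL, t_end = 200,
                      match_tol = 1e-4) {
  if (is.null(grid_x)) grid_x <- seq(0, model$alpha1, length.out = 21)
  if (is.null(grid_y)) grid_y <- seq(0, model$alpha2, length.out = 21)
  fp <- fixed_points(model)
  nodes <- fp[fp$class == "stable_node", , drop = FALSE]
  starts <- expand.grid(x0 = grid_x, y0 = grid_y)
  basin <- vapply(seq_len(nrow(starts)), function(i) {
    tr <- suppressWarnings(
      toggle_trajectory(model, c(starts$x0[i], starts$y0[i]), t_end = t_end))
    final <- attr(tr, "final")
    d <- sqrt((nodes$x - final[1])^2 + (nodes$y - final[2])^2)
    if (length(d) && min(d) < match_tol) which.min(d) else NA_integer_
  }, integer(1))
  structure(cbind(starts, basin = basin), nodes = nodes)
}

#' Plot nullclines, fixed points and (optionally) a trajectory
#'
#' @param x a [toggle_model()].
#' @param trajectory optional [toggle_trajectory()] to overlay.
#' @param xlim,ylim axis limits (defaults `[0, alpha]`).
#' @param ... passed to [plot()].
#' @export
plot.toggle_model <- function(x, trajectory = NULL, xlim = NULL, ylim = NULL,
                              ...) {
  model <- x
  if (is.null(xlim)) xlim <- c(0, model$alpha1 * 1.05)
  if (is.null(ylim)) ylim <- c(0, model$alpha2 * 1.05)
  xs <- seq(xlim[1], xlim[2], length.out = 300)
  ys <- seq(ylim[1], ylim[2], length.out = 300)
  plot(NA, xlim = xlim, ylim = ylim, xlab = "x", ylab = "y", ...)
  graphics::lines(xs, model$alpha2 / (1 + xs^model$beta2), col = "steelblue")
  graphics::lines(model$alpha1 / (1 + ys^model$beta1), ys, col = "firebrick")
  fp <- fixed_points(model)
  graphics::points(fp$x, fp$y, pch = ifelse(fp$class == "stable_node", 19, 1),
                   cex = 1.4)
  if (!is.null(trajectory))
    graphics::lines(trajectory$x, trajectory$y, lty = 2)
  invisible(model)
}

#' Stochastic toggle simulation (Euler-Maruyama)
#'
#' Additive-noise Euler-Maruyama integration with a reflecting boundary at
#' zero, as an extension linking the deterministic switch to rising
#' fluctuations (critical slowing down) near the bifurcation. Identical
#' seeds give identical ensembles.
#'
#' @param model a [toggle_model()].
#' @param noise_sd additive noise intensity.
#' @param n_steps number of Euler steps.
#' @param dt step size; must satisfy the explicit-scheme stability
#'   heuristic `dt <= 0.25` (linear relaxation rate 1).
#' @param seed optional integer seed.
#' @param init start state (default: the first stable node, or `(alpha1/2,
#'   alpha2/2)` if none).
#' @param n_paths ensemble size (default 1).
#' @return list of class `toggle_ensemble`: `time` (length `n_steps + 1`),
#'   `x` and `y` (matrices, steps x paths), plus the call parameters.
#' @export
stochastic_simulate <- function(model, noise_sd, n_steps, dt = 0.05,
                                seed = NULL, init = NULL, n_paths = 1) {
  if (dt > 0.25)
    stop("dt = ", dt, " too large for the explicit scheme (require dt <= 0.25)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    fp <- fixed_points(model)
    nodes <- fp[fp$class == "stable_node", ]
    init <- if (nrow(nodes)) c(nodes$x[1], nodes$y[1]) else
      c(model$alpha1 / 2, model$alpha2 / 2)
  }
  X <- matrix(init[[1]], n_steps + 1, n_paths)
  Y <- matrix(init[[2]], n_steps + 1, n_paths)
  sq <- noise_sd * sqrt(dt)
  for (s in seq_len(n_steps)) {
    x <- X[s, ]; y <- Y[s, ]
    dx <- (model$alpha1 / (1 + y^model$beta1) - x) * dt
    dy <- (model$alpha2 / (1 + x^model$beta2) - y) * dt
    if (noise_sd > 0) {
      dx <- dx + sq * stats::rnorm(n_paths)
      dy <- dy + sq * stats::rnorm(n_paths)
    }
    X[s + 1, ] <- abs(x + dx)   # reflecting boundary at 0
    Y[s + 1, ] <- abs(y + dy)
  }
  structure(list(time = (0:n_steps) * dt, x = X, y = Y,
                 noise_sd = noise_sd, dt = dt, seed = seed, init = init),
            class = "toggle_ensemble")
}

#' Simulate method for toggle models
#'
#' Convenience wrapper around [stochastic_simulate()] conforming to the
#' [stats::simulate()] generic: `nsim` paths of `n_steps` steps.
#'
#' @param object a [toggle_model()].
#' @param nsim ensemble size.
#' @param seed optional integer seed.
#' @param noise_sd,n_steps,dt,init see [stochastic_simulate()].
#' @param ... ignored.
#' @return a `toggle_ensemble`.
#' @export
simulate.toggle_model <- function(object, nsim = 1, seed = NULL,
                                  noise_sd = 0.05, n_steps = 1000,
                                  dt = 0.05, init = NULL, ...) {
  stochastic_simulate(object, noise_sd = noise_sd, n_steps = n_steps,
                      dt = dt, seed = seed, init = init, n_paths = nsim)
}

#' Stationary variance of a stochastic ensemble tail
#'
#' Pooled variance of `x` (and `y`) over the last `tail_frac` of every
#' path, a simple estimator of the stationary fluctuation size used to
#' demonstrate critical slowing down.
#'
#' @param ensemble a `toggle_ensemble`.
#' @param tail_frac fraction of each path treated as stationary (default
#'   0.5).
#' @return named numeric `c(var_x, var_y)`.
#' @export
stationary_variance <- function(ensemble, tail_frac = 0.5) {
  n <- nrow(ensemble$x)
  keep <- seq.int(ceiling(n * (1 - tail_frac)), n)
  c(var_x = stats::var(as.vector(ensemble$x[keep, ])),
    var_y = stats::var(as.vector(ensemble$y[keep, ])))
}
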