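# Choosing the cost-minimal per-capita incentive theta* subject to a
# minimum long-run cooperation frequency omega.
#
# The cost E(theta) is non-decreasing in theta for selection intensities up
# to a threshold beta*, and develops an interior local maximum theta1 and
# local minimum theta2 above it (a phase transition in beta). The decision
# procedure therefore compares E at the feasibility bound theta0(omega)
# with E at theta2 when the latter exists and is feasible.
#
# beta* and theta2 are located numerically: beta* by bisection on a
# monotonicity predicate over a dense theta grid, theta2 by bracketing sign
# changes of a central-difference derivative of E and refining with
# uniroot. The non-monotone region concentrates near -delta with width
# O(1/beta) (stationary points satisfy theta = log(u)/beta - delta with u
# an O(1) root), hence the scan window (0, -delta + 50/beta].

.scan_window <- function(game, N, beta, theta_max = NULL) {
  hi <- -payoff_delta(game, N) + 50 / beta
  if (!is.null(theta_max)) hi <- max(hi, theta_max)
  c(1e-6, hi)
}

#' Minimum incentive guaranteeing a cooperation frequency
#'
#' Inverting the closed form of the cooperation frequency gives the
#' smallest per-capita incentive ensuring a long-run cooperation frequency
#' of at least `omega`:
#' `theta0(omega) = log(omega/(1-omega)) / ((N-1) beta) - delta`.
#' At `omega = 0.5` this is exactly `-delta`.
#'
#' @inheritParams transition_probs
#' @param omega required minimum cooperation frequency, strictly in (0, 1).
#' @return The bound `theta0` (payoff units);
#'   `cooperation_frequency(theta0) == omega`.
#' @examples
#' theta_min(game_dg(1.8, 1), N = 3, beta = 1, omega = 0.7) # 2.3236
#' @export
theta_min <- function(game, N, beta, omega) {
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(beta, "beta", lower = 0, strict_lower = TRUE)
  .check_number(omega, "omega", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  log(omega / (1 - omega)) / ((N - 1) * beta) - payoff_delta(game, N)
}

#' Is the expected cost monotone in the incentive?
#'
#' Scans `E(theta)` on a dense grid over `(0, -delta + 50/beta]` (optionally
#' extended) and reports whether any decreasing segment exists, together
#' with the most negative grid derivative and its location. Monotonicity
#' holds exactly when `beta <= beta_star`.
#'
#' @inheritParams transition_probs
#' @param mode `"reward"` or `"punishment"`.
#' @param n_grid grid resolution (default 2000).
#' @param theta_max optional extension of the upper end of the scan window.
#' @return A list with `monotone` (logical), `min_derivative` and `argmin`
#'   (location of the most negative derivative).
#' @export
is_monotone <- function(game, N, beta, mode = c("reward", "punishment"),
                        n_grid = 2000L, theta_max = NULL) {
  mode <- .check_mode(mode)
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(beta, "beta", lower = 0, strict_lower = TRUE)
  w <- .scan_window(game, N, beta, theta_max)
  th <- seq(w[1], w[2], length.out = n_grid)
  E <- .cost_values(game, N, beta, th, mode)
  dE <- diff(E) / diff(th)
  k <- which.min(dE)
  # decreasing only if below the round-off floor of the E evaluations
  tol <- 1e-12 * max(abs(E), 1) / (th[2] - th[1])
  list(monotone = dE[k] >= -tol,
       min_derivative = dE[k],
       argmin = (th[k] + th[k + 1]) / 2)
}

#' Phase-transition threshold of the selection intensity
#'
#' The cost `E(theta)` is non-decreasing for all `beta <= beta_star` and
#' non-monotone above it. `beta_star` is located by bisection on the
#' monotonicity predicate, after doubling an upper bracket until a
#' non-monotone `beta` is found.
#'
#' @inheritParams is_monotone
#' @param tol relative bisection tolerance on `beta_star` (default 1e-4).
#' @return The threshold `beta_star` (units 1/payoff).
#' @examples
#' \donttest{
#' beta_star(game_dg(1.8, 1), N = 3, mode = "reward") # 5.752
#' }
#' @export
beta_star <- function(game, N, mode = c("reward", "punishment"),
                      tol = 1e-4, n_grid = 2000L) {
  mode <- .check_mode(mode)
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(tol, "tol", lower = 0, strict_lower = TRUE)
  lo <- 1e-3
  hi <- 1
  expand <- 0L
  while (is_monotone(game, N, hi, mode, n_grid = n_grid)$monotone) {
    hi <- hi * 2
    expand <- expand + 1L
    if (expand > 40L)
      stop("bracket expansion failed: E(theta) appears monotone for all ",
           "beta up to ", hi)
  }
  while ((hi - lo) / ((hi + lo) / 2) > tol) {
    mid <- (hi + lo) / 2
    if (is_monotone(game, N, mid, mode, n_grid = n_grid)$monotone)
      lo <- mid
    else
      hi <- mid
  }
  (hi + lo) / 2
}

# Central-difference derivative of E with relative step.
.cost_deriv <- function(game, N, beta, theta, mode) {
  h <- pmax(1e-6, 1e-4 * theta)
  (.cost_values(game, N, beta, theta + h, mode) -
     .cost_values(game, N, beta, pmax(theta - h, 1e-9), mode)) / (2 * h)
}

# All stationary points of E on the scan window: brackets where the grid
# derivative changes sign, refined by uniroot on the central-difference
# derivative. Returns a numeric vector (possibly empty), increasing.
.stationary_points <- function(game, N, beta, mode, n_grid = 2000L,
                               theta_max = NULL) {
  w <- .scan_window(game, N, beta, theta_max)
  th <- seq(w[1], w[2], length.out = n_grid)
  E <- .cost_values(game, N, beta, th, mode)
  dE <- diff(E)
  flip <- which(dE[-length(dE)] * dE[-1] < 0)
  roots <- vapply(flip, function(k) {
    uniroot(function(t) .cost_deriv(game, N, beta, t, mode),
            lower = th[k], upper = th[k + 2], tol = 1e-6)$root
  }, numeric(1))
  sort(roots)
}

#' Largest stationary point of the expected cost
#'
#' Above the phase transition `E(theta)` rises to a local maximum `theta1`,
#' falls to a local minimum `theta2`, then rises again; `theta2` is the
#' candidate interior optimum. Returns `NA` when no stationary point exists
#' (i.e. `beta <= beta_star`). The returned value carries the full set of
#' stationary points as attribute `"stationary_points"`; a warning is
#' issued if more than two are found (guaranteed exactly two only for
#' moderate population sizes, checked numerically up to N = 100).
#'
#' @inheritParams is_monotone
#' @return `theta2` (payoff units), or `NA_real_` below the transition.
#' @examples
#' \donttest{
#' theta_two(game_dg(1.8, 1), N = 3, beta = 10, mode = "reward") # 2.16
#' }
#' @export
theta_two <- function(game, N, beta, mode = c("reward", "punishment"),
                      n_grid = 2000L, theta_max = NULL) {
  mode <- .check_mode(mode)
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(beta, "beta", lower = 0, strict_lower = TRUE)
  pts <- .stationary_points(game, N, beta, mode, n_grid, theta_max)
  if (length(pts) == 0L)
    return(structure(NA_real_, stationary_points = numeric(0)))
  if (length(pts) > 2L)
    warning("E(theta) has ", length(pts), " stationary points; using the ",
            "largest (two-sign-change structure verified only for N <= 100)",
            call. = FALSE)
  structure(max(pts), stationary_points = pts)
}

#' Cost-minimal incentive guaranteeing a cooperation level
#'
#' Solves `min E(theta)` over `theta >= theta0(omega)` by the
#' phase-transition decision procedure:
#' below the threshold (`beta <= beta_star`) the cost is non-decreasing so
#' `theta* = theta0`; above it, the interior local minimum `theta2` wins
#' exactly when it is feasible (`theta2 > theta0`) and cheaper
#' (`E(theta2) < E(theta0)`; ties go to `theta0`).
#'
#' @inheritParams is_monotone
#' @param omega required minimum cooperation frequency, strictly in (0, 1).
#' @param bstar optionally, a precomputed [beta_star()] value to reuse
#'   across calls (e.g. in an omega sweep); `NULL` recomputes it.
#' @return An object of class `"optimization_result"`: a list with
#'   `theta0`, `beta_star`, `theta2` (`NA` below the transition),
#'   `theta_star`, `cost_at_optimum`, and `branch` (one of
#'   `"theta0_below_threshold"`, `"theta0_wins"`, `"theta2_wins"`,
#'   `"theta2_below_theta0"`).
#' @examples
#' \donttest{
#' optimize_incentive(game_dg(1.8, 1), N = 3, beta = 10,
#'                    mode = "reward", omega = 0.7) # theta* = theta2 = 2.16
#' }
#' @export
optimize_incentive <- function(game, N, beta,
                               mode = c("reward", "punishment"), omega,
                               n_grid = 2000L, bstar = NULL) {
  mode <- .check_mode(mode)
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(beta, "beta", lower = 0, strict_lower = TRUE)
  theta0 <- theta_min(game, N, beta, omega)
  above_n0 <- N > 100L
  if (above_n0)
    warning("N > 100: the exactly-two-stationary-points structure is ",
            "verified numerically only up to N = 100", call. = FALSE)
  if (is.null(bstar)) bstar <- beta_star(game, N, mode, n_grid = n_grid)
  if (beta <= bstar) {
    theta2 <- NA_real_
    theta_star <- theta0
    branch <- "theta0_below_threshold"
  } else {
    theta2 <- as.numeric(theta_two(game, N, beta, mode, n_grid = n_grid,
                                   theta_max = 2 * theta0))
    if (is.na(theta2) || theta2 <= theta0) {
      theta_star <- theta0
      branch <- "theta2_below_theta0"
    } else {
      E0 <- .cost_values(game, N, beta, theta0, mode)
      E2 <- .cost_values(game, N, beta, theta2, mode)
      if (E0 <= E2) {
        theta_star <- theta0
        branch <- "theta0_wins"
      } else {
        theta_star <- theta2
        branch <- "theta2_wins"
      }
    }
  }
  structure(list(
    game = game, N = N, beta = beta, mode = mode, omega = omega,
    theta0 = theta0, beta_star = bstar, theta2 = theta2,
    theta_star = theta_star,
    cost_at_optimum = .cost_values(game, N, beta, theta_star, mode),
    branch = branch, above_N0 = above_n0
  ), class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("Optimal %s incentive (N = %d, beta = %g, omega = %g):\n",
              x$mode, x$N, x$beta, x$omega))
  cat(sprintf("  theta0 = %.6g, beta* = %.4g, theta2 = %s\n",
              x$theta0, x$beta_star,
              if (is.na(x$theta2)) "absent" else sprintf("%.6g", x$theta2)))
  cat(sprintf("  theta* = %.6g with E(theta*) = %.6g  [branch: %s]\n",
              x$theta_star, x$cost_at_optimum, x$branch))
  invisible(x)
}

#' Cost difference between reward and punishment
#'
#' `Er(theta) - Ep(theta)`, computed from the shared visit profile: the two
#' schemes drive identical dynamics and differ only in the per-state
#' spending weight, so the difference is
#' `theta * sum_i v_i (2i - N)`. It is negative for `theta < -delta`
#' (reward cheaper), zero at `theta = -delta`, positive above.
#'
#' @inheritParams transition_probs
#' @return The signed difference (payoff units).
#' @export
compare_schemes <- function(game, N, beta, theta) {
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(beta, "beta", lower = 0)
  .check_number(theta, "theta", lower = 0)
  v <- drop(.visit_matrix(game, N, beta, theta))
  i <- seq_len(N - 1L)
  theta * sum(v * (2 * i - N))
}
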