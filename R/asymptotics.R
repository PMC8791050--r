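# Closed-form bounds and limits of the expected incentive cost: finite-N
# sandwich bounds, the infinite-population ratio limit, and the weak- and
# strong-selection limits. These double as convergence oracles for the
# fundamental-matrix computation.

# Euler-Mascheroni constant, 16 significant digits.
.EULER_GAMMA <- 0.57721566490153286

#' Harmonic number H_N
#'
#' `H_N = sum_{j=1}^{N-1} 1/j`, the quantity that sets the leading scale
#' `N^2 H_N theta` of the expected incentive cost.
#'
#' @param N population size (integer >= 2).
#' @return The partial harmonic sum up to `N - 1`.
#' @examples
#' harmonic_number(3) # 1.5
#' @export
harmonic_number <- function(N) {
  N <- .check_count(N, "N", lower = 2L)
  sum(1 / seq_len(N - 1L))
}

#' Finite-population sandwich bounds on the expected cost
#'
#' For every population size `N`, selection intensity and game, the expected
#' total cost satisfies
#' `N^2 theta / 2 * (H_N + 1/(N-1)) <= E(theta) <= N (N-1) theta (H_N + 1)`.
#'
#' @param N population size (integer >= 3).
#' @param theta per-capita incentive (>= 0).
#' @return Named vector `c(lower, upper)` in payoff units.
#' @examples
#' finite_bounds(3, 1) # c(9, 15)
#' @export
finite_bounds <- function(N, theta) {
  N <- .check_count(N, "N", lower = 3L)
  .check_number(theta, "theta", lower = 0)
  H <- harmonic_number(N)
  c(lower = N^2 * theta / 2 * (H + 1 / (N - 1)),
    upper = N * (N - 1) * theta * (H + 1))
}

#' Normalizer for the infinite-population limit
#'
#' The scale `N^2 theta / 2 * (log N + gamma)` against which `E(theta)` is
#' compared in the large-`N` limit (`gamma` is the Euler-Mascheroni
#' constant). Plotting `E / largeN_normalizer` against `N` converges to the
#' [largeN_ratio_limit()] constant.
#'
#' @inheritParams finite_bounds
#' @return The normalizing value (payoff units).
#' @export
largeN_normalizer <- function(N, theta) {
  N <- .check_count(N, "N", lower = 2L)
  .check_number(theta, "theta", lower = 0)
  N^2 * theta / 2 * (log(N) + .EULER_GAMMA)
}

#' Infinite-population limit constant of the cost ratio
#'
#' As `N -> Inf`, `E(theta) / (N^2 theta / 2 (log N + gamma))` tends to
#' `1 + exp(-beta |theta + delta_inf|)` where `delta_inf` is the
#' large-population payoff difference: `-c` for the Donation game and
#' `-c (1 - r/n)` for the Public Goods game. The approach is slow, of order
#' `1 / log N`.
#'
#' @param game a [game_dg()] or [game_pgg()] specification.
#' @param beta intensity of selection (> 0).
#' @param theta per-capita incentive (>= 0).
#' @return The dimensionless limit constant, in (1, 2].
#' @examples
#' largeN_ratio_limit(game_dg(2, 1), beta = 1, theta = 1) # 2: theta = c
#' @export
largeN_ratio_limit <- function(game, beta, theta) {
  .check_game(game)
  .check_number(beta, "beta", lower = 0, strict_lower = TRUE)
  .check_number(theta, "theta", lower = 0)
  delta_inf <- if (game$kind == "DG") -game$c else
    -game$c * (1 - game$r / game$n)
  1 + exp(-beta * abs(theta + delta_inf))
}

#' Weak-selection limit of the expected cost
#'
#' As `beta -> 0` the chain becomes the neutral drift chain and
#' `E(theta) -> N^2 theta H_N`, identically for reward and punishment.
#'
#' @inheritParams finite_bounds
#' @return The limit value (payoff units).
#' @examples
#' weak_selection_limit(3, 1) # 13.5
#' @export
weak_selection_limit <- function(N, theta) {
  N <- .check_count(N, "N", lower = 3L)
  .check_number(theta, "theta", lower = 0)
  N^2 * theta * harmonic_number(N)
}

#' Strong-selection limit of the expected cost
#'
#' As `beta -> Inf` the cost tends to a piecewise-linear function of `theta`
#' with an exact three-way branch at `theta = -delta` (the incentive that
#' exactly neutralises the defector advantage):
#'
#' * reward: `N^2 theta / 2 * (1/(N-1) + H_N)` below, `N^2 theta H_N` at,
#'   `N^2 theta / 2 * (1 + H_N)` above `-delta`;
#' * punishment: the mirror image, `N^2 theta / 2 * (1 + H_N)` below and
#'   `N^2 theta / 2 * (H_N + 1/(N-1))` above.
#'
#' The branch is selected by exact floating-point comparison with `-delta`;
#' pass `theta = -delta` literally to obtain the knife-edge value.
#'
#' @inheritParams finite_bounds
#' @param delta the (negative) composition-independent payoff difference,
#'   e.g. from [payoff_delta()].
#' @param mode `"reward"` or `"punishment"`.
#' @return The limit value (payoff units).
#' @export
strong_selection_limit <- function(N, theta, delta,
                                   mode = c("reward", "punishment")) {
  mode <- .check_mode(mode)
  N <- .check_count(N, "N", lower = 3L)
  .check_number(theta, "theta", lower = 0)
  .check_number(delta, "delta", upper = 0, strict_upper = TRUE)
  H <- harmonic_number(N)
  if (theta == -delta) return(N^2 * theta * H)
  below <- theta < -delta
  if (mode == "reward") {
    if (below) N^2 * theta / 2 * (1 / (N - 1) + H)
    else       N^2 * theta / 2 * (1 + H)
  } else {
    if (below) N^2 * theta / 2 * (1 + H)
    else       N^2 * theta / 2 * (H + 1 / (N - 1))
  }
}

#' All closed-form bounds and limits for one parameter set
#'
#' Convenience bundle of [harmonic_number()], [finite_bounds()],
#' [largeN_ratio_limit()], [weak_selection_limit()] and
#' [strong_selection_limit()] for the given game, `N`, `beta` and `theta`.
#'
#' @inheritParams largeN_ratio_limit
#' @param N population size (integer >= 3).
#' @return An object of class `"limit_report"` (a list; serialise with
#'   [jsonlite::toJSON()] or [write_run()]).
#' @export
limit_report <- function(game, N, beta, theta) {
  N <- .check_game_N(game, N, min_N = 3L)
  d <- payoff_delta(game, N)
  b <- finite_bounds(N, theta)
  structure(list(
    game = game, N = N, beta = beta, theta = theta, delta = d,
    harmonic = harmonic_number(N),
    lower_bound = unname(b["lower"]),
    upper_bound = unname(b["upper"]),
    largeN_ratio = largeN_ratio_limit(game, beta, theta),
    largeN_normalizer = largeN_normalizer(N, theta),
    weak_limit = weak_selection_limit(N, theta),
    strong_limit_reward = strong_selection_limit(N, theta, d, "reward"),
    strong_limit_punishment = strong_selection_limit(N, theta, d, "punishment")
  ), class = "limit_report")
}

#' @export
print.limit_report <- function(x, ...) {
  cat(sprintf("Cost bounds and limits (N = %d, beta = %g, theta = %g):\n",
              x$N, x$beta, x$theta))
  cat(sprintf("  H_N = %.6g, delta = %.6g\n", x$harmonic, x$delta))
  cat(sprintf("  finite-N bounds: [%.6g, %.6g]\n", x$lower_bound,
              x$upper_bound))
  cat(sprintf("  weak-selection limit:  %.6g\n", x$weak_limit))
  cat(sprintf("  strong-selection limit: reward %.6g, punishment %.6g\n",
              x$strong_limit_reward, x$strong_limit_punishment))
  cat(sprintf("  large-N ratio limit: %.6g (normalizer %.6g)\n",
              x$largeN_ratio, x$largeN_normalizer))
  invisible(x)
}
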