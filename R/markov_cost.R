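# Absorbing birth-death chain over cooperator counts 0..N under a per-capita
# incentive theta, and the expected total incentive cost obtained from its
# fundamental matrix.
#
# The chain moves i -> i +/- 1 with probability
#   u_{i,i+/-1} = (N-i)/N * i/N * (1 + exp(-/+ beta (delta + theta)))^{-1},
# so the Fermi bias depends on the state only through the composition factor
# i(N-i)/N^2: the shifted payoff difference delta + theta is constant. Both
# reward and punishment produce the same dynamics (a reward +theta to
# cooperators shifts the imitation argument exactly as a punishment -theta
# to defectors); they differ only in the per-state spending weight.

# Saturating logistic factors: plogis never exponentiates a large positive
# argument, so beta up to 1e3 and beyond is safe.
.fermi_up <- function(beta, x) plogis(beta * x)
.fermi_dn <- function(beta, x) plogis(-beta * x)

#' One-step transition probabilities of the incentive chain
#'
#' Probabilities of losing one cooperator, staying, and gaining one
#' cooperator in a single pairwise-comparison update, at state `i` (number
#' of cooperators) under per-capita incentive `theta`. Jumps of two or more
#' are impossible.
#'
#' @inheritParams payoff_cooperator
#' @param beta intensity of selection (>= 0, units 1/payoff).
#' @param theta per-capita incentive (payoff units, >= 0).
#' @param i a single transient state index in `1..N-1`.
#' @return Named numeric vector `c(down, stay, up)` summing to 1.
#' @examples
#' g <- game_dg(1.8, 1)
#' transition_probs(g, N = 3, beta = 2, theta = 1.9, i = 1) # (1/9, 7/9, 1/9)
#' @export
transition_probs <- function(game, N, beta, theta, i) {
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(beta, "beta", lower = 0)
  .check_number(theta, "theta", lower = 0)
  i <- .check_states(i, N)
  if (length(i) != 1L) .invalid("i must be a single state index")
  x <- payoff_delta(game, N) + theta
  g <- i * (N - i) / N^2
  up <- g * .fermi_up(beta, x)
  down <- g * .fermi_dn(beta, x)
  c(down = down, stay = 1 - up - down, up = up)
}

# Expected sojourn counts v_i = (n_{1,i} + n_{N-1,i})/2 for a vector of
# theta values at once: rows 1 and N-1 of the fundamental matrix
# (I - U)^{-1} are obtained by solving (I - U)^T y = e_1 and e_{N-1} with a
# Thomas (LU, no pivoting) sweep. I - U is strictly diagonally dominant at
# the boundary rows and weakly inside, so the sweep is stable. The sweeps
# are vectorised across the theta grid (columns), which is what makes the
# optimizer's dense scans cheap.
#
# Returns an (N-1) x length(thetas) matrix of visit counts. The fundamental
# matrix counts the starting state as one visit (standard convention; pinned
# empirically by the worked cost values it reproduces).
.visit_matrix <- function(game, N, beta, thetas) {
  m <- N - 1L
  i <- seq_len(m)
  g <- i * (N - i) / N^2
  x <- payoff_delta(game, N) + thetas
  up <- outer(g, .fermi_up(beta, x))   # m x T
  dn <- outer(g, .fermi_dn(beta, x))
  dg <- up + dn                        # diagonal of A = I - U
  # A^T is tridiagonal with sub-diagonal -up[k-1,] and super-diagonal
  # -dn[k+1,]. Forward elimination shared by both right-hand sides.
  Tn <- length(thetas)
  cp <- matrix(0, m, Tn)
  d1 <- matrix(0, m, Tn)  # rhs e_1
  dm <- matrix(0, m, Tn)  # rhs e_{N-1}
  cp[1L, ] <- -dn[2L, ] / dg[1L, ]
  d1[1L, ] <- 1 / dg[1L, ]
  for (k in 2:m) {
    den <- dg[k, ] + up[k - 1L, ] * cp[k - 1L, ]
    if (k < m) cp[k, ] <- -dn[k + 1L, ] / den
    d1[k, ] <- (up[k - 1L, ] * d1[k - 1L, ]) / den
    dm[k, ] <- ((if (k == m) 1 else 0) + up[k - 1L, ] * dm[k - 1L, ]) / den
  }
  r1 <- d1
  rm <- dm
  for (k in (m - 1L):1L) {
    r1[k, ] <- d1[k, ] - cp[k, ] * r1[k + 1L, ]
    rm[k, ] <- dm[k, ] - cp[k, ] * rm[k + 1L, ]
  }
  v <- (r1 + rm) / 2
  if (any(!is.finite(v)) || any(v <= 0))
    stop("fundamental-matrix solve produced non-positive or non-finite ",
         "visit counts; invalid transition structure")
  v
}

# Bare cost values theta * sum_i w_i v_i(theta), vectorised over theta.
# Internal fast path used by the optimizer, sweeps and tests.
.cost_values <- function(game, N, beta, thetas, mode) {
  i <- seq_len(N - 1L)
  w <- if (mode == "reward") i else N - i
  v <- .visit_matrix(game, N, beta, thetas)
  as.numeric(thetas * colSums(w * v))
}

#' Expected number of visits to each transient state
#'
#' Expected sojourn counts `v_i = (n_{1,i} + n_{N-1,i}) / 2` of the
#' incentive chain, where `n_{k,i}` are fundamental-matrix entries and the
#' average reflects a mutant arising at either monomorphic end with equal
#' probability. Computed by a tridiagonal solve in O(N).
#'
#' @inheritParams transition_probs
#' @return Numeric vector of length `N - 1` of strictly positive expected
#'   visit counts (state `i` = `i` cooperators).
#' @examples
#' expected_visits(game_dg(1.8, 1), N = 3, beta = 5, theta = 1.9) # (4.5, 4.5)
#' @export
expected_visits <- function(game, N, beta, theta) {
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(beta, "beta", lower = 0)
  .check_number(theta, "theta", lower = 0)
  drop(.visit_matrix(game, N, beta, theta))
}

#' Expected total cost of institutional reward or punishment
#'
#' The institution spends `theta * i` per update when rewarding the `i`
#' cooperators present, or `theta * (N - i)` when punishing the defectors.
#' Accumulated over the expected sojourns of the chain started from a single
#' mutant (at either end, with probability 1/2 each) until absorption, the
#' expected total cost is
#' `E(theta) = theta/2 * sum_i (n_{1,i} + n_{N-1,i}) * w_i`
#' with weight `w_i = i` (reward) or `N - i` (punishment).
#'
#' `beta = 0` is admitted solely for checking the weak-selection limit
#' `N^2 theta H_N`; optimization refuses it.
#'
#' @inheritParams transition_probs
#' @param mode `"reward"` or `"punishment"`.
#' @return An object of class `"cost_result"`: a list with `expected_cost`,
#'   the `visits` profile, and the call parameters.
#' @examples
#' g <- game_dg(1.8, 1)
#' expected_cost(g, N = 3, beta = 10, theta = 2.16, mode = "reward")
#' @export
expected_cost <- function(game, N, beta, theta,
                          mode = c("reward", "punishment")) {
  mode <- .check_mode(mode)
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(beta, "beta", lower = 0)
  .check_number(theta, "theta", lower = 0)
  v <- drop(.visit_matrix(game, N, beta, theta))
  i <- seq_len(N - 1L)
  w <- if (mode == "reward") i else N - i
  structure(list(
    game = game, N = N, beta = beta, theta = theta, mode = mode,
    expected_cost = theta * sum(w * v), visits = v
  ), class = "cost_result")
}

#' @export
print.cost_result <- function(x, ...) {
  cat(sprintf(
    "Expected total %s cost E(theta = %g) = %.6g  (N = %d, beta = %g)\n",
    x$mode, x$theta, x$expected_cost, x$N, x$beta))
  invisible(x)
}

.logsumexp <- function(v) {
  M <- max(v)
  M + log(sum(exp(v - M)))
}

#' Fixation probabilities of a single mutant
#'
#' `rho_DC` is the probability that one cooperator arising in a defector
#' population takes over; `rho_CD` the reverse. Both follow from the
#' classical ratio-of-transition-rates formula for birth-death chains; the
#' per-state products are accumulated in the log domain so that large
#' `beta` cannot overflow. At `beta = 0` both equal `1/N`.
#'
#' @inheritParams transition_probs
#' @return Named numeric vector `c(rho_DC, rho_CD)`, both in (0, 1).
#' @examples
#' fixation_probabilities(game_dg(1.8, 1), N = 3, beta = 0, theta = 0) # 1/3, 1/3
#' @export
fixation_probabilities <- function(game, N, beta, theta) {
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(beta, "beta", lower = 0)
  .check_number(theta, "theta", lower = 0)
  k <- seq_len(N - 1L)
  a <- beta * (payoff_cooperator(game, N, k) - payoff_defector(game, N, k) +
                 theta)
  # T-(k)/T+(k) = exp(-a_k) for the cooperator-count chain; the chain seen
  # by a defector mutant at k defectors has ratio exp(+a_{N-k}).
  rho_dc <- exp(-.logsumexp(c(0, cumsum(-a))))
  rho_cd <- exp(-.logsumexp(c(0, cumsum(rev(a)))))
  c(rho_DC = rho_dc, rho_CD = rho_cd)
}

#' Long-run frequency of cooperation
#'
#' In the small-mutation limit the population hops between the two
#' monomorphic states with rates given by the fixation probabilities, and
#' the stationary frequency of full cooperation is
#' `rho_DC / (rho_DC + rho_CD)`. The ratio telescopes to
#' `exp(beta (N-1) (delta + theta))`, giving the closed logistic form used
#' here.
#'
#' @inheritParams transition_probs
#' @return A frequency in (0, 1).
#' @examples
#' cooperation_frequency(game_dg(1.8, 1), N = 3, beta = 10, theta = 1.9) # 0.5
#' @export
cooperation_frequency <- function(game, N, beta, theta) {
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(beta, "beta", lower = 0)
  .check_number(theta, "theta", lower = 0)
  plogis(beta * (N - 1) * (payoff_delta(game, N) + theta))
}
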