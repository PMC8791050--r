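# Cooperation dilemmas: the Donation game (DG) and the Public Goods game
# (PGG). Both share the property that the average payoff advantage of a
# defector over a cooperator is the same in every population composition,
# which is what makes the incentive-cost chain tridiagonal with a
# state-independent Fermi bias.

#' Donation game specification
#'
#' In the Donation game a cooperator pays a cost `c` to confer a benefit
#' `b > c` on its co-player; a defector pays nothing and confers nothing.
#' It is the special case of the Prisoner's Dilemma in which the payoff
#' difference between a cooperator and a defector does not depend on the
#' population composition.
#'
#' @param b benefit of cooperation received by the co-player (payoff units);
#'   must exceed `c`.
#' @param c cost of cooperation (payoff units, > 0).
#' @return An object of class `"game_spec"`.
#' @examples
#' g <- game_dg(b = 1.8, c = 1)
#' payoff_delta(g, N = 3) # -1.9
#' @seealso [game_pgg()], [payoff_delta()]
#' @export
game_dg <- function(b, c) {
  .check_number(c, "c", lower = 0, strict_lower = TRUE)
  .check_number(b, "b", lower = c, strict_lower = TRUE)
  structure(list(kind = "DG", b = b, c = c), class = "game_spec")
}

#' Public Goods game specification
#'
#' Players interact in groups of size `n` sampled from the population.
#' Cooperators contribute `c` to a common pool; the pool is multiplied by
#' `r` and shared equally among all `n` group members. The dilemma condition
#' is `1 < r < n`.
#'
#' @param c individual contribution (payoff units, > 0).
#' @param r multiplication factor of the pool, `1 < r < n`.
#' @param n group size (integer >= 2, at most the population size `N` when
#'   payoffs are evaluated).
#' @return An object of class `"game_spec"`.
#' @examples
#' g <- game_pgg(c = 1, r = 3, n = 5)
#' payoff_delta(g, N = 50) # -110/245
#' @export
game_pgg <- function(c, r, n) {
  .check_number(c, "c", lower = 0, strict_lower = TRUE)
  n <- .check_count(n, "n", lower = 2L)
  .check_number(r, "r", lower = 1, upper = n,
                strict_lower = TRUE, strict_upper = TRUE)
  structure(list(kind = "PGG", c = c, r = r, n = n), class = "game_spec")
}

#' @export
print.game_spec <- function(x, ...) {
  if (x$kind == "DG") {
    cat(sprintf("Donation game: b = %g, c = %g\n", x$b, x$c))
  } else {
    cat(sprintf("Public Goods game: c = %g, r = %g, n = %d\n", x$c, x$r, x$n))
  }
  invisible(x)
}

.check_game <- function(game) {
  if (!inherits(game, "game_spec"))
    .invalid("game must be a game_spec (see game_dg(), game_pgg())")
  invisible(game)
}

.check_game_N <- function(game, N, min_N = 2L) {
  .check_game(game)
  N <- .check_count(N, "N", lower = min_N)
  if (game$kind == "PGG" && game$n > N)
    .invalid("PGG group size n = ", game$n, " exceeds population size N = ", N)
  N
}

.check_states <- function(i, N) {
  if (!is.numeric(i) || length(i) < 1L || any(!is.finite(i)) ||
      any(i != round(i)))
    .invalid("i must be integer state indices")
  if (any(i < 1L) || any(i > N - 1L))
    .invalid("i must lie in 1..N-1 (transient cooperator counts)")
  as.integer(i)
}

#' Average payoff of a cooperator
#'
#' Average payoff of a cooperator in a well-mixed population of size `N`
#' containing `i` cooperators and `N - i` defectors. For the Donation game
#' this is `((i-1)(b-c) + (N-i)(-c)) / (N-1)`; for the Public Goods game the
#' hypergeometric average over group compositions collapses to the closed
#' form `(rc/n) (1 + (i-1)(n-1)/(N-1)) - c`.
#'
#' @param game a [game_dg()] or [game_pgg()] specification.
#' @param N population size (integer >= 2; >= `n` for the PGG).
#' @param i cooperator count(s), each in `1..N-1`; vectorised.
#' @return Average payoff(s), same length as `i`.
#' @examples
#' payoff_cooperator(game_dg(1.8, 1), N = 3, i = 2) # -0.1
#' @export
payoff_cooperator <- function(game, N, i) {
  N <- .check_game_N(game, N)
  i <- .check_states(i, N)
  if (game$kind == "DG") {
    ((i - 1) * (game$b - game$c) + (N - i) * (-game$c)) / (N - 1)
  } else {
    game$r * game$c / game$n * (1 + (i - 1) * (game$n - 1) / (N - 1)) - game$c
  }
}

#' Average payoff of a defector
#'
#' Counterpart of [payoff_cooperator()]: `i b / (N-1)` for the Donation game
#' and `r c (n-1) i / (n (N-1))` for the Public Goods game.
#'
#' @inheritParams payoff_cooperator
#' @return Average payoff(s), same length as `i`.
#' @export
payoff_defector <- function(game, N, i) {
  N <- .check_game_N(game, N)
  i <- .check_states(i, N)
  if (game$kind == "DG") {
    i * game$b / (N - 1)
  } else {
    game$r * game$c * (game$n - 1) * i / (game$n * (N - 1))
  }
}

#' Composition-independent payoff difference delta
#'
#' The difference `delta = payoff_cooperator(i) - payoff_defector(i)` is the
#' same for every cooperator count `i` in these two games, and is always
#' negative (the defining property of a cooperation dilemma). It equals
#' `-(c + b/(N-1))` for the Donation game and
#' `-c (1 - r(N-n) / (n(N-1)))` for the Public Goods game.
#'
#' @inheritParams payoff_cooperator
#' @return A single negative number (payoff units).
#' @examples
#' payoff_delta(game_dg(1.8, 1), N = 3)  # -1.9
#' payoff_delta(game_dg(1.8, 1), N = 50) # -1.03673...
#' @export
payoff_delta <- function(game, N) {
  N <- .check_game_N(game, N)
  if (N == 2L)
    warning("N = 2 is degenerate for the full cost pipeline (single ",
            "transient state); game-level quantities only", call. = FALSE)
  if (game$kind == "DG") {
    -(game$c + game$b / (N - 1))
  } else {
    -game$c * (1 - game$r * (N - game$n) / (game$n * (N - 1)))
  }
}

# Explicit hypergeometric-sum forms of the PGG average payoffs. Test oracle
# for the closed forms above; choose() returns 0 for impossible group
# compositions, which keeps the sums well defined for i < n.
.pgg_sum_cooperator <- function(game, N, i) {
  j <- 0:(game$n - 1)
  vapply(i, function(ii) {
    sum(choose(ii - 1, j) * choose(N - ii, game$n - 1 - j) /
          choose(N - 1, game$n - 1) *
          ((j + 1) * game$r * game$c / game$n - game$c))
  }, numeric(1))
}

.pgg_sum_defector <- function(game, N, i) {
  j <- 0:(game$n - 1)
  vapply(i, function(ii) {
    sum(choose(ii, j) * choose(N - 1 - ii, game$n - 1 - j) /
          choose(N - 1, game$n - 1) * j * game$r * game$c / game$n)
  }, numeric(1))
}
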