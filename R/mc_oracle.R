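# Seeded Monte Carlo simulation of the incentive chain. This is the
# independent validation route for the fundamental-matrix computation: each
# replicate walks the birth-death chain step by step (self-loops simulated
# explicitly, so sojourn counts follow the same convention as the
# fundamental matrix, which counts the starting state) and accumulates the
# per-step spending theta * i (reward) or theta * (N - i) (punishment)
# until absorption.

# Walk `replicates` chains to absorption, vectorised across replicates.
# start: integer vector of starting states (length replicates).
# Returns list(counts = replicates x (N-1) sojourn matrix or NULL,
#              fixed_at_N = logical vector).
.walk_chain <- function(game, N, beta, theta, start, record_visits = TRUE) {
  m <- N - 1L
  i <- seq_len(m)
  x <- payoff_delta(game, N) + theta
  g <- i * (N - i) / N^2
  p_up <- g * .fermi_up(beta, x)
  p_dn <- g * .fermi_dn(beta, x)
  R <- length(start)
  states <- as.integer(start)
  counts <- if (record_visits) matrix(0L, R, m) else NULL
  fixed <- logical(R)
  act <- seq_len(R)
  while (length(act)) {
    s <- states[act]
    if (record_visits)
      counts[cbind(act, s)] <- counts[cbind(act, s)] + 1L
    u <- runif(length(act))
    go_dn <- u < p_dn[s]
    go_up <- !go_dn & u < p_dn[s] + p_up[s]
    s2 <- s - as.integer(go_dn) + as.integer(go_up)
    states[act] <- s2
    done <- s2 == 0L | s2 == N
    fixed[act[done & s2 == N]] <- TRUE
    act <- act[!done]
  }
  list(counts = counts, fixed_at_N = fixed)
}

.start_states <- function(start_rule, N, replicates) {
  switch(start_rule,
         half_half = sample(c(1L, N - 1L), replicates, replace = TRUE),
         S1 = rep(1L, replicates),
         SN1 = rep(N - 1L, replicates),
         .invalid("unknown start rule"))
}

#' Simulate the incentive chain and its total cost
#'
#' Monte Carlo counterpart of [expected_cost()]: `replicates` independent
#' walks of the chain from a single mutant (by default arising at either
#' monomorphic end with probability 1/2, matching the analytic visit
#' convention), each accumulating one cost increment per step, including at
#' the initial state. Bit-reproducible for a fixed `seed`.
#'
#' @inheritParams expected_cost
#' @param replicates number of independent replicates (>= 2 so a standard
#'   error is defined).
#' @param seed integer RNG seed, recorded in the result.
#' @param start_rule `"half_half"` (mutant at state 1 or `N - 1` with equal
#'   probability), `"S1"`, or `"SN1"`.
#' @return An object of class `"sim_result"`: mean total cost and standard
#'   error, per-state mean sojourn counts with standard errors, the
#'   proportion of replicates absorbed at full cooperation, and the
#'   configuration (replicates, seed, start rule).
#' @examples
#' g <- game_dg(1.8, 1)
#' s <- simulate_cost(g, N = 3, beta = 1, theta = 1.9, mode = "reward",
#'                    replicates = 1000, seed = 7)
#' s$mean_cost # near 13.5 * 1.9
#' @export
simulate_cost <- function(game, N, beta, theta,
                          mode = c("reward", "punishment"),
                          replicates = 10000L, seed = 1L,
                          start_rule = c("half_half", "S1", "SN1")) {
  mode <- .check_mode(mode)
  start_rule <- match.arg(start_rule)
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(beta, "beta", lower = 0)
  .check_number(theta, "theta", lower = 0)
  replicates <- .check_count(replicates, "replicates", lower = 2L)
  seed <- .check_count(seed, "seed", lower = -.Machine$integer.max)
  set.seed(seed)
  start <- .start_states(start_rule, N, replicates)
  walk <- .walk_chain(game, N, beta, theta, start, record_visits = TRUE)
  i <- seq_len(N - 1L)
  w <- if (mode == "reward") i else N - i
  cost_per_rep <- theta * as.numeric(walk$counts %*% w)
  visit_means <- colMeans(walk$counts)
  visit_sd <- sqrt(pmax(colMeans(walk$counts^2) - visit_means^2, 0) *
                     replicates / (replicates - 1))
  p_fix <- mean(walk$fixed_at_N)
  structure(list(
    game = game, N = N, beta = beta, theta = theta, mode = mode,
    mean_cost = mean(cost_per_rep),
    se_cost = sd(cost_per_rep) / sqrt(replicates),
    visit_means = visit_means,
    visit_se = visit_sd / sqrt(replicates),
    fixation_estimate = p_fix,
    fixation_se = sqrt(p_fix * (1 - p_fix) / replicates),
    replicates = replicates, seed = seed, start_rule = start_rule
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "Simulated %s cost: %.4f +/- %.4f (SE), %d replicates, seed %d\n",
    x$mode, x$mean_cost, x$se_cost, x$replicates, x$seed))
  cat(sprintf("  absorbed at full cooperation: %.4f +/- %.4f\n",
              x$fixation_estimate, x$fixation_se))
  invisible(x)
}

#' Estimate a fixation probability by simulation
#'
#' Walks the chain from a fixed single-mutant state and reports the
#' proportion of walks in which the mutant fixates, with its binomial
#' standard error: from state 1 (one cooperator) fixation means absorption
#' at full cooperation and the proportion estimates `rho_DC`; from state
#' `N - 1` (one defector) fixation means absorption at full defection and
#' the proportion estimates `rho_CD`. Independent check of
#' [fixation_probabilities()].
#'
#' @inheritParams simulate_cost
#' @param start `"S1"` (estimates `rho_DC`) or `"SN1"` (estimates
#'   `rho_CD`).
#' @return List with `proportion`, `se`, `replicates`, `seed`, `start`.
#' @export
estimate_fixation <- function(game, N, beta, theta, replicates = 10000L,
                              seed = 1L, start = c("S1", "SN1")) {
  start <- match.arg(start)
  N <- .check_game_N(game, N, min_N = 3L)
  .check_number(beta, "beta", lower = 0)
  .check_number(theta, "theta", lower = 0)
  replicates <- .check_count(replicates, "replicates", lower = 1L)
  seed <- .check_count(seed, "seed", lower = -.Machine$integer.max)
  set.seed(seed)
  walk <- .walk_chain(game, N, beta, theta,
                      .start_states(start, N, replicates),
                      record_visits = FALSE)
  p <- if (start == "S1") mean(walk$fixed_at_N) else mean(!walk$fixed_at_N)
  list(proportion = p,
       se = sqrt(p * (1 - p) / replicates),
       replicates = replicates, seed = seed, start = start)
}
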