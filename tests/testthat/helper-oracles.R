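# Shared fixtures and independent oracles. The oracles deliberately take
# the naive route (dense inversion, explicit products) so they share no
# code with the package's tridiagonal / log-domain production paths.

dg18 <- game_dg(b = 1.8, c = 1)
dg2 <- game_dg(b = 2, c = 1)
pgg1 <- game_pgg(c = 1, r = 3, n = 5)

# Visit profile via dense inversion of I - U (full fundamental matrix).
dense_visits <- function(game, N, beta, theta) {
  d <- payoff_delta(game, N)
  i <- seq_len(N - 1)
  g <- i * (N - i) / N^2
  up <- g * plogis(beta * (d + theta))
  dn <- g * plogis(-beta * (d + theta))
  U <- matrix(0, N - 1, N - 1)
  for (k in i) {
    U[k, k] <- 1 - up[k] - dn[k]
    if (k < N - 1) U[k, k + 1] <- up[k]
    if (k > 1) U[k, k - 1] <- dn[k]
  }
  fund <- solve(diag(N - 1) - U)
  (fund[1, ] + fund[N - 1, ]) / 2
}

dense_cost <- function(game, N, beta, theta, mode = "reward") {
  v <- dense_visits(game, N, beta, theta)
  i <- seq_len(N - 1)
  w <- if (mode == "reward") i else N - i
  theta * sum(w * v)
}

# Fixation probabilities by the explicit product formula (no log domain;
# valid for moderate beta).
product_fixation <- function(game, N, beta, theta) {
  k <- seq_len(N - 1)
  a <- beta * (payoff_cooperator(game, N, k) - payoff_defector(game, N, k) +
                 theta)
  rho_dc <- 1 / (1 + sum(cumprod(exp(-a))))
  rho_cd <- 1 / (1 + sum(cumprod(exp(rev(a)))))
  c(rho_dc, rho_cd)
}
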