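test_that("transition probabilities match the Fermi birth-death rule", {
  # neutral tilt theta = -delta: both Fermi factors are 1/2
  expect_equal(transition_probs(dg18, 3, beta = 7, theta = 1.9, i = 1),
               c(down = 1 / 9, stay = 7 / 9, up = 1 / 9))
  # direct evaluation at beta = 10, theta = 2.16 (Fermi argument 2.6)
  tp <- transition_probs(dg18, 3, beta = 10, theta = 2.16, i = 1)
  expect_equal(unname(tp["up"]), (2 / 9) / (1 + exp(-2.6)), tolerance = 1e-12)
  expect_equal(unname(tp["down"]), (2 / 9) / (1 + exp(2.6)), tolerance = 1e-12)
  # rows sum to one and up/down = exp(beta (delta + theta)) across a grid
  for (N in c(3, 7, 20)) {
    d <- payoff_delta(dg2, N)
    for (beta in c(0, 0.5, 3)) {
      for (i in c(1, N %/% 2, N - 1)) {
        tp <- transition_probs(dg2, N, beta, theta = 0.8, i = i)
        expect_equal(sum(tp), 1, tolerance = 1e-12)
        expect_equal(unname(tp["up"] / tp["down"]), exp(beta * (d + 0.8)),
                     tolerance = 1e-10)
      }
    }
  }
  # strong-selection saturation with theta > -delta: down vanishes
  tp <- transition_probs(dg18, 5, beta = 800, theta = 3, i = 2)
  expect_equal(unname(tp["up"]), 2 * 3 / 25, tolerance = 1e-10)
  expect_lt(tp["down"], 1e-12)
})

test_that("expected visits: hand-inverted 2x2 case and positivity", {
  # N = 3, theta = -delta: I - U = [[2/9,-1/9],[-1/9,2/9]], fundamental
  # matrix [[6,3],[3,6]], visits (4.5, 4.5) at any beta
  for (beta in c(0.3, 2, 50)) {
    expect_equal(expected_visits(dg18, 3, beta, 1.9), c(4.5, 4.5),
                 tolerance = 1e-12)
  }
  for (N in c(3, 6, 17)) {
    v <- expected_visits(dg2, N, 1.2, 0.4)
    expect_true(all(v > 0) && all(is.finite(v)))
  }
})

test_that("tridiagonal solve agrees with dense fundamental-matrix inversion", {
  for (N in c(3, 6, 12, 20)) {
    for (beta in c(0, 0.7, 5, 40)) {
      for (theta in c(0.2, 1.9, 6)) {
        expect_equal(expected_visits(dg18, N, beta, theta),
                     dense_visits(dg18, N, beta, theta), tolerance = 1e-10)
      }
    }
    expect_equal(expected_visits(pgg1, N + 3, 1.4, 0.7),
                 dense_visits(pgg1, N + 3, 1.4, 0.7), tolerance = 1e-10)
  }
})

test_that("expected cost reproduces the worked N = 3 reward values", {
  expect_equal(expected_cost(dg18, 3, 10, 1.845, "reward")$expected_cost,
               23.602, tolerance = 1e-3)
  expect_equal(expected_cost(dg18, 3, 10, 2.16, "reward")$expected_cost,
               25.6124, tolerance = 1e-4)
  # neutral tilt closed form N^2 theta H_N = 13.5 * 1.9 for both schemes
  for (mode in c("reward", "punishment")) {
    expect_equal(expected_cost(dg18, 3, 10, 1.9, mode)$expected_cost,
                 25.65, tolerance = 1e-10)
  }
})

test_that("reward and punishment share one visit profile", {
  for (N in c(3, 9, 24)) {
    for (theta in c(0.3, 1.5, 4)) {
      er <- expected_cost(dg2, N, 2.2, theta, "reward")
      ep <- expected_cost(dg2, N, 2.2, theta, "punishment")
      expect_equal(er$visits, ep$visits)
      # Er + Ep = theta * N * sum(v)
      expect_equal(er$expected_cost + ep$expected_cost,
                   theta * N * sum(er$visits), tolerance = 1e-10)
    }
    # equal cost exactly at the neutral tilt theta = -delta
    d <- payoff_delta(dg2, N)
    expect_equal(expected_cost(dg2, N, 3, -d, "reward")$expected_cost,
                 expected_cost(dg2, N, 3, -d, "punishment")$expected_cost,
                 tolerance = 1e-12)
  }
})

test_that("fixation probabilities: neutral limit, symmetry, closed-form ratio", {
  for (N in c(3, 8, 41)) {
    expect_equal(unname(fixation_probabilities(dg18, N, 0, 0.7)),
                 c(1 / N, 1 / N), tolerance = 1e-12)
    # symmetric chain at theta = -delta
    d <- payoff_delta(dg18, N)
    fp <- fixation_probabilities(dg18, N, 2, -d)
    expect_equal(unname(fp["rho_DC"]), unname(fp["rho_CD"]),
                 tolerance = 1e-12)
  }
  # (N-1)(delta + theta) = 2 gives rho_DC / rho_CD = e^2
  fp <- fixation_probabilities(dg18, 3, 1, 2.9)
  expect_equal(unname(fp["rho_DC"] / fp["rho_CD"]), exp(2),
               tolerance = 1e-10)
  # log-domain path survives strong selection where the naive product
  # overflows: cooperation heavily disfavoured, so rho_DC collapses to 0
  # cleanly (graceful underflow, no NaN) while rho_CD stays near certainty
  fp <- fixation_probabilities(dg18, 60, 1000, 0.1)
  expect_true(all(is.finite(fp)))
  expect_lt(fp["rho_DC"], 1e-300)
  expect_gt(fp["rho_CD"], 0.9)
})

test_that("product form and closed exponential form of the ratio agree", {
  set.seed(7)
  for (rep in 1:25) {
    N <- sample(3:30, 1)
    beta <- runif(1, 0.05, 4)
    theta <- runif(1, 0, 5)
    g <- if (rep %% 2 == 0) dg18 else pgg1
    if (g$kind == "PGG") N <- max(N, g$n)
    d <- payoff_delta(g, N)
    fp <- fixation_probabilities(g, N, beta, theta)
    po <- product_fixation(g, N, beta, theta)
    expect_equal(unname(fp), po, tolerance = 1e-10)
    expect_equal(unname(fp["rho_DC"] / fp["rho_CD"]),
                 exp(beta * (N - 1) * (d + theta)), tolerance = 1e-10)
    # stationary-distribution frequency equals the closed logistic form
    expect_equal(cooperation_frequency(g, N, beta, theta),
                 unname(fp["rho_DC"] / (fp["rho_DC"] + fp["rho_CD"])),
                 tolerance = 1e-10)
  }
})

test_that("cooperation frequency inverts exactly at theta0 and at -delta", {
  expect_equal(cooperation_frequency(dg18, 3, 10, 1.9), 0.5)
  for (omega in c(0.1, 0.5, 0.7, 0.999)) {
    th0 <- theta_min(dg18, 6, 2.5, omega)
    expect_equal(cooperation_frequency(dg18, 6, 2.5, th0), omega,
                 tolerance = 1e-12)
  }
})

test_that("markov-chain inputs are validated", {
  expect_error(expected_visits(dg18, 2, 1, 1), class = "coopcost_invalid")
  expect_error(transition_probs(dg18, 3, 1, 1, i = 3),
               class = "coopcost_invalid")
  expect_error(expected_cost(dg18, 3, 1, -0.5), class = "coopcost_invalid")
  expect_error(expected_cost(dg18, 3, 1, 1, "bribe"),
               class = "coopcost_invalid")
})
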