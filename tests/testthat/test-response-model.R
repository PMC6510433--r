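# The per-name response model, its penalized fit, normalization and the
# baseline/fitted/saturated comparison.

simple_params <- function(k = 0.8, mu = c(50, 0, 0), s = 15, alpha = 1,
                          g = 0.2) {
  name_params(k = k, mu = mu, Sigma = s^2 * diag(3), alpha = alpha, g = g)
}

test_that("q_rate matches its closed forms", {
  p <- simple_params()
  gamma <- 0.01
  # at the peak the exponent vanishes
  expect_equal(q_rate(p, gamma, p$mu), gamma * p$g + (1 - gamma) * p$k)
  # half-rate contour: alpha = 1 and m = 2 ln 2 halves the non-lapse part
  d <- sqrt(2 * log(2)) * 15
  z <- p$mu + c(d, 0, 0)
  expect_equal(q_rate(p, gamma, z) - gamma * p$g,
               (1 - gamma) * p$k / 2, tolerance = 1e-12)
  # far away the rate decays to the lapse floor
  expect_equal(q_rate(p, gamma, c(50, 4000, 0)), gamma * p$g)
  # rates are monotone in the Mahalanobis distance
  ds <- seq(0, 100, by = 5)
  rates <- vapply(ds, function(d) q_rate(p, gamma, p$mu + c(0, d, 0)),
                  numeric(1))
  expect_true(all(diff(rates) <= 0))
  # invariant boxes are enforced
  expect_error(name_params(k = 0.5, mu = c(0, 0, 0), Sigma = diag(3)),
               "eigenvalues")
  expect_error(name_params(k = 1.5, mu = c(0, 0, 0), Sigma = 100 * diag(3)))
})

test_that("name log-likelihood has the binomial closed form", {
  chips <- data.frame(subject = rep(1:2, each = 5),
                      r = rep(c(0.5, 0.6), 5), g = 0.5, b = 0.5,
                      name = rep(c("x", "y"), each = 5))
  tab <- naming_table(chips, clean = FALSE)$table
  p <- simple_params(g = 0.5)
  ll <- name_log_likelihood(tab, "x", p, gamma = 0.01)
  # direct evaluation
  Q <- q_rate(p, 0.01, tab$lab)
  r <- tab$counts[, "x"]; s <- rowSums(tab$counts) - r
  expect_equal(ll, sum(lchoose(r + s, r) + r * log(Q) + s * log(1 - Q)))
  # doubling the counts doubles the non-combinatoric part
  tab2 <- tab
  tab2$counts <- tab$counts * 2L
  ll2 <- name_log_likelihood(tab2, "x", p, gamma = 0.01)
  b1 <- sum(lchoose(r + s, r)); b2 <- sum(lchoose(2 * (r + s), 2 * r))
  expect_equal(ll2 - b2, 2 * (ll - b1), tolerance = 1e-9)
})

test_that("binomial likelihood is maximized at the empirical rate", {
  # one chip with r = 6 of R = 10: likelihood of Q peaks at 0.6
  r <- 6; s <- 4
  llq <- function(Q) lchoose(r + s, r) + r * log(Q) + s * log(1 - Q)
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_equal(grid[which.max(vapply(grid, llq, numeric(1)))], 0.6)
})

test_that("normalized model distributions sum to one and respect symmetry", {
  m <- synthetic_naming_model(n_names = 3, seed = 1)
  z <- matrix(runif(30), ncol = 3)
  P <- normalize_model(m, z)
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-12)
  expect_true(all(P > 0))
  # two identical names split the mass equally everywhere
  p1 <- name_params(0.5, c(50, 0, 0), 200 * diag(3), 1, 0.5)
  twin <- naming_model(list(a = p1, b = p1))
  P2 <- normalize_model(twin, z)
  expect_equal(P2[, 1], P2[, 2], tolerance = 1e-12)
  expect_equal(P2[, 1], rep(0.5, 10), tolerance = 1e-12)
})

test_that("the penalty shrinks support and the fit is deterministic", {
  set.seed(10)
  # a small name: 2 responses at one chip among background responses
  df <- rbind(
    make_records(list(rep("bg", 30), rep("bg", 30))),
    data.frame(subject = c(3, 4), r = 0.8, g = 0.2, b = 0.2,
               name = "rare"))
  tab <- naming_table(df)$table
  f0 <- fit_name(tab, "rare", lambda = 0, restarts = 2, seed = 1,
                 maxit = 200)
  f100 <- fit_name(tab, "rare", lambda = 100, restarts = 2, seed = 1,
                   maxit = 200)
  expect_gt(f0$k * det(f0$Sigma), f100$k * det(f100$Sigma))
  # deterministic given the seed
  f100b <- fit_name(tab, "rare", lambda = 100, restarts = 2, seed = 1,
                    maxit = 200)
  expect_equal(f100$mu, f100b$mu)
  expect_equal(f100$k, f100b$k)
  # a name supported only by lapse-like noise is driven to its floor
  expect_lt(f100$k, 0.01)
})

test_that("fitting is invariant to vocabulary and chip order", {
  m <- synthetic_naming_model(n_names = 3, seed = 2)
  d <- synthetic_naming_dataset(m, n_chips = 4^3, responses_per_chip = 20,
                                seed = 3)
  tab <- d$table
  # shuffle chips and vocabulary
  set.seed(11)
  ord_c <- sample(nrow(tab$chips))
  tab2 <- tab
  tab2$chips <- tab$chips[ord_c, ]
  tab2$lab <- tab$lab[ord_c, ]
  tab2$counts <- tab$counts[ord_c, rev(seq_along(tab$vocabulary))]
  tab2$vocabulary <- rev(tab$vocabulary)
  nm <- tab$vocabulary[1]
  f1 <- fit_name(tab, nm, restarts = 1, seed = 5, maxit = 100)
  f2 <- fit_name(tab2, nm, restarts = 1, seed = 5, maxit = 100)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-6)
  expect_equal(f1$k, f2$k, tolerance = 1e-6)
})

test_that("model comparison nests, counts parameters and prefers honestly", {
  m <- synthetic_naming_model(n_names = 4, seed = 3)
  d <- synthetic_naming_dataset(m, n_chips = 6^3, responses_per_chip = 40,
                                seed = 4)
  fit <- fit_naming_model(d$table, restarts = 2, maxit = 250, seed = 5)
  mc <- model_comparison(d$table, fit)
  ll <- mc$log_likelihood
  expect_gte(ll["saturated"], ll["fitted"])
  expect_gte(ll["fitted"], ll["baseline"])
  N <- length(d$table$vocabulary); Nc <- nrow(d$table$chips)
  expect_equal(unname(mc$n_parameters),
               c(N - 1, 12 * N, Nc * (N - 1)))
  expect_equal(unname(mc$verdicts["fitted_vs_baseline"]),
               "fitted preferred")
  expect_equal(unname(mc$verdicts["saturated_vs_fitted"]),
               "fitted preferred")
  # a vocabulary mismatch is an error
  m2 <- synthetic_naming_model(n_names = 2, seed = 9)
  expect_error(model_comparison(d$table, m2), "vocabular")
})

test_that("data generated from the baseline keeps the baseline preferred", {
  set.seed(12)
  g <- c(a = 0.5, b = 0.3, c = 0.2)
  chips <- matrix(runif(3 * 30), ncol = 3)
  df <- do.call(rbind, lapply(seq_len(nrow(chips)), function(i)
    data.frame(subject = rep(1:5, 4), r = chips[i, 1], g = chips[i, 2],
               b = chips[i, 3],
               name = sample(names(g), 20, TRUE, g))))
  tab <- naming_table(df)$table
  fit <- fit_naming_model(tab, restarts = 2, maxit = 150, seed = 6)
  mc <- model_comparison(tab, fit)
  expect_equal(unname(mc$verdicts["fitted_vs_baseline"]),
               "baseline preferred")
})

test_that("rank-power sampling bias demo matches its design", {
  bd <- bhattacharyya_bias_demo(reps = 500, seed = 1)
  expect_equal(unname(round(100 * bd$leading_probabilities)),
               c(34, 13, 7, 5))
  expect_gt(bd$mean_angle, 0.7)
  expect_lt(bd$mean_angle, 1.0)
  # two population copies of the distribution are at angle zero
  p <- rank_power_multinomial(1.4, 804)
  expect_equal(bhattacharyya_angle(p, p), 0)
  expect_error(bhattacharyya_bias_demo(n_samples = 31, support = 10))
})
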