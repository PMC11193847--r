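test_that("noiseless mediation recovers the exact algebra", {
  t <- rep(0:1, 10)
  f <- fit_mediation(t, 2 * t, 0.5 * (2 * t))
  expect_equal(f$a, 2)
  expect_equal(f$b, 0.5)
  expect_equal(f$c_prime, 0)
  expect_equal(f$acme, 1)
  expect_equal(f$prop_mediated, 1)
  expect_equal(f$acme + f$ade, f$total)
})

test_that("outcome independent of mediator gives near-zero ACME", {
  set.seed(61)
  t <- rep(0:1, 50)
  m <- t + rnorm(100)
  y <- 0.7 * t + rnorm(100)
  f <- fit_mediation(t, m, y)
  expect_lt(abs(f$b), 0.3)
  expect_lt(abs(f$acme), 0.3)
  expect_equal(f$acme + f$ade, f$total, tolerance = 1e-12)
})

test_that("input validation catches degenerate designs", {
  expect_error(fit_mediation(rep(1, 10), rnorm(10), rnorm(10)), "constant")
  expect_error(fit_mediation(1:3, 1:3, 1:3), "n >= 4")
  expect_error(fit_mediation(1:5, 1:4, 1:5), "lengths")
})

test_that("point estimates recover planted parameters on average", {
  acmes <- props <- numeric(200)
  for (r in seq_len(200)) {
    md <- gen_mediation_data(synth_config(seed = 5000 + r))
    f <- fit_mediation(md$treatment, md$mediator, md$outcome)
    acmes[r] <- f$acme
    props[r] <- f$prop_mediated
  }
  gt <- attr(gen_mediation_data(synth_config(seed = 5001)), "ground_truth")
  expect_equal(gt$acme, 0.4)
  se <- stats::sd(acmes) / sqrt(length(acmes))
  expect_lt(abs(mean(acmes) - 0.4), 2 * se + 0.005)
  sep <- stats::sd(props) / sqrt(length(props))
  expect_lt(abs(mean(props) - 0.5), 2 * sep + 0.01)
})

test_that("bootstrap is deterministic, covers the point estimate, and the
           CI collapses for noiseless data", {
  md <- gen_mediation_data(synth_config(seed = 3))
  f1 <- bootstrap_mediation(md$treatment, md$mediator, md$outcome,
                            sims = 200, seed = 9)
  f2 <- bootstrap_mediation(md$treatment, md$mediator, md$outcome,
                            sims = 200, seed = 9)
  expect_identical(f1$ci, f2$ci)
  expect_identical(f1$p_mediation, f2$p_mediation)
  expect_lte(f1$ci["acme", "lo"], f1$acme)
  expect_gte(f1$ci["acme", "hi"], f1$acme)
  # noiseless perfect mediation: interval collapses onto the estimate
  t <- rep(0:1, 10)
  f0 <- bootstrap_mediation(t, 2 * t, t, sims = 100, seed = 2)
  expect_equal(unname(f0$ci["acme", ]), c(1, 1))
})

test_that("bootstrap p-value is calibrated under the mediation null", {
  # b = 0: no mediation; the ACME bootstrap p should reject at ~ alpha
  rej <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    cfg <- synth_config(seed = 7000 + r,
                        mediation_params = list(a = 0.8, b = 0, c_prime = 0.4,
                                                sd_m = 1, sd_y = 1, n = 50))
    md <- gen_mediation_data(cfg)
    f <- bootstrap_mediation(md$treatment, md$mediator, md$outcome,
                             sims = 199, seed = 100 + r)
    if (f$p_mediation < 0.05) rej <- rej + 1
  }
  rate <- rej / reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
})

test_that("covariates enter both models", {
  set.seed(90)
  n <- 400
  t <- rep(0:1, length.out = n)
  x <- rnorm(n)
  m <- 0.8 * t + 0.5 * x + rnorm(n, 0, 0.5)
  y <- 0.4 * t + 0.5 * m + 0.7 * x + rnorm(n, 0, 0.5)
  f_with <- fit_mediation(t, m, y, covariates = cbind(x))
  expect_lt(abs(f_with$acme - 0.4), 0.15)
  fb <- bootstrap_mediation(t, m, y, covariates = cbind(x), sims = 100,
                            seed = 4)
  expect_lte(fb$ci["acme", "lo"], fb$ci["acme", "hi"])
})

test_that("sensitivity curve anchors at the point estimate and matches the
           constrained-likelihood oracle", {
  set.seed(55)
  n <- 50
  t <- rep(0:1, n / 2)
  m <- 0.8 * t + rnorm(n)
  y <- 0.4 * t + 0.5 * m + rnorm(n)
  f <- fit_mediation(t, m, y)
  sc <- sensitivity_curve(f, seq(-0.9, 0.9, 0.1))
  i0 <- which(abs(sc$rho_grid) < 1e-9)
  expect_equal(sc$acme_at_rho[i0], f$acme, tolerance = 1e-8)
  for (rho in c(-0.6, -0.2, 0.3, 0.7)) {
    i <- which(abs(sc$rho_grid - rho) < 1e-9)
    expect_equal(sc$acme_at_rho[i], oracle_acme_at_rho(t, m, y, rho),
                 tolerance = 1e-3, info = paste("rho =", rho))
  }
  # monotone in rho for fixed data
  expect_true(all(diff(sc$acme_at_rho) < 0) ||
                all(diff(sc$acme_at_rho) > 0))
  expect_error(sensitivity_curve(f, c(0, 1)), "\\(-1, 1\\)")
})

test_that("rho_zero locates the planted error correlation", {
  set.seed(66)
  n <- 500
  rho_star <- 0.5
  t <- rep(0:1, n / 2)
  Z <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, rho_star,
                                                    rho_star, 1), 2))
  m <- 0.8 * t + Z[, 1]
  y <- 0.4 * t + Z[, 2]        # no true mediation: Y ignores M given errors
  f <- fit_mediation(t, m, y)
  sc <- sensitivity_curve(f, seq(-0.9, 0.9, 0.05))
  expect_lt(abs(sc$rho_zero - rho_star), 0.1)
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  widths <- vapply(c(50, 200, 800), function(n) {
    cfg <- synth_config(seed = 321,
                        mediation_params = list(a = 0.8, b = 0.5,
                                                c_prime = 0.4, sd_m = 1,
                                                sd_y = 1, n = n))
    md <- gen_mediation_data(cfg)
    f <- bootstrap_mediation(md$treatment, md$mediator, md$outcome,
                             sims = 400, seed = 5)
    diff(f$ci["acme", ])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3] / widths[1], 0.5)
})
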