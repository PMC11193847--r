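test_that("wilcoxon rank-sum matches the enumeration oracle when exact", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  set.seed(23)
  for (n1 in 2:4) {
    for (n2 in n1:(8 - n1)) {
      x <- sample(100, n1); y <- sample(200, n2) + 0.5
      expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                   oracle_wilcoxon_p(x, y), tolerance = 1e-12,
                   info = paste(n1, n2))
    }
  }
})

test_that("wilcoxon null rejection rate is nominal", {
  # attainable level at n = 6/6 by full enumeration of rank assignments
  combos <- utils::combn(12, 6)
  sums <- colSums(matrix(seq_len(12)[combos], nrow = 6))
  mu <- 6 * 13 / 2
  pvals <- vapply(sums, function(s) mean(abs(sums - mu) >= abs(s - mu)),
                  numeric(1))
  nominal <- mean(pvals < 0.05)
  set.seed(77)
  reps <- 10000
  rej <- 0
  for (i in seq_len(reps)) {
    if (wilcoxon_rank_sum(rnorm(6), rnorm(6))$p_value < 0.05) rej <- rej + 1
  }
  rate <- rej / reps
  se <- sqrt(nominal * (1 - nominal) / reps)
  expect_lt(abs(rate - nominal), 3 * se)
})

test_that("student t reproduces the closed-form example and degenerates", {
  r <- student_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(r$p_value, 0.2878641, tolerance = 1e-6)
  expect_equal(student_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(student_t(c(2, 2), c(2, 2))$p_value, 1)
  d <- student_t(c(2, 2), c(3, 3))
  expect_equal(d$p_value, 0)
  expect_true(d$degenerate)
})

test_that("t-test type-I error is near nominal under the null", {
  set.seed(5)
  reps <- 5000
  p <- replicate(reps, student_t(rnorm(6), rnorm(6))$p_value)
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("BH adjustment is step-up with monotonicity", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj[order(p)]), seq_along(p))  # rank-monotone
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("VIP satisfies the normalization identity on arbitrary inputs", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(10:40, 1); p <- sample(3:15, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(0, 1), length.out = n)
    for (a in c(1, 2)) {
      v <- plsda_vip(X, y, n_components = a)
      expect_equal(sum(v$vip^2), p, tolerance = 1e-8)
    }
  }
  expect_error(plsda_vip(cbind(a = rep(1, 8), b = rnorm(8)),
                         rep(c(0, 1), 4)), "constant")
})

test_that("VIP singles out a perfectly separating variable", {
  set.seed(8)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 4] <- y * 4 + rnorm(n, 0, 0.05)
  v <- plsda_vip(X, y)
  expect_equal(unname(which.max(v$vip)), 4)
  expect_gt(v$vip[4], 1)
})

test_that("VIP is near one everywhere when classes are identical", {
  set.seed(19)
  maxes <- replicate(20, {
    X <- matrix(rnorm(30 * 8), 30, 8)
    which.max(plsda_vip(X, rep(c(0, 1), 15))$vip)
  })
  # no variable is systematically the most important under the null
  expect_gt(length(unique(maxes)), 3)
})

test_that("single-component VIP agrees with the mixOmics reference", {
  set.seed(44)
  X <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(NULL, paste0("V", 1:6)))
  y <- factor(rep(c("a", "b"), 15))
  X[, 2] <- X[, 2] + (y == "b") * 2
  ours <- plsda_vip(X, y, n_components = 1)$vip
  ref <- mixOmics::vip(mixOmics::plsda(X, y, ncomp = 1))[, 1]
  expect_equal(unname(ours), unname(ref[names(ours)]), tolerance = 1e-6)
})

test_that("PCA projection explains variance and reconstructs", {
  line <- cbind(1:10, 2 * (1:10) + 3)
  pc <- pca_project(line, 2)
  expect_equal(pc$explained_variance[1], 1, tolerance = 1e-12)
  set.seed(3)
  X <- matrix(rnorm(20 * 5), 20, 5)
  pc <- pca_project(X, 5)
  expect_equal(sum(pc$explained_variance), 1, tolerance = 1e-12)
  # reconstruction with full rank
  Xhat <- pc$scores %*% t(pc$loadings)
  Xc <- sweep(X, 2, pc$center)
  expect_equal(Xhat, Xc, tolerance = 1e-10, ignore_attr = TRUE)
  # rotation invariance of explained variance
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  pc2 <- pca_project(X %*% Q, 5)
  expect_equal(pc2$explained_variance, pc$explained_variance,
               tolerance = 1e-10)
  expect_error(pca_project(X[1, , drop = FALSE]), "2 samples")
})
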