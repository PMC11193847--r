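# Linear causal mediation: point estimates, nonparametric bootstrap
# percentile intervals, and a sequential-ignorability sensitivity curve.
#
# Model: M = a*T (+ covariates), Y = c'*T + b*M (+ covariates), both by
# OLS. ACME = a*b, ADE = c', total = a*b + c'. For continuous treatments
# effects are per unit of T; set `scale_treatment = TRUE` to report per
# 1 SD of T.

# closed-form OLS for the two mediation regressions (no covariates);
# returns c(a, b, cprime)
.fit_tm_y <- function(t, m, y) {
  tc <- t - mean(t); mc <- m - mean(m); yc <- y - mean(y)
  stt <- sum(tc^2); smm <- sum(mc^2); stm <- sum(tc * mc)
  sty <- sum(tc * yc); smy <- sum(mc * yc)
  if (stt <= 0) stop("rank-deficient design: constant treatment")
  if (smm <= 0) stop("rank-deficient design: constant mediator")
  det <- stt * smm - stm^2
  a <- stm / stt
  if (det / (stt * smm) < 1e-12) {
    # T and M (numerically) collinear: the noiseless perfect-mediation
    # case. Attribute the effect through the mediator (b from Y ~ M) and
    # leave the direct effect as the total-effect remainder.
    b <- smy / smm
    return(c(a = a, b = b, cprime = sty / stt - b * a))
  }
  c(a = a,
    b = (stt * smy - stm * sty) / det,
    cprime = (smm * sty - stm * smy) / det)
}

.fit_with_covariates <- function(t, m, y, covariates) {
  Xm <- cbind(1, t, covariates)
  Xy <- cbind(1, t, m, covariates)
  if (qr(Xy)$rank < ncol(Xy)) stop("rank-deficient design")
  cm <- qr.coef(qr(Xm), m)
  cy <- qr.coef(qr(Xy), y)
  c(a = unname(cm[2]), b = unname(cy[3]), cprime = unname(cy[2]))
}

#' Fit a linear mediation model (point estimates)
#'
#' @param treatment numeric or two-level vector; the exposure T.
#' @param mediator numeric vector M.
#' @param outcome numeric vector Y.
#' @param covariates optional numeric matrix, included in both models.
#' @param scale_treatment divide a continuous T by its SD so effects are
#'   per 1 SD change.
#' @return object of class "mediation_fit": list with a, b, c_prime (ADE),
#'   acme, total, prop_mediated, prop_flagged (|prop| > 1 or total ~ 0), n.
#' @export
fit_mediation <- function(treatment, mediator, outcome, covariates = NULL,
                          scale_treatment = FALSE) {
  t <- treatment
  if (is.factor(t) || is.character(t)) {
    lev <- unique(as.character(t))
    if (length(lev) != 2) stop("non-numeric treatment must have two levels")
    t <- as.numeric(as.character(t) == lev[2])
  }
  t <- as.numeric(t)
  m <- as.numeric(mediator); y <- as.numeric(outcome)
  n <- length(t)
  if (length(m) != n || length(y) != n) stop("unequal input lengths")
  if (n < 4) stop("need n >= 4")
  if (stats::sd(t) == 0) stop("treatment is constant")
  if (scale_treatment) t <- t / stats::sd(t)
  co <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  est <- if (is.null(co)) .fit_tm_y(t, m, y) else
    .fit_with_covariates(t, m, y, co)
  acme <- est[["a"]] * est[["b"]]
  total <- acme + est[["cprime"]]
  prop <- if (abs(total) < .Machine$double.eps^0.5) NA_real_ else
    acme / total
  structure(list(
    a = est[["a"]], b = est[["b"]], c_prime = est[["cprime"]],
    acme = acme, ade = est[["cprime"]], total = total,
    prop_mediated = prop,
    prop_flagged = is.na(prop) || abs(prop) > 1,
    n = n, treatment = t, mediator = m, outcome = y, covariates = co
  ), class = "mediation_fit")
}

#' Bootstrap mediation analysis with percentile intervals
#'
#' Nonparametric case resampling of rows; percentile confidence intervals
#' at `conf` for ACME, ADE, the total effect and the mediated proportion;
#' two-sided bootstrap p-value for the ACME,
#' p = 2 * min(frac(acme* <= 0), frac(acme* >= 0)), clipped to
#' [1/sims, 1]. Resamples with constant treatment are redrawn (at most 100
#' rounds). Deterministic given `seed`.
#'
#' @inheritParams fit_mediation
#' @param sims number of bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed for the resampling.
#' @return a "mediation_fit" augmented with `ci` (matrix), `p_mediation`,
#'   `sims`, `seed`, `boot_acme`.
#' @export
bootstrap_mediation <- function(treatment, mediator, outcome,
                                covariates = NULL, sims = 1000,
                                conf = 0.95, seed = 1,
                                scale_treatment = FALSE) {
  fit <- fit_mediation(treatment, mediator, outcome, covariates,
                       scale_treatment)
  t <- fit$treatment; m <- fit$mediator; y <- fit$outcome
  n <- fit$n
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  if (is.null(fit$covariates)) {
    idx <- matrix(sample.int(n, n * sims, replace = TRUE), nrow = n)
    for (round in seq_len(100)) {
      Tb <- matrix(t[idx], nrow = n)
      bad <- which(apply(Tb, 2, function(v) stats::var(v) == 0))
      if (!length(bad)) break
      if (round == 100) stop("constant-treatment resamples persisted")
      idx[, bad] <- sample.int(n, n * length(bad), replace = TRUE)
    }
    Tb <- matrix(t[idx], nrow = n)
    Mb <- matrix(m[idx], nrow = n)
    Yb <- matrix(y[idx], nrow = n)
    # vectorised centered cross-moments across resamples
    cc <- function(A) sweep(A, 2, colMeans(A))
    Tc <- cc(Tb); Mc <- cc(Mb); Yc <- cc(Yb)
    stt <- colSums(Tc^2); smm <- colSums(Mc^2); stm <- colSums(Tc * Mc)
    sty <- colSums(Tc * Yc); smy <- colSums(Mc * Yc)
    det <- stt * smm - stm^2
    a_b <- stm / stt
    b_b <- (stt * smy - stm * sty) / det
    c_b <- (smm * sty - stm * smy) / det
    # collinear T/M resamples (noiseless mediation): mediator attribution
    col <- det / (stt * smm) < 1e-12
    if (any(col)) {
      b_b[col] <- smy[col] / smm[col]
      c_b[col] <- sty[col] / stt[col] - b_b[col] * a_b[col]
    }
  } else {
    a_b <- b_b <- c_b <- numeric(sims)
    for (s in seq_len(sims)) {
      for (round in seq_len(100)) {
        i <- sample.int(n, n, replace = TRUE)
        if (stats::var(t[i]) > 0) break
        if (round == 100) stop("constant-treatment resamples persisted")
      }
      est <- .fit_with_covariates(t[i], m[i], y[i],
                                  fit$covariates[i, , drop = FALSE])
      a_b[s] <- est[["a"]]; b_b[s] <- est[["b"]]; c_b[s] <- est[["cprime"]]
    }
  }
  acme_b <- a_b * b_b
  total_b <- acme_b + c_b
  prop_b <- ifelse(abs(total_b) < .Machine$double.eps^0.5, NA_real_,
                   acme_b / total_b)
  ci <- rbind(acme = stats::quantile(acme_b, probs, names = FALSE),
              ade = stats::quantile(c_b, probs, names = FALSE),
              total = stats::quantile(total_b, probs, names = FALSE),
              prop_mediated = stats::quantile(prop_b, probs,
                                              names = FALSE, na.rm = TRUE))
  colnames(ci) <- c("lo", "hi")
  p_med <- 2 * min(mean(acme_b <= 0), mean(acme_b >= 0))
  fit$ci <- ci
  fit$p_mediation <- min(max(p_med, 1 / sims), 1)
  fit$sims <- sims
  fit$seed <- seed
  fit$conf <- conf
  fit$boot_acme <- acme_b
  fit
}

#' Sequential-ignorability sensitivity curve for the ACME
#'
#' For each assumed correlation rho between the mediator-model and
#' outcome-model errors, the bias-adjusted ACME in the linear-linear case
#' is
#'   ACME(rho) = a * (s1/s2) * (rho_t - rho * sqrt((1-rho_t^2)/(1-rho^2)))
#' where s1, s2 are the residual SDs of the reduced-form regressions
#' Y ~ T (+X) and M ~ T (+X), and rho_t their residual correlation.
#' ACME(0) equals the unadjusted ACME exactly; the curve crosses zero at
#' rho = rho_t.
#'
#' @param fit a "mediation_fit" from [fit_mediation()].
#' @param rho_grid grid of rho values in (-1, 1).
#' @return object of class "mediation_sensitivity": list with `rho_grid`,
#'   `acme_at_rho`, `rho_zero`.
#' @export
sensitivity_curve <- function(fit, rho_grid = seq(-0.9, 0.9, by = 0.1)) {
  stopifnot(inherits(fit, "mediation_fit"))
  if (any(abs(rho_grid) >= 1)) stop("rho grid must lie in (-1, 1)")
  t <- fit$treatment; m <- fit$mediator; y <- fit$outcome
  Xr <- cbind(1, t, fit$covariates)
  qx <- qr(Xr)
  e2 <- stats::residuals(stats::lm.fit(Xr, m))
  e1 <- stats::residuals(stats::lm.fit(Xr, y))
  s1 <- sqrt(sum(e1^2) / length(e1))
  s2 <- sqrt(sum(e2^2) / length(e2))
  rho_t <- sum(e1 * e2) / (length(e1) * s1 * s2)
  acme <- fit$a * (s1 / s2) *
    (rho_t - rho_grid * sqrt((1 - rho_t^2) / (1 - rho_grid^2)))
  # zero crossing by linear interpolation between grid sign changes
  rho_zero <- NA_real_
  sg <- sign(acme)
  ch <- which(sg[-1] * sg[-length(sg)] < 0)
  if (length(ch)) {
    i <- ch[1]
    rho_zero <- rho_grid[i] + (rho_grid[i + 1] - rho_grid[i]) *
      (0 - acme[i]) / (acme[i + 1] - acme[i])
  } else if (any(sg == 0)) {
    rho_zero <- rho_grid[which(sg == 0)[1]]
  }
  structure(list(rho_grid = rho_grid, acme_at_rho = acme,
                 rho_zero = rho_zero, rho_tilde = rho_t),
            class = "mediation_sensitivity")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("mediation fit (n = %d): ACME = %.4g, ADE = %.4g, total = %.4g",
              x$n, x$acme, x$ade, x$total))
  if (!is.na(x$prop_mediated)) {
    cat(sprintf(", prop. mediated = %.1f%%", 100 * x$prop_mediated))
  }
  cat("\n")
  if (!is.null(x$ci)) {
    cat(sprintf("  %d%% percentile CI for ACME: [%.4g, %.4g], p = %.3g (%d sims)\n",
                round(100 * x$conf), x$ci["acme", "lo"], x$ci["acme", "hi"],
                x$p_mediation, x$sims))
  }
  invisible(x)
}
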