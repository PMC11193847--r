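# Statistical primitives shared by the quantification and network modules:
# two-group tests, BH adjustment, PLS-DA with VIP scores, and PCA.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value (full permutation distribution of the rank sum) when the
#' combined sample size is at most `exact_below_n` and there are no ties;
#' otherwise the normal approximation with tie and continuity correction.
#' Identical samples (zero rank-sum deviation everywhere) give p = 1.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param exact_below_n switch point for the exact distribution.
#' @return list with `statistic` (rank-sum W), `p_value`, `method`,
#'   `n_per_group`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_below_n = 25) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "wilcoxon (degenerate)",
                n_per_group = c(length(x), length(y))))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= exact_below_n && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (use_exact) "wilcoxon exact" else "wilcoxon normal approx",
       n_per_group = c(length(x), length(y)))
}

#' Two-sided two-sample t-test
#'
#' Classical equal-variance Student's t by default; Welch by flag. Zero
#' pooled variance is handled explicitly: equal means give p = 1, unequal
#' means give p = 0 with a degenerate flag.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param welch use Welch's unequal-variance form.
#' @return list with `statistic`, `p_value`, `method`, `n_per_group`,
#'   `degenerate`.
#' @export
student_t <- function(x, y, welch = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, p_value = 1, method = "t (degenerate)",
                  n_per_group = c(length(x), length(y)), degenerate = TRUE))
    }
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p_value = 0,
                method = "t (degenerate)",
                n_per_group = c(length(x), length(y)), degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = !welch, alternative = "two.sided")
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (welch) "welch t" else "student t",
       n_per_group = c(length(x), length(y)), degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in [0,1]; NAs propagate.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' PLS-DA with VIP scores
#'
#' Partial least squares regression of a binary class indicator on
#' column-standardised predictors (NIPALS-style sequential component
#' extraction with deflation), followed by variable importance in
#' projection:
#'   VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )
#' where SS_a is the y-variance explained by component a. The VIPs satisfy
#' sum_j VIP_j^2 = p (the number of variables) exactly.
#'
#' @param X numeric matrix, samples x variables.
#' @param y class labels (two levels) or a numeric vector.
#' @param n_components number of PLS components (default 1, the first
#'   projection component).
#' @return list with `vip` (named per variable), `n_components`,
#'   `explained_y_variance` (per component), `weights`, `scores`.
#' @export
plsda_vip <- function(X, y, n_components = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (is.factor(y) || is.character(y)) {
    lev <- unique(as.character(y))
    if (length(lev) != 2) stop("y must have exactly two classes")
    if (min(table(y)) < 2) stop("need >= 2 samples per class")
    y <- as.numeric(as.character(y) == lev[2])
  }
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), n_components >= 1)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Xs <- scale(X)
  ys <- as.numeric(scale(y))
  p <- ncol(Xs)
  A <- min(n_components, p, nrow(Xs) - 1L)
  W <- matrix(0, p, A, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, nrow(Xs), A)
  ss <- numeric(A)
  E <- Xs
  f <- ys
  for (a in seq_len(A)) {
    w <- crossprod(E, f)                      # p x 1 weight vector
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) { A <- a - 1L; break }
    w <- w / nw
    t_a <- E %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(E, t_a) / tt             # X loadings
    q_a <- sum(f * t_a) / tt                  # y loading
    ss[a] <- q_a^2 * tt                       # y-variance explained
    W[, a] <- w
    Tm[, a] <- t_a
    E <- E - t_a %*% t(p_a)
    f <- f - t_a * q_a
  }
  if (A < 1) stop("no PLS component could be extracted")
  W <- W[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]
  ss <- ss[seq_len(A)]
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")   # unit-norm weights
  vip <- sqrt(p * colSums(t(wn^2) * ss) / sum(ss))
  names(vip) <- colnames(X)
  list(vip = vip, n_components = A,
       explained_y_variance = ss / sum(ys^2),
       weights = W, scores = Tm)
}

#' Principal component analysis projection
#'
#' Centered (optionally unit-variance scaled) SVD with a deterministic sign
#' convention: within each component the largest-magnitude loading is
#' positive.
#'
#' @param X numeric matrix, samples x variables.
#' @param n_components number of components, at most min(n-1, p).
#' @param scale. scale columns to unit variance.
#' @return list with `scores`, `loadings`, `explained_variance` (fractions),
#'   `sdev`, `center`, `scale`.
#' @export
pca_project <- function(X, n_components = 2, scale. = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples")
  k <- min(n_components, nrow(X) - 1L, ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  tot <- sum(pc$sdev^2)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) { rot[, j] <- -rot[, j]; sco[, j] <- -sco[, j] }
  }
  list(scores = sco, loadings = rot,
       explained_variance = pc$sdev[seq_len(k)]^2 / tot,
       sdev = pc$sdev, center = pc$center, scale = pc$scale)
}
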