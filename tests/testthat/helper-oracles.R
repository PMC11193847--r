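# Independent oracles used across the suite. Each re-derives the quantity
# with a different, brute-force method from the implementation it checks.

# exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (no ties assumed)
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  sums <- apply(combos, 2, function(i) sum(r[i]))
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# exact two-sided Spearman p by full permutation enumeration (small n)
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  obs <- abs(stats::cor(rank(x), rank(y)))
  rs <- vapply(perms(seq_len(n)),
               function(p) abs(stats::cor(rank(x), rank(y)[p])),
               numeric(1))
  mean(rs >= obs - 1e-12)
}

# naive per-row BAKO re-tally over a catalog + KO table
oracle_screen_tally <- function(catalog, ko_table, bako_kos) {
  per_mag_kos <- split(ko_table$ko_id, ko_table$mag_id)
  bamags <- character(0)
  mag_count <- gene_count <- integer(0)
  for (id in catalog$mag_id) {
    kos <- per_mag_kos[[id]]
    hits <- kos[kos %in% bako_kos]
    if (length(hits) == 0) next
    bamags <- c(bamags, id)
    for (k in unique(hits)) {
      mag_count[k] <- (if (is.na(mag_count[k])) 0L else mag_count[k]) + 1L
    }
    tb <- table(hits)
    for (k in names(tb)) {
      gene_count[k] <- (if (is.na(gene_count[k])) 0L else gene_count[k]) +
        as.integer(tb[[k]])
    }
  }
  list(bamags = sort(bamags),
       mag_count = mag_count[sort(names(mag_count))],
       gene_count = gene_count[sort(names(gene_count))])
}

# independent structure-transition oracle for the biotransformation engine:
# represents a BA as a plain character vector and re-derives every product
# by its own switch logic
oracle_enumerate_pairs <- function(names, mode, dict = ba_structures()) {
  key <- function(v) paste(v, collapse = "|")
  rows <- lapply(seq_len(nrow(dict)), function(i)
    c(dict$c3[i], dict$c6[i], dict$c7[i], dict$c12[i], dict$c5[i]))
  names(rows) <- dict$name
  bykey <- stats::setNames(dict$name, vapply(rows, key, character(1)))
  posidx <- c("3" = 1, "6" = 2, "7" = 3, "12" = 4)
  out <- character(0)
  for (nm in names) {
    s <- rows[[nm]]
    cand <- list()
    for (pos in c("3", "6", "7", "12")) {
      i <- posidx[[pos]]
      st <- s[i]
      mk <- function(newstate) { v <- s; v[i] <- newstate; v }
      if (st %in% c("a", "b")) {
        if (mode %in% c("direct_epimerization", "both")) {
          cand <- c(cand, list(mk(if (st == "a") "b" else "a")))
        }
        cand <- c(cand, list(mk("-")))          # dehydroxylation
        if (mode %in% c("composite_via_oxo", "both")) {
          cand <- c(cand, list(mk("oxo")))      # oxidation
        }
      }
      if (st == "oxo" && mode %in% c("composite_via_oxo", "both")) {
        cand <- c(cand, list(mk("a")), list(mk("b")))  # reductions
      }
    }
    if (mode %in% c("direct_epimerization", "both")) {
      v <- s; v[5] <- if (s[5] == "a") "b" else "a"
      cand <- c(cand, list(v))                  # 5-epimerization
    }
    for (v in cand) {
      pn <- bykey[key(v)]
      if (!is.na(pn) && pn %in% names && pn != nm) {
        out <- c(out, paste(nm, pn, sep = "->"))
      }
    }
  }
  sort(unique(out))
}

# constrained-likelihood numeric oracle for the mediation sensitivity
# curve: maximize the joint Gaussian likelihood of (M, Y) | T with the
# error correlation fixed at rho, return the implied ACME = beta2 * gamma
oracle_acme_at_rho <- function(t, m, y, rho) {
  nll <- function(th) {
    a2 <- th[1]; b2 <- th[2]; a3 <- th[3]; b3 <- th[4]; g <- th[5]
    ls2 <- th[6]; ls3 <- th[7]
    s2 <- exp(ls2); s3 <- exp(ls3)
    e2 <- m - a2 - b2 * t
    e3 <- y - a3 - b3 * t - g * m
    q <- (e2 / s2)^2 - 2 * rho * (e2 / s2) * (e3 / s3) + (e3 / s3)^2
    n <- length(t)
    n * log(2 * pi) + n * log(s2 * s3) + n / 2 * log(1 - rho^2) +
      sum(q) / (2 * (1 - rho^2))
  }
  cm <- stats::coef(stats::lm(m ~ t))
  cy <- stats::coef(stats::lm(y ~ t + m))
  start <- c(cm[1], cm[2], cy[1], cy[2], cy[3],
             log(stats::sd(stats::residuals(stats::lm(m ~ t)))),
             log(stats::sd(stats::residuals(stats::lm(y ~ t + m)))))
  fit <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-12))
  unname(fit$par[2] * fit$par[5])
}

# deterministic small MAG fixture used by several magscreen tests
make_mag_fixture <- function(n = 50, seed = 42) {
  cfg <- synth_config(seed = seed, n_mags = n)
  gen_mag_catalog(cfg)
}
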