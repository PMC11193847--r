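# Spearman correlation networks. Two edge rules mirror the two analyses:
# exact |r| = 1 for the small-n (n = 5/6) rumen BA/microbe/function data,
# and BH-adjusted p < alpha for the serum bipartite family.

#' Pairwise Spearman correlation and p-value matrices
#'
#' Average ranks for ties; exact p-values (no ties, n <= `exact_below_n`)
#' via the exact null distribution of the rank statistic, otherwise the
#' t-approximation. Constant features give NA rows/columns and are later
#' excluded from networks.
#'
#' @param X numeric matrix, samples x features (>= 3 samples).
#' @param exact_below_n maximum n for the exact p-value.
#' @return list with matrices `r` and `p` (features x features, diagonal
#'   r = 1, p = NA).
#' @export
spearman_matrix <- function(X, exact_below_n = 9) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need >= 3 samples")
  m <- ncol(X)
  feats <- colnames(X) %||% paste0("F", seq_len(m))
  r <- p <- matrix(NA_real_, m, m, dimnames = list(feats, feats))
  diag(r) <- 1
  const <- apply(X, 2, function(v) length(unique(v)) == 1L)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (const[i] || const[j]) next
      ties <- anyDuplicated(X[, i]) > 0 || anyDuplicated(X[, j]) > 0
      ct <- suppressWarnings(stats::cor.test(
        X[, i], X[, j], method = "spearman",
        exact = (n <= exact_below_n) && !ties))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(r)[const] <- NA_real_
  list(r = r, p = p)
}

#' Build a correlation network from r/p matrices
#'
#' `rule = "exact_unit"` keeps pairs with |r| = 1 (within 1e-12 of exact
#' rank arithmetic); `rule = "bh_alpha"` applies BH adjustment across all
#' tested pairs and keeps adjusted p < alpha. Node types, when supplied,
#' are attached to the node table (BA, taxon, KO, CAZyme, metabolite).
#'
#' @param r,p matrices from [spearman_matrix()] (or a bipartite subset —
#'   rows and columns may differ, in which case all row x column pairs form
#'   the family).
#' @param rule "exact_unit" or "bh_alpha".
#' @param alpha significance level for the BH rule.
#' @param node_types optional named character vector of type tags.
#' @return object of class "ba_network": list with `nodes` (data.frame
#'   name, type) and `edges` (data.frame node_a, node_b, r, p, p_adj, rule).
#' @export
build_network <- function(r, p, rule = c("exact_unit", "bh_alpha"),
                          alpha = 0.05, node_types = NULL) {
  rule <- match.arg(rule)
  if (rule == "bh_alpha" && (alpha <= 0 || alpha >= 1)) {
    stop("alpha must lie in (0, 1)")
  }
  stopifnot(all(dim(r) == dim(p)))
  bipartite <- !identical(rownames(r), colnames(r))
  if (bipartite) {
    idx <- which(!is.na(r), arr.ind = TRUE)
  } else {
    idx <- which(upper.tri(r) & !is.na(r), arr.ind = TRUE)
  }
  ed <- data.frame(
    node_a = rownames(r)[idx[, 1]], node_b = colnames(r)[idx[, 2]],
    r = r[idx], p = p[idx], p_adj = rep(NA_real_, nrow(idx)),
    rule = rep(rule, nrow(idx)),
    stringsAsFactors = FALSE)
  if (rule == "exact_unit") {
    keep <- abs(abs(ed$r) - 1) <= 1e-12
  } else {
    ed$p_adj <- bh_adjust(ed$p)
    keep <- !is.na(ed$p_adj) & ed$p_adj < alpha
  }
  ed <- ed[keep, , drop = FALSE]
  rownames(ed) <- NULL
  nodes <- unique(c(rownames(r), colnames(r)))
  types <- if (is.null(node_types)) rep(NA_character_, length(nodes)) else
    unname(node_types[nodes])
  structure(list(
    nodes = data.frame(name = nodes, type = types, stringsAsFactors = FALSE),
    edges = ed), class = "ba_network")
}

#' Top-k hub nodes by degree
#'
#' Degree over the network's edge list; deterministic alphabetical
#' tie-break, with a flag when the k-th hub is tied with the next node.
#'
#' @param network a "ba_network".
#' @param k number of hubs to return.
#' @return data.frame with columns name, degree, tied.
#' @export
hub_nodes <- function(network, k = 1) {
  stopifnot(inherits(network, "ba_network"))
  ed <- network$edges
  if (nrow(ed) == 0) {
    return(data.frame(name = character(0), degree = integer(0),
                      tied = logical(0)))
  }
  deg <- table(c(ed$node_a, ed$node_b))
  d <- data.frame(name = names(deg), degree = as.integer(deg),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$degree, d$name), , drop = FALSE]
  k <- min(k, nrow(d))
  out <- d[seq_len(k), , drop = FALSE]
  out$tied <- vapply(seq_len(k), function(i) {
    sum(d$degree == out$degree[i]) > sum(out$degree == out$degree[i])
  }, logical(1))
  rownames(out) <- NULL
  out
}

#' @export
print.ba_network <- function(x, ...) {
  cat("ba_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}
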