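# Quantitative bile-acid pool accounting: dilution correction,
# primary/secondary classification, pool totals, the rumen-transformed
# fraction, and VIP + t-test differential selection.

#' Dilution-corrected metabolite concentration
#'
#' C_M = C_F * V_F / V_S: the final measured concentration times the
#' diluted volume over the original sample volume.
#'
#' @param c_f measured concentration, nmol/L.
#' @param v_f final (diluted) volume, uL.
#' @param v_s sample volume, uL (> 0).
#' @return concentration in the original sample, nmol/L.
#' @export
dilute_concentration <- function(c_f, v_f, v_s) {
  if (any(v_s <= 0)) stop("sample volume V_S must be > 0")
  if (any(c_f < 0) || any(v_f < 0)) stop("inputs must be non-negative")
  c_f * v_f / v_s
}

#' Classify bile acids as primary / secondary / unclassified
#'
#' Names are normalized first; names absent from the scheme are flagged
#' "unknown", never dropped.
#'
#' @param names character vector of BA names.
#' @param scheme a [ba_class_scheme()]-style list.
#' @return data.frame with columns name (canonical) and class.
#' @export
classify_bas <- function(names, scheme = ba_class_scheme()) {
  canon <- normalize_ba_name(names)
  cls <- rep("unknown", length(canon))
  cls[canon %in% scheme$primary] <- "primary"
  cls[canon %in% scheme$secondary] <- "secondary"
  cls[canon %in% scheme$unclassified] <- "unclassified"
  data.frame(name = canon, class = cls, stringsAsFactors = FALSE)
}

# internal: coerce/validate a concentration matrix layout
.check_conc <- function(values) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  values
}

#' Per-sample bile-acid pool totals
#'
#' Sums concentrations over the primary and secondary class members per
#' sample; the total includes unclassified and unknown BAs. Missing cells
#' count as absent (0).
#'
#' @param values numeric matrix, samples x BAs (colnames = BA names).
#' @param scheme a [ba_class_scheme()]-style list.
#' @return data.frame with columns sample, primary_total, secondary_total,
#'   total (nmol/L).
#' @export
pool_totals <- function(values, scheme = ba_class_scheme()) {
  values <- .check_conc(values)
  if (ncol(values) == 0 || nrow(values) == 0) {
    return(data.frame(sample = rownames(values) %||% character(0),
                      primary_total = numeric(nrow(values)),
                      secondary_total = numeric(nrow(values)),
                      total = numeric(nrow(values))))
  }
  cls <- classify_bas(colnames(values), scheme)$class
  values[is.na(values)] <- 0
  data.frame(
    sample = rownames(values) %||% as.character(seq_len(nrow(values))),
    primary_total = rowSums(values[, cls == "primary", drop = FALSE]),
    secondary_total = rowSums(values[, cls == "secondary", drop = FALSE]),
    total = rowSums(values),
    row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of the bile-acid pool transformed in the rumen
#'
#' On group-mean concentrations: the summed concentration of BAs not among
#' the exogenously supplemented set, divided by the summed concentration of
#' all BAs. Conjugate/sulfate forms of exogenous BAs are not stripped; the
#' exogenous set is taken literally.
#'
#' @param group_means named numeric vector of mean concentrations (names =
#'   canonical BA ids).
#' @param exogenous character vector of supplemented BA names; defaults to
#'   the six supplemented BAs.
#' @return fraction in [0, 1].
#' @export
transformed_fraction <- function(group_means, exogenous = exogenous_bas()) {
  if (!length(exogenous)) stop("exogenous set must be non-empty")
  stopifnot(!is.null(names(group_means)))
  total <- sum(group_means)
  if (total <= 0) stop("zero total bile-acid concentration")
  nm <- normalize_ba_name(names(group_means))
  sum(group_means[!nm %in% normalize_ba_name(exogenous)]) / total
}

#' Differential bile acids by the joint VIP + t-test rule
#'
#' A BA is significant iff its PLS-DA VIP exceeds `vip_threshold` AND its
#' two-group test p-value is below `alpha`. Zero-variance BAs are flagged
#' non-significant (VIP undefined) rather than dropped. Direction is the
#' sign of the treated-minus-control mean difference.
#'
#' @param values numeric matrix, samples x BAs.
#' @param groups vector of two group labels, length nrow(values).
#' @param control label of the control group; defaults to the first level.
#' @param test "student_t" or "wilcoxon".
#' @param alpha significance level for the test p-value.
#' @param vip_threshold VIP cut-off.
#' @param welch use Welch's t (when test = "student_t").
#' @return data.frame with columns name, class, p, vip, direction,
#'   significant, degenerate.
#' @export
differential_bas <- function(values, groups, control = NULL,
                             test = c("student_t", "wilcoxon"),
                             alpha = 0.05, vip_threshold = 1.0,
                             welch = FALSE) {
  test <- match.arg(test)
  values <- .check_conc(values)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  if (min(table(groups)) < 3) stop("need >= 3 samples per group")
  control <- control %||% lev[1]
  treated <- setdiff(lev, control)
  bas <- colnames(values)
  cls <- classify_bas(bas)$class
  sds <- apply(values, 2, stats::sd)
  usable <- sds > 0
  vip <- rep(NA_real_, length(bas))
  if (sum(usable) >= 1) {
    # identical group distributions can defeat weight extraction; VIPs
    # then stay undefined and nothing is called significant
    vr <- tryCatch(
      plsda_vip(values[, usable, drop = FALSE],
                as.numeric(groups == treated), n_components = 1),
      error = function(e) NULL)
    if (!is.null(vr)) vip[usable] <- vr$vip
  }
  p <- direction <- numeric(length(bas))
  for (j in seq_along(bas)) {
    x <- values[groups == treated, j]
    y <- values[groups == control, j]
    direction[j] <- sign(mean(x) - mean(y))
    p[j] <- if (!usable[j]) NA_real_ else if (test == "student_t") {
      student_t(x, y, welch = welch)$p_value
    } else {
      wilcoxon_rank_sum(x, y)$p_value
    }
  }
  significant <- usable & !is.na(vip) & vip > vip_threshold &
    !is.na(p) & p < alpha
  data.frame(name = bas, class = cls, p = p, vip = vip,
             direction = direction, significant = significant,
             degenerate = !usable, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Mutual differential bile acids between two experiments
#'
#' Intersection of two differential lists after normalization; ordered by
#' descending absolute effect from the first list when effects are
#' supplied, alphabetically otherwise.
#'
#' @param list_a,list_b character vectors of BA names.
#' @param effects_a optional named numeric vector of effects for `list_a`.
#' @return character vector of canonical names.
#' @export
mutual_differentials <- function(list_a, list_b, effects_a = NULL) {
  a <- normalize_ba_name(list_a)
  b <- normalize_ba_name(list_b)
  both <- intersect(a, b)
  if (!is.null(effects_a)) {
    names(effects_a) <- normalize_ba_name(names(effects_a))
    eff <- abs(effects_a[both])
    eff[is.na(eff)] <- -Inf
    both <- both[order(-eff, both)]
  } else {
    both <- sort(both)
  }
  both
}
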