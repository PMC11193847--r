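# Rule-based bile-acid biotransformation engine. Four operator classes act
# on the steroid ring positions:
#   epimerization  (pos 3/6/7/12): flips an existing OH alpha<->beta;
#                  at position 5 it flips the ring-junction configuration.
#   dehydroxylation (pos 3/6/7/12): removes an OH regardless of its
#                  orientation (the classical 7alpha-dehydroxylation label
#                  is kept even for 7beta substrates; the substrate's
#                  orientation is recorded on the edge).
#   oxidation       (pos 3/6/7/12): OH -> oxo (HSDH oxidative half).
#   reduction       (pos 3/6/7/12): oxo -> OH at a target orientation
#                  (HSDH reductive half); oxidation followed by reduction
#                  to the opposite orientation composes to epimerization.

.OPERATOR_CLASSES <- c("epimerization", "dehydroxylation", "oxidation",
                       "reduction")

#' Construct a reaction operator
#'
#' @param class one of "epimerization", "dehydroxylation", "oxidation",
#'   "reduction".
#' @param position steroid position: 3, 5, 6, 7 or 12. Position 5 admits
#'   epimerization only.
#' @param target_orientation "a" or "b"; required for reduction, ignored
#'   otherwise.
#' @return list of class "ba_operator".
#' @export
reaction_operator <- function(class, position, target_orientation = NA) {
  class <- match.arg(class, .OPERATOR_CLASSES)
  if (!position %in% c(3, 5, 6, 7, 12)) stop("invalid position: ", position)
  if (position == 5 && class != "epimerization") {
    stop("position 5 admits epimerization only")
  }
  if (class == "reduction" && !target_orientation %in% c("a", "b")) {
    stop("reduction requires target_orientation 'a' or 'b'")
  }
  structure(list(class = class, position = position,
                 target_orientation = target_orientation),
            class = "ba_operator")
}

#' Apply a reaction operator to a bile-acid structure
#'
#' Returns the product structure, or NULL when the operator's precondition
#' fails on the substrate (no OH to epimerize/remove/oxidise, no oxo to
#' reduce). The product name is looked up in `dict`; structures not in the
#' dictionary receive a systematic positional name.
#'
#' @param s one-row data.frame as in [ba_structures()], or a BA name to be
#'   resolved against `dict`.
#' @param op a [reaction_operator()].
#' @param dict structure dictionary used for product naming.
#' @return one-row data.frame like `s`, or NULL.
#' @export
apply_operator <- function(s, op, dict = ba_structures()) {
  stopifnot(inherits(op, "ba_operator"))
  if (is.character(s)) {
    i <- match(s, dict$name)
    if (is.na(i)) stop("unknown structure: ", s)
    s <- dict[i, , drop = FALSE]
  }
  if (op$position == 5) {
    s$c5 <- if (s$c5 == "a") "b" else "a"
  } else {
    col <- paste0("c", op$position)
    st <- s[[col]]
    new <- switch(op$class,
      epimerization = if (st %in% c("a", "b")) {
        if (st == "a") "b" else "a"
      },
      dehydroxylation = if (st %in% c("a", "b")) "-",
      oxidation = if (st %in% c("a", "b")) "oxo",
      reduction = if (st == "oxo") op$target_orientation
    )
    if (is.null(new)) return(NULL)
    s[[col]] <- new
  }
  i <- match(.structure_key(s), .structure_key(dict))
  s$name <- if (!is.na(i)) dict$name[i] else .systematic_name(s)
  rownames(s) <- NULL
  s
}

# the operator universe tried during enumeration
.operator_universe <- function(mode) {
  ops <- list()
  direct <- mode %in% c("direct_epimerization", "both")
  composite <- mode %in% c("composite_via_oxo", "both")
  for (pos in c(3, 6, 7, 12)) {
    if (direct) ops <- c(ops, list(reaction_operator("epimerization", pos)))
    ops <- c(ops, list(reaction_operator("dehydroxylation", pos)))
    if (composite) {
      ops <- c(ops, list(reaction_operator("oxidation", pos)),
               list(reaction_operator("reduction", pos, "a")),
               list(reaction_operator("reduction", pos, "b")))
    }
  }
  if (direct) ops <- c(ops, list(reaction_operator("epimerization", 5)))
  ops
}

# edge orientation label: the orientation the reaction produces/consumes
.edge_orientation <- function(substrate, product, op) {
  if (op$position == 5) return(product$c5)
  col <- paste0("c", op$position)
  switch(op$class,
         epimerization = product[[col]],
         dehydroxylation = substrate[[col]],   # orientation removed
         oxidation = substrate[[col]],
         reduction = product[[col]])
}

#' Enumerate the biotransformation graph over a bile-acid set
#'
#' Tries every applicable operator on every structure and keeps an edge iff
#' the product is itself in the set. `direct_epimerization` emits
#' epimerization and dehydroxylation edges; `composite_via_oxo` decomposes
#' epimerization into its oxidation + opposite-orientation reduction
#' half-steps (oxo intermediates appear only when they are in the set);
#' `both` emits the union.
#'
#' @param names character vector of BA names present in `dict`, all distinct.
#' @param mode "direct_epimerization", "composite_via_oxo" or "both".
#' @param dict structure dictionary.
#' @return object of class "ba_graph": list with `nodes` (character) and
#'   `edges` (data.frame substrate, product, class, position, orientation).
#' @export
enumerate_edges <- function(names, mode = c("both", "direct_epimerization",
                                            "composite_via_oxo"),
                            dict = ba_structures()) {
  mode <- match.arg(mode)
  .validate_structures(dict)
  if (anyDuplicated(names)) stop("duplicate structures in input set")
  miss <- setdiff(names, dict$name)
  if (length(miss)) stop("structures not in dictionary: ",
                         paste(miss, collapse = ", "))
  ops <- .operator_universe(mode)
  rows <- list()
  for (nm in names) {
    s <- dict[match(nm, dict$name), , drop = FALSE]
    for (op in ops) {
      prod <- apply_operator(s, op, dict)
      if (is.null(prod) || !(prod$name %in% names) || prod$name == nm) next
      rows[[length(rows) + 1L]] <- data.frame(
        substrate = nm, product = prod$name, class = op$class,
        position = op$position,
        orientation = .edge_orientation(s, prod, op),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(substrate = character(0), product = character(0),
               class = character(0), position = integer(0),
               orientation = character(0), stringsAsFactors = FALSE)
  edges <- unique(edges)
  rownames(edges) <- NULL
  structure(list(nodes = names, edges = edges, mode = mode),
            class = "ba_graph")
}

#' The proposed rumen biotransformation pathway edges
#'
#' The substrate/product pairs of the proposed pathway among the rumen
#' bile acids: 7beta-, 3beta-, 5alpha- and 6beta-epimerizations plus
#' 7alpha-dehydroxylations linking CA, HCA and CDCA derivatives.
#'
#' @return data.frame with columns substrate, product, reaction.
#' @export
expected_pathway_edges <- function() {
  omcap <- paste0(.OMEGA, "-MCA")
  e <- function(s, p, r) data.frame(substrate = s, product = p, reaction = r,
                                    stringsAsFactors = FALSE)
  rbind(
    e("CA", "UCA", "7b-epimerization"),
    e("CA", "3-DHCA", "3-oxidation"),
    e("CA", "alloCA", "5a-epimerization"),
    e("HCA", "HDCA", "7a-dehydroxylation"),
    e("HDCA", "isoHDCA", "3b-epimerization"),
    e("CDCA", "LCA", "7a-dehydroxylation"),
    e("CDCA", "UDCA", "7b-epimerization"),
    e("UDCA", "LCA", "7-dehydroxylation"),
    e("LCA", "DHLCA", "3-oxidation"),
    e("UDCA", "isoUDCA", "3b-epimerization"),
    e("HCA", omcap, "7b-epimerization"),
    e(omcap, "HDCA", "7-dehydroxylation"),
    e("DHLCA", "isoLCA", "3b-reduction"),
    e("isoUDCA", "isoLCA", "7-dehydroxylation")
  )
}

#' Validate an enumerated graph against an expected edge list
#'
#' Partitions the expected substrate/product pairs into those found in the
#' graph and those missing, and lists graph edges (as unique pairs) not in
#' the expected set.
#'
#' @param graph a "ba_graph" from [enumerate_edges()].
#' @param expected data.frame with columns substrate, product.
#' @return list with data.frames `found`, `missing`, `extra`.
#' @export
validate_pathway <- function(graph, expected = expected_pathway_edges()) {
  stopifnot(inherits(graph, "ba_graph"))
  unk <- setdiff(c(expected$substrate, expected$product), graph$nodes)
  if (length(unk)) stop("expected edges reference unknown structures: ",
                        paste(unique(unk), collapse = ", "))
  gpairs <- unique(graph$edges[, c("substrate", "product")])
  gk <- paste(gpairs$substrate, gpairs$product, sep = "->")
  ek <- paste(expected$substrate, expected$product, sep = "->")
  found <- expected[ek %in% gk, , drop = FALSE]
  missing <- expected[!ek %in% gk, , drop = FALSE]
  extra <- gpairs[!gk %in% ek, , drop = FALSE]
  rownames(found) <- rownames(missing) <- rownames(extra) <- NULL
  list(found = found, missing = missing, extra = extra)
}

#' Transitive closure of biotransformation from seed bile acids
#'
#' Which members of `names` are derivable from `seeds` along enumerated
#' edges (including the seeds themselves).
#'
#' @param seeds character vector, subset of `names`.
#' @param names the structure set to enumerate over.
#' @param mode passed to [enumerate_edges()].
#' @param dict structure dictionary.
#' @return character vector of reachable names.
#' @export
reachable <- function(seeds, names, mode = "both", dict = ba_structures()) {
  if (!all(seeds %in% names)) stop("seeds must be a subset of the set")
  g <- enumerate_edges(names, mode, dict)
  reach <- seeds
  repeat {
    nxt <- unique(g$edges$product[g$edges$substrate %in% reach])
    new <- setdiff(nxt, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  sort(reach)
}

#' @export
print.ba_graph <- function(x, ...) {
  cat("ba_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (mode:", x$mode, ")\n")
  invisible(x)
}
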