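test_that("operators implement the epimerization/dehydroxylation/redox rules", {
  expect_equal(apply_operator("CA", reaction_operator("epimerization", 7))$name,
               "UCA")
  expect_equal(apply_operator("HCA",
                              reaction_operator("dehydroxylation", 7))$name,
               "HDCA")
  expect_null(apply_operator("LCA", reaction_operator("epimerization", 12)))
  expect_equal(apply_operator("DHLCA",
                              reaction_operator("reduction", 3, "b"))$name,
               "isoLCA")
  expect_equal(apply_operator("CA", reaction_operator("epimerization", 5))$name,
               "alloCA")
  expect_error(reaction_operator("oxidation", 5), "position 5")
  expect_error(reaction_operator("reduction", 3), "target_orientation")
  # known products are named from the dictionary ...
  expect_equal(apply_operator("DCA",
                              reaction_operator("oxidation", 12))$name,
               "12-ketoLCA")
  # ... unknown ones fall back to a systematic positional name
  s <- apply_operator("MDCA", reaction_operator("oxidation", 3))
  expect_match(s$name, "3-oxo", fixed = TRUE)
})

test_that("epimerization is an involution and preserves hydroxyl count", {
  dict <- ba_structures()
  nOH <- function(s) sum(unlist(s[c("c3", "c6", "c7", "c12")]) %in%
                           c("a", "b"))
  for (nm in dict$name) {
    s <- dict[dict$name == nm, ]
    for (pos in c(3, 5, 6, 7, 12)) {
      op <- reaction_operator("epimerization", pos)
      p <- apply_operator(s, op)
      if (is.null(p)) next
      expect_equal(apply_operator(p, op)$name, nm)
      expect_equal(nOH(p), nOH(s))
      # dehydroxylation strictly decreases hydroxyl count
      if (pos != 5) {
        d <- apply_operator(s, reaction_operator("dehydroxylation", pos))
        expect_equal(nOH(d), nOH(s) - 1)
      }
    }
  }
})

test_that("oxidation then opposite reduction composes to epimerization", {
  dict <- ba_structures()
  for (nm in c("CA", "HDCA", "UDCA", "LCA")) {
    for (pos in c(3, 6, 7, 12)) {
      s <- dict[dict$name == nm, ]
      st <- s[[paste0("c", pos)]]
      if (!st %in% c("a", "b")) next
      ox <- apply_operator(s, reaction_operator("oxidation", pos))
      red <- apply_operator(ox, reaction_operator("reduction", pos,
                                                  if (st == "a") "b" else "a"))
      epi <- apply_operator(s, reaction_operator("epimerization", pos))
      expect_equal(red$name, epi$name)
    }
  }
})

test_that("two-node and three-node enumerations match hand enumeration", {
  g <- enumerate_edges(c("CA", "UCA"), "direct_epimerization")
  expect_equal(nrow(g$edges), 2)
  expect_setequal(paste(g$edges$substrate, g$edges$product, sep = "->"),
                  c("CA->UCA", "UCA->CA"))
  expect_true(all(g$edges$class == "epimerization" & g$edges$position == 7))
  g3 <- enumerate_edges(c("HDCA", "6-ketoLCA", "MDCA"), "composite_via_oxo")
  k3 <- paste(g3$edges$substrate, g3$edges$product, g3$edges$class)
  expect_true("HDCA 6-ketoLCA oxidation" %in% k3)
  expect_true("6-ketoLCA MDCA reduction" %in% k3)
  expect_false(any(g3$edges$class == "epimerization"))
  gb <- enumerate_edges(c("HDCA", "6-ketoLCA", "MDCA"), "both")
  kb <- paste(gb$edges$substrate, gb$edges$product, gb$edges$class)
  expect_true("HDCA MDCA epimerization" %in% kb)
})

test_that("enumeration equals the independent transition oracle", {
  dict <- ba_structures()
  sets <- list(
    mutual_differential_bas(),
    union(mutual_differential_bas(), c("CA", "isoUDCA")),
    dict$name,                         # full dictionary (28 structures)
    c("LCA", "DHLCA", "isoLCA")
  )
  for (mode in c("direct_epimerization", "composite_via_oxo", "both")) {
    for (s in sets) {
      g <- enumerate_edges(s, mode)
      got <- sort(unique(paste(g$edges$substrate, g$edges$product,
                               sep = "->")))
      expect_equal(got, oracle_enumerate_pairs(s, mode))
    }
  }
})

test_that("every stated pathway edge is recovered in both mode", {
  nodes <- union(mutual_differential_bas(), c("CA", "isoUDCA"))
  g <- enumerate_edges(nodes, "both")
  rep_ <- validate_pathway(g)
  expect_equal(nrow(rep_$missing), 0)
  expect_equal(nrow(rep_$found), nrow(expected_pathway_edges()))
  # the CDCA -> UDCA edge is a 7-epimerization
  e <- g$edges[g$edges$substrate == "CDCA" & g$edges$product == "UDCA", ]
  expect_true(all(e$class == "epimerization" & e$position == 7))
  # empty expected: everything is extra
  r0 <- validate_pathway(g, expected_pathway_edges()[0, ])
  expect_equal(nrow(r0$found), 0)
  expect_equal(nrow(r0$extra), nrow(unique(g$edges[, 1:2])))
})

test_that("reachability is the transitive closure over enumerated edges", {
  expect_setequal(reachable("LCA", c("LCA", "DHLCA", "isoLCA"), "both"),
                  c("LCA", "DHLCA", "isoLCA"))
  full <- c("CA", "UCA")
  expect_setequal(reachable(full, full), full)
  expect_error(reachable("HDCA", c("CA", "UCA")), "subset")
})

test_that("degenerate inputs are rejected", {
  expect_error(enumerate_edges(c("CA", "CA")), "duplicate")
  expect_error(enumerate_edges("not-a-BA"), "not in dictionary")
  g <- enumerate_edges(c("CA", "UCA"))
  bad <- data.frame(substrate = "CA", product = "XYZ")
  expect_error(validate_pathway(g, bad), "unknown structures")
})
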