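test_that("quality score is completeness minus five times contamination", {
  expect_equal(quality_score(90, 2), 80)
  expect_equal(quality_score(100, 0), 100)
  expect_equal(quality_score(80, 10), 30)
  expect_error(quality_score(101, 0), "completeness")
  expect_error(quality_score(90, -1), "contamination")
})

test_that("filtering is strict at the printed thresholds and idempotent", {
  cat <- data.frame(mag_id = c("m1", "m2", "m3"),
                    completeness = c(81, 80, 95),
                    contamination = c(9, 5, 10))
  f <- filter_mags(cat)
  expect_equal(f$mag_id, "m1")
  # inclusive mode keeps the boundary cases
  expect_equal(filter_mags(cat, inclusive = TRUE)$mag_id,
               c("m1", "m2", "m3"))
  allpass <- data.frame(mag_id = c("a", "b"), completeness = c(90, 99),
                        contamination = c(1, 2))
  expect_equal(filter_mags(allpass), allpass)
  expect_equal(filter_mags(filter_mags(cat)), filter_mags(cat))
  expect_warning(filter_mags(cat[0, ]), "empty")
})

test_that("filtering a synthetic catalog matches a row-by-row re-check", {
  gen <- gen_mag_catalog(synth_config(seed = 3, n_mags = 5000))
  f <- filter_mags(gen$catalog)
  keep <- logical(nrow(gen$catalog))
  for (i in seq_len(nrow(gen$catalog))) {
    keep[i] <- gen$catalog$completeness[i] > 80 &&
      gen$catalog$contamination[i] < 10
  }
  expect_equal(nrow(f), sum(keep))
  expect_equal(f$mag_id, gen$catalog$mag_id[keep])
})

test_that("BAKO screen counts agree with the brute-force tally", {
  gen <- make_mag_fixture(n = 400, seed = 11)
  s <- screen_bakos(gen$catalog, gen$ko_table)
  o <- oracle_screen_tally(gen$catalog, gen$ko_table, bako_catalog()$ko)
  expect_equal(s$bamag_ids, o$bamags)
  expect_equal(s$per_ko_mag_count, o$mag_count)
  expect_equal(s$per_ko_gene_count, o$gene_count)
  expect_equal(s$totals[["total_bako_genes"]],
               sum(s$per_ko_gene_count))
  # structural invariants
  expect_true(all(s$per_ko_gene_count >= s$per_ko_mag_count))
  expect_lte(s$totals[["n_bamags"]], s$totals[["n_filtered_mags"]])
  expect_true(all(s$bamag_s_ids %in% s$bamag_ids))
})

test_that("malformed KO ids are rejected with a count", {
  gen <- make_mag_fixture(n = 30, seed = 5)
  bad <- rbind(gen$ko_table,
               data.frame(gene_id = "gX", mag_id = gen$catalog$mag_id[1],
                          ko_id = "notako"))
  expect_message(s <- screen_bakos(gen$catalog, bad), "rejected")
  expect_equal(s$n_rejected_rows, 1L)
})

test_that("proportion report uses raw floats with printed-style rounding", {
  s <- list(per_ko_mag_count = c(K07007 = 3013),
            per_ko_gene_count = c(K07007 = 4623),
            totals = c(n_filtered_mags = 3954, n_bamags = 3585,
                       total_bako_genes = 7840))
  pr <- summarize_proportions(s)
  expect_equal(pr$per_ko$mag_pct, 100 * 3013 / 3585)
  expect_equal(pr$per_ko$mag_pct_printed, 84)
  expect_equal(pr$per_ko$gene_pct_printed, 59)
  # single KO carried by all BAMAGs
  s2 <- list(per_ko_mag_count = c(K01442 = 10),
             per_ko_gene_count = c(K01442 = 12),
             totals = c(n_filtered_mags = 20, n_bamags = 10,
                        total_bako_genes = 12))
  expect_equal(summarize_proportions(s2)$per_ko$mag_pct, 100)
  s2$totals["n_bamags"] <- 0
  expect_error(summarize_proportions(s2), "denominator")
})

test_that("taxonomy breakdown tallies fractions that sum to one", {
  cat <- data.frame(
    mag_id = paste0("m", 1:5),
    taxonomy = c(rep("d__Bacteria;p__X;c__C;o__O;f__Lachnospiraceae;g__G;s__", 3),
                 "d__Bacteria;p__X;c__C;o__O;f__Bacteroidaceae;g__G;s__S p",
                 "d__Bacteria"))
  b <- taxonomy_breakdown(cat, "family")
  expect_equal(sum(b$fraction), 1, tolerance = 1e-12)
  expect_equal(b$count[b$taxon == "Lachnospiraceae"], 3L)
  expect_equal(b$count[b$taxon == "unlabeled"], 1L)
  expect_equal(sum(b$count), nrow(cat))
  # species rank: only one labelled record
  bs <- taxonomy_breakdown(cat, "species")
  expect_equal(bs$count[bs$taxon == "unlabeled"], 4L)
})

test_that("planted prevalences are recovered within 3 binomial SDs", {
  p <- 0.84
  n <- 5000
  cfg <- synth_config(seed = 21, n_mags = n,
                      bako_prevalence = c(K07007 = p))
  gen <- gen_mag_catalog(cfg)
  carriers <- length(unique(gen$ko_table$mag_id))
  tol <- 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(carriers / n - p), tol)
})

test_that("isolate screening merges duplicate organisms", {
  iso <- data.frame(
    organism_id = c("org1", "org1", "org2", "org3"),
    ko_id = c("K03453", "K01442", "K03453", "K99999"))
  s <- screen_isolates(iso)
  expect_equal(s$n_organisms, 3L)
  expect_equal(s$carriers, c("org1", "org2"))
  expect_equal(s$non_carriers, "org3")
  expect_equal(s$per_ko_organism_count,
               c(K01442 = 1L, K03453 = 2L))
})

test_that("species normalization and BAMD union collapse aliases", {
  nm <- data.frame(gtdb_name = "Prevotella sp900314947",
                   ncbi_name = "Prevotellaceae bacterium X")
  expect_equal(
    normalize_species_name(c("Candidatus Prevotella sp900314947"), nm),
    "prevotellaceae bacterium x")
  bamd <- build_bamd(c("A sp1", "B sp2", "C sp3"), c("D sp4", "E sp5"))
  expect_length(bamd, 5)
  bamd2 <- build_bamd(c("Prevotella sp900314947"),
                      c("prevotellaceae Bacterium X"), nm)
  expect_length(bamd2, 1)
  conf <- rbind(nm, data.frame(gtdb_name = "Prevotella sp900314947",
                               ncbi_name = "Other name"))
  expect_error(build_bamd("x", "y", conf), "conflicting")
})

test_that("set analysis reproduces the union/intersection logic", {
  s <- set_analysis(bamd = c("a", "b", "c"),
                    detected_species = c("b", "c", "d"),
                    diff_lists = list(c("a", "b"), c("b", "c"), character(0)))
  expect_equal(s$t_bamd, c("b", "c"))
  expect_equal(s$dfm_s, c("a", "b", "c"))
  expect_equal(s$dfm_with_bako, c("a", "b", "c"))
  s2 <- set_analysis(c("x"), c("x"), list(c("q"), c("r")))
  expect_length(s2$dfm_with_bako, 0)
  # randomized membership check
  set.seed(9)
  bamd <- paste0("sp", sample(300, 100))
  det <- paste0("sp", sample(300, 50))
  dl <- list(paste0("sp", sample(300, 30)), paste0("sp", sample(300, 20)),
             paste0("sp", sample(300, 10)))
  s3 <- set_analysis(bamd, det, dl)
  expect_equal(sort(s3$dfm_with_bako),
               sort(unique(unlist(dl))[unique(unlist(dl)) %in% bamd]))
})
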