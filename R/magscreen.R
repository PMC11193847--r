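# MAG quality filtering and screening for bile-acid-metabolism-associated
# KEGG orthologs (BAKOs), taxonomy summaries, isolate screening and the
# BAMD (BA metabolism microbiome database) set logic.

.KO_PATTERN <- "^K[0-9]{5}$"
.TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

#' Default BAKO catalog
#'
#' The core set of bile-acid-metabolism-associated KEGG orthologs detected
#' in rumen genomes: baiN, BASS, BSH, SLC10A7, 3a-HSDH, 7a-HSDH, baiB,
#' AMACR and HADH. The full screened catalog is configurable (the curated
#' screen used 82 KOs); additional KO ids can be appended via `extra_kos`.
#'
#' @param extra_kos optional character vector of further KO ids (K#####).
#' @return data.frame with columns ko, symbol, description, core.
#' @export
bako_catalog <- function(extra_kos = NULL) {
  d <- data.frame(
    ko = c("K07007", "K03453", "K01442", "K14347", "K00038", "K00076",
           "K15868", "K01796", "K00022"),
    symbol = c("baiN", "BASS", "BSH", "SLC10A7", "3a-HSDH", "7a-HSDH",
               "baiB", "AMACR", "HADH"),
    description = c(
      "3-dehydro-bile acid delta4,6-reductase",
      "bile acid:Na+ symporter family",
      "bile salt hydrolase (choloylglycine hydrolase)",
      "solute carrier family 10 member 7 (Na+/bile acid cotransporter)",
      "3alpha-hydroxysteroid dehydrogenase",
      "7alpha-hydroxysteroid dehydrogenase",
      "bile acid-coenzyme A ligase",
      "alpha-methylacyl-CoA racemase",
      "3-hydroxyacyl-CoA dehydrogenase"),
    core = TRUE, stringsAsFactors = FALSE)
  if (!is.null(extra_kos)) {
    extra_kos <- setdiff(unique(extra_kos), d$ko)
    if (length(extra_kos)) {
      bad <- !grepl(.KO_PATTERN, extra_kos)
      if (any(bad)) stop("invalid KO ids: ",
                         paste(extra_kos[bad], collapse = ", "))
      d <- rbind(d, data.frame(ko = extra_kos, symbol = NA_character_,
                               description = NA_character_, core = FALSE))
    }
  }
  if (anyDuplicated(d$ko)) stop("duplicate KO ids in catalog")
  d
}

#' MAG quality score
#'
#' Completeness minus five times contamination (the standard MIMAG-style
#' quality score). Both inputs are percentages.
#'
#' @param completeness percent in [0, 100].
#' @param contamination percent >= 0.
#' @return numeric score (dimensionless).
#' @export
quality_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100)) {
    stop("completeness must lie in [0, 100]")
  }
  if (any(contamination < 0)) stop("contamination must be >= 0")
  completeness - 5 * contamination
}

#' Filter a MAG catalog on completeness and contamination
#'
#' Keeps MAGs with completeness strictly above `min_completeness` and
#' contamination strictly below `max_contamination` (thresholds as
#' printed: > 80%, < 10%); an inclusive mode is available. Exact duplicate
#' MAG ids are dropped first (input catalogs are assumed dereplicated).
#' Order-preserving and idempotent.
#'
#' @param catalog data.frame with columns mag_id, completeness,
#'   contamination (and usually taxonomy).
#' @param min_completeness,max_contamination thresholds in percent.
#' @param inclusive use >= / <= at the boundaries.
#' @return the filtered catalog.
#' @export
filter_mags <- function(catalog, min_completeness = 80,
                        max_contamination = 10, inclusive = FALSE) {
  stopifnot(all(c("mag_id", "completeness", "contamination") %in%
                  names(catalog)))
  if (nrow(catalog) == 0) {
    warning("empty MAG catalog")
    return(catalog)
  }
  catalog <- catalog[!duplicated(catalog$mag_id), , drop = FALSE]
  keep <- if (inclusive) {
    catalog$completeness >= min_completeness &
      catalog$contamination <= max_contamination
  } else {
    catalog$completeness > min_completeness &
      catalog$contamination < max_contamination
  }
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse GTDB-style taxonomy strings
#'
#' Splits semicolon-delimited rank strings with d__/p__/c__/o__/f__/g__/s__
#' prefixes into a seven-column data.frame; missing or unprefixed ranks
#' become "".
#'
#' @param taxonomy character vector of GTDB taxonomy strings.
#' @return data.frame with columns domain..species.
#' @export
parse_taxonomy <- function(taxonomy) {
  prefixes <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  out <- matrix("", nrow = length(taxonomy), ncol = 7,
                dimnames = list(NULL, .TAX_RANKS))
  for (i in seq_along(taxonomy)) {
    if (is.na(taxonomy[i]) || !nzchar(taxonomy[i])) next
    parts <- trimws(strsplit(taxonomy[i], ";", fixed = TRUE)[[1]])
    for (p in parts) {
      j <- match(substr(p, 1, 3), prefixes)
      if (!is.na(j)) out[i, j] <- substring(p, 4)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Screen a filtered MAG catalog for BAKO carriers
#'
#' A MAG is a BAMAG iff its annotated KO set intersects the BAKO catalog.
#' Returns per-KO MAG counts, per-KO gene counts, the BAMAG id set, and the
#' species-resolved subset (BAMAGs-s: BAMAGs whose taxonomy has a non-empty
#' species rank).
#'
#' @param catalog (filtered) MAG catalog data.frame.
#' @param ko_table data.frame with columns gene_id, mag_id, ko_id.
#' @param bako a [bako_catalog()] data.frame.
#' @return object of class "screen_summary": list with `bamag_ids`,
#'   `bamag_s_ids`, `per_ko_mag_count`, `per_ko_gene_count`, `totals`,
#'   `n_rejected_rows`.
#' @export
screen_bakos <- function(catalog, ko_table, bako = bako_catalog()) {
  stopifnot(all(c("gene_id", "mag_id", "ko_id") %in% names(ko_table)))
  bad <- !grepl(.KO_PATTERN, ko_table$ko_id)
  n_rejected <- sum(bad)
  if (n_rejected) {
    message(n_rejected, " KO-table row(s) with malformed KO ids rejected")
    ko_table <- ko_table[!bad, , drop = FALSE]
  }
  ko_table <- ko_table[ko_table$mag_id %in% catalog$mag_id, , drop = FALSE]
  hits <- ko_table[ko_table$ko_id %in% bako$ko, , drop = FALSE]
  bamag_ids <- sort(unique(hits$mag_id))
  per_mag <- tapply(hits$mag_id, hits$ko_id,
                    function(m) length(unique(m)))
  per_gene <- table(hits$ko_id)
  kos <- sort(unique(hits$ko_id))
  per_ko_mag_count <- stats::setNames(as.integer(per_mag[kos]), kos)
  per_ko_gene_count <- stats::setNames(as.integer(per_gene[kos]), kos)
  species <- if ("taxonomy" %in% names(catalog)) {
    tx <- parse_taxonomy(catalog$taxonomy)
    stats::setNames(tx$species, catalog$mag_id)
  } else {
    stats::setNames(rep("", nrow(catalog)), catalog$mag_id)
  }
  bamag_s_ids <- bamag_ids[nzchar(species[bamag_ids])]
  structure(list(
    bamag_ids = bamag_ids,
    bamag_s_ids = bamag_s_ids,
    per_ko_mag_count = per_ko_mag_count,
    per_ko_gene_count = per_ko_gene_count,
    totals = c(n_filtered_mags = nrow(catalog),
               n_bamags = length(bamag_ids),
               total_bako_genes = nrow(hits)),
    n_rejected_rows = n_rejected
  ), class = "screen_summary")
}

# printed-style rounding: nearest integer when >= 1%, two decimals below
.printed_pct <- function(pct) {
  ifelse(pct >= 1, round(pct), round(pct, 2))
}

#' Proportion report from a screen summary
#'
#' MAG-level percentage per KO (over BAMAGs), gene-level percentage per KO
#' (over all BAKO genes), and the BAMAG fraction of the filtered catalog.
#' Raw floats are authoritative; a printed-style rounding (nearest integer
#' at >= 1%, two decimals below 1%) is attached for display.
#'
#' @param summary a "screen_summary", or a list with elements
#'   `per_ko_mag_count`, `per_ko_gene_count` and `totals` (named vector
#'   with n_filtered_mags, n_bamags, total_bako_genes).
#' @return list with data.frame `per_ko` (ko, mag_count, mag_pct,
#'   mag_pct_printed, gene_count, gene_pct, gene_pct_printed) and
#'   `bamag_fraction_pct`, `bamag_fraction_printed`.
#' @export
summarize_proportions <- function(summary) {
  tot <- summary$totals
  if (tot[["n_bamags"]] <= 0 || tot[["total_bako_genes"]] <= 0 ||
      tot[["n_filtered_mags"]] <= 0) {
    stop("zero denominator in screen totals")
  }
  kos <- union(names(summary$per_ko_mag_count),
               names(summary$per_ko_gene_count))
  mg <- summary$per_ko_mag_count[kos]
  gn <- summary$per_ko_gene_count[kos]
  mg[is.na(mg)] <- 0L
  gn[is.na(gn)] <- 0L
  mag_pct <- 100 * mg / tot[["n_bamags"]]
  gene_pct <- 100 * gn / tot[["total_bako_genes"]]
  frac <- 100 * tot[["n_bamags"]] / tot[["n_filtered_mags"]]
  list(
    per_ko = data.frame(
      ko = kos, mag_count = as.integer(mg),
      mag_pct = as.numeric(mag_pct),
      mag_pct_printed = .printed_pct(as.numeric(mag_pct)),
      gene_count = as.integer(gn),
      gene_pct = as.numeric(gene_pct),
      gene_pct_printed = .printed_pct(as.numeric(gene_pct)),
      row.names = NULL, stringsAsFactors = FALSE),
    bamag_fraction_pct = frac,
    bamag_fraction_printed = .printed_pct(frac))
}

#' Taxonomic composition of BAMAGs at a rank
#'
#' Fractions over records with a non-empty label at the requested rank,
#' plus an "unlabeled" bucket; fractions sum to 1.
#'
#' @param catalog MAG catalog rows for the BAMAGs (needs `taxonomy`).
#' @param rank one of domain, phylum, class, order, family, genus, species.
#' @return data.frame with columns taxon, count, fraction, sorted by
#'   descending count ("unlabeled" last).
#' @export
taxonomy_breakdown <- function(catalog, rank = "family") {
  rank <- match.arg(rank, .TAX_RANKS)
  tx <- parse_taxonomy(catalog$taxonomy)
  lab <- tx[[rank]]
  lab[!nzchar(lab)] <- "unlabeled"
  cnt <- sort(table(lab), decreasing = TRUE)
  d <- data.frame(taxon = names(cnt), count = as.integer(cnt),
                  fraction = as.integer(cnt) / sum(cnt),
                  stringsAsFactors = FALSE)
  unl <- d$taxon == "unlabeled"
  d <- rbind(d[!unl, , drop = FALSE], d[unl, , drop = FALSE])
  rownames(d) <- NULL
  d
}

#' Screen cultured-isolate annotations for BAKO carriers
#'
#' Duplicate organism ids are merged (union of KO sets) before screening.
#' Returns per-KO organism counts and the carrier / non-carrier partition.
#'
#' @param isolates data.frame with columns organism_id, ko_id.
#' @param bako a [bako_catalog()] data.frame.
#' @return list with `per_ko_organism_count`, `carriers`, `non_carriers`,
#'   `n_organisms`, `carrier_ratio`.
#' @export
screen_isolates <- function(isolates, bako = bako_catalog()) {
  stopifnot(all(c("organism_id", "ko_id") %in% names(isolates)))
  isolates <- unique(isolates[, c("organism_id", "ko_id")])
  orgs <- sort(unique(isolates$organism_id))
  hits <- isolates[grepl(.KO_PATTERN, isolates$ko_id) &
                     isolates$ko_id %in% bako$ko, , drop = FALSE]
  carriers <- sort(unique(hits$organism_id))
  per <- tapply(hits$organism_id, hits$ko_id,
                function(o) length(unique(o)))
  kos <- sort(unique(hits$ko_id))
  list(per_ko_organism_count = stats::setNames(as.integer(per[kos]), kos),
       carriers = carriers,
       non_carriers = setdiff(orgs, carriers),
       n_organisms = length(orgs),
       carrier_ratio = length(carriers) / max(1L, length(orgs)))
}

#' Normalize a species name for cross-database set logic
#'
#' Lowercases, collapses whitespace, strips a leading "Candidatus", then
#' applies a GTDB -> NCBI name map. Placeholder "sp."-suffixed names stay
#' distinct identities; unmapped names pass through unchanged.
#'
#' @param names character vector of species names.
#' @param name_map optional data.frame with columns gtdb_name, ncbi_name.
#' @return character vector of canonical species names.
#' @export
normalize_species_name <- function(names, name_map = NULL) {
  x <- gsub("\\s+", " ", trimws(names))
  x <- sub("^[Cc]andidatus ", "", x)
  x <- tolower(x)
  if (!is.null(name_map)) {
    stopifnot(all(c("gtdb_name", "ncbi_name") %in% names(name_map)))
    key <- tolower(gsub("\\s+", " ", trimws(name_map$gtdb_name)))
    val <- tolower(gsub("\\s+", " ", trimws(name_map$ncbi_name)))
    if (any(tapply(val, key, function(v) length(unique(v))) > 1)) {
      conf <- names(which(tapply(val, key, function(v)
        length(unique(v))) > 1))
      stop("conflicting name-map entries for: ",
           paste(conf, collapse = ", "))
    }
    m <- match(x, key)
    x[!is.na(m)] <- val[m[!is.na(m)]]
  }
  x
}

#' Build the BA metabolism microbiome database (BAMD)
#'
#' Union of the species-resolved BAMAG names and the BAKO-carrying isolate
#' names, after species-name normalization through the GTDB -> NCBI map.
#'
#' @param species_bamags character vector of species names from MAGs.
#' @param isolate_carriers character vector of isolate organism names.
#' @param name_map optional GTDB -> NCBI map (gtdb_name, ncbi_name).
#' @return sorted character vector of canonical species names.
#' @export
build_bamd <- function(species_bamags, isolate_carriers, name_map = NULL) {
  sort(unique(c(normalize_species_name(species_bamags, name_map),
                normalize_species_name(isolate_carriers, name_map))))
}

#' BAMD / detected-species / differential-microbe set logic
#'
#' T-BAMD is the BAMD restricted to species detected in the study; DFM-s is
#' the union of the three differential-species lists (rank-sum, LEfSe,
#' ANCOM-BC); their intersection with the BAMD gives the differential
#' species with BAKO function.
#'
#' @param bamd canonical species-name set.
#' @param detected_species canonical names detected in the study.
#' @param diff_lists list of up to three canonical-name character vectors.
#' @return list with `t_bamd`, `dfm_s`, `dfm_with_bako` and `venn` counts.
#' @export
set_analysis <- function(bamd, detected_species, diff_lists) {
  stopifnot(is.list(diff_lists))
  t_bamd <- sort(intersect(bamd, detected_species))
  dfm_s <- sort(unique(unlist(diff_lists)))
  dfm_with_bako <- sort(intersect(dfm_s, bamd))
  list(t_bamd = t_bamd, dfm_s = dfm_s, dfm_with_bako = dfm_with_bako,
       venn = c(n_bamd = length(bamd),
                n_detected = length(detected_species),
                n_t_bamd = length(t_bamd),
                n_dfm_s = length(dfm_s),
                n_dfm_with_bako = length(dfm_with_bako)))
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("screen_summary:", x$totals[["n_bamags"]], "BAMAGs of",
      x$totals[["n_filtered_mags"]], "filtered MAGs;",
      x$totals[["total_bako_genes"]], "BAKO genes\n")
  invisible(x)
}
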