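# Synthetic inputs with planted ground truth. The generator emulates the
# study's input tables so every downstream stage is testable without the
# external sequence archives: MAG quality/prevalence draws, spiked BA
# concentration matrices with mass-conserving conversion along
# biotransformation edges, and treatment -> mediator -> outcome triads.

# rumen taxa weighted so Lachnospiraceae/Bacteroidaceae/Prevotella dominate
.rumen_taxa <- function() {
  tax <- function(phylum, class, order, family, genus, species = "") {
    paste0("d__Bacteria;p__", phylum, ";c__", class, ";o__", order,
           ";f__", family, ";g__", genus, ";s__", species)
  }
  d <- rbind(
    c(tax("Firmicutes_A", "Clostridia", "Lachnospirales", "Lachnospiraceae",
          "Butyrivibrio", "Butyrivibrio fibrisolvens"), 8),
    c(tax("Firmicutes_A", "Clostridia", "Lachnospirales", "Lachnospiraceae",
          "Blautia", "Blautia sp900066145"), 4),
    c(tax("Firmicutes_A", "Clostridia", "Lachnospirales", "Lachnospiraceae",
          "Roseburia", ""), 3),
    c(tax("Bacteroidota", "Bacteroidia", "Bacteroidales", "Bacteroidaceae",
          "Prevotella", "Prevotella ruminicola"), 7),
    c(tax("Bacteroidota", "Bacteroidia", "Bacteroidales", "Bacteroidaceae",
          "Prevotella", "Prevotella sp900317535"), 4),
    c(tax("Bacteroidota", "Bacteroidia", "Bacteroidales", "Bacteroidaceae",
          "Prevotella", ""), 3),
    c(tax("Firmicutes_A", "Clostridia", "Oscillospirales",
          "Acutalibacteraceae", "UBA1227", ""), 5),
    c(tax("Firmicutes_A", "Clostridia", "Oscillospirales", "Ruminococcaceae",
          "Ruminococcus", "Ruminococcus flavefaciens"), 4),
    c(tax("Firmicutes_A", "Clostridia", "Oscillospirales", "Ruminococcaceae",
          "Faecalibacterium", ""), 2),
    c(tax("Bacteroidota", "Bacteroidia", "Bacteroidales", "Rikenellaceae",
          "Alistipes", "Alistipes sp. CAG_435"), 2),
    c(tax("Bacteroidota", "Bacteroidia", "Bacteroidales", "Muribaculaceae",
          "UBA7173", ""), 2),
    c(tax("Firmicutes_C", "Negativicutes", "Acidaminococcales",
          "Acidaminococcaceae", "Succiniclasticum",
          "Succiniclasticum sp002342505"), 2),
    c(tax("Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae",
          "Lactobacillus", "Lactobacillus paralimentarius"), 1),
    c(tax("Fibrobacterota", "Fibrobacteria", "Fibrobacterales",
          "Fibrobacteraceae", "Fibrobacter", "Fibrobacter succinogenes"), 2),
    c(tax("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
          "Succinivibrionaceae", "Succinivibrio", ""), 1),
    c(tax("Spirochaetota", "Spirochaetia", "Treponematales",
          "Treponemataceae", "Treponema", "Treponema bryantii"), 1),
    c(tax("Synergistota", "Synergistia", "Synergistales", "Synergistaceae",
          "Fretibacterium", "Fretibacterium fastidiosum"), 1),
    c(paste0("d__Archaea;p__Methanobacteriota;c__Methanobacteria;",
             "o__Methanobacteriales;f__Methanobacteriaceae;",
             "g__Methanobrevibacter;s__Methanobrevibacter ruminantium"), 2),
    c(tax("Firmicutes_A", "Clostridia", "Christensenellales",
          "Christensenellaceae", "Christensenella", ""), 1),
    c(tax("Actinobacteriota", "Coriobacteriia", "Coriobacteriales",
          "Atopobiaceae", "Olsenella", "Olsenella umbonata"), 1)
  )
  data.frame(taxonomy = d[, 1], weight = as.numeric(d[, 2]),
             stringsAsFactors = FALSE)
}

# default per-MAG BAKO prevalences: the screen's carrier counts over the
# 3954 dereplicated high-quality MAGs
.default_prevalence <- function() {
  c(K07007 = 3013 / 3954, K03453 = 1482 / 3954, K01442 = 431 / 3954,
    K14347 = 19 / 3954, K00038 = 5 / 3954, K00076 = 4 / 3954,
    K15868 = 3 / 3954, K01796 = 3 / 3954)
}

# swine-derived supplement composition (mass fractions)
.default_spike_composition <- function() {
  c(HCA = 0.807, CDCA = 0.127, CA = 0.012, HDCA = 0.044,
    TCDCA = 0.006, TCA = 0.004)
}

#' Default biotransformation conversion edges for the generator
#'
#' Fractions of a substrate's spiked mass converted to each product in the
#' treated group, chosen by closed-form mass accounting so the expected
#' rumen-transformed fraction of the treated pool is about 0.35. Per
#' substrate the outgoing fractions sum to at most 1.
#'
#' @return data.frame with columns substrate, product, fraction.
#' @export
default_conversion_edges <- function() {
  omcap <- paste0(.OMEGA, "-MCA")
  e <- function(s, p, f) data.frame(substrate = s, product = p,
                                    fraction = f, stringsAsFactors = FALSE)
  rbind(
    e("HCA", omcap, 0.25), e("HCA", "HDCA", 0.08),
    e("CDCA", "UDCA", 0.40), e("CDCA", "LCA", 0.30),
    e("CA", "UCA", 0.30), e("CA", "alloCA", 0.20),
    e("CA", "3-DHCA", 0.10),
    e("HDCA", "isoHDCA", 0.30), e("HDCA", "6-ketoLCA", 0.20),
    e("LCA", "DHLCA", 0.30)
  )
}

#' Synthetic-data generator configuration
#'
#' Bundles and validates all generator parameters. Identical configurations
#' (including the seed) give bit-identical outputs.
#'
#' @param seed integer RNG seed.
#' @param n_mags number of MAGs to draw.
#' @param bako_prevalence named vector, KO id -> carrier probability.
#' @param quality_law list: completeness_mean/sd (truncated-normal percent),
#'   contamination_mean (exponential, percent).
#' @param copy_number_mean mean gene copies per carried KO (geometric law,
#'   >= 1).
#' @param n_samples_per_group samples per group in concentration matrices.
#' @param baseline_mean control-group mean concentration per BA, nmol/L.
#' @param baseline_cv log-normal coefficient of variation of the baseline.
#' @param spike_total total spiked BA mass in the treated group, nmol/L.
#' @param spike_composition named mass fractions of the supplement.
#' @param conversion_fractions data.frame substrate/product/fraction.
#' @param group_effects named multiplicative effects applied to treated
#'   means on top of spiking (default none).
#' @param noise_cv multiplicative log-normal noise CV on concentrations.
#' @param mediation_params list: a, b, c_prime, sd_m, sd_y, n.
#' @return object of class "synth_config".
#' @export
synth_config <- function(seed = 1,
                         n_mags = 1000,
                         bako_prevalence = .default_prevalence(),
                         quality_law = list(completeness_mean = 92,
                                            completeness_sd = 7,
                                            contamination_mean = 3),
                         copy_number_mean = 1.3,
                         n_samples_per_group = 6,
                         baseline_mean = 20,
                         baseline_cv = 0.5,
                         spike_total = 50000,
                         spike_composition = .default_spike_composition(),
                         conversion_fractions = default_conversion_edges(),
                         group_effects = numeric(0),
                         noise_cv = 0.2,
                         mediation_params = list(a = 0.8, b = 0.5,
                                                 c_prime = 0.4, sd_m = 1,
                                                 sd_y = 1, n = 200)) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (n_mags < 1 || n_samples_per_group < 1) stop("counts must be positive")
  if (any(bako_prevalence < 0 | bako_prevalence > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  if (is.null(names(bako_prevalence)) ||
      !all(grepl(.KO_PATTERN, names(bako_prevalence)))) {
    stop("bako_prevalence must be named by KO ids (K#####)")
  }
  cf <- conversion_fractions
  if (nrow(cf)) {
    if (any(cf$fraction < 0 | cf$fraction > 1)) {
      stop("conversion fractions must lie in [0, 1]")
    }
    outflow <- tapply(cf$fraction, cf$substrate, sum)
    if (any(outflow > 1 + 1e-12)) {
      stop("conversion fractions leaving a node sum to > 1: ",
           paste(names(outflow)[outflow > 1 + 1e-12], collapse = ", "))
    }
  }
  if (abs(sum(spike_composition) - 1) > 1e-6) {
    stop("spike composition must sum to 1")
  }
  if (copy_number_mean < 1) stop("copy_number_mean must be >= 1")
  mp <- mediation_params
  if (mp$n < 4) stop("mediation n must be >= 4")
  if (mp$sd_m < 0 || mp$sd_y < 0) stop("noise SDs must be >= 0")
  structure(list(
    seed = as.integer(seed), n_mags = as.integer(n_mags),
    bako_prevalence = bako_prevalence, quality_law = quality_law,
    copy_number_mean = copy_number_mean,
    n_samples_per_group = as.integer(n_samples_per_group),
    baseline_mean = baseline_mean, baseline_cv = baseline_cv,
    spike_total = spike_total, spike_composition = spike_composition,
    conversion_fractions = cf, group_effects = group_effects,
    noise_cv = noise_cv, mediation_params = mp
  ), class = "synth_config")
}

# run `expr` under a locally-seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic MAG catalog and KO annotation table
#'
#' Each MAG draws completeness (truncated normal) and contamination
#' (exponential), a taxonomy string from the shipped rumen dictionary, and
#' an independent Bernoulli per KO at its planted prevalence; carriers
#' receive a geometric number (mean `copy_number_mean`) of gene rows per
#' carried KO.
#'
#' @param cfg a [synth_config()].
#' @return list with `catalog` (mag_id, completeness, contamination,
#'   taxonomy) and `ko_table` (gene_id, mag_id, ko_id).
#' @export
gen_mag_catalog <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_mags
    ql <- cfg$quality_law
    comp <- stats::rnorm(n, ql$completeness_mean, ql$completeness_sd)
    comp <- pmin(100, pmax(50, comp))
    cont <- stats::rexp(n, rate = 1 / ql$contamination_mean)
    taxa <- .rumen_taxa()
    tx <- sample(taxa$taxonomy, n, replace = TRUE, prob = taxa$weight)
    mag_id <- sprintf("MAG%05d", seq_len(n))
    catalog <- data.frame(mag_id = mag_id,
                          completeness = round(comp, 2),
                          contamination = round(cont, 2),
                          taxonomy = tx, stringsAsFactors = FALSE)
    kos <- names(cfg$bako_prevalence)
    rows <- list()
    # geometric copy number with mean `copy_number_mean` (support >= 1)
    pgeom <- 1 / cfg$copy_number_mean
    for (k in kos) {
      carry <- stats::runif(n) < cfg$bako_prevalence[[k]]
      ids <- mag_id[carry]
      if (!length(ids)) next
      copies <- 1L + stats::rgeom(length(ids), pgeom)
      rows[[k]] <- data.frame(mag_id = rep(ids, copies),
                              ko_id = k, stringsAsFactors = FALSE)
    }
    ko_table <- if (length(rows)) do.call(rbind, rows) else
      data.frame(mag_id = character(0), ko_id = character(0))
    ko_table <- ko_table[order(ko_table$mag_id, ko_table$ko_id), ,
                         drop = FALSE]
    ko_table <- data.frame(
      gene_id = sprintf("gene%06d", seq_len(nrow(ko_table))),
      ko_table, row.names = NULL, stringsAsFactors = FALSE)
    list(catalog = catalog, ko_table = ko_table)
  })
}

# expected (noise-free) group-mean concentrations implied by a config;
# spiked mass is conserved across substrate -> product transfers
.expected_ba_means <- function(cfg) {
  edges <- cfg$conversion_fractions
  bas <- unique(c(names(cfg$spike_composition), mutual_differential_bas(),
                  edges$substrate, edges$product,
                  names(cfg$group_effects)))
  control <- stats::setNames(rep(cfg$baseline_mean, length(bas)), bas)
  mass <- stats::setNames(rep(0, length(bas)), bas)
  mass[names(cfg$spike_composition)] <-
    cfg$spike_total * cfg$spike_composition
  # node-by-node single pass in edge-list order: all outgoing fractions of
  # a substrate apply to its mass at the moment the node is processed
  for (s in unique(edges$substrate)) {
    sub <- edges[edges$substrate == s, , drop = FALSE]
    base <- mass[[s]]
    moved <- base * sub$fraction
    mass[[s]] <- base - sum(moved)
    for (i in seq_len(nrow(sub))) {
      mass[[sub$product[i]]] <- mass[[sub$product[i]]] + moved[i]
    }
  }
  treated <- control + mass
  if (length(cfg$group_effects)) {
    ge <- cfg$group_effects
    treated[names(ge)] <- treated[names(ge)] * ge
  }
  list(control = control, treated = treated)
}

#' Generate a synthetic bile-acid concentration matrix
#'
#' Control samples draw log-normal noise around a common baseline; treated
#' samples receive the exogenous spikes, partially converted along the
#' configured biotransformation edges (total spiked mass is conserved
#' across substrate -> product transfers before noise), then any
#' multiplicative group effects, then log-normal noise at `noise_cv`.
#'
#' @param cfg a [synth_config()].
#' @return list with `values` (samples x BAs matrix, nmol/L), `groups`
#'   (character vector, "control"/"treated"), and `ground_truth` (expected
#'   control/treated means and the planted differential set).
#' @export
gen_ba_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  miss <- setdiff(unique(c(cfg$conversion_fractions$substrate,
                           cfg$conversion_fractions$product,
                           names(cfg$group_effects))),
                  c(ba_structures()$name, exogenous_bas()))
  if (length(miss)) stop("names not in the structure dictionary: ",
                         paste(miss, collapse = ", "))
  mu <- .expected_ba_means(cfg)
  .with_seed(cfg$seed + 1L, {
    nps <- cfg$n_samples_per_group
    bas <- names(mu$control)
    sdlog_base <- sqrt(log(1 + cfg$baseline_cv^2))
    sdlog_noise <- sqrt(log(1 + cfg$noise_cv^2))
    draw <- function(means, sdlog) {
      # log-normal with the requested mean and CV
      vapply(means, function(m) {
        if (m <= 0) rep(0, nps) else
          stats::rlnorm(nps, log(m) - sdlog^2 / 2, sdlog)
      }, numeric(nps))
    }
    ctrl <- draw(mu$control, sdlog_base)
    trt <- draw(mu$treated, sdlog_noise)
    values <- rbind(ctrl, trt)
    rownames(values) <- c(sprintf("C%02d", seq_len(nps)),
                          sprintf("T%02d", seq_len(nps)))
    colnames(values) <- bas
    planted <- bas[mu$treated / mu$control >= 2]
    list(values = values,
         groups = rep(c("control", "treated"), each = nps),
         ground_truth = list(control_mean = mu$control,
                             treated_mean = mu$treated,
                             planted_differential = planted))
  })
}

#' Generate a synthetic mediation triad
#'
#' Binary balanced treatment; M = a*T + N(0, sd_m); Y = c'*T + b*M +
#' N(0, sd_y). The ground-truth ACME is a*b.
#'
#' @param cfg a [synth_config()].
#' @return data.frame with columns treatment, mediator, outcome; attribute
#'   "ground_truth" holds a, b, c_prime, acme, prop_mediated.
#' @export
gen_mediation_data <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  mp <- cfg$mediation_params
  .with_seed(cfg$seed + 2L, {
    n <- mp$n
    t <- rep(c(0, 1), length.out = n)
    m <- mp$a * t + stats::rnorm(n, 0, mp$sd_m)
    y <- mp$c_prime * t + mp$b * m + stats::rnorm(n, 0, mp$sd_y)
    out <- data.frame(treatment = t, mediator = m, outcome = y)
    acme <- mp$a * mp$b
    attr(out, "ground_truth") <- list(
      a = mp$a, b = mp$b, c_prime = mp$c_prime, acme = acme,
      prop_mediated = if (acme + mp$c_prime == 0) NA_real_ else
        acme / (acme + mp$c_prime))
    out
  })
}
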