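# rumenba

Tools for analysing bile acid (BA) metabolism by the rumen microbiome.

Gut microbes transform liver-derived primary bile acids (CA, CDCA, HCA, …)
into secondary bile acids (DCA, LCA, HDCA, UDCA, …) through deconjugation,
7α-dehydroxylation and hydroxyl epimerization, with systemic consequences
for host lipid, glucose and amino-acid metabolism. The rumen — the large
anaerobic forestomach of ruminants — normally contains almost no bile
acids, so which of these transformations its microbiome can perform, and
which organisms and genes carry them, is a genuine question. `rumenba`
packages the quantitative machinery for answering it from standard
bioinformatics outputs:

- **MAG/isolate screening** (`filter_mags`, `screen_bakos`,
  `screen_isolates`): filter metagenome-assembled genomes on
  completeness > 80% and contamination < 10% (quality score
  *Q = completeness − 5 × contamination*), screen KEGG-ortholog
  annotations for BA-metabolism-associated KOs (BAKOs: *baiN* K07007,
  *BASS* K03453, *BSH* K01442, *SLC10A7* K14347, *3α-HSDH* K00038,
  *7α-HSDH* K00076, *baiB* K15868, *AMACR* K01796, *HADH* K00022, plus a
  configurable extension list), and summarise carrier ("BAMAG")
  proportions, taxonomy breakdowns and the BAMD / T-BAMD / DFM-s set
  logic (`build_bamd`, `set_analysis`).
- **Quantitative BA accounting** (`dilute_concentration`, `classify_bas`,
  `pool_totals`, `transformed_fraction`, `differential_bas`):
  dilution-corrected concentrations *C_M = C_F · V_F / V_S* (nmol/L),
  primary/secondary/unclassified classification, per-sample pool totals,
  the rumen-transformed fraction of the pool, and differential BA
  selection by the joint rule VIP > 1 ∧ p < 0.05 (PLS-DA VIP with
  Student's *t* or Wilcoxon rank-sum).
- **A rule-based biotransformation engine** (`ba_structures`,
  `apply_operator`, `enumerate_edges`, `validate_pathway`, `reachable`):
  bile acids encoded by their C3/C6/C7/C12 hydroxyl/oxo states and C5
  configuration; epimerization, dehydroxylation, oxidation and reduction
  operators; exhaustive enumeration of the transformation graph among any
  BA set, with direct-epimerization and oxo-intermediate (HSDH
  oxidation/reduction) modes.
- **Correlation networks** (`spearman_matrix`, `build_network`,
  `hub_nodes`): Spearman networks under the exact |r| = 1 rule used for
  small-n rumen data, and under Benjamini–Hochberg-adjusted p < 0.05 for
  larger (e.g. serum bipartite) families.
- **Causal mediation** (`fit_mediation`, `bootstrap_mediation`,
  `sensitivity_curve`): linear mediation with ACME = a·b, ADE = c′,
  proportion mediated ACME/(ACME + ADE), nonparametric bootstrap
  percentile intervals (sims = 1000, conf = 0.95), and the
  sequential-ignorability sensitivity curve ACME(ρ) over the assumed
  error correlation ρ.
- **Synthetic data with planted ground truth** (`synth_config`,
  `gen_mag_catalog`, `gen_ba_matrix`, `gen_mediation_data`) and an
  orchestrated pipeline (`run_pipeline`) writing provenance-headed
  TSV/CSV/JSON outputs.

## Worked example

```r
library(rumenba)

# per-KO carrier counts from a screen of 3954 filtered MAGs
counts <- list(
  per_ko_mag_count  = c(K07007 = 3013, K03453 = 1482, K01442 = 431),
  per_ko_gene_count = c(K07007 = 4623, K03453 = 2716, K01442 = 466),
  totals = c(n_filtered_mags = 3954, n_bamags = 3585,
             total_bako_genes = 7840))
pr <- summarize_proportions(counts)
pr$per_ko[, c("ko", "mag_count", "mag_pct_printed", "gene_pct_printed")]
#>       ko mag_count mag_pct_printed gene_pct_printed
#> 1 K07007      3013              84               59
#> 2 K03453      1482              41               35
#> 3 K01442       431              12                6
pr$bamag_fraction_pct
#> [1] 90.7  (90.66768 unrounded: 3585 of 3954 MAGs carry a BAKO)

# biotransformation graph over the 15 mutually increased BAs (+ CA,
# isoUDCA), checked against the stated pathway
g <- enumerate_edges(union(mutual_differential_bas(), c("CA", "isoUDCA")),
                     mode = "both")
g
#> ba_graph: 17 nodes, 42 edges (mode: both)
nrow(validate_pathway(g)$missing)
#> [1] 0        # all 14 stated pathway edges are enumerated

# synthetic treated group: share of the BA pool transformed by microbes
cfg <- synth_config(seed = 42)
ba <- gen_ba_matrix(cfg)
transformed_fraction(colMeans(ba$values[ba$groups == "treated", ]))
#> [1] 0.35

# bootstrap mediation on a generated triad (planted ACME = 0.4)
md <- gen_mediation_data(cfg)
bootstrap_mediation(md$treatment, md$mediator, md$outcome,
                    sims = 1000, seed = 42)
#> mediation fit (n = 200): ACME = 0.3872, ADE = 0.5884, total = 0.9756, prop. mediated = 39.7%
#>   95% percentile CI for ACME: [0.2307, 0.5931], p = 0.001 (1000 sims)
```

The screen percentages say that *baiN* dominates the BAKO catalog (84% of
carrier MAGs, 59% of BAKO genes), with the bile-acid transporter *BASS*
and bile salt hydrolase *BSH* next; 91% of high-quality rumen MAGs carry
at least one BAKO. The graph enumeration shows that the 15 mutually
increased bile acids are closed under the five reaction classes of the
proposed pathway, and the mediation fit recovers a planted indirect
effect with its bootstrap uncertainty.

## Vignette

`vignettes/rumen-bile-acids.Rmd` documents the models, the reaction
semantics of the biotransformation engine, the statistical conventions
(tests, VIP, bootstrap, sensitivity analysis), what the synthetic-data
generator does and does not emulate, and the package's design decisions
and limitations.
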