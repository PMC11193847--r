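---
title: "Rumen bile-acid metabolism: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rumen bile-acid metabolism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenba)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the numerical
conventions, and what the synthetic-data generator does and does not
emulate.

## The problem

Primary bile acids are synthesized in the liver; gut microbes deconjugate
them and rework the steroid core — removing or flipping hydroxyls at the
C3, C6, C7 and C12 positions and epimerizing the C5 ring junction — to
produce secondary bile acids with different receptor affinities. The
rumen is an unusual habitat for this chemistry because bile does not
normally reach it; establishing which transformations its microbiome can
run requires (i) finding the genes, by screening genome catalogs for
bile-acid-metabolism-associated KEGG orthologs (BAKOs), (ii) measuring
the compounds, by targeted metabolomics of supplemented incubations and
animals, (iii) explaining the chemistry, with an explicit reaction model
over bile-acid structures, and (iv) linking microbes to host outcomes,
with correlation networks and mediation analysis. Each package module
implements one of these stages behind a small, testable surface.

## Genome screening

MAGs are filtered on completeness > 80% and contamination < 10%. The
thresholds are strict inequalities; an inclusive flag exists because
"over 80%" is ambiguous at the boundary and catalogs differ in how they
round. The quality score `quality_score()` is the standard MIMAG-style
*completeness − 5 × contamination*; it is reported but not used by the
filter, which applies the two marginal thresholds directly.

A MAG is a BAKO-carrying MAG (BAMAG) iff its KO set intersects the BAKO
catalog. The shipped catalog contains the nine KOs observed in rumen
genomes and isolates (baiN, BASS, BSH, SLC10A7, 3α-HSDH, 7α-HSDH, baiB,
AMACR, HADH); the full curated screen behind it used 82 KOs, so the
catalog accepts arbitrary extensions (`bako_catalog(extra_kos = ...)`).
Two KO-to-enzyme attributions conflict in the source annotations (K00038
appears both as 3α-HSDH and as AMACR); the catalog resolves this as
K00038 = 3α-HSDH and K01796 = AMACR and screens both.

Proportion reports keep the raw floating-point percentages as the
authoritative values and attach a "printed-style" rounding (nearest
integer at ≥ 1%, two decimals below 1%) purely for display, because
published small-count percentages are frequently inconsistent with their
own denominators.

Species-name set logic (BAMD construction, the T-BAMD intersection with
detected species, and the DFM-s differential union) runs on normalized
names: lowercase, whitespace-collapsed, "Candidatus" stripped, then a
GTDB-to-NCBI map applied. Placeholder "sp." names are deliberately kept
distinct — collapsing them would merge unrelated genomes.

## Quantitative bile-acid accounting

Concentrations are dilution-corrected as *C~M~ = C~F~ · V~F~ / V~S~*
(nmol/L; volumes in µL). The classification scheme ships the measured
pool partitioned into 9 primary, 17 secondary and 7 unclassified bile
acids; the sulfated conjugates CDCA-3-sulfate and GCA-3-sulfate sit in
the primary list because that is how the measured panel classifies them,
even though they are conjugated species. Unknown compounds are flagged,
never dropped, so pool totals always count every measured analyte.

The *transformed fraction* is computed on group-mean concentrations: the
summed mean concentration of bile acids outside the exogenously
supplemented set (HCA, CDCA, CA, HDCA, TCDCA, TCA), divided by the
summed mean concentration of all bile acids. Group means rather than
per-sample fractions are used because the quantity describes a group's
pool composition; per-sample fractions would weight samples by their
inverse totals.

Differential bile acids follow the joint rule **VIP > 1 and p < 0.05**.
The VIP comes from a single-component PLS-DA (`plsda_vip`): predictors
are autoscaled, the class indicator is regressed by sequential NIPALS
weight extraction, and
VIP~j~ = √( p · Σ~a~ SS~a~ (w~ja~/‖w~a~‖)² / Σ~a~ SS~a~ ), which
satisfies Σ~j~ VIP~j~² = p exactly. A plain PLS-DA is used rather than an
orthogonalized (OPLS) variant: with the first projection component only,
the two give the same discriminant direction, and plain PLS-DA is the
reconstruction that open tooling can verify (the suite cross-checks
against mixOmics). The companion test is classical equal-variance
Student's *t* by default — matching the SPSS convention of the field —
with Welch and Wilcoxon variants by flag. Constant-valued analytes have
undefined VIP and are reported as flagged non-significant. Because the
joint rule intersects the *t* rule, its type-I rate can never exceed the
test's marginal rate; the suite verifies the marginal rate is nominal
and the joint set is a subset.

## The biotransformation engine

A bile acid is encoded by four position states (C3, C6, C7, C12 ∈
{α-OH, β-OH, oxo, absent}) and the C5 configuration (5α "allo" / 5β).
Side-chain conjugation and sulfation are carried as tags; `strip_conjugation`
models bile salt hydrolase as a tag-stripping map and the ring operators
never touch tagged positions. Four operator classes act on the ring:

- **epimerization** flips an existing OH α↔β (at C5 it flips the
  ring-junction configuration);
- **dehydroxylation** removes an OH *regardless of orientation* — the
  field labels the reaction "7α-dehydroxylation" even for 7β substrates
  (e.g. ω-MCA → HDCA), so the operator matches any OH and records the
  substrate's orientation on the edge;
- **oxidation** (OH → oxo) and **reduction** (oxo → OH at a chosen
  orientation) are the two HSDH half-reactions; oxidation followed by
  reduction to the opposite orientation composes exactly to
  epimerization, and the suite asserts this identity.

`enumerate_edges` tries every applicable operator on every structure and
keeps an edge iff the product is in the input set. The
`direct_epimerization` mode emits one-step epimerization edges; the
`composite_via_oxo` mode decomposes epimerization into its half-steps and
emits oxo intermediates only when they are themselves in the set; `both`
takes the union. Two encodings are deliberately ambiguous in the source
chemistry and both are emitted: CA → 3-DHCA is named a
"3β-epimerization" although 3-DHCA is a 3-oxo species, so the engine
realises it as oxidation@3 (and also emits CA → 3β-CA, the true
3β-epimer, when present); and the 6β relationship HDCA ↔ MDCA appears
both directly and via 6-ketoLCA.

The stated pathway references CA and isoUDCA, which are not among the 15
mutually increased bile acids, so pathway validation enumerates over the
union (17 structures). All 14 stated edges are recovered in `both` mode;
the enumerated set also contains additional chemically valid edges (for
example 12-dehydroxylations) which the validator reports as "extra"
rather than suppressing, since the engine's contract is exhaustive
enumeration, not curation.

## Correlation networks

Spearman correlations use average ranks; p-values use the exact null
distribution for n ≤ 9 without ties and the t-approximation otherwise.
Two edge rules mirror two analysis regimes. For very small n (five or
six informative samples, as when the control group has essentially no
bile acids), the only defensible cut-off is |r| = 1: the test applies a
1e-12 tolerance after rank arithmetic, and tied ranks make |r| = 1
unattainable, which is the intended behaviour. For larger families the
`bh_alpha` rule adjusts across exactly the tested family — for a
bipartite serum analysis, all (differential BA × differential metabolite)
pairs, not the full symmetric matrix — and keeps adjusted p < α. Hub
extraction is a degree count with a deterministic alphabetical tie-break.

## Mediation

The linear structural model is M = a·T + ε~M~, Y = c′·T + b·M + ε~Y~
(covariates optional in both equations). ACME = a·b, ADE = c′, total =
a·b + c′ exactly, and the proportion mediated is ACME/total — a signed
quantity that can exceed 1 in magnitude when ACME and total have opposite
signs, in which case it is flagged rather than clipped. Treatments may be
binary or continuous; continuous treatments can be scaled to 1 SD so the
effects have a unit. Inference is by nonparametric case resampling with
percentile intervals (defaults sims = 1000, conf = 0.95) and the
two-sided bootstrap sign p-value clipped to [1/sims, 1]; resamples with a
constant treatment are redrawn. When a resample makes T and M exactly
collinear (the noiseless perfect-mediation corner), the fit attributes
the effect through the mediator (b from Y ~ M, c′ as the total-effect
remainder), which reproduces the textbook algebra for noiseless data.

The sensitivity analysis asks how the ACME changes if the two error
terms are correlated (a violation of sequential ignorability). In the
linear case the bias-adjusted effect has the closed form
ACME(ρ) = a · (s₁/s₂) · ( ρ̃ − ρ √((1 − ρ̃²)/(1 − ρ²)) ), where s₁, s₂
are the residual SDs of the reduced-form regressions Y ~ T and M ~ T and
ρ̃ their residual correlation. ACME(0) equals the unadjusted a·b
algebraically, and the curve crosses zero exactly at ρ = ρ̃. The test
suite verifies the closed form against a numeric oracle that maximizes
the joint Gaussian likelihood with the error correlation held fixed.

## The synthetic-data generator

The generator plants known ground truth at the study's conditions so that
every downstream module is testable without external archives:

- **MAG catalogs**: completeness ~ Normal(92, 7) truncated to [50, 100]
  and contamination ~ Exponential(mean 3), chosen so roughly 92% of MAGs
  pass the quality filter, matching the observed pass rate at catalog
  scale; per-KO carriage is independent Bernoulli at the default
  prevalences taken from the published carrier counts over 3954 MAGs
  (e.g. K07007 at 3013/3954); carriers receive a geometric number of
  gene copies with mean 1.3, which reproduces observed gene/MAG ratios
  of ≈ 1.3–1.8. Taxonomy strings come from a weighted dictionary of
  rumen taxa with Lachnospiraceae, Bacteroidaceae and *Prevotella*
  dominant.
- **Concentration matrices**: control samples draw log-normal noise (CV
  50%) around a 20 nmol/L baseline per bile acid — "very rare" relative
  to the spike; treated samples receive a 50 000 nmol/L total spike with
  the supplement's composition (80.7% HCA, 12.7% CDCA, 1.2% CA, 4.4%
  HDCA, 0.6% TCDCA, 0.4% TCA), converted along the default
  biotransformation edges with fractions fixed once by closed-form mass
  accounting so the expected transformed fraction of the treated pool is
  ≈ 0.35; measurement noise is multiplicative log-normal at CV 20% (no
  per-sample dispersions are published, so the CV is a conventional
  targeted-metabolomics figure). Spiked mass is conserved across
  substrate → product transfers before noise, and the generator rejects
  configurations whose outgoing fractions at any node exceed 1.
- **Mediation triads**: binary balanced treatment, a = 0.8, b = 0.5,
  c′ = 0.4, unit noise SDs, n = 200, giving planted ACME = 0.4 and
  proportion mediated 0.5.

What the generator does **not** emulate: correlated KO carriage (real
BAKOs co-occur phylogenetically, so synthetic per-KO shares of BAMAGs
run a few points higher than the published ones — the independence
assumption thins multi-carriers), compositionality and sequencing depth
effects, batch structure in metabolomics, heavy-tailed concentration
outliers, and any read-level or assembly artefacts. Tests passing on
synthetic data therefore validate the computational contracts —
filtering, counting, classification, enumeration, calibration of tests
and intervals — not the biology of any particular rumen.

## Numerical conventions and problem sizes

Determinism: every generator and the bootstrap take explicit seeds and
restore the caller's RNG state; identical configurations are
bit-identical. Exact-method switch points: Wilcoxon enumerates when the
combined n ≤ 25 without ties; Spearman is exact for n ≤ 9 without ties.
Degenerate inputs have defined outcomes rather than errors wherever a
defensible value exists (identical samples give p = 1; zero-variance
analytes are flagged; zero totals raise errors). The |r| = 1 rule uses a
1e-12 tolerance; PCA fixes signs by making each component's
largest-magnitude loading positive.

The shipped test suite sizes its simulations to be decisive yet quick:
prevalence recovery and oracle re-tallies at 10⁴ MAGs, 1 000 null
simulations for the differential rule at n = 6/group, 10 000 null
Wilcoxon draws, 500 mediation replicates at n = 200 with 1 000 bootstrap
resamples each, and full-dictionary (28-structure) graph enumeration
against an independent transition oracle. These sizes give Monte-Carlo
standard errors well below the asserted tolerances (all stochastic
assertions use 2–3 SE bands computed from the simulation itself).

## Known limitations

- The biotransformation engine covers ring positions 3/6/7/12 and the
  C5 configuration only; side-chain chemistry (amidation beyond tags,
  sulfation position, oxo side-chains) and kinetics are out of scope.
- Mediation models are linear with a single mediator; binary outcomes
  and interaction models are not implemented.
- LEfSe and ANCOM-BC are consumed as name lists, not reimplemented;
  their internal statistics are deliberately out of scope.
- The BH family for a bipartite network must be supplied as the
  bipartite r/p block; passing the full symmetric matrix changes the
  family and therefore the adjusted p-values.
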