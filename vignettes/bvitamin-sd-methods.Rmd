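---
title: "Methods: B vitamin synthesis/utilization dynamics in gut multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: B vitamin synthesis/utilization dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitaminSD)
```

## The problem

In the lower gastrointestinal tract, most dietary B vitamins have already
been absorbed upstream, so the local pool available to the host is largely
microbial. That pool is governed by a balance between gut bacteria that
synthesize B vitamins and bacteria that consume them for their own
downstream metabolism. Dietary fiber shifts this balance: under fiber
deprivation, transcripts for downstream-utilization enzymes of several
vitamins rise, so the net host-available pool falls even where synthesis is
unchanged. `vitaminSD` implements the computational side of this analysis:

1. **Metatranscriptome S/D stage** — aggregate taxon-stratified gene-family
   abundances into per-vitamin synthesis (S) and downstream-utilization (D)
   relative abundances, form the per-sample log2 S/D ratio, and compare
   diet groups.
2. **Metabolome stage** — prevalence-filter metabolite concentration
   tables, normalize/log/autoscale them, rank differential metabolites
   against a reference diet, order heatmap rows by Ward clustering, and
   classify microbiota-dependent metabolites by detection-set algebra
   across colonization states.
3. **Statistics core** — ROUT robust outlier exclusion at Q = 1%, a
   Shapiro–Wilk-gated choice between heteroscedastic ANOVA and
   Kruskal–Wallis, Benjamini–Hochberg adjustment, and Pearson correlation
   with significance.
4. **Integration** — correlate log-transformed cecal B vitamin
   concentrations with immune-population frequencies (% of CD45+ cells),
   honoring matched versus pooled sample designs.
5. **Synthetic-data generator** — produces all pipeline inputs with
   planted, recoverable effects, so every stage is verifiable without
   external data.

## The S/D model

For each sample $j$ and vitamin $v$,

$$S_{vj} = 100 \times \frac{\sum_{f \in \mathcal{S}_v} \mathrm{CPM}_{fj}}{10^6},
\qquad
D_{vj} = 100 \times \frac{\sum_{f \in \mathcal{D}_v} \mathrm{CPM}_{fj}}{10^6},$$

where $\mathcal{S}_v$ and $\mathcal{D}_v$ are the enzyme features annotated
as synthesis/upstream and downstream-utilization for $v$, and CPM values
are renormalized so each sample's unstratified (TOTAL) rows sum to $10^6$.
The denominators are **all** mapped non-host transcripts, not only
B-vitamin transcripts, so $S$ and $D$ are percentages of the whole
metatranscriptome. The summary statistic is $\log_2(S_{vj}/D_{vj})$.

**Pseudocount rule.** If any sample has $D_{vj} = 0$ for a vitamin, one is
added to $S$ and $D$ of *all* samples for that vitamin before the ratio:
$\log_2((S+1)/(D+1))$. Applying the shift to every sample (not only the
zero ones) keeps ratios comparable within the vitamin; the
`pseudocount_applied` flag records which vitamins took this path. By
default the shift operates on the percent relative-abundance scale; a
`scale = "cpm"` option applies it on the CPM scale instead, since the
scale of "plus one" is a genuine degree of freedom.

**Ratio granularity.** The ratio is computed per sample and tested across
samples with a two-sided unpaired Welch t test per vitamin — a group
comparison requires within-group replicates, and n = 4 mice per group is
the emulated design. Direction is the sign of the group-mean difference;
the significance mask uses raw p ≤ 0.05 (the gray mask of an S/D heatmap),
with BH-adjusted values reported alongside.

**Annotation roles.** Classification follows the *colonically absorbed
form* of each vitamin: the kinase producing thiamine pyrophosphate (TPP,
taken up by the colonic TPP transporter) is upstream (S), and bacterial
pantothenate/pyridoxal kinases are upstream because host enzymes readily
dephosphorylate those compounds in the lumen. Transporter (T) records are
carried but excluded from both S and D sums by default — the S/D contrast
names only synthesis and downstream utilization — with a flag to merge T
into D. The bundled `builtin_demo_annotation()` is a small synthetic
fixture covering all 8 vitamins and these rules; real analyses supply
their full manual annotation through `load_annotation()`.

**Taxon attribution.** Stratified rows (`FEATURE|taxon`) are summed per
taxon; any gap between a feature's TOTAL row and its named strata is
assigned to the explicit `"unclassified"` stratum, never redistributed.
Conservation (strata + unclassified = total, within 1e-6 relative
tolerance) is validated at parse time and re-checked by tests.

## Metabolome processing

* **Detection call**: a metabolite is present in a sample iff its
  concentration is reported and positive; present in a group iff present
  in ≥ 1 sample of the group.
* **Prevalence filter**: keep metabolite $m$ iff some group $g$ satisfies
  $2\,\mathrm{det}(m,g) \ge n_g$ — the integer form of "detected in at
  least half of one experimental group", chosen to avoid float rounding
  ambiguity (2 of 4 passes; 2 of 5 fails).
* **Normalization**: concentrations are divided by the per-sample size
  factor (cecal weight in g or serum volume in µL).
* **Imputation**: values missing after the filter are imputed at one-fifth
  of the metabolite's minimum observed normalized value. This is the
  documented default of the metabolomics suite this workflow emulates; it
  is recorded in the `provenance` attribute rather than claimed to be the
  original authors' choice.
* **Log and autoscale**: log10 (the metabolomics-suite convention, also
  recorded in provenance), then per-metabolite mean-centering and division
  by the sample standard deviation (n − 1 denominator, fixed so the
  two-sample toy example is exactly ±1/√2). Zero-variance rows are dropped
  with a message.
* **Differential ranking**: the emulated workflow fits a "linear
  mixed-effect model using limma" with the fiber-free group as reference;
  with one observation per mouse and no stated random effect this reduces
  to a fixed-effects group-factor model, so the default path is an
  ordinary vectorised F test on the reference-coded design. A
  `moderation = TRUE` flag switches to limma's empirical-Bayes variance
  moderation, which narrows any remaining gap. Ranking uses ascending raw
  p ("lowest P values"); BH-adjusted values are reported per metabolite.
* **Ward ordering**: `hclust` with the Ward.D2 update on Euclidean row
  distances. Leaf order is canonicalized by placing, at every merge, the
  subtree containing the lexicographically smallest row label first, so
  the order is reproducible and invariant to row permutation when merge
  heights are untied.
* **Set analysis**: per-colonization detection sets on one diet yield
  UpSet-style exclusive region counts; `colonized_only()` returns
  $(\mathrm{SPF} \cup \mathrm{14SM}) \setminus \mathrm{GF}$, the
  microbiota-dependent metabolites for that diet.

## Statistics core

**ROUT** (robust outlier exclusion, Q = 1% by default) is specialised to
the univariate constant model: robust location = median; robust scale
RSDR = 68.27th percentile of absolute residuals × $n/(n-K)$ with $K = 1$;
each residual converted to a two-sided p-value via the t distribution with
$n - K$ df; the $i$-th most extreme residual is flagged while its p-value
stays below $i\,Q/n$ (a step-down FDR ladder). With zero spread nothing is
flagged; fewer than three values is refused. The variant is recorded in
`method_detail` so results are auditable.

**Gated group tests**: Shapiro–Wilk per group at α = 0.05 (a conventional
gate; the emulated workflow states only "normally distributed"). If all
groups pass, the heteroscedastic ANOVA branch reports the Welch ANOVA
statistic and p (the decision p-value) plus the Brown–Forsythe F*
statistic — the "Brown–Forsythe and Welch ANOVA" of graphical statistics
software is a combined report, not a single statistic, so both are
computed and the Welch p decides. Otherwise Kruskal–Wallis. A zero-variance
group makes Shapiro–Wilk undefined and routes the family to
Kruskal–Wallis with a warning. ROUT is applied per group before testing
(whether the original workflow pooled groups first is not stated; per
group is this package's documented choice).

**BH adjustment** wraps the standard step-up procedure; tests verify it
against a brute-force implementation of the definition on exhaustive
random instances.

## Integration stage

Vitamin concentrations are normalized by the size factor and
log10-transformed. Non-detected values are imputed at one-fifth of the
vitamin's minimum detected normalized value (consistent with the
metabolome stage) so that germ-free and fiber-free samples with
undetectable riboflavin or nicotinate still enter the correlation — the
emulated figure uses all mice; an `na_action = "omit"` option drops them
pairwise instead. Pearson r and p are computed per (vitamin, population)
cell, BH-adjusted across the whole matrix, and masked at adjusted
p < 0.05.

**Matched vs pooled pairing.** Groups whose metabolome and immune tables
share sample IDs are paired one-to-one (matched). For groups without ID
overlap the original pooling is underspecified, so both behaviors are
exposed and labeled rather than silently chosen: `pairing = "rank"` pairs
within-group observations by rank after sorting both ID lists (truncating
to the shorter), and `pairing = "strict"` drops such groups with a
warning. The mode used per group is reported in the result.

## The synthetic-data generator

The generator's defaults *are* the emulated study conditions:

* **Groups**: five diets (SC1, SC2, IN, FS, FF) for SPF mice and SC1/FF
  for 14SM and GF mice, n = 4 per group. The metatranscriptome generator
  restricts itself to SPF SC2/IN/FF, the diets with metatranscriptomes in
  the emulated design.
* **Counts**: negative-binomial with dispersion 0.05 (a CV of roughly 22%
  for abundant transcripts, moderate biological variability typical of
  controlled gnotobiotic designs) and per-sample depths uniform on
  0.5–2 million, so CPM renormalization is non-trivial.
* **Planted S/D effects**: downstream elevation of $\delta = 2$ log2 units
  in fiber-free-like diets for B2, B3 and B7, and a synthesis reduction
  for B9 — the direction pattern of the emulated findings. With n = 4 and
  the default noise these effects are recovered (correct sign, p ≤ 0.05,
  all four vitamins simultaneously) in ≥ 95% of seeds, and the
  no-effect configuration keeps the per-vitamin flag rate near the
  nominal 5%.
* **Microbiota-dependent metabolites**: the planted colonized-only sets
  contain 98 metabolites for the SC1 diet and a 66-metabolite subset for
  the FF diet — the printed set counts of the emulated analysis, used
  here as generator defaults and recovered exactly by
  `detection_sets()` + `colonized_only()`. Riboflavin and nicotinate are
  members (they are undetectable in germ-free hosts); the other vitamins
  are present at low concentrations everywhere. Host-derived metabolites
  get 5% missing-at-random dropout with at least one detected sample per
  group guaranteed, so set membership is exact by construction, not by
  chance.
* **Vitamin–immune correlations**: planted via a shared latent factor,
  `z = r·z_vitamin + sqrt(1 − r²)·noise`, mapped to a frequency scale of
  mean 5%, SD 1.5% of CD45+ cells and clamped to [0.01, 100]. Defaults
  plant r = −0.8 for riboflavin/mast cells, nicotinate/NK cells and
  pantothenate/Th17 cells. Targets with |r| > 0.99 are refused with the
  attainable bound.

**What the generator does not emulate**: real taxon phylogeny,
compositional correlations between metabolites, batch effects,
non-detection that depends on concentration (dropout is at random), or
read-level sequencing artifacts. Passing recovery tests therefore shows
the pipeline's algebra and inference are correct under the planted model;
it does not validate profiler output or annotation quality on real data.

## Numerical choices and degenerate inputs

* Ties in differential ranking are broken by metabolite name; Ward leaf
  order ties by smallest row label.
* A vitamin with no annotated features yields S = D = 0, which triggers
  the pseudocount path and a ratio of exactly 0.
* Group comparisons with both groups constant return statistic 0, p = 1
  (identical means) rather than an error.
* Zero-variance vectors in correlation return an `NA` sentinel cell.
* All generators are integer-seeded; sub-seeds are small fixed offsets of
  the configured seed, and identical configurations are byte-reproducible.

## Problem sizes in the shipped checks

The test-suite and acceptance-script simulations use the study-scale
designs (n = 4 per group; 60 gene families; 220 metabolites; 8 vitamins ×
12 populations) with 100–1000 replicate seeds per property — sizes chosen
so each recovery or error-rate estimate has a standard error well below
the margin it is compared against.

## Known limitations

* The ROUT constant-model variant reproduces the published description of
  the method, not any specific commercial implementation's numerics.
* The demo annotation is a teaching fixture (~30 enzymes); real S/D
  analyses need the full manual pathway annotation for quantitative
  relative abundances.
* The fixed-effects differential model ignores batch as a random effect;
  with batch structure in real data, `moderation = TRUE` plus a batch
  covariate in a custom design would be the next step, which this package
  does not automate.
* Pooled-rank pairing in the integration stage is one defensible
  construction of an underspecified design; conclusions that depend on it
  should be checked against `pairing = "strict"`.
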