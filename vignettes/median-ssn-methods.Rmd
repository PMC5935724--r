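---
title: "Group-median single-sample networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-median single-sample networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medssn)
```

## The problem

When gene expression and lipid amounts are measured on the *same* animals —
for instance after a dual RNA/lipid extraction from one liver sample — the
interesting biology is often not in which variables move, but in which
*relationships* between variables move: a treatment that switches on hepatic
lipogenesis changes how lipogenic transcripts co-vary with triglyceride
accumulation. With the group sizes typical of mouse studies (five animals
per cell of a genotype × treatment factorial), fitting per-group correlation
networks and differencing them is hopeless: a Spearman coefficient estimated
from five points has enormous variance.

The group-median single-sample network (SSN) statistic implemented here
approaches this differently. Classical SSN analysis measures how much adding
*one* sample to a large reference cohort perturbs every pairwise
correlation. For a small-cohort factorial design the method is modified in
two ways: the reference is the untreated wild-type cell itself (five
animals, genetically homogeneous, low inter-individual variability), and the
per-sample perturbations of each non-reference group are aggregated by their
entry-wise **median**, so no single animal dominates the group's
perturbation profile.

## The statistic

For variables $j,k$ and reference samples $R$ (with $|R| \ge 3$):

1. $SCC_{ref}(j,k)$ — Spearman correlation over $R$ (Pearson on mid-ranks;
   average ranks for ties).
2. For each sample $s$ of a perturbed group $G$:
   $\Delta SCC_s(j,k) = SCC_{R \cup \{s\}}(j,k) - SCC_{ref}(j,k)$.
   The reference never grows by more than one sample at a time.
3. $m_G(j,k) = \operatorname{median}_{s \in G} \Delta SCC_s(j,k)$.
4. Standardization over **all** $\binom{p}{2}$ pairs of the group (gene–gene
   pairs included, not just lipid pairs):
   $z_{jk} = \dfrac{m_G(j,k) - \bar m_G}{s_{m_G}}$
   with the sample ($n-1$) standard deviation, and the two-sided normal
   p-value $p_{jk} = 2(1 - \Phi(|z_{jk}|))$.
5. Selection: pairs with $p < \alpha$ (default 0.05, no multiple-testing
   correction; Benjamini–Hochberg behind `adjust = "BH"`), by default
   restricted to pairs touching at least one lipid variable. A positive
   median is reported as a *gain*, a negative one as a *loss* of
   correlation.

Under the default 2×2 factorial this yields three group networks —
treated wild type, untreated knockout, treated knockout — each relative to
the untreated wild-type reference.

Before the correlation stage every variable is normalized to the mean of
the reference group (division, preserving positivity; subtraction behind a
flag). Because step 1 uses ranks, any strictly increasing per-variable
transform — including this normalization — leaves the entire downstream
result bit-identical; the package tests this invariance explicitly. A
Shapiro–Wilk screen of all variables is recorded with the result: the
default method is Spearman regardless (fold-change and lipid data are
right-skewed), and `method = "auto"` follows the screen's recommendation.

### Conventions fixed by this implementation

The source method leaves several details open; this package fixes them and
tests them:

* **Sidedness.** p-values are two-sided; gains and losses are both
  reported and distinguished by a `direction` attribute.
* **Standard-deviation convention.** Sample ($n-1$) s.d. in the z-score;
  with ~3000 pairs the distinction from $n$ is negligible, but the
  convention is fixed.
* **Background distribution.** All pairs — including gene–gene pairs —
  form the z-score background; the lipid restriction applies only at
  selection.
* **Degenerate input.** A variable constant within the reference group is a
  hard error (its rank correlation is undefined, and one undefined column
  would corrupt the background distribution of every pair). A variable
  constant within a *perturbed* group is fine: each of its samples is added
  to the non-constant reference individually.
* **Tie handling.** Mid-ranks (average ranks), the standard Spearman
  convention.

## The synthetic-data generator

No measurements are deposited with the motivating study, so the package
ships a generator that emulates the *statistical structure* the analysis
assumes, making every downstream stage testable end to end.

The model is log-normal. For sample $i$ in group $g$ and variable $j$:

$$\log x_{ij} = \mu_{gj} + \lambda_j F_i + a_{g,e(j)} U_{e(j),i}
  + b_{g,e(j)} V_{j,i} + \sigma \varepsilon_{ij}$$

* $\mu_{gj}$ — group mean shifts. Defaults emulate an LXR-agonist liver
  study: a 26-gene lipogenic cluster induced 4-fold (log-scale shift
  $\log 4$) only in the treated wild-type cell, four genes repressed 2-fold
  in that same cell, triglycerides up 2.5-fold and the MUFA/(SFA+MUFA)
  ratio up 1.5-fold there. The magnitudes are realistic for strong LXR
  activation (established target genes respond severalfold) but are
  generator choices, not measured values.
* $F_i$ — a latent "lipogenesis" factor inducing baseline gene–lipid
  correlation; default loadings 0.6 for lipogenic genes, triglycerides and
  the MUFA ratio, 0.3 for the remaining lipids, 0.2 elsewhere.
* $U_e$ — one shared component per *planted edge* $e$; $V_j$ — an
  independent filler component. For a pair with target Spearman $\rho_s$ in
  group $g$, the underlying Gaussian correlation is set to
  $r = 2\sin(\pi\rho_s/6)$ and the loadings solve $a_g^2 = |r_g|\,v$,
  $b_g^2 = v(1-|r_g|) - \sigma^2$ with a common marginal variance
  $v = \sigma^2 / (1 - \max_g |r_g|)$. Two properties follow: the
  population Spearman correlation of the pair equals the target *exactly*
  in every group (rank correlations are invariant to the exponentiation),
  and the marginal variance of each planted variable is *identical across
  groups* — a planted gain or loss changes the dependence and nothing
  else. Without the filler term, dropping the coupling would also shrink
  the perturbed group's marginal spread, and its samples would land
  mid-rank in the reference, silently erasing the very signal the edge is
  supposed to carry.
* $\sigma$ — residual log-scale noise, default 0.3 (≈ 30% coefficient of
  variation, a typical magnitude for qPCR fold changes and lipid assays at
  this scale).
* One RNG stream, seeded once per study: latent factors, then per planted
  edge the shared and two filler components, then the residual matrix.
  Identical seeds give bit-identical studies.

What the generator does **not** emulate: heteroscedastic assay noise,
detection floors and censoring, correlated technical batches, heavy-tailed
outlier animals, and the dense, block-structured correlation among real
lipid-metabolism transcripts beyond a single latent factor. Passing tests
therefore demonstrate that the statistic behaves as designed under its own
assumptions, not that those assumptions hold for any particular real
dataset.

The companion Ct-table generator produces qPCR cycle-threshold values whose
ΔΔCt analysis (normalization to a housekeeping transcript, then to the
reference group, fold $= 2^{-\Delta\Delta Ct}$) inverts the configured
expression levels exactly when cycle noise is zero — the package's ΔΔCt
implementation is validated by exact round trip.

## Power: what the median-SSN can and cannot see

The package includes its own calibration experiment
(`planted_recovery_experiment()`): replicated synthetic studies at the
default layout (4 groups × 5 samples, 74 genes + 4 lipids) carrying one
planted lipid–gene **loss** edge (reference Spearman 0.9 dropping by
$\Delta\rho \in \{0.3, 0.6, 0.9\}$) in the treated wild-type cell, with all
groups otherwise drawn from the reference generative law. Two properties
hold at 200 replicates per effect size (the experiment shares seeds across
effect sizes, a common-random-numbers design that stabilizes the
comparison):

* the planted edge's selection rate at $\Delta\rho = 0.9$ clearly exceeds
  the mean selection rate of unplanted lipid-touching pairs;
* the detection rate is monotone non-decreasing in $\Delta\rho$.

Two honest caveats, both direct consequences of $n=5$ rank statistics:

* **Absolute power is modest.** A Spearman coefficient over six points is
  coarse (its support has steps of ~0.09), so even a complete loss of a
  0.9 correlation is detected in roughly one replicate in ten at
  $\alpha = 0.05$ — far above the null rate, but nothing like certainty.
  The method is a screen, not a test with controlled power.
* **Mean shifts dominate the background.** When a treatment induces a
  large cluster of genes in the same cell (the default generator's 26-gene,
  4-fold induction), every added sample of that cell ranks at the top of
  every induced gene, producing large coordinated correlation *gains*
  across hundreds of gene–gene pairs. The all-pairs background standard
  deviation inflates (~0.22 vs ~0.15 without shifts), and a pure
  correlation-loss edge can no longer reach $|z| > 1.96$ at all. This is
  why the calibration experiment switches the mean shifts off, and it is a
  real limitation to keep in mind when interpreting loss edges in strongly
  perturbed cells: in such data the method predominantly reports the gains
  that accompany the coordinated induction.

## The supporting computations

* **Bland–Altman agreement** (`bland_altman()`): relative differences
  $d_i = (x_i - y_i)/((x_i+y_i)/2)$ — appropriate when error scales with
  the measured amount — summarized by bias, sample s.d., and limits of
  agreement at bias ± 1.96 s.d. (fixed multiplier, not a t-quantile).
  Coverage of the limits is validated by simulation (~95% at $n = 1000$).
* **Phase-volume estimation** (`estimate_phase_volume()`): scaling an
  aliquot's tracer counts to the whole organic phase,
  $V = V_{aliquot} \cdot (cpm_{input} - cpm_{aqueous})/cpm_{aliquot}$.
* **Group comparisons** (`pooled_t_tests()`): two-sided Student's t with a
  pooled variance estimate, with a per-variable one-way ANOVA across all
  cells reported alongside (reported, not gating, by default).
* **Panel clustering** (`hierarchical_clusters()`): variables z-scored
  across samples, 1 − Pearson correlation distance, average linkage, cut at
  k = 4 — standard expression-heatmap practice; Euclidean distance and
  Ward linkage are selectable. The motivating presentation does not state
  its clustering parameters, so cluster membership of specific genes is
  not something this package (or anyone) can reproduce exactly; the
  defaults are a documented convention, validated on planted block
  structure instead.

## Problem sizes used in validation

The shipped test suite and acceptance script run entirely on synthetic
data at the study's own scale: 20 samples × 78 variables for pipeline
runs; 200 replicates per effect size for the recovery experiment; 100
random instances (4–12 samples, up to 20 variables, with and without ties)
for the oracle-equivalence check of the correlation engine against an
independent mid-rank implementation; 100 replicates of 1000 pairs for
Bland–Altman coverage; 1000 replicates for the Shapiro type-I check.

## A worked run

```{r run, eval = FALSE}
st <- generate_study(study_config(seed = 1))
res <- run_ssn(st$table, st$design)
res
#> ssn_result: 3 group network(s) vs reference 'WT:vehicle' (spearman)
#> network_result 'WT:T09': 11 selected edge(s) of 3003 pairs (alpha = 0.05, lipid-touching only)
#> network_result 'KO:vehicle': 41 selected edge(s) of 3003 pairs (alpha = 0.05, lipid-touching only)
#> network_result 'KO:T09': 30 selected edge(s) of 3003 pairs (alpha = 0.05, lipid-touching only)
```

Each network can be flattened to an edge table (`to_edge_table()`) or
written as SIF/GraphML (`write_graph_file()`) for Cytoscape-style viewers;
the `direction` attribute encodes gain/loss (the blue/red of a typical
rendering) and `width` carries $|m_G|$ so edge thickness is proportional to
the size of the correlation change.

## Known limitations

* The normal reference distribution for the z-scores is an approximation:
  median-ΔSCC values across pairs are bounded, dependent (every pair shares
  the reference cohort) and discrete at $n = 5$. The p-values are a ranking
  device inherited from the method, not calibrated tail probabilities —
  one reason the package reports the empirical null selection rate in its
  recovery experiment.
* Selection at raw $p < 0.05$ over ~3000 dependent pairs implies a
  non-trivial family-wise error; `adjust = "BH"` is available but off by
  default to match the method as published.
* The pipeline has no missing-data rule; values must be complete and
  finite, and validation rejects anything else rather than imputing.
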