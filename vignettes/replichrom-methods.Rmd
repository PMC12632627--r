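---
title: "Models and methods in replichrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in replichrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replichrom)
```

# Scope

replichrom analyses the three genomic layers that together describe a
stem cell's regulatory state: replication timing from fraction-sorted
Repli-seq, histone-mark occupancy from ChIC-ChIP fragment data, and
pseudobulk single-cell expression — and integrates them across two cell
types (called A and B throughout; in the motivating system these are
germline and somatic cyst stem cells of the fly testis). Every analysis
stage is exercised on synthetic data with planted ground truth, so the
whole pipeline is testable end to end without any sequencing data.

# The replication-timing model

## Logit timing scores

Cells are flow-sorted into four S-phase fractions (E, EM, LM, L) and
sequenced per fraction. Fragment midpoints are counted in non-overlapping
1 kb bins; consecutive bins are treated as approximately independent
observations, and every 3 kb sliding window (3 bins, 1 kb step) is scored
from the counts of all its samples.

The four fractions are collapsed to a binomial: the early half (E + EM)
versus the late half (LM + L). Writing $y$ for the window's
depth-normalized early-half count and $m$ for its total, the model is

$$ y \sim \mathrm{Binomial}(m, \mathrm{logit}^{-1}\theta), \qquad
   \theta \sim \mathcal{N}(0, \tau^2), $$

and the reported timing score is the posterior mean of $\theta$: positive
means early replication, negative late. The posterior is computed by
trapezoid quadrature on $\theta \in [-12, 12]$ with 2001 nodes, in log
space. The binomial likelihood depends on the per-sample counts only
through their sums, so $(y, m)$ are sufficient; tests verify agreement
with a $10^5$-node dense-grid oracle to $10^{-4}$.

Design choices here that the underlying experiment leaves open:

* **Binary collapse.** A single logit parameter is the minimal logistic
  model consistent with "early enrichment gives a positive score". An
  ordinal encoding of the four fractions would use more of the signal but
  needs extra cut-point parameters; the collapse is exposed as the
  `within_half_split` nuisance in the generator precisely because the
  model never looks inside a half.
* **Prior scale** $\tau = 2$ covers early-half shares from roughly 0.02
  to 0.98 and keeps empty windows at the prior mean 0 (flagged
  `no_data`).
* **Depth normalization.** Counts are divided by per-(sample, fraction)
  size factors (library totals over their median) and rounded before the
  binomial likelihood. This is the field's equal-S-phase-gates
  assumption: each fraction library represents an equal share of
  S-phase. A consequence worth understanding: timing becomes *relative*
  within a cell type. If one cell type has a large genuinely-early
  heterochromatic compartment, its arms shift relatively later after
  normalization, and a differential comparison against another cell type
  will report relative calls on the arms as well as the absolute ones at
  the compartment. The synthetic end-to-end test asserts the planted
  architecture (directions, block recovery, co-enrichment) rather than
  the absence of such relative calls.

## Differential timing and nested region calling

For two cell types on the same window grid the package compares a full
model (independent $\theta_A, \theta_B$, each with the $\mathcal{N}(0,
\tau^2)$ prior) against a reduced model (shared $\theta$) by the Bayes
factor $K$, computed from quadrature marginal likelihoods in log space.
Binomial coefficients cancel; with no data $K = 1$, and identical
high-depth data give $K < 1$ (the Occam penalty of the extra parameter).

Region calling is nested two-threshold: seed windows at $K \ge 10$ are
extended through contiguous windows with $K \ge 3$ and a consistent sign
of $\Delta = \mathbb{E}[\theta_A] - \mathbb{E}[\theta_B]$; runs separated
by at most 3 kb merge; regions narrower than 20 kb are discarded. Only
the 20 kb minimum is dictated by the underlying method description; the
seed/extend thresholds and gap are this package's defaults, chosen so
that a null genome at default depth yields well under 1% called coverage
(verified in the acceptance suite), and all are config keys.

## Smoothing, Z-scores and domain summaries

LOESS smoothing for display is a fixed-bandwidth (default span 100 kb)
tricube-weighted local linear fit per chromosome. The bandwidth is
parameterized in bp rather than as a fraction of points so that the
amount of smoothing does not depend on chromosome length; degree-1 local
fits reproduce linear tracks exactly, and a chromosome shorter than the
span falls back to a global linear fit with a warning.

RT Z-scores standardize each cell type's scores to mean 0 and unit
variance over all windows with data, using the population-sd convention
(divisor $n$). Chromosomal-domain summaries average window Z-scores by
window midpoint over a 12-domain map (four autosomal arms, their four
pericentromeric blocks, chromosomes 4, X and Y, and one rDNA repeat
unit); the timing labels (Early above 0.5, Early-Mid above 0, Late-Mid
above −0.5, Late at or below) are package defaults, since no boundary
values are dictated by the method.

# The ChIC-ChIP enrichment model

Fragments are filtered to MAPQ ≥ 20 and mononucleosomal lengths
(120–200 bp by default; the method description prescribes filtering but
not bounds) and their midpoints counted in 20 bp bins. Per bin, counts
follow a negative-binomial regression

$$ \log \mu = \beta_0 + \log(2)\,\mathrm{L2FC}\cdot 1[\mathrm{IP}]
   + \log s, $$

with $\beta_0$ the H3 (input) abundance intercept and L2FC the IP
enrichment coefficient, fitted by a vectorized per-bin Newton MLE. The
dispersion is shared genome-wide — per-bin dispersions are not
identifiable at mononucleosome depth — and estimated by method of
moments on the input replicates, floored at $10^{-8}$ where the model
collapses to the Poisson closed form $\hat\mu = \sum k / \sum s$.

Densities are Gaussian-smoothed (σ = 40 bp, i.e. 2 bins; kernel
truncated at 4σ and normalized) per chromosome with reflecting
boundaries, which conserves total mass exactly. Log2 fold enrichment is
$\log_2((\mathrm{IP} + \epsilon)/(\mathrm{input} + \epsilon))$ with
floor $\epsilon = 10^{-6}$ after both densities are rescaled to a common
total mass — the minimal depth correction of IP against input. The
equal-mass rescaling deliberately removes any genome-wide multiplicative
offset: a track that is globally 2× its input is a depth difference, not
enrichment, and scores 0. Callers comparing tracks already on a common
scale can set `normalize = FALSE`, in which case a 2× input is +1
exactly. Smoothing is applied to per-condition mean counts rather than
to regression predictions; at matched size factors the two coincide in
expectation, and the regression coefficients remain available per bin.

TSS metaprofiles (±1 kb, strand-flipped for minus-strand genes) and
length-weighted gene-body means summarize the tracks per expression
category. A locus is called cell-type specific when its L2FE exceeds
+0.2 in one cell type and falls below −0.2 in the other — the
opposite-sign rule — and per-domain percentages of labeled bp are
reported.

# The expression model

Pseudobulk CPM per cluster is the (optionally cell-weighted) gene total
scaled to $10^6$. A gene is "on" when CPM is strictly above 5 — so CPM
exactly 5 is off — and "on" genes split into low/medium/high at the
tertiles of their log CPM within the cluster (the category boundaries
are package choices; only the on/off threshold is dictated).
Cell-cycle reweighting assigns each cell the weight
$(1/3)/\hat{p}_{\text{phase}}$ within its cluster so the weighted G1, S
and G2/M shares are exactly one third each.

Shrunken log2 fold changes condition the two Poisson gene totals on
their sum, giving a binomial in which the log-odds are
$\log(L_A/L_B) + \beta \log 2$ — exactly the Poisson-with-offsets model
— with a $\mathcal{N}(0, 1)$ prior on the log2 effect $\beta$,
integrated on the same quadrature grid as the timing model. The s-value
is the posterior probability that the estimated sign is wrong,
$\min(P(\beta \le 0), P(\beta \ge 0))$, capped at 0.5. A gene is
selected when its posterior fold change exceeds 1.5 on the linear scale
(|L2FC| > log2 1.5) and its s-value is below $10^{-4}$; the 1.5
threshold is read on the linear scale (the alternative log2-scale
reading is available by passing `fc_thr = 2^1.5`). This model is a
deliberate simplification of the original contamination-covariate
regression: ambient-decontamination scores are out of scope here, so no
contamination covariate exists to adjust for. X-to-autosome ratios use
the median CPM of expressed genes (robust to the heavy upper tail of
expression).

# The synthetic world

The generators state one fixed world; they are pure functions of
(config, seed) and always emit their truth objects.

* **Genome**: a fly-like ~5.2 Mb miniature (four split autosomal arms,
  chr4, X, Y, one 8 kb rDNA unit; pericentromeric fraction 0.3, the
  approximate heterochromatin share of the fly genome).
* **Timing truth**: a smooth shared field (sd 1.2, ~50 kb correlation),
  pericentromeres and Y late (−2), and in cell A the pericentromeres,
  chr4 and rDNA early (+1.5) — the architecture observed in germline
  stem cells; planted differential blocks (default two of 50 kb) set
  $\theta^*_{A} - \theta^*_{B} = \pm 3$. Scores clamp to ±3.
* **Repli-seq counts**: per bin and replicate, fraction counts are
  Poisson with the logistic early-half split (50/50 within halves — the
  model never uses the within-half structure) at depth 50 per bin per
  replicate, with log-normal (sdlog 0.2) library factors to exercise
  normalization. Four fractions × 2 replicates give the 8 samples of a
  two-replicate design.
* **Chromatin**: nucleosomes every 185 bp with 20 bp phasing jitter;
  fragment lengths truncated-normal (150 ± 15, 100–220 bp); IP counts
  negative-binomial at dispersion 0.1 around the planted per-bin
  enrichment; 5% of fragments get MAPQ < 20. Three mark patterns:
  promoter-peaked (+1/+2 nucleosomes of expressed genes), body-broad,
  and heterochromatin-domain-broad.
* **Expression**: log-normal baseline means, 30% of genes off per
  cluster, planted DE genes at |log2 FC| = 2, X-linked means halved in
  cell A (no dosage compensation in the germline-like cluster), and
  different cell-cycle mixtures per cluster (25/50/25 vs 40/30/30).

What the generators do **not** emulate: mappability and GC structure,
ambient contamination (the decontamination algorithm is out of scope, so
its target artifact is not simulated), doublets, read-level errors, or
phase-dependent expression (phase labels exist only to exercise
compositional reweighting). A green synthetic test therefore establishes
the statistical machinery — calibration, recovery, invariances — not
robustness to those artifacts.

# Numerical choices and degenerate inputs

* Quadrature bounds ±12 on the logit scale hold all posterior mass for
  any data the prior admits; marginal likelihoods are computed by
  log-sum-exp and never underflow to 0 or overflow to ∞.
* Windows with no data keep $\theta = 0$ and are excluded from Z-score
  moments; a zero-variance track is an error, not a silent NaN.
* All-zero bins in the NB regression are flagged with missing
  coefficients; a condition that is empty while the other is not gets a
  missing L2FC rather than ±∞.
* Region calling with an empty track returns an empty table, not an
  error; ties at $\theta = 0$ in quadrant assignment are labeled
  Boundary; the TSS-to-window map breaks distance ties to the left
  window.
* Off-chromosome fragment midpoints are tallied in a reject report,
  never silently dropped.

# Interface

The exported functions and `run_pipeline()` (stages: simulate → timing →
differential calling → chic tracks → expression → integration) are the
interface; configuration is the nested R list `rc_config()`, every
threshold above being one key. `scripts/acceptance.R` in the source
repository re-runs the full pipeline from a seed.

```{r example, eval = FALSE}
res <- run_pipeline(seed = 1)
res$region_summary$A          # 12-domain RT Z-score summary, cell A
res$regions                   # called differential-timing regions
res$expression$xa             # X:A ratios per cluster
```

# Known limitations

* Differential-timing calls are relative within the normalization
  described above; absolute genome-wide timing shifts between cell types
  are not identifiable from fraction shares alone.
* The shared NB dispersion underfits bins with atypical biological
  variability; per-bin dispersion would need far deeper replication.
* The DE model ignores per-cell variability beyond Poisson counting
  (it models pseudobulk totals); with strong overdispersion its
  s-values are anti-conservative, which is why selection also requires
  a 1.5-fold effect.
* BAM/CRAM parsing is out of scope: fragment tables are tab-separated
  text, produced by an external alignment step.
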