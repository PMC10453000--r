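---
title: "Cancer type-specific gene regulatory networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cancer type-specific gene regulatory networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncogrn)
```

# Overview

`oncogrn` reconstructs cancer type-specific gene regulatory networks (GRNs)
from a multi-class expression corpus, restricted to a curated gold standard of
transcription factor (TF) to target pairs, and derives four downstream
read-outs per cancer type:

1. a **classification score** in [0, 1] for any query sample — the fraction
   of that type's random-forest trees voting for it;
2. a **GRN status** percentage — how closely the query expresses the type's
   GRN genes relative to the training distribution, standardized so training
   samples of the type average 100%;
3. a **network influence score (NIS)** per TF — a signed, importance-weighted
   measure of how much the TF's subnetwork separates a query group from the
   type, ranking candidate drivers of a fate change;
4. a **best-cutoff survival scan** relating one gene's expression to patient
   survival through all cutoffs between the expression quartiles, with FDR
   gating.

A synthetic-data generator stands in for the original microarray corpora so
that every stage is testable offline.

# Preprocessing

Probe-level matrices are collapsed to genes by averaging the probes that map
to the same gene; each array is then divided by its total intensity and
rescaled to a fixed column total (default `1e5`). The fixed total is a
numerical convenience only: every downstream statistic is scale-free per
column, so the constant changes nothing but the printed magnitude. Training
and query data go through the same path.

The source procedure excludes arrays that fail "quality control" without
defining the check. `qc_filter()` is a documented, platform-agnostic
substitute, not a reconstruction: a sample is excluded when its log total
intensity or its median inter-sample Spearman correlation is more than
`k_mad` (default 5) median absolute deviations from the cohort median. The
rule is order-invariant and conservative at the default.

# The synthetic corpus — the stated world

The generator plants, for each of `n_classes` classes, `n_tfs_per_class` TF
hubs with `targets_per_tf` targets each (all genes disjoint), plus
`n_background_genes` unregulated genes. Intensities are multiplicative
log-normal around a positive baseline:

$$x_{gs} = b_g \cdot e_{gs} \cdot \exp(\varepsilon),\qquad
  \varepsilon \sim N(0, \sigma^2),$$

where the effect $e_{gs}$ equals `hub_effect` when gene $g$ belongs to the
program of the class of sample $s$ and 1 otherwise. Defaults are the
conditions the evaluation states: 17 classes, 20 samples/class, 5 TFs/class
with 10 targets each, `hub_effect = 4`, `noise_sd = 0.5`. Free choices, made
once: 1000 background genes and 100 decoy gold-standard pairs (so the edge
threshold has true negatives to reject, at a realistic planted:decoy ratio),
and a constant baseline of 100 (typical microarray scale; a constant makes
the noise-free checks exact).

TF activity is proxied by TF expression: a class's TFs and their targets are
co-elevated together. Query samples are generated with an `attenuation`
parameter: the fraction of the class program (chosen at random once per
call) expressed at the class level; `attenuation = 1` reproduces the training
law, `0` the background law. A variant silences exactly one named TF hub —
the planted perturbation used to validate NIS ranking.

What the generator does **not** emulate: probe-level chemistry, batch and
platform effects, correlated background structure, compositional shifts from
very large expression programs, and subtype heterogeneity. A green test
therefore establishes algorithmic correctness on well-posed planted signal,
not performance on real arrays.

Survival cohorts draw expression log-normally; event times are exponential
with hazard $h_0 e^{\beta\,\mathbf 1\{x > c\}}$ for a planted cutoff $c$, so
the scan's optimum is well-defined. "Independent censoring at rate $r$" is
realized by an independent exponential censoring time with rate
$h_0\,r/(1-r)$, which makes the expected censored fraction exactly $r$ when
$\beta = 0$.

# Network reconstruction

For every gold-standard pair present in the matrix, the correlation $\rho$
across all training samples is computed, then background-corrected in the
spirit of the context likelihood of relatedness (CLR): gene $i$'s
correlations to every other gene in the gold-standard gene universe form its
null distribution, and

$$z_{ij} = \sqrt{\tfrac{1}{2}\big(\max(0,z_i)^2 + \max(0,z_j)^2\big)},\qquad
  z_i = \frac{|\rho_{ij}| - m_i}{s_i},$$

with edges retained at $z_{ij} \ge$ `z_threshold` (default 2) and the edge
sign taken from the sign of $\rho$. Two numerical choices matter:

* **Robust background.** $m_i, s_i$ are the median and MAD of gene $i$'s
  absolute correlation row (falling back to mean/SD when the MAD
  degenerates). A hub gene's row is contaminated by its own true partners;
  mean/SD absorbs that signal into the null and suppresses true edges, while
  median/MAD does not, and under a pure-noise corpus the two calibrations
  agree.
* **Pearson by default, Spearman pluggable.** With intensity-scale data and
  many classes, the per-class prevalence is small (1/17 at the defaults), and
  rank correlation compresses the planted co-elevation toward the background
  sampling noise — measured on the default world it halves edge recall and
  breaks hub recovery, while Pearson on the normalized intensities keeps the
  leverage of the elevated samples and separates true pairs from background
  by several standard deviations at the same threshold. Rank correlation
  remains available (`method = "spearman"`) for heavy-tailed real corpora.

Communities are detected on the undirected weighted edge graph with InfoMap
(the map equation), seeded for determinism; Louvain is available as a
fallback. A community is assigned to a class when it is hypergeometrically
enriched (Bonferroni across all class-by-community tests, familywise
`alpha = 0.05`) in the class's top `top_k = 100` template genes — the genes
whose profiles correlate best with the class's one-vs-rest indicator. Each
community maps to at most one class (smallest p wins); a class GRN is the
union of its assigned communities with induced edges. The assignment test is
our concretization: the source states the goal (assigning subnetworks to
tissue types) but not the procedure.

# Classification

One balanced random forest per class (one-vs-rest), 1000 trees, Gini splits,
`mtry = floor(sqrt(p))`, grown to purity. No random-forest package is
assumed; the forest is implemented in compiled code with a balanced bootstrap
(equal draws from the class and the rest), which keeps the 1-of-17 positives
from being swamped. Features per class are its GRN genes united with its top
100 template genes — the fallback when a GRN comes out empty; the source does
not state the classifier's feature space. Per-gene importances (mean decrease
in Gini) become the GRN weights $w_g$, normalized to sum to 1.

Evaluation uses precision–sensitivity curves: at each distinct score cutoff,
precision $= TP/(TP+FP)$ (1 by convention when nothing is called) and
sensitivity $= TP/(TP+FN)$; the area (AUPR) is the step-wise integral
anchored at sensitivity 0. Whether the headline "mean AUC" of the source is
AUPR or AUROC is not stated; we take AUPR, consistent with the
precision–recall presentation, and report AUROC alongside. Confidence
intervals are seeded percentile bootstraps over validation samples.

Under label permutation, a balanced forest's out-of-sample vote level is
about 0.5 (not the class prevalence): each balanced tree sees equally many
"positives" and "negatives" with no learnable structure. The null-calibration
test checks this.

# GRN status

The source describes GRN status as "the average z-score of all genes in a
GRN, weighted by their significance to the classifier, standardized to the
average of the training samples". Taken literally this is ill-posed: a plain
average z-score has training mean near zero, so ratio standardization would
divide by ~0. The implemented reconstruction maps each gene's capped z-score
to a proximity score and normalizes the weighted mean:

$$z_g = \mathrm{clip}\Big(\frac{x_g - \hat\mu_g}{\hat\sigma_g},\ \pm z_{cap}\Big),\qquad
  s_g = \frac{z_{cap} - |z_g|}{z_{cap}} \in [0,1],\qquad
  \mathrm{status} = 100\cdot\frac{\sum_g w_g s_g}{m_c},$$

with $z_{cap} = 3$, $\hat\mu_g, \hat\sigma_g$ from the class's training
samples, and $m_c$ the class's mean raw score over its own training samples —
so training samples average exactly 100%. Dysregulation is penalized
symmetrically (over- and under-expression alike); the source does not state a
direction. Missing genes count as maximally dysregulated. A $\hat\sigma$
floor of $10^{-3}\hat\mu$ guards degenerate variances.

**Variance moderation.** With 10 training samples per class after the half
split, raw per-gene $\hat\sigma$ are noisy, which biases out-of-sample
$|z|$ upward: matched-type queries would systematically score ~5–10% below
training. Per-gene variances are therefore shrunk toward the class trend on
the squared-coefficient-of-variation scale by empirical-Bayes moderation
(the standard small-$n$ device of the microarray literature); the prior
degrees of freedom are estimated from the excess spread of $\log CV^2$ over
its chi-squared sampling expectation, so the strength of pooling adapts to
the data rather than being tuned. A residual droop of a few percent remains
— it is the irreducible error of the 10-sample training means — which is why
matched queries average ~95%, not 100%.

# Network influence score

The source defines the NIS only by its purpose (ranking TFs whose modulation
would drive the fate change). The implemented score is the simplest linear
reconstruction consistent with that: for TF $t$ with targets $T(t)$ in the
class GRN,

$$\mathrm{NIS}(t) = w_t \bar z_t + \sum_{g \in T(t)} w_g \bar z_g\, s(t,g),$$

where $\bar z$ is the mean capped z-score of the query group against the
class training distribution and $s(t,g)$ the sign of the training correlation
on the edge. The most negative NIS marks the most under-established
subnetwork; tables are sorted ascending with ties broken by TF name. Scores
are computed on group means by default (matching per-tissue bar plots), with
a per-sample mode available. Whether the original engine weights target
dysregulation by importance, edge weight, or both is unknown; this choice is
documented as a reconstruction.

# Survival

`km_curve()` is the product-limit estimator; `logrank_test()` pools ties and
uses the hypergeometric variance; `cox_hr()` maximizes the single-covariate
partial likelihood by Newton iteration with Breslow tie handling, and its
score test at $\beta = 0$ equals the log-rank chi-squared on tie-free data —
this identity is what justifies running the cutoff scan with the log-rank
statistic while the source says cutoffs were "assessed using Cox regression";
the reported hazard ratio at the selected cutoff comes from a full Cox fit.

`scan_cutoffs()` takes as candidates all distinct observed expression values
strictly between the lower and upper quartiles, computes Benjamini–Hochberg
q-values across the scan (within the gene — whether the original tool pools
across genes is not stated), accepts only $q < 0.10$, and selects the
smallest p (ties: smallest cutoff). When nothing passes the gate an explicit
no-selection marker is returned rather than a forced split.

# Reproducibility and numerical conventions

* One global seed fans out to per-stage seeds through a deterministic hash;
  identical configurations give byte-identical outputs, and every artifact
  embeds an 8-hex-digit hash of the resolved configuration.
* Degenerate inputs: zero-total arrays, singleton classes, empty GRNs, empty
  gold standards, monotone Cox likelihoods and all-identical expression are
  rejected or signaled explicitly, never silently patched.
* The half split puts the extra sample of an odd class into training.

# Known limitations

* The GRN-status transform and the NIS formula are reconstructions of an
  engine whose exact definitions are not published in the source; both are
  flagged above and in the function documentation.
* Acceptance-scale results are scaled-down synthetic analogs; nothing here
  reproduces results on the original microarray corpora or patient cohorts.
* The classifier aggregates subtypes into one class per cancer type; no
  multi-label or hierarchical classification is attempted.
* Community detection quality degrades for worlds with very few classes,
  where cross-class anticorrelation contaminates the CLR background; the
  test suite uses decoy pairs to keep the background realistic at small
  scale.
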