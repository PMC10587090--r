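---
title: "Methods: ensemble PAM50 classification and its stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble PAM50 classification and its stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamstab)
```

## The classification model

PAM50 subtyping is nearest-centroid classification: a tumor's expression of
the 50 signature genes, made *relative* by per-gene centering, is correlated
with five subtype centroids and the highest correlation wins. Writing
$e_{gs}$ for the FPKM of gene $g$ in sample $s$, one classification run
computes

$$x_{gs} = \log_2(e_{gs} + 0.1) - m_g, \qquad
  \hat{k}(s) = \arg\max_k \; \rho\!\left(x_{\cdot s},\, c_{\cdot k}\right),$$

where $m$ is the centering vector, $c_{\cdot k}$ the centroid of subtype
$k$, and $\rho$ Spearman's rank correlation with mid-ranks for ties. There
is deliberately **no minimum correlation cut-off**: the argmax is returned
even when every correlation is negative, so the classifier is total and
downstream tabulations have no holes.

Because the centering vector depends on which samples form the reference
population, a single run inherits that population's composition bias. The
ensemble therefore draws `n_sets` (default 100) balanced reference sets —
each a without-replacement draw of a configured number of samples per
subtype — and classifies every tumor once per set, centering with the
set's per-gene **median** of $\log_2(\mathrm{FPKM}+0.1)$. The reported
call `PAM50_NC` is the majority vote; per-centroid correlations are
averaged over the runs, and the second-best subtype `PAM50_NC_2nd` is the
runner-up of these mean correlations among the four non-called subtypes.
`delta`, the mean-correlation margin between best and second-best, measures
how distinct a tumor's subtype assignment is.

Choices the literature leaves open, fixed here:

- *Centering statistic*: the per-gene median (robust, conventional for
  research-use PAM50 centering); configurable to the mean.
- *Reference-set composition*: equal counts per subtype (5 of each) by
  default, configurable. Balancing requires provisional labels; in
  simulations the generating truth is used, on real data a first-pass
  classification with cohort-wide median centering. The circularity this
  introduces is inherent to reference-set balancing and is documented
  rather than hidden.
- *Tie-breaks*: vote ties resolve to the higher mean correlation, then to
  the fixed alphabetical subtype order (Basal, HER2E, LumA, LumB, Normal)
  with a warning; an exact tie between the second and third mean
  correlation makes the second-best subtype *ambiguous* (`NA`), and such
  samples are excluded from second-best tabulations and counted separately.
- *Degenerate profiles*: a centered profile constant across genes has no
  rank correlation; the sample is excluded with a warning instead of
  receiving an arbitrary call.

## Gene clusters and the perturbation sweep

The 50 signature genes contain strongly co-expressed blocks, so removing a
biological theme from the classifier means removing a *cluster*, not a
gene. The shipped partition (`pam50_fixture_partition()`) has seven
clusters — proliferation (21 genes), steroid response (9), basal keratins
(8), the 17q12 amplicon pair *ERBB2*/*GRB7*, *ACTR3B*/*PHGDH*,
*GPR160*/*TMEM45B*, and the singleton *FGFR4* — plus five unassigned genes
(*MYC*, *MMP11*, *BAG1*, *MDM2*, *BLVRA*). The amplicon/receptor split of
{*ERBB2*, *GRB7*, *FGFR4*} reflects genomic proximity (17q12 co-amplification
versus 5q35) and their very different pairwise co-expression. Clusters 4,
6, 7 and the unassigned bucket are fixed by construction; the completion of
clusters 1–3 and 5 assigns the remaining genes by their canonical biology
and is therefore partly inferred rather than estimated from data — users
with a cohort-derived partition can supply their own TSV. The surrogate
estimator `cluster_genes()` (average-linkage hierarchical clustering on
$1-\rho$ with a correlation-threshold cut, singletons below a co-expression
floor left unassigned) recovers planted modules exactly in testing and
stands in for heavier core-clustering machinery whose algorithm is outside
this package's scope.

The **leave-one-gene-cluster-out** sweep removes one cluster at a time from
the centroids, every reference centering vector, and the expression matrix
— the 45 clustered genes form the background gene content; unassigned genes
are outside the sweep entirely (a config flag can retain them as a fixed,
never-removed background for sensitivity analysis). The full ensemble then
re-classifies every tumor. A tumor **switches** when its original call
appears in at most half of the perturbed runs:
$\text{votes}(PAM50_{NC}) \le \lfloor n_{sets}/2 \rfloor$, i.e. 50 of 100.
Note the rule is a vote-share condition, not a call-change condition: it is
equivalent to "the perturbed majority call differs" only when calls carry
strict majorities, which holds throughout the regimes simulated here and is
asserted where tests rely on it. Tumors that never switch under any
single-cluster exclusion are **K0** cases; `corr_delta` records how much
better (or worse) the perturbed call correlates than the original.

## K0 refinement

Within one clinical subgroup (default ERpHER2n, the dominant group), the K0
tumors of each subtype define refined centroids: the arithmetic **mean
FPKM** per gene (the deliberate, literal construction — not the median).
All tumors of the subgroup are then reclassified *single-sample*: raw FPKM
against each K0 centroid by Spearman correlation, with no offset, log
transform or centering. Because only within-sample ranks enter, the call is
exactly invariant to any strictly increasing transform of a tumor's profile
— the property that makes the refined classifier deployable on single
samples where no reference population exists. A guard of at least 5
contributing K0 tumors per subtype (configurable down to 1) avoids
single-tumor centroids; subtypes failing it are dropped with a warning, and
all tumors are still classified against the available centroid set, which
is recorded.

## The synthetic cohort generator

The generator is the package's study population, not a tuning knob. Per
sample it draws a clinical subgroup (defaults: TNBC 10.3%, ERnHER2p 4.1%,
ERpHER2p 8.8%, ERpHER2n 76.8%), a subtype from a conditional table matching
observed population composition (e.g. 73.3% of TNBC are Basal; printed
percentage rows are renormalized to sum to exactly 1), and expression

$$\log_2\text{-scale: } x_{gs} = c_{g,k(s)} + \varepsilon_{gs}, \quad
  \varepsilon \sim N(0, \sigma^2), \qquad
  e_{gs} = \max\!\big(2^{\,x_{gs} + b_g + u_s} - 0.1,\; 0\big)$$

with per-gene baseline $b$ (default constant 3, putting median FPKM near
8), per-sample library jitter $u_s \sim N(0, 0.15^2)$, and noise
$\sigma = 0.4$ by default — enough to spread `delta` over a realistic range
while keeping subtype identity recoverable. ER/PR/HER2 statuses are
assigned consistently with the drawn subgroup (so subgroup derivation
round-trips), and OS/DRFI are exponential with per-subtype hazards ordered
LumA best / Basal worst (0.020–0.065 per year OS) under independent
exponential censoring whose rate $\mu = \tfrac{c}{1-c}\lambda$ yields an
expected censored fraction $c$ (default 0.7) in every arm.

The shipped centroid matrix is likewise **synthetic**: cluster-level
subtype prototypes plus small fixed gene offsets and a tie-breaking term
that keeps all within-column values distinct. It reproduces the canonical
inter-centroid correlation pattern (Basal most distinct; HER2E correlated
with Basal/LumB; LumA with Normal and LumB), which is what the second-best
and perturbation analyses exercise.

What the generator does *not* emulate — and what green tests therefore do
not establish about real tumors: full-transcriptome context, tumor purity,
histology–expression correlations, non-proportional hazards, platform
effects, and real centroid estimation noise. Conclusions from this package
about real cohorts require real centroids and real expression data; the
synthetic stack validates the *machinery* (exactness of rules, invariances,
parameter recovery), not biological effect sizes.

## Numerical and reproducibility choices

- Spearman everywhere uses mid-ranks for ties; correlation equality in
  tests is asserted to $10^{-12}$ against an independent brute-force
  implementation.
- The $+0.1$ FPKM offset is applied uniformly before any log transform;
  gene-set scores use the same offset and no centering; metagene rank
  scores scale mid-ranks to $[0,1]$ as $(r-1)/(n-1)$.
- All randomness is seeded. The pipeline fans a single master seed into
  per-stage sub-seeds as $(33\,\text{seed} + k) \bmod (2^{31}-1)$, so each
  stage is independently reproducible and reruns are byte-identical.
- ER−/PR+/HER2− tumors fit none of the four clinical subgroups and are
  labelled `unclassified` (PR enters only the triple-negative rule), as are
  tumors with unknown required markers — partial cohorts run rather than
  error.
- Cox models use the Efron tie approximation; log-rank tests are two-sided.
- Test and acceptance problem sizes — 600-tumor cohorts for end-to-end
  runs, 500 for noisy recovery, 300 samples for module recovery, 2000 per
  arm for hazard-ratio recovery — are chosen so stochastic checks sit far
  from their thresholds while the whole suite stays fast on a laptop.

## Known limitations

- The package starts at the FPKM matrix; quantification upstream is out of
  scope, as are risk-of-recurrence scores, pathway enrichment, and
  rule-based single-sample predictors.
- Reference-set balancing needs provisional labels (see above); with badly
  wrong labels the balanced draws inherit that bias.
- The K0 procedure is single-pass by design; iterating it (re-deriving K0
  tumors from K0 calls) is deliberately not offered.
- Combined exclusion of several gene clusters at once is not supported:
  with too few remaining genes rank correlations lose meaning.
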