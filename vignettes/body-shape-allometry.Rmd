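---
title: "Methods: body-shape allometry, PGLS with Pagel's lambda, and RRPP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: body-shape allometry, PGLS with Pagel's lambda, and RRPP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squamorph)
```

# The measurement model

`squamorph` quantifies whole-body shape from skeletal specimens with
formula-defined ratios. For one specimen,

* **hbER** `= (L_H + L_B) / L_R` — cranial length plus the sum of all
  vertebral centrum lengths, divided by body depth (the mean of the four
  longest rib curve lengths). Dimensionless; larger is more elongate.
* **head ER** `= L_H / H_H` — cranial length over cranial height.
* **AEI** per vertebral region `= sum(L_V) / mean(H_V)` — summed centrum
  lengths over mean vertebral height, for the cervical, thoracic,
  lumbar, and sacral series separately.
* **body size** — the geometric mean of 11 measurements.

Which 11 measurements enter the geometric mean is a genuine design
choice: the source description ("cranium, vertebrae, and ribs; N = 11")
does not enumerate them. We use cranial length, cranial height, the four
regional summed centrum lengths, the four regional mean vertebral
heights, and body depth. This is the unique reading consistent with a
count of 11 from those three measurement families, and it makes the
geometric mean exactly scale-equivariant with the ratio statistics
scale-invariant — the property the analyses rely on.

Species values are computed **index-first**: each ratio is computed per
specimen and then averaged arithmetically across conspecific specimens,
and ln transforms are taken of the species means. Averaging indices
rather than raw bones avoids conflating specimens with different
vertebral counts; the alternative (mean skeleton, then indices) is
available as `aggregate_species(..., rule = "mean_then_index")` for
sensitivity checks. Specimens violating a measurement precondition
(e.g. fewer than four ribs) are excluded with a warning rather than
aborting a run, mirroring opportunistic museum sampling. Missing limb
bones are legal: a limb length is reported only for specimens with all
required bones for the requested mode (full: scapula + humerus + radius
+ third metacarpal and femur + tibia + third metatarsal; reduced: long
bones only), and species without any limb material carry `NA` limb
fields and are excluded — with a reported count — from limb analyses.

# Phylogenetic regression

All models are generalized least squares with residual covariance
`sigma^2 * V(lambda)`, where `V[i, j]` is the shared root-to-MRCA branch
length of species *i* and *j* and Pagel's `lambda` multiplies the
off-diagonal entries. `lambda` is estimated by maximum likelihood
(not REML), profiled over exactly [0, 1] by a 101-point grid followed by
bounded scalar refinement; the returned optimum is guaranteed (and
tested) to be at least as good as the best grid point. At the optimum,
coefficients are exact GLS through a factorization of `V(lambda)`:

* For ultrametric trees the whole `lambda` family shares one eigenbasis
  (`V(lambda) = U (lambda L + (1 - lambda) d I) U'`), so the data are
  rotated once and each `lambda` evaluation is `O(n p)`. This is what
  makes per-replicate `lambda` re-estimation affordable inside the
  bootstrap.
* Non-ultrametric trees fall back to a Cholesky factorization per
  `lambda`; they are accepted without rescaling because the transform is
  defined on any covariance.

Reported summaries: ML `sigma^2`, log-likelihood, and an adjusted R²
computed on the whitened scale as `1 - (1 - R^2)(n - 1)/(n - k - 1)`
with `k` the number of non-intercept columns, where R² compares the
model's whitened residual SS to that of the intercept-only GLS at the
same `lambda`. Residuals are returned on the response scale and satisfy
the GLS normal equations `X' V(lambda)^-1 e = 0` (tested to 1e-8).

**ANCOVA.** Ecotype differences in allometry are fitted as
`ln shape ~ ln size * ecotype` with treatment contrasts (chipmunk is the
reference, alphabetically) and assessed with Type II sums of squares:
each term against the model containing all terms that do not contain
it, with `lambda` held at the full-model estimate. Marginality
violations (an interaction without its main effects) are an error.

**Bootstrap confidence intervals.** CIs are parametric: `n_reps`
responses are simulated from `N(X beta_hat, s^2 V(lambda_hat))` and the
full model is refitted — including `lambda` re-estimation — to each;
the 95% interval is the (2.5%, 97.5%) percentile of the replicate
coefficients. Two numerical choices matter:

* `s^2` is the *unbiased* residual-variance estimate, not the ML one.
  The ML estimate is low by a factor `(n - p)/n`, which systematically
  shrinks percentile intervals; with the ANCOVA design (p = 8) at n = 87
  this is a 4-5 coverage-point bias. The acceptance suite measures
  coverage directly (95% +/- 3% over hundreds of seeded simulations).
* Per-group slopes are computed per replicate as sums of replicate
  coefficients (reference slope + interaction), never by interval
  arithmetic on marginal CIs.

Replicates that fail to converge are dropped and counted; everything is
deterministic given the seed.

**Allometry calls.** Because the responses are dimensionless ratios,
isometry is a slope of 0 (configurable). A bootstrap CI entirely above
the isometric slope is positive allometry, entirely below is negative,
anything else is not significant; a zero-width CI exactly at the
reference is not significant. Two ecotypes are flagged as having
different slopes under the symmetric rule — each slope outside the
other's CI — with the one-directional matrix also reported, since the
source description of the rule is one-way.

**Size correction** replaces a ln trait by its PGLS residual against ln
geometric-mean size. Size-corrected rib length is defined this way and
reused both as an allometry response and as the rib component in the
RRPP decomposition. Ecotype means of size-corrected limb lengths come
from the phylogenetic group-means model `trait ~ 0 + ecotype`, with
bootstrap CIs and the mean-outside-the-other's-CI difference rule.

# RRPP decomposition

The association between body shape and its six components (head ER,
four AEIs, size-corrected rib length) is a phylogenetic multiple
regression assessed by the randomized residual permutation procedure:

* Response and design — including the intercept column — are whitened by
  a triangular factor of `V`. By default the `lambda = 1` (Brownian)
  covariance of the pruned tree is used and is *not* re-estimated inside
  the permutations; a different `lambda` is a config option, since the
  source procedure does not state one.
* Sums of squares are **sequential** (entry order). The published
  component table sums its term SS to the printed total — the signature
  of a sequential decomposition — so predictor order is fixed to that
  table's order (head ER, cervical, thoracic, lumbar, sacral AEI,
  size-corrected rib length). `R^2(term) = SS(term)/SS(total)`, and
  `sum(SS) + SS(residual) = SS(total)` is asserted on every fit.
* For each term, the null distribution of its F statistic permutes the
  residuals of the reduced model (all preceding terms), adds them to the
  reduced fitted values, and recomputes F; one shared permutation per
  iteration serves all terms. The observed statistic is included in its
  own null, so `p >= 1/(n_iter + 1)`. For n <= 8 an exact mode
  enumerates all n! permutations (tested against a brute-force oracle at
  n = 6). Effect sizes Z standardize the observed log-F within the
  log-transformed null.
* Benjamini-Hochberg adjustment (step-up, hand-implemented and tested
  against the closed form) is applied within each model's table, as in
  the published component tables, not across models.

# The synthetic world

The generator's defaults state the system the package targets:

| parameter | default | rationale |
|---|---|---|
| species | 87; ecotypes 15/11/29/32 | the study's sample |
| tree | pure-birth, depth 1 | only the covariance structure matters |
| root ln size | 3.5 (~33 mm geometric mean) | mid-sized squirrel skeleton |
| BM variance of ln size | 0.15 | tip SD ~0.39 ln units, a realistic ~4x size range |
| shape slopes `b_g` | 0.24 / 0.12 / -0.11 / -0.02 | the per-ecotype allometries the method must detect |
| residual SD, `lambda` | 0.05, 0.8 | weak residual scatter with strong phylogenetic signal |
| component slopes | 0.18 / 0.22 / 0 / -0.09 / 0 | head ER and AEI allometries of the all-squirrel analyses |
| specimens per species | 1-5, noise CV 3% | museum sampling and caliper repeatability |
| vertebral counts | 7/12/7/3 | mammalian vertebral counts are nearly constant |
| limb missingness | 11/87 | fraction of species lacking limb material |

Ecotypes are assigned as contiguous blocks in cladewise tip order, which
approximates the real clustering of ecotypes into clades (random
assignment is a flag). Specimen synthesis inverts the measurement
formulas exactly: a unit-depth skeleton is built from the drawn ratios
(fixed length fractions 0.22/0.12/0.30/0.26/0.10 across cranium and
regions, equal centra within a region), then rescaled so the
11-component geometric mean equals the species' Brownian ln size.
Body depth — hence **rib length — is therefore derived** from the
ratios and size rather than given its own free allometric slope: the
formulas tie hbER, the AEIs, the geometric mean and depth together, and
a free rib slope would make an exactly invertible geometry impossible.
A consequence we consider a feature: size-corrected rib length is
genuinely associated with shape in the synthetic world, as it is in real
squirrels. With noise CV = 0 the round trip
specimens -> indices -> species traits is exact to 1e-10 (tested);
with noise, each measurement gets independent unit-mean lognormal error.

What the generator does **not** emulate: real measurement-error
covariance within a specimen, intraspecific allometry, sexual
dimorphism, vertebral-count variation, non-ultrametric trees, or
realistic distributions beyond orders of magnitude. A green recovery
test therefore establishes that the estimators are correct and
calibrated under the stated model, not that the model is adequate for
any particular empirical dataset.

# Degenerate inputs and tie-breaks

* Zero residual variance (a response exactly linear in the design)
  yields zero-width bootstrap CIs at the point estimates.
* `lambda = 0` gives a diagonal covariance: PGLS coefficients then equal
  OLS, which is also the star-phylogeny behavior (tested).
* ape cannot distinguish an unrooted binary tree from a star phylogeny
  (both are basal polytomies): the rooting-required error is raised only
  for a basal trichotomy with more than three tips; wider polytomies are
  treated as genuinely rooted.
* Tied R² values in `rank_components` keep the model's entry order, with
  a message.
* Species-name matching between data and tree is exact after normalizing
  spaces/underscores both ways, and every mismatch is reported by name:
  silent drops corrupt comparative analyses.

# Known limitations

* No OU or early-burst covariance models, no measurement-error PGLS, no
  multivariate (matrix-response) RRPP.
* The percentile parametric bootstrap is slightly conservative-to-
  anticonservative depending on `lambda` boundary effects; measured
  coverage at the stated worlds is within 95% +/- 3% (see the acceptance
  suite), but worlds with `lambda` pinned at 0 or 1 can deviate further.
* Reproduction of the published squirrel numbers requires the study's
  supplementary species table and pruned tree, which this package does
  not redistribute; the corresponding acceptance test runs only when
  those files are supplied.
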