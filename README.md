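# squamorph

Body-shape allometry and axial morphometrics for squirrel ecotypes.

Squirrels (Sciuridae) span four locomotor ecotypes — chipmunks, gliding
squirrels, ground squirrels, and tree squirrels — whose bodies range from
robust burrowers to gracile gliders. `squamorph` implements, as a tested
and reusable R package, a complete comparative analysis of how overall
body *shape* scales with body *size* across such a clade, and of which
cranial and axial components drive shape evolution. It is aimed at
morphologists and phylogenetic comparative biologists working from
museum-specimen skeletal measurements plus a dated phylogeny.

## The statistics at its core

**Elongation morphometrics.** Body shape is the head-body elongation
ratio

    hbER = (L_H + L_B) / L_R

with `L_H` the cranial length, `L_B` the summed vertebral centrum
lengths, and `L_R` the body depth (mean of the four longest ribs).
Regional elongation is the axial elongation index per vertebral region
`V` (cervical, thoracic, lumbar, sacral):

    AEI_V = sum(L_V) / mean(H_V)

Head elongation is `L_H / H_H`, and body size is the geometric mean of
the 11 cranial/axial measurements (cranial length and height, four
regional centrum-length sums, four regional mean vertebral heights, body
depth). All are computed per specimen, averaged to species, and
ln-transformed before modeling.

**Phylogenetic regression.** Models are fitted by generalized least
squares with residual covariance `sigma^2 * V(lambda)`, where `V` is the
Brownian-motion covariance of the tree and Pagel's `lambda` scales its
off-diagonals; `lambda` is estimated by maximum likelihood on [0, 1].
Allometry uses an ANCOVA design, `ln shape ~ ln size * ecotype`, with
Type II sums of squares. Per-ecotype slopes get 95% parametric-bootstrap
confidence intervals (1,000 replications, `lambda` re-estimated per
replicate); because hbER is dimensionless, isometry is a slope of 0, and
a CI excluding 0 is positive or negative allometry. Limb lengths are
size-corrected by taking PGLS residuals against ln geometric-mean size.

**Variance decomposition.** The contribution of each component (head ER,
four AEIs, size-corrected rib length) to body shape is quantified by a
phylogenetic multiple regression assessed with the randomized residual
permutation procedure (RRPP, 1,000 iterations): sequential SS on
phylogenetically whitened data, per-term permutation p-values, log-F
effect sizes Z, and Benjamini–Hochberg adjustment within each table.

A synthetic-data module (pure-birth trees, Brownian ln size,
ecotype-specific allometric lines, exact specimen synthesis with
measurement noise) makes the entire pipeline testable with no external
data.

## Worked example

```r
library(squamorph)
cfg   <- sim_config(n_species = 40, seed = 42)   # four-ecotype synthetic world
tree  <- simulate_tree(cfg)
world <- simulate_traits(tree, cfg)

fit <- fit_pgls(ln_hbER ~ ln_body_size * ecotype, world$traits, tree)
fit
#> Phylogenetic GLS (Pagel's lambda)
#>   ln_hbER ~ ln_body_size * ecotype
#>   n = 40, lambda = 0.929 (ML), sigma2 = 0.001917, logLik = 89.338
#>   R2 = 0.860, adjusted R2 = 0.829

boot <- bootstrap_cis(fit, n_reps = 500, seed = 1)
round(cbind(slope = boot$group_slopes$point, boot$group_slopes$ci), 3)
#>           slope  lower  upper
#> chipmunk  0.304  0.190  0.424
#> gliding   0.062 -0.124  0.231
#> ground   -0.155 -0.244 -0.063
#> tree     -0.035 -0.110  0.035

classify_allometry(-0.155, c(-0.244, -0.063))
#> slope -0.155 [-0.244:-0.063] vs isometry 0 -> negative
```

The generating world had slopes 0.24 (chipmunk), 0.12 (gliding), -0.11
(ground), -0.02 (tree): the chipmunk and ground slopes are recovered with
the correct allometry calls, the weak gliding and tree slopes are
(correctly, at n = 40) not distinguishable from isometry.

End-to-end, from a measurement CSV and a Newick tree:

```r
cfg <- pipeline_config(measurements_csv = "measurements.csv",
                       tree = "tree.nwk", out_dir = "out", seed = 1)
run_pipeline(cfg)   # allometry_*.csv, limb_*.csv, rrpp_components.csv
```

or from the shell:

```sh
Rscript -e 'squamorph::squamorph_cli()' run-all \
  --measurements-csv measurements.csv --tree tree.nwk --out-dir out --seed 1
```

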