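# bdhns

Microbe–disease association prediction via **b**i-**d**irectional
**h**eterogeneous **n**etwork **s**election.

Catalogues of experimentally supported microbe–disease associations (such
as HMDAD exports) are sparse: most pairs have never been examined. `bdhns`
ranks the unobserved pairs for researchers prioritising candidate microbes
for a disease (or candidate diseases for a microbe). It is aimed at
computational biologists working with curated association tables plus the
usual annotation side-channels: organ residence of microbes, a disease
hierarchy (MeSH-like DAG), disease gene sets with a weighted functional
gene network (HumanNet-like), and disease–symptom co-occurrence weights.

## Method at a glance

1. **Similarity fusion.** Gaussian interaction profile (GIP) kernels
   `GM`/`GD` over association profiles, `exp(-r‖x_i − x_j‖²)` with
   bandwidth normalised by the mean squared profile norm; microbial
   functional similarity `FM` from shared (organ, disease) annotations;
   disease semantic (`DSS`, Wang-style DAG contributions `Δ^depth`),
   functional (`DF`, max normalised log-likelihood gene scores) and
   symptom (`TD`, cosine) similarities. Fused:
   `SM = GM` where `FM = 0` else the mean, and
   `SD = (GD + DSS + TD + DF)/4`.
2. **Bi-directional heterogeneous network.** Direction-specific cross
   correlations `A′_SD = SD·A`, `A′_SM = A·SM`; heterogeneous adjacency
   `[SD, A′_SD; A′_SMᵀ, SM]`; a row-stochastic transition matrix `W` whose
   cross-type mass is the jump probability `φ` distributed over associated
   partners.
3. **Neighbour topology.** An enhanced random walk with restart,
   `P(t+1) = (1−r)·Wᵀ·P(t) + r·P(0)`, `P(0) = I`, `r = 0.1`, `t = 20`;
   node attributes are the per-node walk distributions.
4. **Selection scoring.** A parameter-free graph convolution
   `H = Â^L·X·R` (normalised adjacency with self-loops, seeded random
   projection to `d = 64`) run twice — full neighbourhood vs same-type-only
   (the causal intervention) — gives paired scores `ŷ`, `ŷˢ` from
   similarity-weighted association support; the causal effect `e = ŷ − ŷˢ`
   selects per pair: `ȳ = ŷ` where `e ≥ m` (default `m = 0`), else `ŷˢ`.

Leave-one-out and five-fold cross-validation drivers with rank-based
ROC/AUC are included, along with a seeded block-structured generator that
emulates all five input tables so the full pipeline runs with no downloads.
See the methods vignette (`vignettes/bdhns-methods.Rmd`) for assumptions,
parameter meanings and known limitations.

## Worked example

```r
library(bdhns)

sim <- generate_mda_dataset(mda_params(seed = 7))   # 15 x 60, 3 planted blocks
fit <- bdhns(sim$A, sim$annotations)
fit
#> Bi-directional heterogeneous network selection model
#>   15 diseases x 60 microbes, 100 known associations
#>   walk: r = 0.1, t = 20 (walk_profile attributes); phi = 0.5; embed dim 64, 2 layer(s)
#>   selection: threshold m = 0, full branch for 56.0% of pairs
#>   selected scores in [0.000, 0.548]

summary(fit)
#> BDHNS fit: 15 diseases x 60 microbes, 100 known associations
#> Selected score quartiles:
#>     0%    25%    50%    75%   100%
#> 0.0000 0.0144 0.0660 0.1755 0.5481
#> Full-aggregation branch chosen for 56.0% of pairs
#> Top novel candidate pairs (unobserved in training):
#>     disease    microbe  y_bar
#>  disease_05 microbe_08 0.5020
#>  disease_14 microbe_53 0.4567
#>  disease_05 microbe_11 0.4545
#>  ...
```

The score `y_bar` is the selected association probability in [0, 1]; the
"top novel" table lists unobserved pairs ranked by it — here the leading
candidates all join diseases and microbes from the same planted block, the
signal the generator hides in every annotation channel. Cross-validated
recovery:

```r
cv <- bdhns_cv(sim$A, sim$annotations, seed = 7)
cv
#> Five-fold cross-validation: 100 positives, 800 candidate negatives
#>   per-fold AUC: 0.639 0.527 0.709 0.658 0.617
#>   AUC = 0.6300
```

(A single seed is noisy; the acceptance script below averages five
datasets. Note the generator's own Bayes ceiling: given the blocks, every
entry is an independent coin flip, so even the true-block oracle averages
only ≈0.80 leave-one-out AUC at these settings.)

`predict(fit)` returns the disease-major pair table, and
`write_predictions(fit, "pred.tsv")` writes it at full precision. A thin
CLI wraps the same functions:

```sh
bdhns simulate --seed 7 --out-dir data/
bdhns predict --associations data/associations.tsv --organs data/organs.tsv \
      --dag data/dag.tsv --gene-sets data/gene_sets.tsv \
      --gene-edges data/gene_edges.tsv --symptoms data/symptoms.tsv \
      --out pred.tsv
bdhns evaluate --associations data/associations.tsv --cv fivefold --seed 1
```

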