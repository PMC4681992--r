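---
title: "Methods: pharmacogenomic growth-inhibition modelling with pgmpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacogenomic growth-inhibition modelling with pgmpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The modelling problem

`pgmpanel` models the 50% growth-inhibition potency (pGI50, the negative
log10 molar GI50) of compounds screened against a cancer cell line panel such
as the NCI60. The central idea of proteochemometric / pharmacogenomic (PGM)
modelling is to train *one* regression model on descriptor pairs

\[
\Phi_{pair}(c, l) = [\, \Phi_c(c) \,\|\, \Phi_{cl}(l) \,],
\]

the concatenation of a compound descriptor (hashed circular count
fingerprints, 256 bits, radius 2) and a cell line descriptor (a profiling
"dataset view" such as transcript levels, or a similarity kernel row). A
single model can then interpolate to unmeasured (compound, cell line) pairs
and — within limits — extrapolate to new cell lines, tissues and chemical
series, which no per-cell-line QSAR model can do.

# Panel curation

Replicate pGI50 records are collapsed per (compound, cell line) pair to the
replicate mean; the sample standard deviation of the replicates (the `n-1`
divisor — the convention is a package choice, applied consistently here and
in the z-score patterns) is kept as the pair's experimental uncertainty.
Pairs measured once carry no sd; a panel-level default uncertainty (the mean
of the available per-pair sds, typically around 0.27 pGI50 units on
NCI60-like data) substitutes wherever a per-point value is needed.

Two curation filters are provided: a *spread* filter retaining compounds
whose cross-cell-line sd of the mean pGI50 strictly exceeds a threshold
(0.5 pGI50 units by default — compounds with a genuinely differential
response), and a *replicate* filter retaining pairs averaged over at least
`k` experiments. View assembly (gene subsets, per-pathway averaging, ternary
copy-number coding with gain/loss cut-offs at log2 ratios 0.58 and −1,
top-variance selection, concatenation) requires complete matrices: missing
profile cells fail assembly rather than being silently imputed.

# Chemical space

Compounds are clustered with a periodic (toroidal) self-organizing map.
Neuron weights are initialized uniformly over the per-column ranges of the
fingerprints; at every step the best-matching unit and its Gaussian
neighbourhood move toward the presented input. The reference description
fixes only the BMU update, so the schedule is a package choice, fully
configurable: neighbourhood radius decaying linearly from `max(width,
height)/2` to 1 and learning rate from 0.5 to 0.01, with the presentation
order reshuffled per epoch under the seed.

The U-matrix assigns each neuron the mean Euclidean distance to its eight
toroidal neighbours. Low heights are basins of mutually similar neurons;
applying a height threshold (default: the 60th percentile of the heights,
because no canonical numeric value exists) and taking 8-connected components
of the foreground on the torus yields the chemical clusters. Compounds whose
BMU falls on a border join the nearest foreground component by toroidal grid
distance, so every compound receives exactly one cluster — as required by the
leave-one-compound-cluster-out validation geometry.

# Learners

The random forest configuration is 100 trees, variance split criterion,
minimum node size 1 and `mtry` equal to the input dimensionality. That
`mtry` makes each split scan every descriptor; at panel scale (tens of
thousands of rows, ~280 descriptors) a single such fit takes several minutes,
and the validation and conformal protocols need dozens of fits. The
panel-scale stages therefore default to `mtry = floor(sqrt(d))`, the standard
regression-forest compromise; this is a runtime choice, not a statistical
one — conformal validity holds for any point model, and the strategy
comparisons are between geometries, not forests. `model_config()` exposes
both settings, and small-table analyses can use the full-`mtry`
configuration unchanged.

The SVM uses a radial kernel with bandwidth parameterization
\(k(u, v) = \exp(-\lVert u - v\rVert^2 / (2\sigma^2))\) (so
\(\gamma = 1/(2\sigma^2)\) in the underlying library), tuned by a seeded
10-fold cross-validated grid search over \(C \in \{2^{-8}, 2^{-6}, \dots,
2^2, 10, 10^2, 10^3\}\) and \(\sigma \in \{2^{-8}, \dots, 2^2\}\), minimizing
CV RMSE with ties broken toward smaller \(C\), then larger \(\sigma\)
(the less complex model). Descriptors are standardized with training-set
statistics for the SVM only; forests see raw columns.

# Metrics

Performance is reported as RMSE and \(R^2_0\), the coefficient of
determination against predictions rescaled by the observed-on-predicted
regression through the origin, \(s = \sum y_i \hat y_i / \sum \hat y_i^2\):

\[
R^2_0 = 1 - \frac{\sum_i (y_i - s\,\hat y_i)^2}{\sum_i (y_i - \bar y)^2}.
\]

\(R^2_0\) is invariant to positive rescaling of the predictions and can be
arbitrarily negative; it is reported as unavailable for groups of fewer than
two pairs or constant observations.

# Validation geometries

Six learning strategies are implemented as split plans over pairs: random
ten-fold pair partition (interpolation), leave-one-cell-line-out,
leave-one-tissue-out (all lines of the tissue held out jointly),
leave-one-compound-cluster-out (driven by the SOM clusters), a
compound-only family QSAR with the same pair folds, and per-cell-line QSAR
models with an internal k-fold inside each line. The identity-style cell
line encodings (Dirac, multitask) cannot represent an unseen line, so the
package refuses to combine them with the cell-line/tissue extrapolation
geometries rather than producing silently meaningless descriptors.

The achievable-performance bounds simulate what measurement noise alone
permits: a sample `A` of pGI50 values (10% of the pairs by default, the size
of a ten-fold test set) gets its per-pair uncertainty added with a uniformly
random half of the signs flipped, giving `B`; metrics of `A` vs `B` bound the
best case, and permuting `A` first bounds the uninformed case. With constant
uncertainty \(\sigma_0\) the best-case RMSE is exactly \(\sigma_0\) in every
repetition, a property the tests assert. y-scrambling permutes the targets
among a random fraction of the pairs (values conserved) and reruns the
ten-fold strategy; a model with real signal must lose it — pooled \(R^2_0\)
goes negative by 75% scrambling on the default synthetic panel.

# Conformal prediction

The split-conformal protocol: 20% of pairs form an external evaluation set;
the remaining 80% splits 70/30 into a proper training set and a calibration
set. A seeded 10-fold CV on the proper training set produces out-of-fold
residuals; the point model is then refit on the whole proper training set and
an error model is trained on the *absolute* residuals (the sign convention is
a package choice — the non-conformity score needs a non-negative difficulty
scale). Calibration pairs are scored with
\(\alpha = |y - \hat y| / \max(\hat\rho, \rho_{floor})\) and sorted;
the threshold at confidence \(1 - \varepsilon\) is the
\(j = \lfloor N_{calib}(1-\varepsilon)\rfloor\)-th smallest score (1-based;
\(j = 0\) raises an error instead of returning a degenerate interval), and
the interval is \(\hat y \pm \alpha_{1-\varepsilon} \max(\hat\rho,
\rho_{floor})\). The floor (default \(10^{-3}\) pGI50 units) guards against
division by near-zero when the error model is overconfident. Calibration and
external predictions use the refit point model, not the CV models.

Validity is checked empirically: on the default synthetic panel the external
coverage at each confidence level in \(\{0.50, \dots, 0.95\}\) stays within
two binomial standard errors of (or above) the nominal level, and the
Spearman correlation between confidence and coverage exceeds 0.99.

# Pathway–drug associations and inhibition patterns

For a drug profile across cell lines and a pathway-level expression matrix
(per-pathway mean of log2 gene levels), the association model is the
tissue-blocked linear regression

\[
pGI_{50} = \beta_p P_i + \beta_T T_i + \varepsilon,
\]

with reference coding for the tissue factor (alphabetically first tissue as
baseline; the choice does not affect \(\beta_p\)) and the factor dropped when
only one tissue is present. Significance is the two-sided t-test on
\(\beta_p\); within each drug, Benjamini–Hochberg flags pathways at FDR <
20%. One model is fit per (drug, pathway) — the pathway's expression is the
sole continuous predictor — and rank-deficient designs (pathway collinear
with the tissue blocks) report unavailable coefficients rather than failing.
Consistency between association tables (e.g. from observed vs model-predicted
profiles) is summarized per drug by the Spearman correlation of the
\(\beta_p\) vectors. Growth-inhibition patterns standardize a drug's profile
to z-scores (sample sd) with optional conformal interval half-widths carried
through on the z scale.

# The synthetic panel generator

Because the real screening data cannot be bundled, every stage is exercised
on generated panels with known ground truth. The generative model is

\[
pGI_{50}(c, l) = \mu_c + a_{T(l)} + \gamma\, s_c^\top z_l + \epsilon_{cl},
\]

with compound potencies \(\mu_c \sim N(6, 1)\), tissue offsets with sd 0.5,
a rank-5 interaction coupling a linear projection of the fingerprint to
latent cell line factors (sd 0.5), and pair noise with sd 0.3. The latent
factors are recoverable from the informative expression-like view (20
features, latent signal plus noise of sd 0.1), so models that see both
fingerprint and view can capture the interaction while compound-only models
cannot — the contrast the strategy comparisons probe. A second, sparse
mutation-like view (40 features, 98% zeros) carries no signal. Replicates:
each retained pair draws 1–3 replicates with probabilities (0.68, 0.22,
0.10), matching the roughly one-third multi-replicate share of NCI60-scale
data, scattered around the pair value with a per-pair sd drawn from a gamma
distribution (shape 4) with mean 0.27 pGI50 units — strictly positive and
right-skewed like observed replicate sds. 7% of the grid is masked as
missing (93% completeness); the noiseless value of every masked cell is kept
in the ground truth so extrapolation can be scored. Planted chemical
clusters own disjoint blocks of high-rate fingerprint bits (Poisson rate 3
vs background 0.05), a separation strong enough that the SOM/U-matrix
pipeline recovers the labels (adjusted Rand ≥ 0.8 in the acceptance suite).
Tissues are assigned round-robin so every tissue is non-empty for
leave-one-tissue-out. One global seed expands into per-stage child seeds;
all outputs are bit-identical under a fixed seed.

What the generator does *not* emulate: real chemical structures (the
fingerprints are count profiles, not molecules), correlated profiling
platforms, heteroscedasticity linked to potency, tissue-specific interaction
structure, or batch effects. Passing tests therefore demonstrate that the
machinery is correct and that the qualitative claims (information sharing
helps; chemical extrapolation is hardest; conformal intervals are valid)
hold under a controlled signal — not that any particular real-data RMSE is
reproduced.

# Problem sizes and numerical choices

The test and acceptance runs use a default panel of 2000 compounds × 20 cell
lines (~37,000 observed pairs; conformal external set ~7,400 pairs) and a
reduced panel of 500 compounds × 15 lines for the six-strategy comparison —
sizes chosen so the full suite completes in well under half an hour on one
core while leaving the coverage estimates' binomial error around half a
percent. SOM recovery runs use 10×10–12×12 maps on 200–500 compounds; the
50×50 default mirrors the reference configuration for full-scale libraries.
Ties in the SVM grid search, in BMU selection (first index wins) and in
cluster relabelling (largest first) are broken deterministically.
Degenerate inputs fail loudly: constant profiles in rank correlations,
all-background U-matrix thresholds, confidence levels below the calibration
resolution, and rank-deficient association designs all raise (or mark)
explicit conditions rather than returning quiet numbers.

# Known limitations

- The SOM neighbourhood/learning schedule and the U-matrix threshold have no
  canonical reference values; cluster *counts* are therefore configuration-
  dependent, and only recovery of planted structure is asserted.
- Dirac/multitask encodings cannot extrapolate in cell line space by
  construction; the package refuses rather than extrapolates.
- The error model regresses absolute residuals; signed-residual or quantile
  difficulty models are not implemented.
- Association models are marginal per pathway; correlated pathways yield
  correlated tests, handled only through the within-drug FDR step.
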