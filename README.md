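# isoclust

Intensity-based hierarchical clustering for detecting structural
**polymorphs** in multi-crystal X-ray diffraction experiments.

When many rotation data sets are collected from nominally identical protein
crystals — or when one continuous helical data set is split into angular
chunks so that different regions of a crystal act as independent partial
data sets — some of them may hold genuinely different structures. `isoclust`
classifies such chunked data sets by the Pearson correlation coefficient
(CC) of their common reflection intensities, using the distance

d_CC = sqrt(1 − CC²)

and Ward-linkage hierarchical clustering, and nominates candidate polymorph
clusters with a simulation-calibrated **isomorphic threshold**

W₁ = R · W₀,  R ≈ 0.6–0.7,

where W₀ is the maximum Ward distance of the dendrogram (its root height)
and the maximal clusters at or below R·W₀ are the candidates. The package
also contains the Monte-Carlo machinery that calibrates R (three-component
Gaussian CC model, replicated CC-matrix sampling, a distribution-overlap
sweep with a 0.9 classification-score criterion), a unit-cell-based
clustering companion (Tukey IQR pre-filter, face-diagonal distances, linear
cell variation reporting), a synthetic two-polymorph data generator for end
to end validation, and a command-line interface.

It is intended for crystallographers and methods developers working with
multi-crystal / helical-scheme data who want a reproducible, scriptable way
to decide which partial data sets may be merged and which belong to
distinct structures.

## Worked example

Generate a labelled synthetic experiment — two structures, 24 chunks each,
40% chunk completeness, within-structure CC 0.97 and between-structure CC
0.96 (the regime where unit-cell clustering fails but intensity clustering
works) — and run the full pipeline:

```r
library(isoclust)

ds <- generate_dataset(synth_spec(n_unique = 5000, completeness = 0.4,
                                  rho_within = 0.97, rho_between = 0.96,
                                  n_chunks_per_group = 24, seed = 42))

D    <- build_distance_matrix(ds$chunks, min_common = 3)
tree <- linkage_cluster(D, method = "ward")
tree
#> <iso_dendrogram> 48 leaves, ward linkage, W0=0.6917 W1=0.296 (W1/W0=0.428)

report <- nominate_polymorphs(tree, R_low = 0.6, R_high = 0.7)
report
#> <polymorph_report> threshold 0.415-0.4842 (W0=0.6917, R=0.6-0.7)
#>   2 candidate cluster(s), 0 outlier cluster(s)
#>   candidate 1: 24 chunks at height 0.2885
#>   candidate 2: 24 chunks at height 0.296
```

The two candidates below the threshold interval 0.415–0.484 are exactly the
two planted 24-chunk groups: both structures were assembled at heights
around 0.29 (pairwise d_CC ≈ 0.24, i.e. CC ≈ 0.97, plus Ward accumulation),
while joining them costs the root height 0.69. `glance(tree)` returns the
same numbers as a one-row tibble; `tidy(report)` gives the per-chunk
assignment table and `autoplot(tree)` draws the dendrogram with the
threshold band.

The calibration simulation behind the 0.6–0.7 interval, at its reference
configuration (CC medians 0.978/0.970/0.962, SDs 0.020/0.019/0.017, two
balanced groups totalling 83 data sets):

```r
sim <- run_simulation(cc_model(), n_a = 42, n_b = 41,
                      replicates = 100, seed = 1)
glance(sim)
#> # A tibble: 1 × 8
#>   replicates mean_W0 mean_W1  sd_W1 mean_R mean_score min_score frac_perfect
#>        <int>   <dbl>   <dbl>  <dbl>  <dbl>      <dbl>     <dbl>        <dbl>
#> 1        100   0.900   0.552 0.0205  0.615      0.941     0.855            0
```

`mean_W1` is the Monte-Carlo estimate of the isomorphic threshold for this
model (reported reference value 0.61 ± 0.03) and `mean_R = W1/W0 ≈ 0.61`
motivates the 0.6–0.7 working ratio. Note the mean two-cut classification
score of 0.94: with independently sampled pair correlations a few leaves
land in the wrong branch in most replicates — see the methods vignette
(`vignettes/polymorph-clustering.Rmd`) for why this differs from the ideal
of perfect classification and what it implies.

## Command line

A thin executable is installed with the package (also runnable as
`Rscript exec/isoclust` from the source tree):

```sh
isoclust synth    --out-dir chunks --n-unique 5000 --chunks-per-group 24 --seed 42
isoclust cluster  --chunks 'chunks/*.tsv' --out-dir run1
isoclust simulate --out-dir sim --replicates 100 --seed 1
isoclust sweep    --out-dir sweep --n-list 100,200,300,500
isoclust cellhca  --cell-table cells.tsv --out-dir cellrun
isoclust split    --input frames.tsv --out-dir chunks --frame-width-deg 0.1
```

Outputs are machine-readable (dendrogram JSON and Newick, assignment and
exclusion TSVs, summary JSON echoing the full configuration); parameters can
come from a YAML `--config` file, with flags taking precedence. Exit codes:
0 success, 2 configuration error, 3 data error.

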