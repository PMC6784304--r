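# handovr

How much does a short hand-over motion tell about the person performing it?
`handovr` is an R package for researchers in movement science and
human–robot interaction who want to quantify the information content of
short joint-angle sequences: whether a few seconds of finger motion identify
the performer, reveal the experimental condition (object, transfer style,
side of the giver), or betray stable personal traits.

The pipeline, end to end:

1. **Trajectories** — T × 20 matrices of hand joint angles (4 rotational
   degrees of freedom per digit × 5 digits; global hand pose excluded),
   either generated synthetically with a controlled effect hierarchy
   (identity ≫ condition ≫ trait) or loaded from delimited-text exports.
2. **Distances** — multivariate dynamic time warping with Euclidean local
   cost over the 20 channels (compiled core), assembled into a symmetric
   dissimilarity matrix.
3. **Embedding** — nonmetric multidimensional scaling minimizing Kruskal's
   stress-1,
   `sigma_1 = sqrt( sum (d_ij - dhat_ij)^2 / sum d_ij^2 )`,
   by isotonic regression alternated with SMACOF majorization, at
   dimensions 1, 2, 3 and 20.
4. **Supervised recognition** — LVQ1 on the embedded coordinates under
   trialwise and participantwise cross-validation, scored by error rate and
   the chi-square cross-tabulation p-value per fold.
5. **Unsupervised coding** — an 8-axis self-organizing map with 2 units per
   axis (2^8 = 256 units); each trajectory is coded by the 8 binary lattice
   coordinates of its best-matching unit.
6. **Statistics** — histogram mutual information in bits with first-order
   Miller–Madow bias correction (two-pass descriptor protocol), and MANOVA
   of the BMU codes (Pillai, Wilks, Hotelling–Lawley, Roy with approximate
   F tests) with backward model reduction of participant properties.

The methods vignette (`vignettes/handover-individuality.Rmd`) documents the
models, parameter choices and numerical decisions in detail.

## Worked example

```r
library(handovr)

cfg <- generator_config(n_pairs = 2, replicates = 1,
                        t_range = c(60L, 80L), seed = 42)
ds  <- filter_valid(generate_dataset(cfg))
ds
#> <handover_dataset> 4 participants, 64 trials (64 valid), 128 trajectories

D   <- distance_matrix(ds$trajectories)   # 128 x 128 DTW dissimilarities
emb <- nmds_embed(D, dim = 3)
glance(emb)
#> # A tibble: 1 × 5
#>     dim stress n_iter converged     n
#>   <int>  <dbl>  <int> <lgl>     <int>
#> 1     3  0.125     11 TRUE        128
```

A stress-1 of 0.125 means the 3-D configuration reproduces the rank order
of the DTW dissimilarities with modest distortion — good enough to see the
cluster structure (`autoplot(emb, metadata = ds$trajectories)` colours by
participant and shapes by giver/receiver role).

```r
cv     <- make_partitions(ds$trajectories, "trialwise", k = 4, seed = 1)
report <- evaluate_factors(emb, ds, c("identity", "content"), cv, seed = 1)
report
#> # A tibble: 2 × 6
#>   design  factor   mean_error mean_asymptotic_significa…¹ n_partitions n_skipped
#> 1 between identity      0                        1.01e-16            4         0
#> 2 within  content       0.578                    1   e+ 0            4         0
```

Reading the rows: the LVQ network recognizes *who* moved from a held-out
trial perfectly (error 0, cross-tabulation p ≈ 1e-16), while at this
projection dimension the beaker *content* is near chance (0.578) — the
identity signature dominates the low-dimensional embedding. The full
pipeline (`run_pipeline(pipeline_config(seed = 1))`) classifies on the
20-dimensional projection, where the condition factors become recoverable
too, and additionally writes the MI matrix, BMU codes and MANOVA tables to
a reproducible report bundle.

## Using your own recordings

`load_external_trials(dir)` ingests the same delimited-text interchange
format the pipeline writes: per trajectory a CSV (`t, a01..a20`, radians)
plus a JSON sidecar with the trial record (condition factors, giver and
receiver, owner, role), and an optional `participants.csv`. Schema
violations are reported with the offending file and field. The returned
dataset drops into `run_pipeline(..., dataset = ...)` unchanged.
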