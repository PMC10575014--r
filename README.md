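# stairclust

Unsupervised detection of stair ambulation in free-living, thigh-worn
accelerometer recordings — aimed at clinicians and researchers monitoring
lower-limb prosthesis users (and healthy walkers) who need to know whether a
person negotiates stairs in daily life, without annotating data or training a
classifier.

## The method

For one subject's tri-axial recording (g units, nominally 20 Hz):

1. zero-phase Butterworth band-pass, 0.4–3 Hz (removes gravity and
   high-frequency artifact);
2. non-overlapping 2 s windows (40 samples), per-window feature bank
   (time-domain statistics, FFT band powers, dominant frequency, spectral
   entropy, axis correlations — 73 features by default, configurable),
   z-scored per subject;
3. seeded t-SNE to 2-D (perplexity 30, exaggeration 4, Euclidean distance,
   no PCA), strictly per subject — pooled multi-subject maps cluster by
   individual, not by activity;
4. DBSCAN (eps 3, minPts 15) on the map;
5. stair assignment. Ground walking dominates free-living data (90–99% of
   windows), so the largest cluster is always a walking cluster. With two
   clusters, the smaller is the stair cluster by elimination. With more, a
   one-component Gaussian *N*(μ, Σ) is fitted to the walking cluster and
   every candidate cluster *i* is scored by

   *P(C_i = C_stairs) = 1 − 1 / (l_i · φ_i)*

   where *l_i* is the negative log-likelihood of the candidate's centroid
   under the walking Gaussian (stair clusters lie farthest from the walking
   mass) and *φ_i* is a compactness rank factor 1, 1.05, 1.10, … from the
   least to the most compact candidate (stair clusters are tighter;
   compactness is the median pairwise distance within the cluster). The
   arg-max candidate becomes the stair cluster; everything else is relabeled
   Walk. One cluster total is an error — there is no contrast to assign.

Evaluation across t-SNE seeds 1–5: stair-cluster purity (fraction of
upstairs/downstairs ground truth inside the detected stair cluster),
initial NMI (raw DBSCAN partition vs the binary truth) and corrected NMI
(after relabeling), plus hypothesis statistics (Shapiro–Wilk, Wilcoxon
rank-sum, paired right-tailed t-test of the NMI improvement). Synthetic
generators for labeled gait signals and for embedding geometries make every
stage testable without any recorded data.

See `vignette("stair-ambulation-detection")` for the full methods account.

## Worked example

Simulate a 140 min free-living recording (95% ground walking at
1.72–1.88 Hz cadence, 5% stairs at 0.95–1.05 Hz), run the pipeline, and
evaluate across the five t-SNE seeds:

```r
library(stairclust)

sim <- simRecording(seed = 3)             # recording + ground-truth track
fs  <- buildFeatureSet(sim$recording, sim$track)   # filter/window/features
report <- evaluateSubject(fs, seeds = 1:5)
report
#> StairEvalReport over 5 t-SNE seeds
#>  seed status nClusters purity nmiInitial nmiCorrected
#>     1     ok         2      1          1            1
#>     2     ok         2      1          1            1
#>     3     ok         2      1          1            1
#>     4     ok         2      1          1            1
#>     5     ok         2      1          1            1
#>   mean purity 1.000 (sd 0.000), NMI initial 1.000 -> corrected 1.000
```

Every seed produces a two-cluster map — the dominant walking cluster and
one stair cluster — so the stair cluster is found by elimination; purity 1
means every window in it is truly upstairs/downstairs, and NMI 1 means the
two-identity model matches the binary ground truth exactly on non-outlier
windows. On this clean harmonic gait model the metrics sit at their
ceiling; real free-living recordings (sensor noise, transitions, annotation
error, idiosyncratic gait) yield lower purity and NMI, and for some
subjects the stair windows never condense into a cluster at all, giving
purity 0 or an error status.

Reading real data instead:

```r
rec   <- readRecording("subject01.csv")        # columns time,x,y,z
track <- readActivityTrack("subject01_labels.csv")  # start,end,label
fs    <- buildFeatureSet(rec, track)
report <- evaluateSubject(fs)
```

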