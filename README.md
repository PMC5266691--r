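# emospect

Spectral EEG correlates of ten positive emotions.

`emospect` implements a complete analysis pipeline for film-clip EEG
studies of discrete positive emotions (amusement, awe, gratitude, hope,
inspiration, interest, joy, love, pride, serenity), for researchers in
affective neuroscience and EEG-based affect recognition. Because such
studies rarely deposit raw data, the package pairs every analysis with a
synthetic-data generator that plants known structure — so each stage can
be validated by how well it recovers what was planted.

## What it computes

**Rating structure.** Participants × clips × items Likert ratings are
summarised by inter-rater reliability (two-way consistency, average-measures
intraclass correlation, `(MS_R − MS_E)/MS_R` with clips as targets and
participants as raters), pairwise Pearson correlations between
cross-participant mean item profiles, a repeated-measures-ANOVA
manipulation check, and Kruskal non-metric MDS on dissimilarities
`d_ij = 1 − r_ij`, from which the ten emotions cluster into
*encouragement*, *playfulness* and *harmony*. Per-clip cluster scores are
means of z-transformed ratings within each cluster.

**Band power.** For each clip, the last 30 s of EEG and a 5-s pre-onset
baseline are transformed with a single rectangular-window FFT; band power
is the mean one-sided periodogram power over DFT bins in theta (3–7 Hz),
low alpha (8–10), alpha (8–13), beta (14–29) and gamma (30–47), baseline
corrected by subtraction. Correlating the corrected power with ratings
over clips, per channel and band, yields channel × band × item
correlation topographies, averaged across participants.

**Classification.** 1-s epochs of the clip window give 5 × 32 = 160
features per epoch (900 positive-clip epochs per participant). Labels come
from the parent clip by median split on an item rating or a cluster score
(an exactly balanced 450/450 partition with deterministic tie-breaking),
or from pairwise cluster-score differences. A linear-kernel SVM (cost 1,
features standardized inside each training fold) is evaluated with
stratified 10-fold cross-validation, per participant and on grand-average
(cross-participant mean) features.

The synthetic generator draws ratings from a latent three-cluster model
with controllable rater noise, and synthesizes EEG whose per-band power in
each clip window is `basePower + Σ_i β[ch,b,i]·z(rating_i) + noise`, by
exact spectral shaping of random-phase noise over a 1/f background. The
planted coefficient array is exported as ground truth for recovery
scoring. See the methods vignette (`vignettes/emospect-methods.Rmd`) for
the model, conventions and design decisions.

## Worked example

```r
library(emospect)

design  <- studyDesign(nParticipants = 4,
                       clips = defaultClips(seed = 8, durationRange = c(30, 40)),
                       seed = 8)
ratings <- generateRatings(design)
round(iccAll(ratings)[c("amusement", "joy", "serenity", "valence")], 2)
#> amusement       joy  serenity   valence
#>      0.87      0.87      0.91      0.92

pos   <- clipIds(design)[design@clips$category == "positive"]
model <- assignClusters(mdsEmbed(ratings, dims = 3, clipScope = pos, seed = 8),
                        "kmeans", seed = 8)
model
#> ClusterModel: 10 items in 3 dims; Kruskal stress-1 = 5.79e-05
#>    playfulness : amusement, interest, joy
#>    encouragement : awe, gratitude, hope, inspiration, pride
#>    harmony : love, serenity

effects  <- effectMap("planted")
features <- participantEpochFeatures(design, ratings, effects, "P01")
features
#> BandPowerTensor ( epoch level ): 900 rows x 32 channels x 5 bands; baseline-corrected

rmat   <- ratingValues(ratings)["P01", pos, ]
labels <- medianSplitLabels(rowInfo(features),
                            setNames(rmat[, "amusement"], rownames(rmat)))
table(labels)
#>  low high
#>  450  450
crossvalClassify(features, labels, seed = 8, task = "amusement",
                 participant = "P01")
#> ClassificationResult [P01 | median_split | amusement]: 98.3% (10-fold range 96.7-98.9)

avg <- topographyPipeline(design, ratings, effects,
                          participants = c("P01", "P02"))
round(recoveryScore(avg, plantedTruth(effects), threshold = 0.1), 3)
#> [1] 0.998
```

Reading the numbers: the generated raters agree strongly (ICC ≈ 0.9), the
ten items embed at near-zero stress and k-means recovers the planted
clusters exactly; the 900 amusement-labeled epochs split 450/450 and
classify far above the 53.3% chance bound (epoch-level folds share clips
between training and test, which is the convention this design follows —
see the vignette); and the two-participant average topography already
matches the planted effect signs on 99.8% of supra-threshold entries.

A file-based interface with the same stages is available from the shell:

```sh
Rscript inst/cli/emospect.R simulate  --config config.yaml --out run/
Rscript inst/cli/emospect.R features  --config config.yaml --out run/
Rscript inst/cli/emospect.R ratings   --config config.yaml --out run/
Rscript inst/cli/emospect.R correlate --config config.yaml --out run/
Rscript inst/cli/emospect.R classify  --config config.yaml --out run/
Rscript inst/cli/emospect.R report    --config config.yaml --out run/
```

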