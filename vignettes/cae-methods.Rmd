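---
title: "Cognitive-associative encoding of tangrams: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive-associative encoding of tangrams: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tangramcae)
```

This vignette documents the models implemented by `tangramcae`, the
parameters that matter, and the design decisions taken where several
reasonable choices existed. It is the package's methodological reference;
the README shows a worked example.

## The encoding

A tangram is a figure assembled from seven fixed convex pieces: two large
right triangles, one medium right triangle, two small right triangles, a
square and a parallelogram, with canonical area ratios
large : medium : small = 4 : 2 : 1 and the square and parallelogram each
equal to the small-triangle pair. The figure's structure is summarized by
classifying the boundary contact of every piece pair into one of six
nominal relation codes:

| code | relation              | geometric condition |
|------|-----------------------|---------------------|
| 0    | no overlap            | no boundary contact |
| 1    | complete line overlap | collinear edges sharing a segment equal to both edges |
| 2    | partial line overlap  | a positive-length shared segment equal to neither edge (or equal to one edge that reaches the other's endpoint) |
| 3    | line containment      | the shared segment equals exactly one edge, lying strictly inside the other |
| 4    | point–line contact    | a vertex coincident with a non-vertex point of an edge |
| 5    | point overlap         | coincident vertices only |

`classify_relationship()` evaluates these conditions with exact segment
arithmetic and a coincidence tolerance, and `encode()` assembles the
7 × 7 symmetric integer matrix over the canonical piece order (large A,
large B, medium, small A, small B, square, parallelogram). Because all
predicates use a tolerance proportional to the figure's bounding-box
diagonal (`1e-6 ×` diagonal by default), the encoding is invariant under
translation, rotation and uniform scaling; the test suite verifies
bit-identity under 1,000 random similarity transforms.

Two conventions deserve explanation:

* **Precedence.** When a piece pair touches at several loci with different
  relation types, the lowest nonzero code is reported. The code order
  reflects cognitive closeness — line-based contact is a tighter coupling
  than point-based contact — so the tightest relation present wins.
* **Identical-piece labels.** The two large triangles (and the two small
  triangles) are physically interchangeable. At import, A/B labels are
  assigned by lexicographic centroid; all distances between encodings
  minimize over the four relabelings of these two pairs, which forms a
  group and therefore preserves the triangle inequality.

## Distance, embedding and separability

`cae_distance()` is the normalized L1 distance over the 21 upper-triangle
cells, minimized over the identical-piece relabelings; codes are small
nominal-ordinal integers, for which L1 is the natural choice that keeps
metric axioms after the group minimization (verified on 1,000 random
triples). `mds_embed()` performs metric multidimensional scaling by SMACOF
majorization (Kruskal stress-1, classical-scaling start plus seven random
restarts under a fixed seed); classical Torgerson scaling is available via
`kind = "classical"`. `separability_test()` runs a pooled-variance Student
t test of a binary label along every embedding axis and reports the axis
with the largest |t| (degrees of freedom n − 2).

## Representation dimensions

* **Animacy** is the fraction of a figure's global annotation labels whose
  canonicalized head noun (lowercase, final token, singularized) appears in
  an editable animate lexicon shipped with the package.
* **Abstraction** is the normalized Shannon entropy of the canonicalized
  label distribution (0 = perfect annotator agreement, 1 = all labels
  distinct); one minus modal agreement is available as an alternative.
* **Local feature density (LFD)** is computed from classification
  efficiency at two matrix granularities. At scale *s* the classifier sees
  the best single *s*-piece submatrix (selected on training folds by summed
  Gini gain of its cells) and is a CART decision tree over the nominal
  relation codes, cross-validated with stratified folds; scale 2 (one
  connection) is the local scale, scale 7 (the full matrix) the global
  scale. Chance is the majority-class frequency, which is robust to class
  imbalance.

The LFD definition needs care. Because the global feature set contains
every local feature set, global accuracy is never structurally below local
accuracy, so the ratio of above-chance excesses cannot express "local
features dominate". We therefore define LFD as the *share* of total
discriminability contributed by the local scale:

```
lfd = eL / (eL + gG),   eL = max(0, accLocal - chance),
                        gG = max(0, accGlobal - accLocal)
```

with the convention `lfd = 0.5` when neither scale beats chance. A label
carried by a single connection gives LFD near 1; a label carried only by
the whole configuration (for instance, the presence of *any*
complete-line-overlap contact anywhere in the matrix) gives LFD near 0.
Under this definition the local excess `eL` and the incremental global
contribution `gG` trade off, and across a pool of datasets mixing local and
global rules their correlation is strongly negative — the same local/global
antagonism seen in behavioral and encoding analyses of tangram sets. The
per-figure variant applies the same share formula to each figure's
out-of-fold true-class probabilities. The **local deviation index** is the
absolute deviation of a figure's LFD from the set median.

The default CART depth in `granularity_profile()` is 12 (cost-complexity
pruning at `cp = 0.001` still limits overfitting): the feature space has
only 21 nominal cells, and rules involving several connections — exactly
the global rules LFD must detect — need more than a handful of splits to
express. `fit_dimension_tree()`, whose purpose is to *rank* critical
connections rather than to measure attainable accuracy, keeps a shallow
default (depth 4) so the importance ranking concentrates on the strongest
splits.

`select_stimuli()` curates a stimulus set by greedy round-robin filling of
the 18 cells of animacy × abstraction-tertile × LFD-tertile after trimming
extreme LFD values, and arranges the selection into nine display groups
(abstraction tertile × LFD tertile) used for ordering dissimilarity
matrices.

## Annotation matching

`train_matcher()` fits a multi-class support vector machine on one-hot
expanded relation features (21 cells × codes 1–5 = 105 binary features —
one-hot because the codes are nominal, and an ordinal embedding would
fabricate structure). Calibrated per-label scores drive the ten-candidate
matching task: `run_matching()` picks the candidate with the highest score
for the query label, breaking ties toward the lowest candidate index and
logging them. Chance is 0.1. Default hyper-parameters (`cost = 10`,
`gamma = 0.1`) suit the binary, noise-free feature space. Part-label bags
are scored by summing per-part scores. A radial kernel outperforms a
linear one whenever the label depends on a conjunction of connections,
mirroring the advantage of nonlinear kernels reported for this task
family.

## The synthetic-data generators

The generators provide every input the analysis stack needs, with known
ground truth; their defaults mirror the study conditions the pipeline is
meant for (85 stimuli × 5 presentations, 61 channels, 500 Hz, epochs
−0.5…1.0 s, baseline −0.4…−0.1 s, 24 subjects).

**Figures.** `gen_figures()` realizes a target relation template by
sequential constructive placement: pieces are placed along the template's
relation graph, each contact snapped exactly (collinear contacts by edge
alignment with randomized overhangs and margins; point contacts inside the
free angular wedge at the anchor), then the figure is re-encoded and
checked against the template, retrying with fresh random choices up to a
bounded budget. Random templates are sampled as path-structured relation
graphs with at most one collinear-type contact (codes 1–3) per piece, and
complete line overlap only between pieces sharing an edge length. These
constraints are not cosmetic: a piece carrying two collinear contacts
frequently forces an unintended third-party contact through the shared
vertex (a medium–small complete overlap plus a small–small containment is
geometrically unsatisfiable, for example), and unconstrained random
forests leave roughly a third of templates unrealizable. Cyclic or
code-1-infeasible user templates raise a flagged error of class
`cae_constructive_failure` rather than failing silently.

**Annotations.** `gen_annotations()` meets the animacy target exactly
(the animate label quota is fixed first) and then selects the integer
partitions of the animate and inanimate label groups whose joint
normalized entropy is closest to the abstraction target, assigning one
distinct word per block. Recovery of both truths on uniform targets
exceeds r = 0.99 (animacy) and r = 0.98 (abstraction), with abstraction
RMSE limited by the entropy spectrum of partitions of ten labels
(coarsest gap ≈ 0.14 near zero diversity).

**Epochs.** `gen_epochs()` adds planted components to spatially structured
noise: rank-limited (default 10) random channel mixing of AR(1) sources
(φ = 0.97 at 500 Hz) plus white sensor noise, scaled to a baseline RMS of
10 arbitrary units. Each component is a Gaussian temporal envelope × a
fixed unit-norm random topography × a per-trial condition value (logical
columns map to ±1, numeric columns are z-scored; `"image"` components give
every stimulus its own topography). Familiarity modulation shifts latency
and scales gain per presentation step. Optional artifacts are dipolar
±100-unit excursions placed after the baseline window, so the ±80
rejection rule must catch them even after average referencing.

**Behavior.** `gen_behavior()` draws lognormal reaction times with
additive log-unit effects (defaults: abstraction +0.2 per SD, animacy
−0.1, LFD −0.05, local deviation −0.1) and a repetition decrement of 0.1
log-units per presentation that stabilizes at the third presentation.
Responses follow the animacy truth with an error rate increasing with
abstraction and are *persistent* within a subject–image pair — perceptual
interpretations rarely flip trial-to-trial — except for designated
change-of-mind images (default 11.5% of images), which flip exactly once
at a random presentation (2–5) in a random direction. Persistence is what
makes the change-of-mind detector's precision and recall exactly 1 on
synthetic data; with independent per-presentation errors, accidental
single-transition sequences would contaminate the measure.

## Decoding pipeline

`preprocess()` applies, in order: average reference, zero-phase
Butterworth band-pass 0.1–40 Hz (forward–backward), baseline subtraction
over −0.4…−0.1 s, and rejection of epochs exceeding ±80 units on any
channel, logging rejected trials.

`decode_timecourse()` fits, per timepoint, a two-class linear discriminant
with analytic (Ledoit–Wolf style) shrinkage of the pooled covariance
toward a scaled identity — the shrinkage intensity is estimated from the
data, which keeps the classifier stable when channels outnumber trials —
under stratified k-fold cross-validation (default 5). It reports, besides
the accuracy curve (chance 0.5), the fold-averaged discriminant vectors
(*weights*) and the forward-model *activation patterns* (data covariance ×
discriminant). The distinction matters: discriminants are whitened by the
noise covariance and need not resemble any physiological topography, while
activation patterns recover planted topographies with cosine similarity
above 0.99 at the group level.

Group-level inference uses the two-sided exact Wilcoxon signed-rank test
against chance at every timepoint across subjects, BH-FDR corrected over
timepoints — the nonparametric test is the package-wide default, matching
the behavioral statistics. `contrast_labels()` builds tertile high-vs-low
contrasts and can equalize the tertile composition of non-target
dimensions across classes by subsampling (covariate control).

`decode_pairwise_images()` computes, for every unordered image pair and
timepoint, cross-validated accuracy with folds grouped by presentation
cycle, so that one image's trials never straddle the train/test split;
image pairs with insufficient trials are imputed by row/column means and
flagged. `temporal_generalization()` trains at each timepoint on one
trial split and tests at every timepoint on the other; the default
familiarity split is presentations 1–2 (unfamiliar) versus 4–5 (familiar),
dropping presentation 3 where reaction times have just stabilized, with an
RT-quantile split available. Cluster-level inference
(`tgm_cluster_test()`) thresholds the across-subject t map (cluster-forming
p = 0.05, two-sided), labels 4-connected clusters, and compares cluster
masses against a sign-flip permutation null (default 1,000 permutations),
separately for above- and below-chance clusters.

## RSA and the time-resolved GLM

`build_model_rdms()` constructs six candidate model RDMs: animacy and
object level as same/different indicators (object level over the nine
display groups — the only grouping structure the curated set defines),
abstraction and LFD as absolute score differences, feature level as the
Jaccard distance between part-tag sets, and connections as the encoding
distance. Stimuli without encodings (natural-image controls) get
connections entries imputed at the maximum observed distance and flagged.
`model_space_mds()` embeds models by classical MDS of one minus the
pairwise Pearson correlation of their lower triangles.

`timewise_glm()` regresses, per subject and timepoint, the centered lower
triangle of the neural RDM on the z-scored model predictors plus an
intercept (ordinary least squares; a pseudo-inverse with a warning when
predictors are collinear). The response is centered, not z-scored, so
coefficients stay on the neural dissimilarity scale and a noiseless
`2 × model` series recovers exactly 2; per-timepoint z-scoring of the
response is available as an option but breaks that calibration. Group
inference is Wilcoxon-vs-zero with BH-FDR applied *jointly* over models ×
timepoints — correcting each model separately would let the family-wise
null rate grow with the number of models (about 26% for six models in
null simulations, against 4% for the joint correction at q = 0.05).

`stimulus_embedding()` offers classical MDS and an exact t-SNE
(perplexity-calibrated affinities by bisection, momentum gradient descent
with early exaggeration, fixed seed) and reports a trustworthiness score;
at the stimulus counts involved (≤ a few hundred) the exact method is
unproblematic and avoids approximation parameters.

## Behavioral statistics

Reaction times are normalized as the within-subject z score of log RT
(plain z is available). All group tests operate on subject-level means —
never on pooled trials — with the Wilcoxon rank-sum test for the animacy
contrast and signed-rank tests for within-subject contrasts, exact p
values for n ≤ 25, and BH-FDR over the four dimension tests.
`repetition_curve()` adds adjacent-presentation signed-rank tests and the
trial-level Pearson correlation between presentation index and normalized
RT. `detect_change_of_mind()` flags a subject–image pair when its ordered
response sequence contains exactly one transition (multi-transition
sequences are treated as unstable and excluded); the image-level expected
count is the mean over subjects of per-subject flagged-image counts, so
fractional counts are meaningful, and the fraction divides by the number
of images under analysis.

## Numerical choices and degenerate inputs

* Coincidence tolerance: `1e-6 ×` bounding-box diagonal, everywhere; the
  perturbation-stability tests jitter vertices by a tenth of the tolerance
  without changing any code.
* Interior-overlap validation: intersection area above `tol × min(piece
  areas)` fails, which tolerates sliver artifacts in traced inputs.
* Ties: matching ties break toward the lowest candidate index (logged);
  tertile ties go to the lower bin; MDS restarts keep the lowest-stress
  solution.
* Degenerate inputs raise typed errors: zero-area pieces, wrong vertex
  counts, missing polygons, single-class targets, empty splits, all-trials
  rejected.

## What the synthetic data do and do not show

The generators produce exact contact geometry, label distributions with
controlled entropy, Gaussian-envelope components in spatially mixed AR
noise, and persistent responses. Passing the recovery and calibration
tests therefore demonstrates that the pipeline measures what it claims to
measure under known ground truth — correct relation classification,
unbiased decoding under the null, recovery of planted latencies,
topographies, model time courses and behavioral effects. It does not
demonstrate performance on recorded EEG: real data add non-Gaussian
artifacts, inter-subject topography variability, trial-count imbalance
after rejection, and annotation idiosyncrasies that no fixed lexicon
captures. Quantities reported by published studies on real tangram
datasets (matching-task accuracies, specific decoding onsets, the exact
local/global correlation) depend on those datasets and are reproduced here
only qualitatively (signs, orderings, calibration properties).

The verification suite and the acceptance script run at reduced problem
sizes chosen to exercise every code path while keeping simulations brisk:
12–16 channels at 40–50 Hz sampling for recovery simulations, 8 channels ×
20 timepoints × 24 subjects × 100 runs for null calibration, 200–400
figures for encoding-level checks, and 75 images × 24 subjects for
behavior. The defaults of the generators themselves remain at the full
study scale.

## Known limitations

* The constructive placer handles acyclic contact structures; cyclic
  templates (closed tangram rings) are flagged as unsatisfiable rather
  than solved — realizing them would require joint optimization over all
  pieces.
* Artifact handling is amplitude rejection only; the preprocessing
  contract exposes no ICA (a hook for externally cleaned epochs is the
  epoch container itself).
* The animate lexicon is English and finite; labels outside it lower
  animacy scores regardless of meaning.
* `cae_distance()` weights all relation codes equally; plausible
  alternatives (weighting by cognitive closeness, spectral graph
  distances) are deliberately out of scope.
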