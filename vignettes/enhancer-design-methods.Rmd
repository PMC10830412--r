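---
title: "Deep and transfer learning for tissue-specific enhancer design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep and transfer learning for tissue-specific enhancer design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

enforge implements a two-stage deep-learning strategy for predicting and
designing tissue-specific enhancers. The premise is that genome-wide
chromatin accessibility (e.g. scATAC-seq pseudo-bulk coverage per tissue) is
abundant, while in-vivo enhancer activity annotations are scarce — typically
a few hundred validated elements per tissue. The strategy:

1. **Sequence-to-accessibility (regression).** A convolutional network maps
   a 1,001-bp DNA window to the log accessibility signal of one tissue,
   trained on hundreds of thousands of tiled genomic windows under a
   chromosome-half hold-out cross-validation plan.
2. **Sequence-to-activity (classification, transfer learning).** The trained
   network re-initializes a classifier of binary in-vivo activity for the
   same tissue: all convolutional and dense weights are copied and kept
   trainable, only the output unit is replaced by a fresh sigmoid head,
   and the model is fine-tuned with a small learning rate. Folds are
   shared between stages, so held-out test sets stay held out end to end.
3. **Interpretation.** Per-nucleotide contribution scores against
   dinucleotide-shuffled reference sequences explain which bases drive a
   prediction; flank-trimmed PWMs summarize recurrent motifs.
4. **Design.** Random 501-bp cores are flanked to 1,001 bp, scored for
   accessibility and activity in every tissue, and filtered for candidates
   predicted active specifically in one target tissue; survivors are
   checked for flank robustness, ranked against a random background, and
   re-scored in the reporter-construct context.

Because genuine scATAC atlases and enhancer databases cannot ship with a
package, enforge includes a first-class synthetic-world generator with a
known ground truth, so the complete pipeline runs and is testable offline.

# The network

Both stages share one architecture operating on one-hot encoded DNA
(A = (1,0,0,0), C = (0,1,0,0), G = (0,0,1,0), T = (0,0,0,1); N encodes as an
all-zero row):

* four 1-D convolutions — filters 256, 120, 60, 60; kernel widths 7, 3, 3, 3;
  zero "same" padding — each followed by batch normalization, ReLU, and
  max-pooling of size 3;
* two dense layers of 64 and 256 units, each with batch normalization,
  ReLU, and dropout 0.4;
* a single output unit: linear for the accessibility regression, sigmoid
  for the activity classification.

Training uses Adam (learning rate 0.005 for the regression stage; 1e-4 for
fine-tuning), mean-squared-error or binary cross-entropy loss, batch size
128, and early stopping on the validation fold with best-weight
restoration. Three replicate models are trained per held-out fold;
replicates that fail the convergence rule (test-set PCC <= 0.1 for
regression; held-out ROC AUC <= 0.7 for classification) are dropped, and
ensemble predictions are the arithmetic mean of the converged replicates.

The network is implemented from first principles in compiled code
(`src/cnn.cpp`): im2col + BLAS matrix products for the convolutions, a
gather/scatter fast path for the one-hot first layer, fused
batch-normalization and ReLU kernels, and analytic backpropagation that
also yields gradients with respect to the input (used by the attribution
module). The forward/backward passes are verified against central finite
differences in the test suite. Internal arithmetic is single precision;
per-channel moments and loss reductions accumulate in double precision.
All stochastic elements — weight initialization (Glorot-uniform),
minibatch shuffling, dropout masks — derive from explicit integer seeds,
so training runs are bit-reproducible on a fixed platform.

## Numerical conventions

* Batch normalization: eps 1e-3, biased batch variance, running statistics
  used at inference. The running-average momentum is 0.9 rather than the
  common 0.99: desk-scale runs take a few hundred gradient steps in total,
  and with momentum 0.99 the inference-time statistics would still be far
  from the batch statistics when early stopping is evaluated, making the
  monitored validation loss meaningless.
* Adam: beta1 0.9, beta2 0.999, eps 1e-7, bias correction.
* Max-pooling drops the trailing remainder (valid pooling), so a 1,001-bp
  input flattens to 12 positions after four pool-3 stages.
* Early stopping monitors the validation loss (the monitored quantity is a
  free choice; validation loss is the natural one for both stages) and
  restores the best-validation weights.

## Desk-scale width and patience

`architecture_spec(width_scale = )` scales the convolution filter counts
(0.25 gives 64, 30, 15, 15) for reduced-cost runs; the dense layers are
computationally negligible and keep their size, preserving capacity where
it costs nothing. `width_scale = 1` reproduces the full architecture.

Early-stopping patience counts epochs, but an epoch is not a fixed amount
of optimization: the full-scale regression stage sees ~2,900 minibatches
per epoch, while the default synthetic world yields ~65. A patience of five
epochs therefore corresponds to wildly different step budgets at the two
scales. The package keeps patience 5 as the `train_config()` default (the
published recipe) and uses patience 10 with at most 30 epochs for its
desk-scale accessibility runs — chosen from this step-count arithmetic and
reported in the pipeline manifests. Fine-tuning keeps patience 20
throughout, with a 15-epoch cap in the packaged comparisons.

# Dataset construction

The regression dataset follows a fixed recipe. The genome is tiled into
1,001-bp windows at a 50-bp stride; the target per window and tissue is the
natural log of the mean depth-normalized coverage over the central 201 bp
(a 1e-3 pseudocount inside the log guards all-zero random windows; windows
with a zero pre-log central mean in any tissue are excluded anyway, so the
pseudocount does not affect the kept windows' ranking). Windows whose
central 151 bp fall entirely within any accessibility peak — peaks of all
tissues combined, each re-centred to 301 bp around its midpoint — form the
positive-signal backbone; a configurable number of random windows
(stratified over ten equal-width bins of the tissue-averaged central-mean
signal) adds negative and intermediate examples. Windows with more than
10% N are excluded up front, and per-tissue outliers below the 0.01 or
above the 0.999 target quantile (linear-interpolation quantiles over the
candidate set) are dropped. Reverse-complement augmentation then doubles
the set with identical targets.

Cross-validation splits by chromosome halves: each chromosome is cut at its
midpoint, halves are assigned to ten folds by seeded round-robin over
halves ordered by decreasing length, and every window inherits the fold of
the half containing its midpoint (a midpoint exactly on the cut goes to the
left half). Each rotation uses one fold for testing, the next for
validation, and the remaining eight for training. The activity stage reuses
this plan unchanged. Held-out evaluation uses only original, non-augmented
windows; training uses the augmented set.

The activity dataset derives from an annotation table of tested fragments
(tile coordinates, stage term, tissue term, active/inactive). A fragment is
labeled active for a tissue when any of its annotations is active between
stages 13 and 16 in one of the tissue's terms; a tissue may additionally
carry exclusion terms (the brain-specific pattern requires no
ventral-nerve-cord activity). Fragments are tiled into 1,001-bp windows
(500-bp stride); positives are tiles of active fragments overlapping a
tissue accessibility peak by at least 151 bp, negatives are tiles of
inactive fragments down-sampled to at most five per fragment. The confident
evaluation set uses peaks overlapping active tiles by at least 201 bp as
positives, peaks in inactive tiles and the inactive tiles themselves as
negatives.

# The synthetic world

`world_config()` / `make_world()` generate the study substrate: a uniform
random genome with tissue-specific motifs planted at Poisson-distributed
positions, per-tissue accessibility equal to baseline + gain x (planted
site log-odds impulses smoothed with a 200-bp triangular kernel) under
multiplicative lognormal noise, peak calls as threshold exceedances of the
locally averaged track (95th background percentile, extended to >= 301 bp),
and an activity table in which a fragment is active for a tissue when some
501-bp core contains at least `activity_rule` planted sites of that
tissue's motif. The generator records every planted site, so downstream
claims (label replay, attribution localization, design enrichment) are
tested against known truth rather than against another model.

Default study conditions, fixed once:

* five chromosomes of 100 kb (500 kb total). Ten chromosome halves make the
  ten-fold chromosome-half plan exactly one half per fold; the resulting
  dataset holds roughly five thousand windows before augmentation.
* three tissues with distinct 8-bp near-consensus motifs (0.95 consensus
  probability, so planted instances are recognizable under the one-mismatch
  match rule while random background rarely is), planted at 0.75 sites/kb
  per tissue. With the
  two-sites-in-501-bp activity rule this yields 150-200 positive activity
  tiles per tissue — deliberately in the range of the least-annotated
  tissues that motivate transfer learning — at ~30% fragment prevalence.
* lognormal noise scale 0.2 on the accessibility tracks.

What the generator does *not* emulate: read-level ATAC noise and Tn5 bias,
fragment-size structure, co-occurring heterotypic motif grammar, GC
composition gradients, repeats. Passing tests on this world demonstrate
that the pipeline's machinery — data construction, optimization, transfer,
attribution, screening — behaves as specified when the signal is
motif-driven; they do not certify performance on real chromatin data.

# Attribution

Contribution scores use multi-reference integrated gradients with
dinucleotide-preserving reference shuffles (Altschul-Erickson Euler-path
sampling; each reference has exactly the input's dinucleotide count table).
For each reference, the path gradient of the model's pre-activation output
(the logit, for classifiers) is averaged over 64 midpoint steps and
projected into hypothetical scores — the attribution each possible base
would receive at each position relative to the reference expectation —
and actual scores are the hypothetical scores at the observed bases.
Summed actual scores approximate f(input) minus the mean reference score
(the completeness identity), exactly for linear models, and the test suite
requires <= 5% relative error for trained models. The relative form of the
identity is only meaningful where the prediction differs from the
reference expectation, so completeness is checked on the most accessible
held-out windows — the sequences attribution is for; on near-baseline
windows the absolute error stays small but the ratio's denominator
vanishes. Maps from the ten fold
models are averaged elementwise. Discovered motifs are summarized as PWMs
trimmed by removing flanking positions with information content below 0.4
bits (uniform background); MEME minimal text is the interchange format.

# Design loop

`screen_candidates()` draws i.i.d. random 501-bp cores (zero-order Markov,
uniform by default), wraps each in random 250-bp flanks to the 1,001-bp
model input, and keeps candidates with target-tissue activity probability
>= 0.8, every off-target tissue activity <= 0.2, and accessibility at or
above the 80th percentile of the screened batch. Survivors rank by target
activity (ties: lower maximal off-target activity, then input order).
Selected cores are re-scored in 100 random flank contexts
(`flank_robustness()`; the candidate passes when the minimum stays above
80% of its selection score), ranked as percentiles against a random
background (fraction of background strictly below the score), and finally
scored inside the actual reporter-construct flanks averaged over the ten
fold models (`final_scores()`).

The published screen sampled three billion cores to select 40; the package
defaults scale this to thousands of cores selecting eight, which preserves
the selection logic while running in seconds. The ground-truth enrichment
check asks whether cores selected by the models satisfy the generative
activity rule (at least `activity_rule` strong PWM matches on either
strand, at 80% of the maximal log-odds score) more often than the random
background — the desk-scale analogue of an in-vivo hit rate.

# Open choices made here

* **"301 bp-centred peak region"** is read literally: every peak is
  re-centred to a fixed 301-bp interval around its midpoint before the
  containment test.
* **Random-window sampling** is stratified over ten equal-width signal bins
  — a deterministic, seedable reading of sampling "with a range of
  accessibility levels".
* **Fold composition** is an implementation artifact (seeded round-robin by
  half length); the plan is serialized with the dataset so runs reproduce.
* **ROC AUC** is used for the classification convergence rule (the rule
  names only "area under the curve"); the choice is recorded in model
  manifests.
* **Accuracy/F1** use a 0.5 probability cutoff, recorded in the metrics
  output.
* **Flank length** is 250 bp on both sides (501 + 2 x 250 = 1,001); the
  flank-robustness screen uses the same length.
* **Evaluation on originals**: augmented reverse-complement copies are
  excluded from every held-out evaluation, matching the original-data
  evaluation convention.
* **Attribution fold choice**: where one replicate per fold is needed, the
  first converged replicate is used.
* **Off-tissue donor selection**: with several donor accessibility models,
  the donor with the best validation-fold AUPRC wins; ties break
  lexicographically by donor name.

# Known limitations

* The CNN engine is single-threaded and CPU-bound; full-width, full-genome
  training is out of reach here (the width-scaled desk runs are the
  supported regime; `width_scale = 1` reproduces the architecture for
  users with more compute).
* Training in single precision with batch normalization can diverge at
  aggressive learning rates on very narrow models; the trainer aborts with
  a diagnostic rather than returning NaNs.
* The synthetic world's activity rule is homotypic (one motif type per
  tissue); combinatorial grammars, which the real system exhibits, are not
  represented.
* Percentile ranking and the accessibility threshold are defined relative
  to the screened batch, so extremely small screens make them coarse.
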