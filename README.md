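# enforge

Deep and transfer learning for predicting tissue-specific enhancer activity
from DNA sequence — and for designing synthetic tissue-specific enhancers
de novo.

## The problem and the approach

Enhancers activate transcription in a cell-type-specific fashion, but for
most tissues only a few hundred elements have been functionally validated —
too few to train a sequence model directly. Genome-wide chromatin
accessibility (scATAC-seq pseudo-bulk coverage per tissue) is far more
abundant and correlates with enhancer function. enforge implements the
two-stage strategy that exploits this asymmetry:

1. **Sequence-to-accessibility model.** A CNN regresses the log mean
   accessibility signal of the central 201 bp of a 1,001-bp window from its
   one-hot encoded sequence: four 1-D convolutions (filters 256, 120, 60,
   60; widths 7, 3, 3, 3; same padding) each with batch norm, ReLU and
   max-pool 3, then dense layers of 64 and 256 units with dropout 0.4, and a
   linear output. Training: Adam (lr 0.005), MSE, batch 128, early stopping,
   ten-fold chromosome-half hold-out cross-validation, reverse-complement
   augmentation, three replicate models per fold with a convergence filter
   (test PCC > 0.1) and replicate-mean ensembling.
2. **Sequence-to-activity model (transfer learning).** The trained
   accessibility weights initialize a binary classifier of in-vivo enhancer
   activity for the same tissue (fresh sigmoid head, all layers trainable),
   fine-tuned with Adam (lr 1e-4), binary cross-entropy, patience 20, on a
   few hundred labeled elements — reusing the same folds so test sets stay
   held out across both stages. Baselines with random initialization or
   off-tissue pre-training isolate the transfer effect.
3. **Attribution.** Per-nucleotide contribution scores via multi-reference
   integrated gradients against dinucleotide-shuffled references
   (Altschul–Erickson sampling), with hypothetical scores projected onto
   the observed sequence; PWMs trimmed at 0.4 bits of flanking information
   content; MEME minimal text IO.
4. **Design.** Random 501-bp cores in random 250-bp flanks are screened for
   high predicted activity and accessibility in one target tissue and low
   activity everywhere else, checked for flank robustness, ranked against a
   random background, and re-scored in the reporter-construct context.

No deep-learning framework is required: the network (forward, backward,
Adam, input gradients) is implemented in compiled code inside the package.

A synthetic-genome generator with planted tissue-specific motifs, derived
accessibility tracks, peak calls, and a known activity rule makes the whole
pipeline runnable and testable offline, with every claim checked against
generative ground truth.

## Worked example

```r
library(enforge)

# a 500-kb synthetic world: 5 chromosomes, 3 tissues with planted motifs
world <- make_world(world_config(seed = 11))
world
#> Synthetic world: 5 chromosome(s) x 100000 bp, 3 tissue(s)
#>   planted sites: 1096 | activity annotations: 340 rows (241 active)
#>   cns: 390 peak(s)
#>   epidermis: 373 peak(s)
#>   gut: 439 peak(s)

# stage-one dataset: tiling, peak-anchored selection, folds, augmentation
ds <- build_regression_dataset(world, seed = 11)
ds
#> Regression dataset: 10058 windows (reverse-complement augmented), 3 tissue target(s)
#>   folds: 1,2,3,4,5,6,7,8,9,10

# accessibility model for one tissue on held-out fold 1 (width-scaled)
spec <- architecture_spec(width_scale = 0.25)
cfg  <- train_config(seed = 11, patience = 10, max_epochs = 30)
ens  <- train_fold_ensemble(ds, test_fold = 1, spec, cfg, replicates = 2,
                            seed = 11)
vapply(ens$models, function(m) m$meta$metric, numeric(1))  # per-replicate PCC

# transfer learning on the small in-vivo activity set
labels <- label_records(world$activity, world_term_map(world))
act <- build_activity_dataset(labels, "cns", world$genome, world$peaks$cns,
                              ds$fold_plan, seed = 11)
clf <- fine_tune(ens$models[[1]], act, test_fold = 1, seed = 1)
clf$meta$metric  # held-out ROC AUC

# nucleotide contributions for one held-out sequence
cm <- contribution_scores(clf, act$seq[1], n_refs = 20, seed = 1)
cm

# design: screen random cores for cns-specific candidates
cand <- screen_candidates(generate_random_cores(4000, seed = 7),
                          list(cns = clf), ens, "cns",
                          selection_policy(max_candidates = 8))
cand
```

`run_pipeline()` (or `inst/scripts/forge.R run-all`) orchestrates all
stages with caching and a JSON run manifest. The methods vignette
(`vignettes/enhancer-design-methods.Rmd`) documents the model, the
synthetic-world assumptions, and every numerical convention.

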