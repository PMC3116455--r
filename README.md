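# semkernels

Semantic kernels and probabilistic multiple kernel learning (pMKL) for
detecting sentences that describe protein–protein interactions (PPIs).

## The problem and who this is for

Literature curation of PPI databases starts by finding the sentences
that report an interaction.  As a bag-of-words classification task this
suffers from synonymy: a test sentence may say *associates* where every
labelled training sentence said *binds*, and a plain kernel sees no
similarity at all.  `semkernels` is for text-mining and systems-biology
groups who want the semi-supervised fix: word co-occurrence structure
harvested from large **unlabelled** corpora is folded directly into the
training kernel, and several such kernels are fused by a probabilistic
classifier that also reports how informative each kernel was.

## The method

Sentences become rows of a count matrix `X` (proteins anonymised to
`PTNGNE1`, `PTNGNE2`, …; lowercased, letters only, stop words removed,
tokens truncated to 10 characters).  A semantic matrix `S` from
unlabelled text smooths the counts, and kernels are built as

    K = kappa( (X + eps) S , (X + eps) S ),    eps = 0.01

with cosine, Gaussian `exp(-theta ||a-b||^2)` or polynomial
`(a.b + 1)^2` for `kappa`.  Two word co-occurrence models supply `S`:

* **HAL** — a window of length `L` slides over each sentence; a word at
  distance `l` before the target scores `L - l + 1`, giving a sparse
  word-by-word matrix `H = H_o + t(H_o)` (per-distance components are
  kept so distance-resolved kernels can be weighted separately);
* **BEAGLE** (context-only) — each word gets a random Gaussian
  *environmental vector* in `D = 4096` dimensions and a target's row
  accumulates the vectors of its sentence co-occurrers, a random-mapping
  compression of the full co-occurrence matrix.

Kernels are fused convexly, `K = sum(beta_s K_s)`, inside a
multinomial-probit model fitted by variational Bayes: latent class
scores carry the prior `N(0, K(beta) + delta I)`, truncated-Gaussian
auxiliary variables realise the probit link, and every update is exact
coordinate ascent so the variational bound is monotone.  `beta` can be
held fixed or inferred on the simplex; the bound's log-determinant
Occam factor is what lets informative kernels outrank flexible noise.
Evaluation follows a 10×10 cross-validation protocol (sentence- or
abstract-level randomisation), inner-CV tuning of `theta` over
`10^(-5:1)`, and the variance-corrected resampled t-test.

A synthetic corpus generator with planted synonym clusters (TRAIN/TEST
halves per cluster) makes the whole pipeline testable without any
external corpus download.

## Worked example

Train on sentences whose interaction triggers come only from the TRAIN
half of each synonym cluster; evaluate on held-out sentences that use
only the TEST half — words never seen with a label.  Smoothing with a
HAL matrix built from 5000 unlabelled sentences recovers the signal:

```r
library(semkernels)

spec <- generator_spec(n_labeled_sentences = 400L, n_trigger_clusters = 8L,
                       n_background = 80L, n_unlabeled_sentences = 5000L,
                       seed = 42L)
train    <- generate_labeled(spec, subset = "train", n = 400L)
heldout  <- generate_labeled(spec, subset = "test",  n = 200L)
unlabeled <- generate_unlabeled(spec)

res <- run_holdout_experiment(
  train, heldout, unlabeled,
  pipelines = list(
    plain = list(kernels = list(list(kind = "gaussian", smoothing = "none"))),
    hal   = list(kernels = list(list(kind = "gaussian", smoothing = "hal")))),
  semantic = list(hal = list(L = 5L)), n_folds = 10L, seed = 42L)
print(res)
compare_pipelines(res, "hal", "plain", metric = "auc")
```

Output:

```
<experiment_result> 20 fold records
  hal                      F = 0.3909 +/- 0.0825  err% = 22.50  AUC = 0.8486 +/- 0.0221
  plain                    F = 0.0000 +/- 0.0000  err% = 31.00  AUC = 0.6602 +/- 0.0456
corrected t = 3.346, p = 0.008574
```

The plain Gaussian pipeline hovers near the class prior (31% error is
the all-negative rate; its F of 0 means it never crosses the 0.5
threshold for a positive) because the held-out trigger words carry no
labelled evidence.  The HAL-smoothed pipeline reaches AUC 0.85: the
unlabelled co-occurrences taught the kernel that TEST-half triggers are
interchangeable with their TRAIN-half cluster mates.  The corrected
t-test on the 10 fold-level AUC pairs calls the difference significant
(p < 0.05).

`run_experiment()` runs the full repeated-CV protocol from a config
list or JSON file (see `?run_experiment`), and
`inst/cli/semkernels-cli.R` exposes `run` / `compare` subcommands for
shell use.

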