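---
title: "Semantic kernels and probabilistic MKL for PPI sentence detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic kernels and probabilistic MKL: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semkernels)
```

## The problem

Curating protein-protein interactions (PPIs) from the literature begins
with finding the sentences that describe an interaction at all.  Treated
as binary sentence classification over bag-of-words counts, the task is
hampered by synonymy: the word that signals an interaction in a test
sentence ("associates") may never have occurred in the labelled training
data, where the annotators' sentences said "binds".  This package
implements a semi-supervised remedy: word co-occurrence statistics
harvested from large *unlabelled* corpora are folded into the kernel of
a supervised classifier, so that lexically different but
distributionally similar words reinforce each other.

## Representation and smoothing

A labelled corpus of $M$ sentences becomes a count matrix
$X \in \mathbb{N}^{M \times N}$ over $N$ features.  Preprocessing:
protein mentions are replaced by per-sentence numbered placeholders
(`PTNGNE1`, `PTNGNE2`, ...), text is lowercased, non-letter characters
are dropped, stop words removed, and surviving tokens truncated to 10
letters.  The rule order (lowercase, strip, stop-drop, truncate) is a
package decision: truncation last prevents truncated forms from
colliding with stop words.  The stop list is configurable and its md5
is recorded in experiment provenance.

A semantic matrix $S$ built from unlabelled text re-weights the counts:

$$K = \kappa\big((X + \varepsilon)S,\ (X + \varepsilon)S\big),$$

with $\varepsilon = 0.01$ added to every entry so that all features
participate in the smoothing even at zero count.  With $S = I$ and
$\varepsilon = 0$ the plain bag-of-words kernel is recovered exactly.
The kernel menu is cosine, Gaussian
$\kappa_g(a,b) = \exp(-\theta\lVert a-b\rVert^2)$ and polynomial
$(a \cdot b + 1)^d$ with $d = 2$; the Gaussian functional form and the
inhomogeneous polynomial are package choices (only the parameter values
are inherited), chosen so the $\theta$ tuning grid
$\{10^{-5}, \dots, 10\}$ keeps its meaning.

## The two semantic models

**HAL** slides a window of length $L$ over each sentence; the last word
in the window is the target, and a preceding word at distance $l$
($1 \le l \le L-1$) adds $L - l + 1$ to the (target, basis) cell of
$H_o$.  Word pairs therefore score more the closer they sit.  The
smoothing matrix is the symmetrised $H = H_o + H_o^\top$, covering
context on both sides.  Per-distance raw-count components $C_l$
(satisfying $H_o = \sum_l (L-l+1)\,C_l$ exactly) are retained so that
distance-resolved kernels $X H_l$ can be built and weighted separately;
we default to raw counts for these components, since the literature
disputes whether decaying distance weights help, and expose the weight
as an option.  The window resets at sentence boundaries by default
(sentences are the classification unit); window crossing is a flag.
Targets are restricted to the labelled vocabulary — similarities are
only useful for features the classifier can see.

**BEAGLE** (context-only variant; the word-order convolution encoding is
out of scope) assigns every basis word a random environmental vector
$e_b \in \mathbb{R}^D$ with i.i.d. $\mathcal{N}(0, 1/D)$ entries, so
$\mathbb{E}\lVert e_b\rVert^2 = 1$ — the scale that makes random
mapping approximately distance-preserving, with distortion shrinking as
$D$ grows.  The row of the target $t$ accumulates, over every sentence
occurrence, the sum of the environmental vectors of the co-occurring
words; an occurrence's own vector is excluded, but other occurrences of
the same word type do contribute.  $D$ defaults to 4096, and the basis
is capped at the first 30000 words encountered for large corpora.
Given a seed, regeneration is bit-identical.

## The classifier

The composite kernel is a convex combination
$K(\beta) = \sum_s \beta_s K_s$, $\beta$ on the simplex.  Per class $c$
a latent score vector $f_c$ over the training points carries the prior
$\mathcal{N}(0, K(\beta) + \delta I)$ — equivalently, a Gaussian prior
on dual weights over training points with kernel-ridge covariance.
Auxiliary variables $y_i \sim \mathcal{N}(f_i, I)$ realise the
multinomial probit link: the observed class is $\arg\max_c y_{ic}$.
Binary problems run through the same two-class multinomial path.

Inference is variational Bayes with a factorised posterior
$q(F)\,q(Y)$, both updates available in closed form given the other, so
every sweep is exact coordinate ascent and the variational bound is
non-decreasing — a property the test suite asserts on every fit.  All
truncated-Gaussian moments reduce, by conditioning on the winning
residual, to one-dimensional integrals evaluated with deterministic
Gauss-Hermite quadrature (32 nodes) on the log scale; $\log\Phi$ via
`pnorm(log.p = TRUE)` keeps the tail arithmetic finite where naive
Mills-ratio formulas overflow.

In `infer` mode, $\beta$ is moved by projected gradient ascent on the
same bound with $q$ frozen, accepting only improving steps, so
monotonicity survives.  The bound's $-\tfrac{C}{2}\log\det$ term is the
Occam factor: a flexible near-identity noise kernel buys its in-sample
fit with a large determinant penalty, while a kernel whose leading
eigenvectors align with the labels explains them cheaply.  This is what
makes the inferred weights a usable ranking of kernel informativeness.
An earlier design with a unit-covariance weight prior and $f = Kw$
lacked this penalty and systematically preferred noise kernels; it was
replaced, and the weight-recovery property test (informative kernel
receives the largest weight in at least 8/10 seeded runs) guards the
behaviour.

There is no tunable regularisation constant: the prior scale is unity
and the nugget is fixed at $\delta = 0.01$ (a conventional jitter that
also keeps Cholesky factorisations of near-singular Gaussian kernels
stable).  Predictions integrate the probit over the latent posterior;
the predictive variance needs the test self-similarity $k(x^*, x^*)$,
which the cross-kernel-only interface cannot supply, so it defaults to
1 — exact for Gaussian and cosine kernels, overridable otherwise.

## Evaluation protocol

Experiments run $r \times k$-fold cross-validation (default
$10 \times 10$) under two randomisation schemes: free sentence
shuffling, or abstract-level assignment in which no abstract is split
between training and test.  The Gaussian $\theta$ is tuned by an inner
$1 \times 3$ CV over powers of ten from $10^{-5}$ to $10$, maximising
inner AUC (an F-score criterion is a switch), ties broken toward the
smaller value; per-fold tuning is the default under the abstract scheme
and a single global parameter under the sentence scheme, both available
under either via config.  Metrics are precision, recall,
$F = 2PR/(P+R)$ (0 when $P+R=0$), error percentage at the 0.5
probability threshold (the thresholding rule is a package decision),
and rank-based AUC with half credit for ties; a single-class fold
reports AUC as missing with a warning.  Fold means average per-fold
values (never the F of pooled P and R), and summaries report standard
errors both over the $kr$ folds and over repetition means, since either
convention is found in practice.

Pipelines are compared with the corrected resampled t-test

$$t = \frac{\bar d}{\sqrt{\hat\sigma^2_d\,(\tfrac{1}{kr} + \tfrac{n_2}{n_1})}},$$

with $n_2/n_1$ the test/train size ratio ($1/9$ at $k=10$) and $kr - 1$
degrees of freedom: the naive paired t-test is anti-conservative under
the training-set overlap of repeated CV, and a simulated correlated
null in the test suite checks the corrected version rejects at roughly
the nominal rate.

## The synthetic world

The generator stands in for a real annotated corpus.  Defaults: 2000
labelled sentences at a 30% positive rate (echoing the roughly
600/1400 class balance of real sentence-level PPI data), sentences of
5-15 tokens over 300 background words, 20 "trigger" clusters of 4
synonyms each, abstracts in blocks of 5 sentences, and a 20000-sentence
unlabelled corpus.  Positives carry at least two protein placeholders
and exactly one trigger; negatives carry placeholders but no trigger
(a leakage rate knob injects label noise if wanted).  Each cluster's
synonyms split into a TRAIN half and a TEST half, and in the unlabelled
corpus cluster-mates co-occur adjacently with probability 0.9 (the
co-occurrence strength), which is what lets HAL and BEAGLE discover
that they are interchangeable.

The central end-to-end check trains on sentences whose triggers come
only from TRAIN halves and evaluates on sentences using only TEST
halves: the plain Gaussian pipeline has no labelled evidence about the
test triggers and performs near chance, while the smoothed pipelines
recover the signal through the unlabelled co-occurrence structure
(AUC around 0.8 in the acceptance run).  A composite of cosine,
HAL-smoothed Gaussian and BEAGLE-smoothed Gaussian is additionally
required never to fall below its worst member on mean AUC.

What a green suite does *not* establish: the generator's language is
i.i.d. background noise plus planted triggers — no syntax, no polysemy,
no burstiness, no named-entity errors — so absolute metric values carry
no meaning for real corpora; only the ordering claims (smoothing helps
under synonym holdout, combination is safe) transplant.  Real-corpus
figures would require the original licensed datasets, which this
package deliberately does not ship or download.

## Numerical and design notes

* Runtime scaling: the acceptance tests run the full $10\times10$
  protocol at $n = 2000$ once and verify determinism on re-run
  repetitions; the synonym-holdout benefit uses 1000 train / 500
  holdout sentences per master seed so that ten seeds stay inside a
  desktop time budget.  Fit cost is one $M \times M$ Cholesky plus
  cheap quadrature sweeps per iteration.
* Convergence: iteration stops when the bound changes by less than
  `tol * (1 + |bound|)` (default `1e-4`, `max_iter = 100`).  The bound
  approaches its limit geometrically; predictions stabilise much
  earlier than the bound's last decimals.
* Vocabulary indices are sorted in the C locale; fold assignments,
  environmental vectors and generators derive per-task seeds from the
  master seed, so every experiment is reproducible bit for bit.
* Degenerate inputs: empty corpora, single-class labels, off-simplex
  weights, indefinite kernels and out-of-range HAL distances all raise
  typed errors rather than propagating silently.
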