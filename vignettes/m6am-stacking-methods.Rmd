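---
title: "Methods: stacked deep learning for m6Am site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked deep learning for m6Am site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

N6,2′-O-dimethyladenosine (m6Am) is a cap-proximal mRNA modification placed
on the first transcribed adenosine. Experimental mapping (m6Am-seq, miCLIP)
is expensive and cannot always separate m6Am from 5′-UTR m6A, so sequence-based
classifiers are used to prioritize candidate sites. The unit of prediction is
a 41-nt window — a candidate adenosine K with δ = 20 flanking nucleotides on
each side, written `A(−δ) … A(−1) K A(+1) … A(+δ)` in 1-based, fully closed
coordinates. A window is positive when its central adenosine is a genuine
m6Am site. The benchmark design this package mirrors holds 1419 positive and
1419 negative training windows plus 355/355 independent test windows, both
balanced 1:1.

## Encodings

Three per-position encodings are provided:

* **One-hot** (L×4): A, C, G, U as indicator vectors. This is the encoding
  the classifiers consume, selected over the alternatives by encoding
  ablation experiments.
* **NCP** (L×3): three binary chemistry channels — ring structure
  (purine A/G = 1), functional group (amino A/C = 1), hydrogen-bond strength
  (strong A/U = 1) — making A = (1,1,1), C = (0,1,0), G = (1,0,0),
  U = (0,0,1). Statements of the second channel's rule are sometimes
  printed inconsistently in this literature; we use the amino/keto
  classification (A and C amino), which also makes the code bijective.
* **ND** (L×1): cumulative density d_i = n/i, the running frequency of the
  symbol at position i within the prefix 1..i. The worked example "AGTAUUCA"
  (densities 1, 0.50, 0.375 for A at bits 1/4/8 and 0.20, 1/3 for U at
  bits 5/6) reproduces only when T is counted as a symbol distinct from U, so
  `encode_nd()` counts literal symbols and accepts T. Every other encoder
  works on the normalized {A,C,G,U} alphabet; since normalized RNA contains
  no T, the distinction is invisible in the pipeline and matters only for
  the worked example.

Characters outside the alphabet are rejected under the default strict policy;
the lenient policy substitutes the pad symbol `N`, which encodes to all-zero
channels.

## The three base classifiers

All three map an L×4 one-hot window to a probability through a sigmoid head
and are trained with Adam on mean binary cross-entropy. They are implemented
on a small reverse-mode autodiff tape written for this package (no deep
learning framework is available in the target environment); every backward
pass is validated against central finite differences in the test suite.

1. **densenet_senet** — a squeeze-and-excitation (SE) attention block applied
   directly to the one-hot input, then six dense blocks. Each dense block's
   layer i consumes the concatenation [x0, …, x_{i−1}], giving X(X+1)/2
   connections for X layers; each block is followed by a 1×1 transition
   convolution and an SE block in the *residual* form `x + g ⊙ x` (the
   original feature map is re-added so gating cannot destroy information).
   The head average-pools positions by 2 and flattens, preserving position
   identity.
2. **dcnn_bilstm** — three parallel dilated-convolution branches at dilation
   rates 1, 2 and 3 (a rate-1 dilated convolution is a standard
   convolution); each branch is conv → conv+ReLU → max-pool(2) → dropout,
   their feature maps are concatenated and read by a bidirectional LSTM whose
   full output sequence feeds the head.
3. **msrn_bigru** — a 64-channel stem, then six cascaded multi-scale residual
   blocks. Each block runs parallel convolutions at kernel sizes 3 and 5
   (64 kernels each), concatenates them, fuses with a 1×1 convolution
   (64 kernels, zero-initialized so every block starts as the identity) and
   adds the block input back. The six block outputs are concatenated
   (hierarchical feature fusion), compressed by a 192-filter 1×1 convolution
   with average pooling, and read by a bidirectional GRU.

Design choices the method description leaves open, fixed here and
overridable through
`base_model_spec()` / `train_config()`:

* "Same" padding everywhere so the three dilated branches stay concatenable.
* Kernel size 3 for dense-block convolutions; multi-scale realized as {3, 5}.
* Recurrent width 32 per direction; dropout 0.3; Adam with learning rate
  1e-3; batch 64; up to 50 epochs with early-stopping patience 5. None of
  these are pinned down by the method description; they are package
  defaults, not fitted values.
* The dense-block non-linearity is ELU.
* Layer normalization follows each convolution. Pipelines in this family
  typically use batch normalization; layer normalization is used instead because
  it is batch-composition-independent, which keeps predictions identical
  between batch-of-one and full-batch evaluation and makes training exactly
  reproducible from a seed on one thread.
* A stride-2 max-pool after the MSRN stem halves the position count before
  the six residual blocks. The structural contract (6 blocks, 64 kernels,
  192 fusion filters) is untouched; the pool placement is a CPU-budget
  choice.

## Stacking

For each of k folds (default 5; stratified, seeded), every architecture is
trained on the other folds and predicts the held-out fold, yielding an n×3
out-of-fold (OOF) probability matrix in which entry (i, j) was produced by a
model that never saw sample i — the leakage audit in the tests checks
exactly this. The meta-learner input concatenates the three OOF
probabilities with the flattened one-hot window (3 + 41·4 = 167 columns; no
scaling of the binary part). The meta-learner is a logistic regression fitted
by Newton/IRLS with a weak L2 penalty (λ = 1e-3, intercept unpenalized) —
the penalty stabilizes the 167-dimensional fit on ~2800 samples and keeps
separable problems finite while changing non-separable fits negligibly.
After the meta-fit, the three base models are refit on the full training data
for deployment (standard stacking practice; the alternative of averaging fold
models is not used). With fewer than three architectures (the ablation
harness supports all seven subsets) the meta width is m + 164 accordingly.

## Evaluation

Threshold metrics follow the standard confusion-matrix definitions:
Sn = TP/(TP+FN), Sp = TN/(TN+FP), ACC, and MCC with the usual
four-factor denominator. Predicted positive means score ≥ threshold
(ties to positive; default threshold 0.5, exposed as a flag). A ratio with a
zero denominator is reported as 0 with a degenerate flag rather than an
error, so an unlucky CV fold cannot crash a summary; MCC is always reported
in [−1, 1] and AUROC/AUPR in [0, 1], never on percentage scales. AUROC is the Mann-Whitney rank statistic with ties
counted 1/2; AUPR is non-interpolated step integration over unique score
thresholds. Cross-validation is stratified, repeated with derived seeds, and
summarized as mean ± population SD over folds. A negative-resampling harness
redraws the negative set (any ratio, e.g. 1:4) and reruns CV for stability
analysis.

## The synthetic generator: what a green test establishes

The generator states a world: windows of length 2δ+1 with the center forced
to `A` in both classes (as in the benchmark, where the center is therefore
uninformative), negatives drawn i.i.d. from a background composition
(default uniform), positives identical except at a few motif offsets where
the emission is `(1−effect)·background + effect·emission`. The default motif
places G, C, U, G, C at offsets +1..+5 with concentration 0.8 — a
qualitative stand-in for the G/C/U enrichment observed immediately
downstream of genuine m6Am sites. The benchmark-shaped surrogate
(`default_benchmark_surrogate()`) uses effect 0.75, chosen once as a
moderate effect: per motif position the favored base appears with
probability ~0.66 in positives versus 0.25 in negatives, giving a Bayes
AUROC near 0.92 — strong enough to be learnable, far from trivially
separable.

What the surrogate does **not** emulate: transcript context and TSS
positioning, sequence redundancy structure (the real benchmark was CD-HIT
filtered), composition skew of real flanks, and any read-level signal. A
green end-to-end test therefore establishes that the pipeline can extract a
planted positional composition signal at realistic sample sizes without
leaking labels — it does not certify accuracy on the real benchmark, which
would require the deposited data and training settings the method
description does not fix.

## Motif analysis

`positional_frequencies()` tabulates per-position base fractions;
`enrichment_table()` compares classes per (position, base) cell with a
two-proportion z-test (pooled SE) and Bonferroni correction over all L×4
cells (two-sample-logo tools do not standardize their test settings; both
the test and the correction are flags here). The fixed central
adenosine is flagged uninformative and never reported significant.

## Numerical and reproducibility notes

* All randomness (weight init, shuffling, dropout, fold assignment,
  generator draws) flows through R's RNG; a single integer seed reproduces a
  run bit-for-bit on one thread. Derived seeds stay below 2^31.
* Ensembles serialize to a directory of JSON files (plain text); reloaded
  ensembles reproduce predictions to ~1e-8 (JSON round-trips doubles at
  ~15 significant digits).
* Training aborts with a diagnostic on non-finite loss; the meta-learner
  warns with its final gradient norm when Newton iterations do not converge.
* Degenerate inputs (empty batches, single-class labels, mismatched window
  lengths) raise typed errors at the API boundary rather than propagating.

## Known limitations

* The architectures run on CPU in R; they are sized for 41-nt windows and
  thousands of samples, not genome-scale scanning.
* The heavy end-to-end tests scale epochs and stacking folds down to fit CI
  budgets (documented in the tests); the defaults above are the recommended
  settings for real use.
* The BCA-motif candidate filter is optional and configurable because the
  motif's positional definition is not standardized.
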