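# m6AmStack

Stacking ensemble deep learning for predicting **N6,2′-O-dimethyladenosine
(m6Am) sites** in RNA.

m6Am is a cap-proximal mRNA modification on the first transcribed adenosine,
implicated in mRNA stability, translation and disease. Wet-lab mapping
(m6Am-seq, miCLIP) is costly and struggles to separate m6Am from nearby m6A,
so sequence-based classifiers are used to prioritize candidate sites. This
package is for computational biologists who want a fully self-contained,
CPU-only, reproducible implementation of such a classifier — including the
data containers, encoders, evaluation harness and a synthetic benchmark
surrogate, so the entire pipeline is testable without downloading anything.

## The model

The unit of prediction is a 41-nt window `A(−20) … A(−1) K A(+1) … A(+20)`
centered on a candidate adenosine K (δ = 20), labeled positive when K is a
genuine m6Am site. Windows are one-hot encoded (41 × 4); nucleotide chemical
property (NCP) and nucleotide density (ND) encodings are provided for
ablation studies.

Three heterogeneous base classifiers map a window to P(m6Am):

* **densenet_senet** — squeeze-and-excitation attention on the input, six
  dense blocks (layer *i* consumes `[x0, …, x(i−1)]`; X(X+1)/2 connections
  per block), each followed by a residual SE block (`x + g ⊙ x`);
* **dcnn_bilstm** — three parallel dilated-convolution branches at rates
  1/2/3 (`y_i = f(Σ_n x_{i+k·n} ω_n + b)`), concatenated and read by a
  bidirectional LSTM;
* **msrn_bigru** — six cascaded multi-scale residual blocks (parallel
  kernel sizes 3/5, 64 kernels, residual pass-through), hierarchical fusion
  through a 192-filter convolution, read by a bidirectional GRU.

They are combined by **stacking**: k-fold out-of-fold (OOF) probabilities —
entry (i, j) always from a model that never saw sample i — are concatenated
with the flattened one-hot features (3 + 41·4 = 167 columns) and fed to a
ridge-penalized logistic-regression meta-learner:

    p(x) = σ( w · [p_dense(x), p_dcnn(x), p_msrn(x), onehot(x)] + b )

Evaluation uses Sn, Sp, ACC, MCC, rank-based AUROC and step-wise AUPR, with
stratified repeated cross-validation (mean ± SD over folds) and a
negative-resampling stability harness. The networks run on a small
reverse-mode autodiff engine written in base R (finite-difference-validated
in the tests); no Python or deep-learning framework is required.

## Worked example

```r
library(m6AmStack)

# a small synthetic cohort: 300 + 300 training windows, 100 + 100 test
motif <- default_motif(effect = 0.9, strength = 0.8)
train <- generate_dataset(300, 300, delta = 20, motif = motif, seed = 42)
test  <- generate_dataset(100, 100, delta = 20, motif = motif, seed = 43)
train
#> <site_dataset> 600 windows (delta=20, length=41): 300 positive, 300 negative, 0 unlabeled

specs <- list(base_model_spec("densenet_senet"),
              base_model_spec("dcnn_bilstm"),
              base_model_spec("msrn_bigru"))
cfg <- train_config(epochs = 4, batch_size = 32, learning_rate = 2e-3, seed = 7)
ens <- fit_stacked_ensemble(specs, train, k_folds = 3, config = cfg, seed = 7)
ens
#> <stacked_ensemble> 3 base models (densenet_senet, dcnn_bilstm, msrn_bigru), meta width 167

metric_report(dataset_labels(test), predict_ensemble(ens, test))
#> Sn 0.8000  Sp 0.7600  ACC 0.7800  MCC 0.5604  AUROC 0.8816  AUPR 0.8726  (n=100+/100-)
```

The test-set report reads: 80% of true sites recovered (Sn), 76% of
non-sites rejected (Sp), a Matthews correlation of 0.56 and a ranking AUROC
of 0.88 — solid for a 600-window training budget and 4 epochs; accuracy
rises with the real defaults (`train_config()`: 50 epochs, patience 5).

The positional enrichment analysis recovers the planted motif (G/C/U-type
enrichment immediately downstream of the central adenosine at position 21):

```r
tab <- enrichment_table(positional_frequencies(train, "positive"),
                        positional_frequencies(train, "negative"))
head(tab[order(tab$p_value), c("position", "base", "diff", "p_adjusted")], 5)
#>     position base      diff   p_adjusted
#> 107       25    G 0.5366667 2.735515e-37
#> 104       22    G 0.5066667 3.437974e-33
#> 147       24    U 0.4900000 4.475620e-31
#> 64        23    C 0.4533333 1.954048e-26
#> 67        26    C 0.4133333 6.906174e-22
```

Real data enters through `read_labeled_windows()` (FASTA with `pos`/`neg`
header tokens, or a `sequence,label` table), `read_fasta()` +
`extract_window()` / `find_candidate_centers()` for scanning transcripts.
A command-line interface wraps the same pipeline
(`inst/cli/m6amstack <subcommand>` or `m6am_cli()` from R) with subcommands
`simulate`, `encode`, `train`, `predict`, `evaluate`, `cv`, `motif`.

## Documentation

The methods vignette (`vignettes/m6am-stacking-methods.Rmd`) documents the
model assumptions, the tunable parameters and their defaults, what the
synthetic generator does and does not emulate, numerical choices, and known
limitations.
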