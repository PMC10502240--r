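# epifusion

Multimodal prediction of epigenetic profiles from local DNA sequence and
global 3D chromatin structure, in pure R.

## The problem

Sequence-based predictors of epigenetic events (transcription-factor
binding, DNase I hypersensitivity, histone marks) score a genomic bin from
its local DNA alone, so two windows with similar sequence always receive
similar predictions. Real epigenomes disagree with that assumption:
pairs of loci with dissimilar sequence can carry near-identical epigenetic
profiles, and vice versa. `epifusion` implements a method built around the
hypothesis that 3D chromatin contact frequency explains much of that
disparity, for three audiences: computational epigenomicists who want the
model family itself, statisticians interested in the disparity test, and
method developers who need a fully synthetic, downloads-free test bed.

The package provides:

- **The disparity test.** For random window pairs with nonzero Hi-C
  interaction frequency, sequence similarity and epigenetic-profile
  similarity are converted to percentile ranks and pairs are partitioned
  into *over* / *consistent* / *under* cells by the rank difference against
  a margin. One-sided Wilcoxon rank-sum tests (exact by enumeration with
  mid-rank ties at small n, tie-corrected normal approximation otherwise)
  ask whether *under* pairs interact more than *consistent* pairs
  (alternative `greater`) and *over* pairs less (alternative `less`).
- **The multimodal model.** A local sequence encoder — three 1D
  convolutions with interspersed max-pooling (320/480/960 kernels of size
  8), or one convolution of size 26 plus a biLSTM (320 units per direction)
  — embeds each 1-kb window in 925 dimensions. A global structure encoder —
  a per-bin MLP over normalized interaction-matrix rows, or a 3-layer graph
  convolutional network over the whole-genome contact graph with all-ones
  768-dimensional node features (optionally replaced by regional sequence
  embeddings) — embeds each window's 100-kb contact bin. The concatenated
  embedding feeds one fully connected layer with 919 sigmoid outputs,
  trained with binary cross-entropy plus L1/L2 penalties, Adam, and early
  stopping (patience 4 within 40 epochs). All layers and gradients are
  implemented in base R matrix algebra and verified against
  finite-difference oracles.
- **Kernel interpretation.** First-layer kernels are converted to
  position-specific frequency matrices from their max-activating test
  subsequences and exported in MEME minimal motif format.
- **Variant effect scoring.** Reference/alternate windows give per-event
  probability and log-odds differences; zero-shot pathogenicity scores
  aggregate |Δp|; an L2 logistic regression over Δlog-odds features runs
  chromosome-grouped 5-fold eQTL cross-validation (X and Y share a fold);
  and a weight-tied Siamese classifier (squared differences of the event
  probabilities into a single sigmoid unit, L2 weight 1e-11) implements
  few-shot fine-tuning.
- **A synthetic data generator** that plants sequence motifs, community-
  structured Poisson contact maps with distance decay, labels driven partly
  by motif presence and partly by 3D community membership (mixing
  proportion β, flip noise ε), and substitution variants with known
  effect direction.

## Worked example

```r
library(epifusion)

cfg <- synthetic_config(n_chroms = 2, chrom_length = 30000,
                        window_length = 1000, resolution = 2000,
                        community_assignment = "round_robin",
                        beta = 0.5, n_variants = 0, seed = 1)
ds <- simulate_dataset(cfg)
report <- run_disparity_test(ds$window_seqs, ds$Y, ds$window_bins,
                             ds$matrix, frac = 0.2, repeats = 3,
                             margin = 10, seed = 7)
report
#> Disparity TestReport: 3 repeat(s), frac=0.2, margin=10
#>  repeat_id n_pairs n_under n_consistent n_over      p_under       p_over
#>          1    1072     420          222    430 8.987391e-02 4.940283e-05
#>          2    1064     423          212    429 2.677202e-05 2.937793e-02
#>          3    1028     406          199    423 2.268008e-04 5.905753e-02
#> frequency of p<.05: under 0.6666667, over 0.6666667
```

With half the events driven by contact communities (β = 0.5), window pairs
whose sequence-similarity percentile lags their profile-similarity
percentile (the *under* cell) interact significantly more than consistent
pairs in most repeats — the planted analogue of the chromatin-proximity
effect the disparity test is designed to detect (at full planting, β = 1,
every repeat rejects decisively). At β = 0 the same pipeline rejects at
the nominal 5% rate.

A command-line interface wraps the same functions
(`inst/cli/epifusion simulate|test-disparity|train|evaluate|extract-motifs|
score-variants|eqtl-cv|fewshot-pathogenicity`); every run writes a JSON
manifest with the resolved configuration, input digests and seed.

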