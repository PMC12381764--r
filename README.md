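# subloc

Multi-label prediction of mRNA subcellular localization from RNA
language-model sequence embeddings, via supervised contrastive
representation learning with label-overlap-aware positive mining and a
cross-attention multi-label decoder head.

## Who this is for

Messenger RNAs localize to multiple subcellular compartments at once
(nucleus, cytosol, exosome, ribosome, membrane, ER, ...), so localization
prediction is a multi-label problem whose labels *overlap*: transcripts
sharing two of three compartments are more alike than transcripts sharing
none. `subloc` is for computational biologists who have (or can compute)
per-sequence embeddings — e.g. the 1280-dimensional CLS-token vector of
an RNA language model — together with a per-sequence compartment
annotation table, and want a tested, deterministic implementation of the
two-stage approach:

1. **Supervised contrastive fine-tuning.** An encoder (three residual
   convolution blocks 1→64→128→256 channels, two 8-head self-attention
   layers, adaptive pooling, a 128-d representation and a unit-norm 64-d
   projection) is trained with the supervised contrastive loss

   L = mean over anchors i with P(i) ≠ ∅ of
   (−1/|P(i)|) Σ_{p∈P(i)} log [ exp(z_i·z_p/τ) / Σ_{a≠i} exp(z_i·z_a/τ) ],

   where the positive set P(i) is mined by thresholding the **label
   overlap** — the Jaccard index of the positive-label sets,
   overlap_ij = Σ_n min(y_in, y_jn) / Σ_n max(y_in, y_jn) — at a
   configurable cutoff (default 0.5). Exact-match SupCon is the special
   case threshold = 1.
2. **Frozen-encoder decoding.** The encoder is frozen (checksum-verified)
   and a cross-attention multi-label head — learned per-class queries, no
   query self-attention, linear cost in the class count — is trained with
   binary cross-entropy; calls are thresholded per compartment with a
   top-1 fallback so every transcript gets at least one compartment.

Also included: FASTA + label-table ingestion with the standard
preprocessing filters (non-standard-nucleotide exclusion, 6,000-nt
end-preserving truncation, OR-merge deduplication, 80%-identity
redundancy reduction via CD-HIT-EST or a built-in greedy k-mer
approximation), stratified cross-validation, a label-structured synthetic
data generator, and the full panel of example-based and ranking-based
multi-label metrics with per-compartment Matthews correlation — each
metric backed by a brute-force oracle in the test suite. The neural
components are implemented in plain R with hand-written backpropagation,
validated by finite-difference gradient checks.

## Worked example

Generate a clustered synthetic dataset (a Gaussian mixture keyed to label
*patterns*, standing in for language-model embeddings over an annotated
transcript set), run both stages, and evaluate on the held-out split:

```r
library(subloc)

panel <- label_panel(c("Nucleus", "Cytosol", "Ribosome"))
spec <- synthetic_spec(
  n_samples = 200, d = 32, panel = panel,
  label_patterns = list(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)),
  centroid_separation = 6, noise_sd = 1, seed = 42)
dat <- synth_generate(spec)

run <- run_two_stage(
  dat$records, dat$embeddings,
  encoder_config = encoder_config(in_dim = 32),
  scl_cfg = scl_config(epochs = 10, batch_size = 50, seed = 1),
  seed = 2)

run
#> <two_stage_run> 160 train / 40 eval
#> # A tibble: 1 × 10
#>   aiming recall_coverage jaccard_accuracy subset_accuracy hamming_loss one_error
#>    <dbl>           <dbl>            <dbl>           <dbl>        <dbl>     <dbl>
#> 1      1           0.988            0.988           0.975      0.00833         0

glance(run$scl_fit)
#> # A tibble: 1 × 6
#>   epochs final_loss first_loss final_pos_anchor_frac overlap_threshold
#>    <int>      <dbl>      <dbl>                 <dbl>             <dbl>
#> 1     10       2.30       3.06                     1               0.5

run$metrics$per_class
#> # A tibble: 3 × 6
#>   class       tp    tn    fp    fn   mcc
#>   <chr>    <int> <int> <int> <int> <dbl>
#> 1 Nucleus     24    16     0     0 1
#> 2 Cytosol     30     9     0     1 0.933
#> 3 Ribosome    25    15     0     0 1
```

Reading the numbers: the three label patterns each share one compartment
(pairwise Jaccard overlap 1/3, below the default 0.5 mining threshold),
so Stage 1 organizes three distinct clusters — the contrastive loss falls
from 3.06 to 2.30 and every anchor finds a positive partner
(`final_pos_anchor_frac = 1`). Stage 2 then recovers the held-out label
sets almost exactly: subset accuracy 0.975 (39 of 40 held-out transcripts
get their complete compartment set right), hamming loss 0.008 (about one
wrong compartment call in 120), and per-compartment MCC at or near 1.

`tidy()`, `glance()`, and `autoplot()` methods expose fits, predictions,
and metric reports as tibbles and ggplots; `cross_validate()` runs the
same two-stage procedure over stratified folds. A thin command-line
front end is installed at `system.file("exec", "subloc", package =
"subloc")` with `simulate`, `preprocess`, `train-scl`, `train-decoder`,
`predict`, `evaluate`, and `cv` subcommands.

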