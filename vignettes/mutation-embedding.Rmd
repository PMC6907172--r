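---
title: "Embedding tumor mutation profiles with a multi-modal autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding tumor mutation profiles with a multi-modal autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A tumor's somatic mutation profile — the vector of per-gene mutation counts
called from sequencing — is extremely high-dimensional (tens of thousands of
protein-coding genes) and extremely sparse: most genes are unmutated in most
samples. Distances computed directly in this space are dominated by noise,
which hurts every downstream task that depends on sample similarity:
clustering tumors by type, classifying subtypes, or exploring relations
between cancers. `mutembed` learns a dense, low-dimensional representation
of these profiles with an autoencoder, and ships the machinery needed to
decide whether the learned space is actually better than the raw one.

Variant consequences are split into two modalities that are modelled
separately: *deleterious* mutations (inframe, frameshift, missense, start
lost, stop gained, stop lost) and *non-deleterious* mutations (synonymous,
splice, 5'/3' UTR). Non-deleterious variants are usually discarded early in
driver-hunting pipelines, but they carry real signal for profile comparison,
so they get their own autoencoder branch rather than being merged with or
dropped from the deleterious counts.

## Preprocessing

`build_count_matrices()` turns annotated mutation records into two aligned
samples-by-genes count matrices, `X_de` and `X_nd`. Three rules matter:

* **Support filtering.** A gene is kept only if it is mutated (in either
  modality) in at least `min_support` samples. The conventional threshold of
  50 presumes a cohort of ~10^4 samples; it scales with the cohort, and the
  package errors with a hint rather than silently returning an empty matrix.
  Support is computed on the combined non-zero pattern so both modalities
  keep a single shared gene index.
* **Zero-one normalization.** Each gene is rescaled to [0, 1] per modality.
  The minimum and maximum are fitted on training rows only and reused for
  held-out rows (clipping anything outside the fitted range), so no
  information leaks from the test set. Constant genes map to zero.
* **Stratified splitting.** `make_split()` draws a train/test split of exact
  floor size (80% by default) and 5 cross-validation folds inside train,
  both stratified by subtype so that every class reaches the test set and
  every fold, as far as class sizes permit. Whether the original analysis
  stratified is not documented; without stratification small subtypes can
  vanish from the test set, which would make the per-subtype benchmark
  undefined, so stratification is the default here.

## The model

Each modality has its own encoder and decoder. Per branch, the encoder is

    input (n genes) -> dense 400, sigmoid -> batch normalization
                    -> dense 50, sigmoid   (branch latent)

The two branch latents are merged into the shared latent space `L_tot`. The
merge operator is genuinely underdetermined by the architecture sketch the
model follows: the branch latents are "merged" yet the final space has the
same width as each branch. Concatenation (100 units) followed by a dense
sigmoid projection back to 50 reconciles both statements and is the default
(`merge = "concat"`); element-wise averaging is available as
`merge = "average"` for users who prefer a parameter-free merge. Each branch
then decodes from the shared latent through its own mirror-image decoder
(dense 400, sigmoid; dense n, sigmoid).

The training objective is the mixture-weighted binary cross-entropy

    E_tot = alpha * E_de + (1 - alpha) * E_nd + beta * sum(w^2)

where each branch loss is the mean binary cross-entropy between the
zero-one-normalized input and its sigmoid reconstruction, and the quadratic
penalty runs over *encoding* weights only (both branch encoders and the
merge projection) — the decoder is left unpenalized, as the point of the
penalty is to regularize the representation, not the reconstruction.
Optimization is plain Adam (0.9/0.999 moment decays) on mini-batches.
Sigmoid is used everywhere because the data live in [0, 1] and the loss is
binary cross-entropy; batch normalization is applied after the first
encoder layer's activation, with running statistics used at prediction time
so the forward pass is deterministic.

The forward and backward passes are implemented directly in base R matrix
algebra. At the scales this package targets the dense matrix products are
BLAS-bound and R adds no meaningful overhead, and an explicit
backpropagation implementation is verified in the test suite against
numerical differentiation, which a framework would not make any easier.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `latent_dim` | 50 | width of the shared latent space |
| `hidden_dim` | 400 | encoder/decoder hidden width |
| `alpha` | 0.5 | deleterious branch weight in the joint loss |
| `beta` | 2e-5 | L2 coefficient on encoding weights |
| `learning_rate` | 1e-3 | Adam step size |
| `batch_size` | 128 | mini-batch rows |
| `epochs` | 50 | epoch budget |
| `early_stop_delta` | 1e-4 | minimum per-epoch validation improvement |
| `patience` | 1 | below-threshold epochs tolerated before stopping |

The defaults for `beta` and `learning_rate` are the values selected by
5-fold cross-validation over the grids `L2 = {5e-5, 2e-5, 1e-5}` and
`lr = {0.005, 0.0025, 0.001}` in the original full-scale analysis;
`tune_hyperparameters()` reruns that search on any cohort (grid points whose
training diverges are disqualified rather than aborting the search). The
early-stopping threshold is not documented anywhere authoritative; 1e-4 on
the validation loss is the package's choice. On small cohorts an "epoch" is
only a handful of gradient steps and single-epoch fluctuations dominate, so
a `patience` of 3–5 (or `early_stop_delta = -Inf` to disable stopping) is
recommended there, along with a batch size of 16–32 so the optimizer still
takes enough steps; the full-data defaults assume ~10^4 samples.

### Choosing the mixture weight

`select_alpha()` implements model selection for `alpha` by an external
quality criterion rather than the loss (whose scale changes with `alpha`
itself): for each candidate weight it trains on train-minus-fold rows,
embeds the held-out fold, clusters the embedding hierarchically into one
cluster per tumor type, and scores the clustering against the true type
labels by normalized mutual information. The weight with the highest
fold-mean MI wins. When only one modality carries signal this search moves
decisively toward the informative branch; with symmetric signal it settles
mid-grid.

## Scoring a representation

Two label-aware scores and one label-free diagnostic are used.

**Kernel target alignment (KTA).** For a representation `X` with labels
`y`, the Gaussian kernel `K[i,j] = exp(-||x_i - x_j||^2 / (2 sigma^2))` is
compared with the ideal target kernel (`+1` same label, `-1` otherwise) by
the normalized Frobenius inner product. KTA is scale-sensitive through
`sigma`, so `tune_sigma()` maximizes it over a log-spaced grid (0.1–100 by
default, 20 points) and comparisons between spaces always use each space's
own maximum — using a single bandwidth for spaces with different diameters
would bias the comparison toward whichever space the bandwidth happens to
suit. With the ±1 target the alignment of an uninformative kernel is
negative (most pairs are cross-class), so negative values are reported
as-is rather than clamped.

**Clustering mutual information.** Each space is clustered by agglomerative
hierarchical clustering (Ward criterion on Euclidean distances — stable on
dense low-dimensional embeddings; the linkage is not documented in the
original description) and scored against the type labels by plug-in mutual
information from the contingency table, in nats. The raw MI is unbounded
above, which contradicts the claimed (0, 1) range of the score unless it is
normalized; `mutual_information()` therefore reports MI normalized by the
arithmetic mean of the two marginal entropies (1 for identical partitions,
0 for independence) and attaches the raw value, so both conventions are
available.

**Reconstruction loss curves.** Training and validation loss per epoch are
kept in the fit's `history` and plotted by `plot()`; convergence of both
curves is the first sanity check that the bottleneck has actually learned
the data rather than memorized or collapsed.

## Subtype classification

With 40-odd imbalanced subtypes, one-vs-rest binary classifiers are a poor
fit; instead a one-class ν-SVM (Gaussian kernel) is trained per subtype on
that subtype's training samples only, and its continuous decision score
ranks held-out samples by membership. AUC-ROC on the common test set
(positives = the subtype's test samples) summarizes each classifier, and
`benchmark_spaces()` repeats the exercise in the latent space and both
input spaces, using each space's KTA-tuned bandwidth and ν = 0.1 (neither
is documented in the original description; ν = 0.1 tolerates a 10% outlier
fraction in the training class, a conventional default). The table's
summary line counts subtypes where the latent AUC strictly exceeds both
input AUCs.

## The synthetic cohort generator

Real pan-cancer mutation data are access-controlled, so `simulate_cohort()`
generates cohorts with the statistical shape the pipeline assumes: nested
type/subtype labels, two modalities, and sparse non-negative counts. Each
cell draws `Binomial(2, p)` — the sum of two Bernoulli trials, which allows
counts above 1 (real samples do hit the same gene twice) while keeping every
marginal expectation analytic for tests. `p` is `marker_rate` on the
sample's own subtype markers (in the modality carrying signal) and
`background_rate` elsewhere. Marker sets of distinct subtypes are disjoint,
and one global seed drives per-subtype derived streams, so cohorts are
reproducible record-for-record.

A configurable fraction of subtypes (10% by default) is designated *noise*:
they have no subtype-level marker set, emulating the real subtypes that no
space classifies better than chance. Naively giving these subtypes
background-only profiles fails its purpose — they become trivially
identifiable as the only low-mutation-burden class. Instead each noise
sample elevates its own random draw from the other subtypes' marker genes:
the burden matches the signal subtypes exactly, but there is no consistent
pattern, so one-class AUC for noise subtypes honestly hovers near 0.5.

What the generator does *not* emulate: mutational signatures (trinucleotide
context), gene length and expression covariates of mutation rate,
inter-sample burden variation (hypermutators), co-occurrence and mutual
exclusivity between drivers, and any correlation structure between the two
modalities beyond shared markers. Passing tests on synthetic cohorts
therefore demonstrates that the pipeline recovers planted structure of this
simple kind — not that it would rank spaces identically on real tumors.

## Numerical choices and degenerate inputs

* Reconstructions are clamped to [1e-7, 1 - 1e-7] inside the cross-entropy
  so that saturated sigmoids cannot produce infinite loss; batch
  normalization adds 1e-5 to the batch variance.
* Training errors out (naming the epoch) if the loss becomes non-finite;
  inside grid searches the same event disqualifies the grid point instead.
* Constant genes normalize to zero; an all-unknown consequence table and an
  empty post-filter gene set are errors with actionable messages.
* Identical partitions are detected structurally in `mutual_information()`
  (one non-zero cell per contingency row and column) and score exactly 1.
* AUC uses average ranks, i.e. tied scores get half credit.
* Weight matrices initialize Glorot-uniform; batch shuffling and
  initialization both derive from the fit's single `seed`.

## Scale of the bundled studies

The test suite and the acceptance script exercise the full pipeline on
cohorts of roughly 300–480 samples and 300–400 genes (8 types × 60 samples
for the embedding-quality study; 6 types × 50 for the mixture-weight
recovery), with the full-size 400-unit/50-latent network, batch size 16 and
up to 50 epochs. These studies use one subtype per type: the generator
plants signal only at the subtype level (disjoint marker sets), so with
several subtypes per type the clustering target at k = number of types is
an arbitrary union of subtype clusters in *every* space and measures label
aggregation rather than embedding quality. Collapsing the hierarchy makes
tumor type the unit of clustering, classification and weight selection
alike. These sizes keep every planted effect detectable while a
complete run stays in the minutes range on one CPU; the same code paths
scale to ~10^4 × ~10^4 inputs unchanged, where the gene-support filter's
default threshold (50) and the default batch size (128) become appropriate.

## Limitations

* The merge operator and the one-class hyperparameters are design choices
  where the original description is silent; both are exposed as arguments.
* KTA and the kernel classifiers are O(m^2) in samples; `tune_sigma()`
  offers seeded subsampling for very large cohorts.
* The latent geometry depends on training length: under-trained encoders
  produce collapsed, near-constant latents whose clustering quality is
  poor even when a non-linear classifier can still find signal in them.
  Monitor the loss curves and the KTA/MI diagnostics together.
* t-SNE is not bundled; the report's 2-d scatter of the latent space uses
  principal components instead.
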