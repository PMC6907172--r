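# mutembed

Multi-modal autoencoder embeddings of tumor somatic mutation profiles, with
the evaluation machinery to decide whether the learned space beats the raw
one.

## What problem this solves

A tumor sample's mutational profile — per-gene somatic mutation counts —
lives in a space of >10⁴ genes and is almost entirely zeros. Distances in
that space are noise-dominated, which degrades clustering, subtype
classification, and any exploration built on sample similarity. `mutembed`
compresses paired mutation-count matrices into a dense latent space of
(by default) 50 dimensions and quantifies, on held-out samples, whether the
compression preserved and cleaned the biological signal. It is aimed at
cancer-genomics analysts who have gene-level, consequence-annotated somatic
mutation calls (MAF-like tables) and want a reusable low-dimensional
representation of their cohort.

## The model

Variant consequences are split into two modalities: **deleterious**
(inframe, frameshift, missense, start lost, stop gained/lost) and
**non-deleterious** (synonymous, splice, UTR) counts, giving aligned
matrices `X_de` and `X_nd`. Each modality gets its own encoder/decoder
branch:

    x_m ∈ [0,1]^n  →  dense 400 (σ) → batchnorm → dense 50 (σ)  = branch latent
    [z_de ; z_nd]  →  dense 50 (σ)                              = shared latent L_tot
    L_tot          →  dense 400 (σ) → dense n (σ)               = x̃_m  (per branch)

trained by Adam on the mixture-weighted objective

    E_tot = α·E_de + (1−α)·E_nd + β·Σ‖w‖²   (encoding weights only),

where each `E_m` is the mean binary cross-entropy of that branch's
reconstruction. The embedding is scored by:

* **Kernel target alignment** — alignment `⟨K, K_yy⟩_F / (‖K‖_F ‖K_yy‖_F)`
  between the Gaussian kernel of a space (bandwidth σ tuned per space) and
  the ideal ±1 label kernel;
* **Clustering mutual information** — Ward hierarchical clustering at
  k = number of tumor types, scored by normalized MI against the true
  labels;
* **Per-subtype one-class ν-SVM classification** — one Gaussian-kernel
  one-class model per subtype, trained only on that subtype, benchmarked by
  test-set AUC-ROC in the latent space and both input spaces.

## Worked example

Simulate a cohort with subtype-specific marker genes, run the full
pipeline, and compare spaces:

```r
library(mutembed)

spec <- cohort_spec(n_types = 6, subtypes_per_type = 1,
                    samples_per_subtype = 50, n_genes = 300,
                    background_rate = 0.01, marker_rate = 0.3,
                    marker_genes_per_subtype = 12,
                    signal_modality = "both",
                    noise_subtype_fraction = 0, seed = 7)
cfg <- pipeline_config(spec, min_support = 8, latent_dim = 50,
                       hidden_dim = 400, epochs = 50, batch_size = 16,
                       early_stop_delta = 1e-5, patience = 5, seed = 7)
report <- run_pipeline(cfg)
print(report)
```

```
Mutation-embedding evaluation report
  300 samples x 286 genes -> latent 50 (compression ratio 5); seed 7
  alpha = 0.50; epochs run = 50
  KTA (tuned sigma): latent 0.3822, de 0.1291, nd 0.1291
  MI at k=6: latent 0.9693, de 0.9073, nd 0.6144
  latent AUC beats both input spaces in 6 of 6 subtypes
```

Reading the numbers: the latent space's kernel aligns with the ideal
type-label kernel three times better than either raw modality (0.38 vs
0.13); hierarchical clustering of the latent coordinates recovers the six
tumor types almost perfectly (normalized MI 0.97 vs 0.91/0.61); and every
subtype's one-class classifier ranks held-out members higher in the latent
space than in either input space. `report$auc` holds the per-subtype table
(primary site, subtype, test count, AUC per space), `report$history` the
loss curves, and `plot_report(report, "figures")` renders loss, KTA-vs-σ,
MI-vs-k and a PCA scatter of the latent space.

Individual stages are exported too: `build_count_matrices()`,
`filter_genes()`, `normalize_zero_one()`, `make_split()`, `mmae()` (the
fitting function, with `predict`/`summary`/`plot`/`residuals` methods),
`encode()`, `tune_sigma()`, `kta()`, `mutual_information()`,
`benchmark_spaces()`, `select_alpha()`, `tune_hyperparameters()`. A thin
CLI lives at `inst/cli/mutembed`:

```sh
Rscript inst/cli/mutembed --config cohort.yaml --seed 1 --outdir out
```

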