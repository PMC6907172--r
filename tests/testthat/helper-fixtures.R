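# Small in-code fixtures shared across test files.

# Default small structured cohort: 4 types x 1 subtype, clear markers.
small_cohort_spec <- function(seed = 42, ...) {
  args <- list(n_types = 4, subtypes_per_type = 1, samples_per_subtype = 30,
               n_genes = 120, background_rate = 0.02, marker_rate = 0.4,
               marker_genes_per_subtype = 8, signal_modality = "both",
               noise_subtype_fraction = 0, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# A normalized pair + split ready for training.
small_training_setup <- function(seed = 42, min_support = 5, ...) {
  co <- simulate_cohort(small_cohort_spec(seed = seed, ...))
  pair <- build_count_matrices(co$records)
  pair <- filter_genes(pair, min_support = min_support)
  split <- make_split(length(pair$sample_ids), 0.8, n_folds = 5,
                      seed = seed, strata = pair$y_subtype)
  pair <- normalize_zero_one(pair, split$train_idx)
  list(cohort = co, pair = pair, split = split)
}

# Deterministic toy records table.
toy_records <- function() {
  data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
    gene = c("g1", "g1", "g2", "g1", "g3", "g2"),
    tumor_type = c("A", "A", "A", "A", "A", "B"),
    tumor_subtype = c("A.1", "A.1", "A.1", "A.2", "A.2", "B.1"),
    consequence = c("Missense", "Stop Gained", "Synonimous", "UTR 3 prime",
                    "Frameshift", "Splice"),
    stringsAsFactors = FALSE
  )
}

# Gaussian blob matrix: k well-separated clouds in p dimensions.
blob_matrix <- function(n_per = 20, k = 2, p = 3, sep = 10, sd = 0.5,
                        seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * p), k, p) * 0 +
    sep * matrix(seq_len(k), k, p)
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * p, sd = sd), n_per, p) +
      matrix(centers[i, ], n_per, p, byrow = TRUE)))
  list(x = X, labels = rep(seq_len(k), each = n_per))
}
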