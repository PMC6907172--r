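test_that("cohort_spec validates its fields with informative errors", {
  expect_error(cohort_spec(background_rate = -0.1), "background_rate")
  expect_error(cohort_spec(background_rate = 0.5, marker_rate = 0.2),
               "marker_rate")
  expect_error(cohort_spec(n_genes = 10, marker_genes_per_subtype = 50),
               "disjoint")
  expect_error(cohort_spec(noise_subtype_fraction = 1.5),
               "noise_subtype_fraction")
})

test_that("degenerate rates give deterministic limiting cohorts", {
  # all-zero rates: no mutation events at all
  spec0 <- cohort_spec(n_types = 2, subtypes_per_type = 2,
                       samples_per_subtype = 5, n_genes = 30,
                       background_rate = 0, marker_rate = 0,
                       marker_genes_per_subtype = 0,
                       noise_subtype_fraction = 0, seed = 1)
  expect_equal(nrow(simulate_cohort(spec0)$records), 0L)

  # marker_rate 1, background 0, deleterious-only: every sample mutates
  # exactly its subtype's markers, always with count 2, only deleterious
  spec1 <- cohort_spec(n_types = 2, subtypes_per_type = 1,
                       samples_per_subtype = 4, n_genes = 40,
                       background_rate = 0, marker_rate = 1,
                       marker_genes_per_subtype = 5,
                       signal_modality = "deleterious_only",
                       noise_subtype_fraction = 0, seed = 1)
  co <- simulate_cohort(spec1)
  expect_true(all(classify_consequence(co$records$consequence) ==
                    "deleterious"))
  pair <- build_count_matrices(co$records)
  for (st in names(co$truth)) {
    rows <- which(pair$y_subtype == st)
    on_markers <- pair$x_de[rows, intersect(co$truth[[st]], pair$genes),
                            drop = FALSE]
    expect_true(all(on_markers == 2))
    off <- setdiff(pair$genes, co$truth[[st]])
    expect_true(all(pair$x_de[rows, off] == 0))
  }
  expect_true(all(pair$x_nd == 0))
})

test_that("same seed reproduces the cohort byte-identically", {
  spec <- small_cohort_spec(seed = 9)
  expect_identical(simulate_cohort(spec), simulate_cohort(spec))
})

test_that("marker gene sets of distinct subtypes are disjoint", {
  co <- simulate_cohort(cohort_spec(n_types = 5, subtypes_per_type = 2,
                                    samples_per_subtype = 3, n_genes = 500,
                                    marker_genes_per_subtype = 20,
                                    noise_subtype_fraction = 0.1, seed = 2))
  all_markers <- unlist(co$truth)
  expect_equal(anyDuplicated(all_markers), 0L)
})

test_that("empirical mutation frequencies match the binomial model", {
  # marker cells: count ~ Binomial(2, p); mean per-trial frequency must sit
  # within 3 binomial standard errors of the marker rate
  p_marker <- 0.4
  p_bg <- 0.01
  spec <- cohort_spec(n_types = 4, subtypes_per_type = 1,
                      samples_per_subtype = 50, n_genes = 200,
                      background_rate = p_bg, marker_rate = p_marker,
                      marker_genes_per_subtype = 10,
                      signal_modality = "both",
                      noise_subtype_fraction = 0, seed = 123)
  co <- simulate_cohort(spec)
  pair <- build_count_matrices(co$records)
  pair$x_de <- pair$x_de  # counts, unnormalized
  for (st in names(co$truth)) {
    rows <- which(pair$y_subtype == st)
    cols <- intersect(co$truth[[st]], pair$genes)
    cells <- 2 * length(rows) * length(cols)  # two trials per cell
    phat <- sum(pair$x_de[rows, cols]) / cells
    se <- sqrt(p_marker * (1 - p_marker) / cells)
    expect_lt(abs(phat - p_marker), 3 * se)
  }
  # background cells across all samples
  bg_genes <- setdiff(pair$genes, unlist(co$truth))
  cells <- 2 * nrow(pair$x_de) * length(bg_genes)
  phat_bg <- sum(pair$x_de[, bg_genes]) / cells
  se_bg <- sqrt(p_bg * (1 - p_bg) / cells)
  expect_lt(abs(phat_bg - p_bg), 3 * se_bg)
})

test_that("noise subtypes match signal subtypes in expected burden", {
  spec <- cohort_spec(n_types = 8, subtypes_per_type = 1,
                      samples_per_subtype = 40, n_genes = 300,
                      background_rate = 0.01, marker_rate = 0.3,
                      marker_genes_per_subtype = 12,
                      noise_subtype_fraction = 0.25, seed = 77)
  co <- simulate_cohort(spec)
  expect_length(co$noise_subtypes, 2L)
  burden <- table(co$records$tumor_subtype) /
    table(co$samples$tumor_subtype)[names(table(co$records$tumor_subtype))]
  noise_burden <- mean(burden[co$noise_subtypes])
  signal_burden <- mean(burden[setdiff(names(burden), co$noise_subtypes)])
  expect_lt(abs(noise_burden - signal_burden) / signal_burden, 0.1)
})

test_that("MAF round-trip preserves records", {
  co <- simulate_cohort(small_cohort_spec(seed = 4))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_maf(co$records, tmp)
  back <- read_maf(tmp)
  expect_equal(back, co$records)
})

test_that("truth map serializes to JSON and reads back", {
  co <- simulate_cohort(small_cohort_spec(seed = 4))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_truth(co, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back[order(names(back))],
               lapply(co$truth, as.character)[order(names(co$truth))])
})
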