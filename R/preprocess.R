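#' Classify a variant consequence term by modality
#'
#' Maps annotated consequence terms to the deleterious / non-deleterious
#' dichotomy used to split the count matrices. Protein-disrupting terms
#' (inframe, frameshift, missense, start lost, stop gained, stop lost) are
#' deleterious; synonymous, splice and 5'/3' UTR terms are non-deleterious;
#' anything else is `"unknown"`. Matching ignores case and separators, and
#' both the "synonimous" and "synonymous" spellings are accepted.
#'
#' @param term Character vector of consequence terms.
#' @return Character vector with values in
#'   `c("deleterious", "non_deleterious", "unknown")`.
#' @examples
#' classify_consequence(c("Missense", "UTR 3 prime", "intergenic"))
#' @export
classify_consequence <- function(term) {
  if (!is.character(term) && !is.factor(term))
    stop("'term' must be character", call. = FALSE)
  key <- gsub("[^a-z0-9]", "", tolower(as.character(term)))
  del <- gsub("[^a-z0-9]", "", tolower(DELETERIOUS_TERMS))
  nondel <- c(gsub("[^a-z0-9]", "", tolower(NON_DELETERIOUS_TERMS)),
              "synonymous")
  out <- rep("unknown", length(key))
  out[key %in% del] <- "deleterious"
  out[key %in% nondel] <- "non_deleterious"
  out[!nzchar(key)] <- "unknown"
  out
}

#' Build paired deleterious / non-deleterious count matrices
#'
#' Aggregates annotated mutation records into two aligned samples-by-genes
#' integer count matrices, one per modality; cell (i, j) holds the number of
#' records of that modality for sample i in gene j. Records whose consequence
#' classifies as `"unknown"` are dropped with a message. Rows and columns are
#' ordered lexicographically so the result is deterministic.
#'
#' @param records Mutation-record data.frame with columns `sample_id`,
#'   `gene`, `tumor_type`, `tumor_subtype`, `consequence`.
#' @return A `"mutation_matrix_pair"`: list with dense matrices `x_de`,
#'   `x_nd` (shared dimnames), `sample_ids`, `genes`, and per-sample label
#'   vectors `y_type`, `y_subtype`. The number of dropped unknown records is
#'   attached as attribute `"n_unknown_dropped"`.
#' @export
build_count_matrices <- function(records) {
  req <- c("sample_id", "gene", "tumor_type", "tumor_subtype", "consequence")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("records are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L)
    stop("no mutation records supplied", call. = FALSE)

  modality <- classify_consequence(records$consequence)
  n_unknown <- sum(modality == "unknown")
  keep <- modality != "unknown"
  if (!any(keep))
    stop("all records have unknown consequence terms; nothing to tabulate",
         call. = FALSE)
  if (n_unknown > 0L)
    message(sprintf("dropping %d record(s) with unknown consequence terms",
                    n_unknown))
  records <- records[keep, , drop = FALSE]
  modality <- modality[keep]

  sample_ids <- sort(unique(records$sample_id))
  genes <- sort(unique(records$gene))
  sf <- factor(records$sample_id, levels = sample_ids)
  gf <- factor(records$gene, levels = genes)

  count_one <- function(mask) {
    tab <- table(sf[mask], gf[mask])
    m <- matrix(as.numeric(tab), nrow = length(sample_ids),
                dimnames = list(sample_ids, genes))
    m
  }
  x_de <- count_one(modality == "deleterious")
  x_nd <- count_one(modality == "non_deleterious")

  lab <- unique(records[, c("sample_id", "tumor_type", "tumor_subtype")])
  if (anyDuplicated(lab$sample_id))
    stop("inconsistent tumor_type/tumor_subtype labels within a sample",
         call. = FALSE)
  lab <- lab[match(sample_ids, lab$sample_id), ]

  pair <- structure(
    list(x_de = x_de, x_nd = x_nd,
         sample_ids = sample_ids, genes = genes,
         y_type = lab$tumor_type, y_subtype = lab$tumor_subtype,
         normalized = FALSE),
    class = "mutation_matrix_pair"
  )
  attr(pair, "n_unknown_dropped") <- n_unknown
  pair
}

#' Construct a mutation matrix pair from existing matrices
#'
#' Low-level constructor used by the simulator-free code paths and by tests.
#'
#' @param x_de,x_nd Numeric samples-by-genes matrices of equal shape.
#' @param y_type,y_subtype Per-sample label vectors (optional).
#' @param normalized Logical flag: are entries already in `[0, 1]`?
#' @return A `"mutation_matrix_pair"`.
#' @export
matrix_pair <- function(x_de, x_nd, y_type = NULL, y_subtype = NULL,
                        normalized = FALSE) {
  if (!all(dim(x_de) == dim(x_nd)))
    stop("x_de and x_nd must have identical dimensions", call. = FALSE)
  if (is.null(rownames(x_de)))
    rownames(x_de) <- rownames(x_nd) <- sprintf("s%04d", seq_len(nrow(x_de)))
  if (is.null(colnames(x_de)))
    colnames(x_de) <- colnames(x_nd) <- sprintf("g%04d", seq_len(ncol(x_de)))
  structure(
    list(x_de = x_de, x_nd = x_nd,
         sample_ids = rownames(x_de), genes = colnames(x_de),
         y_type = y_type, y_subtype = y_subtype,
         normalized = normalized),
    class = "mutation_matrix_pair"
  )
}

#' @export
print.mutation_matrix_pair <- function(x, ...) {
  nz <- mean((x$x_de + x$x_nd) != 0)
  cat(sprintf("Mutation matrix pair: %d samples x %d genes (%s), %.2f%% cells non-zero\n",
              length(x$sample_ids), length(x$genes),
              if (isTRUE(x$normalized)) "zero-one normalized" else "raw counts",
              100 * nz))
  if (!is.null(x$y_type))
    cat(sprintf("  labels: %d tumor types / %d subtypes\n",
                length(unique(x$y_type)), length(unique(x$y_subtype))))
  invisible(x)
}

#' Filter genes by cohort-wide mutation support
#'
#' Keeps a gene only if the number of samples carrying at least one mutation
#' in it — counting both modalities together — reaches `min_support`. Both
#' matrices are restricted to the same kept-gene set, preserving order, so
#' the pair keeps a single shared gene index.
#'
#' @param pair A `"mutation_matrix_pair"`.
#' @param min_support Minimum number of supporting samples (default 50, the
#'   conventional threshold for cohorts of ~10^4 samples; scale it down for
#'   small cohorts).
#' @return The filtered pair. Idempotent.
#' @export
filter_genes <- function(pair, min_support = 50) {
  stopifnot(inherits(pair, "mutation_matrix_pair"))
  if (min_support < 1) stop("min_support must be >= 1", call. = FALSE)
  support <- colSums((pair$x_de + pair$x_nd) > 0)
  keep <- support >= min_support
  if (!any(keep))
    stop(sprintf(paste0("no gene is mutated in at least %d samples; ",
                        "consider a lower min_support"), min_support),
         call. = FALSE)
  pair$x_de <- pair$x_de[, keep, drop = FALSE]
  pair$x_nd <- pair$x_nd[, keep, drop = FALSE]
  pair$genes <- pair$genes[keep]
  pair
}

#' Zero-one normalize each gene within each modality
#'
#' Rescales every gene column to `[0, 1]` by `(x - min) / (max - min)`, with
#' the minimum and maximum computed over `fit_rows` only (typically the
#' training rows, so no information leaks from held-out samples). Constant
#' genes map to all zeros; values on non-fit rows falling outside the fitted
#' range are clipped into `[0, 1]`. Applying the transform twice with the
#' same `fit_rows` is the identity.
#'
#' @param pair A `"mutation_matrix_pair"`.
#' @param fit_rows Integer row indices over which to fit the ranges
#'   (default: all rows).
#' @return The normalized pair, with `normalized = TRUE` and the fitted
#'   ranges stored in `pair$norm_ranges`.
#' @export
normalize_zero_one <- function(pair, fit_rows = seq_along(pair$sample_ids)) {
  stopifnot(inherits(pair, "mutation_matrix_pair"))
  if (length(fit_rows) == 0L) stop("fit_rows must be non-empty", call. = FALSE)
  norm_one <- function(x) {
    lo <- apply(x[fit_rows, , drop = FALSE], 2L, min)
    hi <- apply(x[fit_rows, , drop = FALSE], 2L, max)
    rng <- hi - lo
    scaled <- sweep(x, 2L, lo, "-")
    nonconst <- rng > 0
    scaled[, nonconst] <- sweep(scaled[, nonconst, drop = FALSE], 2L,
                                rng[nonconst], "/")
    scaled[, !nonconst] <- 0
    scaled[scaled < 0] <- 0
    scaled[scaled > 1] <- 1
    list(x = scaled, lo = lo, hi = hi)
  }
  de <- norm_one(pair$x_de)
  nd <- norm_one(pair$x_nd)
  pair$x_de <- de$x
  pair$x_nd <- nd$x
  pair$normalized <- TRUE
  pair$norm_ranges <- list(de = list(lo = de$lo, hi = de$hi),
                           nd = list(lo = nd$lo, hi = nd$hi))
  pair
}

#' Subset a mutation matrix pair by rows
#'
#' @param pair A `"mutation_matrix_pair"`.
#' @param rows Integer row indices to keep.
#' @return The row-subset pair.
#' @export
subset_rows <- function(pair, rows) {
  stopifnot(inherits(pair, "mutation_matrix_pair"))
  pair$x_de <- pair$x_de[rows, , drop = FALSE]
  pair$x_nd <- pair$x_nd[rows, , drop = FALSE]
  pair$sample_ids <- pair$sample_ids[rows]
  if (!is.null(pair$y_type)) pair$y_type <- pair$y_type[rows]
  if (!is.null(pair$y_subtype)) pair$y_subtype <- pair$y_subtype[rows]
  pair
}

#' Stratified train/test split with cross-validation folds
#'
#' Partitions `n_samples` rows into a training set of exactly
#' `floor(train_fraction * n_samples)` rows and a test set, then divides the
#' training rows into `n_folds` disjoint folds. When per-sample strata (e.g.
#' subtype labels) are supplied, both the split and the folds are stratified
#' so every class is represented in test and across folds as far as class
#' sizes permit; overall sizes are kept exact by largest-remainder
#' allocation. Deterministic given `seed`.
#'
#' @param n_samples Total number of rows.
#' @param train_fraction Fraction of rows assigned to training (default 0.8).
#' @param n_folds Number of cross-validation folds within train (default 5).
#' @param seed Integer seed.
#' @param strata Optional per-sample vector of class labels of length
#'   `n_samples`.
#' @return A `"split_plan"`: list with `train_idx`, `test_idx`, `folds`
#'   (list of `n_folds` integer vectors partitioning `train_idx`), `seed`.
#' @examples
#' sp <- make_split(10, 0.8, n_folds = 2, seed = 1)
#' length(sp$train_idx)  # 8
#' @export
make_split <- function(n_samples, train_fraction = 0.8, n_folds = 5,
                       seed = 1L, strata = NULL) {
  if (n_samples < n_folds)
    stop("n_samples must be at least n_folds", call. = FALSE)
  n_train <- floor(train_fraction * n_samples)
  if (n_folds > n_train)
    stop("n_folds exceeds the number of training samples", call. = FALSE)
  if (is.null(strata)) strata <- rep(1L, n_samples)
  if (length(strata) != n_samples)
    stop("strata must have length n_samples", call. = FALSE)

  set.seed(seed)
  groups <- split(seq_len(n_samples), strata)
  ## largest-remainder allocation of the exact train size across strata
  exact <- vapply(groups, length, 1L) * train_fraction
  base <- pmin(floor(exact), vapply(groups, length, 1L))
  rem <- n_train - sum(base)
  if (rem > 0) {
    frac <- exact - floor(exact)
    room <- vapply(groups, length, 1L) - base
    ord <- order(frac, decreasing = TRUE)
    for (g in ord) {
      if (rem == 0) break
      if (room[g] > 0) {
        base[g] <- base[g] + 1L
        rem <- rem - 1L
      }
    }
    ## fall back to any remaining room if fractional parts were exhausted
    while (rem > 0) {
      g <- which(vapply(groups, length, 1L) - base > 0)[1L]
      base[g] <- base[g] + 1L
      rem <- rem - 1L
    }
  }
  train_idx <- integer(0)
  for (g in seq_along(groups)) {
    shuffled <- sample(groups[[g]])
    train_idx <- c(train_idx, shuffled[seq_len(base[g])])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_samples), train_idx)

  ## stratified folds: deal each stratum's (shuffled) train rows round-robin
  fold_of <- integer(n_samples)
  offset <- 0L
  for (g in seq_along(groups)) {
    rows <- intersect(sample(groups[[g]]), train_idx)
    if (length(rows))
      fold_of[rows] <- ((seq_along(rows) - 1L + offset) %% n_folds) + 1L
    offset <- offset + length(rows)
  }
  folds <- lapply(seq_len(n_folds), function(f) sort(which(fold_of == f)))

  structure(list(train_idx = train_idx, test_idx = sort(test_idx),
                 folds = folds, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan: %d train / %d test, %d folds (seed %d)\n",
              length(x$train_idx), length(x$test_idx), length(x$folds),
              x$seed))
  invisible(x)
}

#' Integer compression ratio of an embedding
#'
#' Ratio between the input dimensionality and the latent dimensionality,
#' floored to an integer (12424 genes into 50 latent dimensions compress
#' 248-fold).
#'
#' @param input_dim Number of input features.
#' @param latent_dim Latent dimensionality.
#' @return Integer ratio `floor(input_dim / latent_dim)`.
#' @export
compression_ratio <- function(input_dim, latent_dim) {
  if (latent_dim <= 0 || input_dim <= 0)
    stop("dimensions must be positive", call. = FALSE)
  as.integer(input_dim %/% latent_dim)
}
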