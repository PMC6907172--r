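#' Cross-validated selection of L2 penalty and learning rate
#'
#' Trains the autoencoder on each (L2, learning-rate) grid point, fold by
#' fold, and scores the held-out fold by mean reconstruction binary
#' cross-entropy (`alpha`-weighted, no penalty term). Returns the argmin
#' grid point and the full fold-mean table. Grid points whose training
#' diverges (non-finite loss) are disqualified rather than aborting the
#' search.
#'
#' @param pair A normalized `"mutation_matrix_pair"`.
#' @param split A `"split_plan"`; its folds drive the cross-validation.
#' @param l2_grid,lr_grid Candidate L2 coefficients and learning rates.
#' @param n_folds_used How many of the split's folds to run per grid point
#'   (all by default; fewer for a cheaper search).
#' @param ... Further arguments to [mmae()] (e.g. `epochs`, `hidden_dim`).
#' @return List with `best` (named list `l2`, `lr`), and `table`
#'   (data.frame `l2`, `lr`, `val_bce`).
#' @export
tune_hyperparameters <- function(pair, split,
                                 l2_grid = c(5e-5, 2e-5, 1e-5),
                                 lr_grid = c(0.005, 0.0025, 0.001),
                                 n_folds_used = length(split$folds), ...) {
  stopifnot(inherits(pair, "mutation_matrix_pair"),
            inherits(split, "split_plan"))
  folds <- split$folds[seq_len(min(n_folds_used, length(split$folds)))]
  grid <- expand.grid(l2 = l2_grid, lr = lr_grid)
  grid$val_bce <- vapply(seq_len(nrow(grid)), function(i) {
    scores <- vapply(folds, function(fold) {
      cv_score_fold(pair, split, fold, beta = grid$l2[i],
                    learning_rate = grid$lr[i], ...)
    }, 0)
    if (all(is.na(scores))) NA_real_ else mean(scores, na.rm = TRUE)
  }, 0)
  if (all(is.na(grid$val_bce)))
    stop("every grid point diverged", call. = FALSE)
  best <- which.min(grid$val_bce)  # NAs never win
  list(best = list(l2 = grid$l2[best], lr = grid$lr[best]), table = grid)
}

## Restrict the pair to (train-minus-fold, fold) rows so test rows never
## enter a tuning fit; returns the subset pair and the fold's positions.
fold_view <- function(pair, split, fold) {
  tr <- setdiff(split$train_idx, fold)
  sub <- subset_rows(pair, c(tr, fold))
  list(pair = sub, val = length(tr) + seq_along(fold))
}

## Train on train-minus-fold, return alpha-weighted validation BCE
## (reconstruction only), or NA if training diverges.
cv_score_fold <- function(pair, split, fold, alpha = 0.5, ...) {
  fv <- fold_view(pair, split, fold)
  fit <- tryCatch(
    mmae(fv$pair, val_rows = fv$val, alpha = alpha, ...),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NA_real_)
  sub <- subset_rows(fv$pair, fv$val)
  xh <- predict(fit, sub, type = "response")
  alpha * bce_mean(sub$x_de, xh$de) + (1 - alpha) * bce_mean(sub$x_nd, xh$nd)
}

#' Select the mixture weight by clustering mutual information
#'
#' For each candidate `alpha`, trains the autoencoder with that mixture
#' weight (fold by fold), embeds the held-out fold, clusters the latent
#' coordinates hierarchically into `k` clusters and scores the clustering
#' against the tumor-type labels by normalized mutual information. The
#' returned `alpha` maximizes the fold-mean MI: when only one modality
#' carries signal the search moves toward the weight favouring that branch,
#' and with symmetric signal it settles mid-grid.
#'
#' @param pair A normalized `"mutation_matrix_pair"` with `y_type` labels.
#' @param split A `"split_plan"`.
#' @param alpha_grid Candidate mixture weights (default the standard
#'   five-point grid 0.1-0.9).
#' @param k Number of clusters (default: the number of tumor types).
#' @param n_folds_used Folds run per alpha (all by default).
#' @param ... Further arguments to [mmae()].
#' @return List with `best_alpha` and `table` (data.frame `alpha`,
#'   `mean_mi`).
#' @export
select_alpha <- function(pair, split, alpha_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         k = length(unique(pair$y_type)),
                         n_folds_used = length(split$folds), ...) {
  stopifnot(inherits(pair, "mutation_matrix_pair"),
            inherits(split, "split_plan"))
  if (is.null(pair$y_type))
    stop("pair must carry tumor-type labels", call. = FALSE)
  if (length(alpha_grid) == 0L)
    stop("alpha grid must be non-empty", call. = FALSE)
  folds <- split$folds[seq_len(min(n_folds_used, length(split$folds)))]
  tab <- data.frame(alpha = alpha_grid, mean_mi = NA_real_)
  for (i in seq_along(alpha_grid)) {
    mis <- vapply(folds, function(fold) {
      fv <- fold_view(pair, split, fold)
      fit <- tryCatch(
        mmae(fv$pair, val_rows = fv$val, alpha = alpha_grid[i], ...),
        error = function(e) NULL
      )
      if (is.null(fit)) return(NA_real_)
      z <- predict(fit, subset_rows(fv$pair, fv$val), type = "latent")
      cl <- hierarchical_cluster(z, min(k, nrow(z)))
      as.numeric(mutual_information(cl, pair$y_type[fold]))
    }, 0)
    tab$mean_mi[i] <- if (all(is.na(mis))) NA_real_
                      else mean(mis, na.rm = TRUE)
  }
  if (all(is.na(tab$mean_mi)))
    stop("training diverged for every alpha", call. = FALSE)
  list(best_alpha = tab$alpha[which.max(tab$mean_mi)], table = tab)
}
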