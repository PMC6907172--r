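#' Configure an end-to-end embedding pipeline run
#'
#' Bundles every knob of the pipeline: where the mutation records come from
#' (a MAF-like TSV or a [cohort_spec()] simulation), the preprocessing
#' thresholds, the autoencoder architecture, the evaluation grids and the
#' master seed. All randomness downstream flows from `seed`.
#'
#' @param input Either a path to a MAF-like TSV or a `"cohort_spec"`.
#' @param min_support Gene support threshold for [filter_genes()].
#' @param train_fraction,n_folds Split geometry (see [make_split()]).
#' @param latent_dim,hidden_dim,branch_dim,alpha,beta,learning_rate,epochs,batch_size,early_stop_delta,patience,merge
#'   Autoencoder settings (see [mmae()]); `alpha = NULL` triggers the
#'   mixture-weight search of [select_alpha()].
#' @param alpha_grid,sigma_grid_,k_grid Evaluation grids.
#' @param search_folds Folds used inside the alpha search.
#' @param nu One-class parameter for [benchmark_spaces()].
#' @param seed Master seed.
#' @param outdir Optional output directory; when set, [run_pipeline()]
#'   writes TSV/JSON artifacts there.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(input,
                            min_support = 50,
                            train_fraction = 0.8, n_folds = 5,
                            latent_dim = 50, hidden_dim = 400,
                            branch_dim = latent_dim,
                            alpha = 0.5, beta = 2e-5, learning_rate = 1e-3,
                            epochs = 50, batch_size = 128,
                            early_stop_delta = 1e-4,
                            patience = 1L,
                            merge = "concat",
                            alpha_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            sigma_grid_ = sigma_grid(),
                            k_grid = NULL,
                            search_folds = 2L,
                            nu = 0.1,
                            seed = 1L,
                            outdir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full mutation-embedding pipeline
#'
#' Executes simulate/read -> count matrices -> gene filter -> split ->
#' zero-one normalization (ranges fit on training rows) -> autoencoder
#' training (optionally preceded by the mixture-weight search) -> embedding
#' -> KTA bandwidth curves, clustering MI table and per-subtype one-class
#' AUC benchmark on the held-out test set. Reruns with the same config
#' reproduce the same report.
#'
#' @param config A `"pipeline_config"`.
#' @param verbose Print stage progress.
#' @return An `"evaluation_report"`: list with `history` (loss curves),
#'   `kta` (per-space curves and tuned bandwidths), `mi` (per-k table),
#'   `auc` (the [benchmark_spaces()] table), `alpha` (used weight and, if
#'   searched, the MI table), `manifest` (seed, dimensions, counts), and the
#'   fitted `model`, `embedding`, `pair`, `split`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("stage: input")
  cohort <- NULL
  records <- stage("input", {
    if (inherits(config$input, "cohort_spec")) {
      cohort <- simulate_cohort(config$input)
      cohort$records
    } else if (is.character(config$input)) {
      read_maf(config$input)
    } else if (is.data.frame(config$input)) {
      config$input
    } else stop("input must be a cohort_spec, a TSV path or a data.frame")
  })

  say("stage: preprocess (%d records)", nrow(records))
  pair <- stage("preprocess", {
    p <- build_count_matrices(records)
    filter_genes(p, min_support = config$min_support)
  })
  split <- stage("split", make_split(
    length(pair$sample_ids), train_fraction = config$train_fraction,
    n_folds = config$n_folds, seed = config$seed, strata = pair$y_subtype))
  pair <- stage("normalize", normalize_zero_one(pair, split$train_idx))

  alpha_used <- config$alpha
  alpha_table <- NULL
  if (is.null(alpha_used)) {
    say("stage: alpha search")
    sel <- stage("alpha_search", select_alpha(
      pair, split, alpha_grid = config$alpha_grid,
      n_folds_used = config$search_folds,
      latent_dim = config$latent_dim, hidden_dim = config$hidden_dim,
      branch_dim = config$branch_dim, beta = config$beta,
      learning_rate = config$learning_rate, epochs = config$epochs,
      batch_size = config$batch_size,
      early_stop_delta = config$early_stop_delta,
      patience = config$patience, merge = config$merge,
      seed = config$seed))
    alpha_used <- sel$best_alpha
    alpha_table <- sel$table
  }

  say("stage: train (alpha = %.2f)", alpha_used)
  val_fold <- split$folds[[1L]]
  fit_rows <- c(setdiff(split$train_idx, val_fold), val_fold)
  sub <- subset_rows(pair, fit_rows)
  model <- stage("train", mmae(
    sub, latent_dim = config$latent_dim, hidden_dim = config$hidden_dim,
    branch_dim = config$branch_dim, alpha = alpha_used, beta = config$beta,
    learning_rate = config$learning_rate, epochs = config$epochs,
    batch_size = config$batch_size,
    early_stop_delta = config$early_stop_delta,
    patience = config$patience, merge = config$merge,
    val_rows = length(fit_rows) - length(val_fold) + seq_along(val_fold),
    seed = config$seed))

  say("stage: embed")
  embedding <- stage("embed", encode(model, pair))

  say("stage: kernel evaluation")
  te <- split$test_idx
  spaces <- list(latent = embedding$z[te, , drop = FALSE],
                 de = pair$x_de[te, , drop = FALSE],
                 nd = pair$x_nd[te, , drop = FALSE])
  kta_res <- stage("kta", lapply(names(spaces), function(sp)
    tune_sigma(spaces[[sp]], pair$y_type[te], grid = config$sigma_grid_,
               space_tag = sp)))
  names(kta_res) <- names(spaces)
  kta_curves <- do.call(rbind, lapply(kta_res, `[[`, "curve"))

  say("stage: cluster evaluation")
  k_grid <- config$k_grid
  if (is.null(k_grid)) k_grid <- length(unique(pair$y_type))
  mi_tab <- stage("cluster_eval", compare_spaces(
    structure(list(z = spaces$latent, sample_ids = pair$sample_ids[te],
                   y_type = pair$y_type[te], y_subtype = pair$y_subtype[te]),
              class = "latent_embedding"),
    subset_rows(pair, te), k_grid = k_grid))

  say("stage: subtype classification")
  auc_tab <- stage("classify", benchmark_spaces(
    embedding, pair, split, nu = config$nu, grid = config$sigma_grid_))

  report <- structure(
    list(history = model$history,
         kta = list(curves = kta_curves,
                    best = vapply(kta_res, `[[`, 0, "best_sigma"),
                    best_kta = vapply(kta_res, `[[`, 0, "best_kta")),
         mi = mi_tab,
         auc = auc_tab,
         alpha = list(used = alpha_used, table = alpha_table),
         manifest = list(seed = config$seed,
                         n_samples = length(pair$sample_ids),
                         n_genes = length(pair$genes),
                         latent_dim = config$latent_dim,
                         compression_ratio = compression_ratio(
                           length(pair$genes), config$latent_dim),
                         n_train = length(split$train_idx),
                         n_test = length(split$test_idx)),
         model = model, embedding = embedding, pair = pair, split = split,
         cohort = cohort),
    class = "evaluation_report")

  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$manifest
  cat("Mutation-embedding evaluation report\n")
  cat(sprintf("  %d samples x %d genes -> latent %d (compression ratio %d); seed %d\n",
              m$n_samples, m$n_genes, m$latent_dim, m$compression_ratio,
              m$seed))
  cat(sprintf("  alpha = %.2f; epochs run = %d\n", x$alpha$used,
              nrow(x$history)))
  cat(sprintf("  KTA (tuned sigma): latent %.4f, de %.4f, nd %.4f\n",
              x$kta$best_kta[["latent"]], x$kta$best_kta[["de"]],
              x$kta$best_kta[["nd"]]))
  k0 <- x$mi[1L, ]
  cat(sprintf("  MI at k=%d: latent %.4f, de %.4f, nd %.4f\n",
              k0$k, k0$mi_latent, k0$mi_de, k0$mi_nd))
  ok <- sum(stats::complete.cases(
    x$auc[, c("auc_latent", "auc_de", "auc_nd")]))
  cat(sprintf("  latent AUC beats both input spaces in %d of %d subtypes\n",
              attr(x$auc, "improved"), ok))
  invisible(x)
}

#' Write report artifacts to a directory
#'
#' Emits `history.tsv`, `kta_curves.tsv`, `mi.tsv`, `auc.tsv` and
#' `report.json` (summary scores + manifest).
#'
#' @param report An `"evaluation_report"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(report$history, "history.tsv")
  wt(report$kta$curves, "kta_curves.tsv")
  wt(report$mi, "mi.tsv")
  wt(as.data.frame(report$auc), "auc.tsv")
  summary_list <- list(
    manifest = report$manifest,
    alpha = report$alpha$used,
    kta_best_sigma = as.list(report$kta$best),
    kta_best = as.list(report$kta$best_kta),
    mi = as.list(report$mi[1L, c("mi_latent", "mi_de", "mi_nd")]),
    auc_improved = attr(report$auc, "improved"),
    nu = attr(report$auc, "nu"))
  jsonlite::write_json(summary_list, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Plot report figures
#'
#' Writes up to three PNG figures: the loss convergence curves, the KTA
#' versus bandwidth curves per space, the MI versus k curves per space, and
#' (optionally) a 2-d principal-component scatter of the latent space
#' colored by tumor type. Sections missing from the report are skipped with
#' a warning.
#'
#' @param report An `"evaluation_report"`.
#' @param dir Output directory for the PNG files.
#' @param scatter Emit the latent-space PCA scatter (default `TRUE`).
#' @return Character vector of files written, invisibly.
#' @export
plot_report <- function(report, dir = ".", scatter = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(name, code) {
    path <- file.path(dir, name)
    grDevices::png(path, width = 900, height = 650, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    code()
    written <<- c(written, path)
  }
  if (!is.null(report$history)) {
    emit("loss_curves.png", function() {
      h <- report$history
      graphics::matplot(h$epoch, cbind(h$train_total, h$val_total),
                        type = "l", lty = 1, lwd = 2,
                        col = c("steelblue", "firebrick"),
                        xlab = "epoch", ylab = "E_tot",
                        main = "Training and validation loss")
      graphics::legend("topright", c("train", "validation"), lty = 1,
                       lwd = 2, col = c("steelblue", "firebrick"),
                       bty = "n")
    })
  } else warning("report lacks a loss history; skipping loss plot")
  if (!is.null(report$kta)) {
    emit("kta_curves.png", function() {
      cv <- report$kta$curves
      tags <- unique(cv$space_tag)
      cols <- grDevices::hcl.colors(length(tags), "Dark 3")
      graphics::plot(NULL, xlim = range(cv$sigma), ylim = range(cv$kta),
                     log = "x", xlab = expression(sigma), ylab = "KTA",
                     main = "Kernel target alignment by bandwidth")
      for (i in seq_along(tags)) {
        sub <- cv[cv$space_tag == tags[i], ]
        graphics::lines(sub$sigma, sub$kta, col = cols[i], lwd = 2)
      }
      graphics::legend("topright", tags, col = cols, lwd = 2, bty = "n")
    })
  } else warning("report lacks KTA curves; skipping KTA plot")
  if (!is.null(report$mi)) {
    emit("mi_curves.png", function() {
      mi <- report$mi
      graphics::matplot(mi$k, cbind(mi$mi_latent, mi$mi_de, mi$mi_nd),
                        type = "b", pch = 19, lty = 1, lwd = 2,
                        col = c("black", "steelblue", "firebrick"),
                        xlab = "clusters k", ylab = "normalized MI",
                        main = "Clustering mutual information by space")
      graphics::legend("topright", c("latent", "deleterious",
                                     "non-deleterious"),
                       col = c("black", "steelblue", "firebrick"),
                       lwd = 2, bty = "n")
    })
  } else warning("report lacks an MI table; skipping MI plot")
  if (scatter && !is.null(report$embedding)) {
    emit("latent_scatter.png", function() {
      pc <- stats::prcomp(report$embedding$z, rank. = 2)
      ty <- factor(report$embedding$y_type)
      cols <- grDevices::hcl.colors(nlevels(ty), "Dark 3")
      graphics::plot(pc$x[, 1], pc$x[, 2], col = cols[as.integer(ty)],
                     pch = 19, cex = 0.6, xlab = "PC1", ylab = "PC2",
                     main = "Latent space (PCA) by tumor type")
      graphics::legend("topright", levels(ty), col = cols, pch = 19,
                       cex = 0.6, bty = "n")
    })
  }
  invisible(written)
}
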