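## Multi-modal autoencoder: two encoder/decoder branches (deleterious and
## non-deleterious mutation profiles) joined in a shared latent layer,
## trained by Adam on a mixture-weighted binary cross-entropy with an L2
## penalty on encoding weights and batch normalization after the encoder
## hidden layer. All linear algebra is base R; no external NN framework.

sigmoid <- function(x) 1 / (1 + exp(-x))

EPS_BN <- 1e-5
EPS_BCE <- 1e-7

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

## Parameter initialization for the full architecture.
## Per branch: input n -> dense H (sigmoid) -> batchnorm -> dense B (sigmoid
## branch latent). Merge: concat(2B) -> dense L (sigmoid, global latent), or
## averaging (requires equal branch dims = L). Decode per branch:
## L -> dense H (sigmoid) -> dense n (sigmoid).
mmae_init <- function(n, hidden, branch, latent, merge) {
  par <- list()
  for (m in c("de", "nd")) {
    par[[paste0("W1_", m)]] <- glorot(n, hidden)
    par[[paste0("b1_", m)]] <- numeric(hidden)
    par[[paste0("gamma_", m)]] <- rep(1, hidden)
    par[[paste0("beta_", m)]] <- numeric(hidden)
    par[[paste0("W2_", m)]] <- glorot(hidden, branch)
    par[[paste0("b2_", m)]] <- numeric(branch)
    par[[paste0("W4_", m)]] <- glorot(latent, hidden)
    par[[paste0("b4_", m)]] <- numeric(hidden)
    par[[paste0("W5_", m)]] <- glorot(hidden, n)
    par[[paste0("b5_", m)]] <- numeric(n)
  }
  if (merge == "concat") {
    par$W3 <- glorot(2L * branch, latent)
    par$b3 <- numeric(latent)
  }
  par
}

## Names of the encoding weight matrices carrying the L2 penalty.
enc_weight_names <- function(par) {
  intersect(c("W1_de", "W1_nd", "W2_de", "W2_nd", "W3"), names(par))
}

affine <- function(x, W, b) sweep(x %*% W, 2L, b, "+")

bce_mean <- function(x, xhat) {
  xh <- pmin(pmax(xhat, EPS_BCE), 1 - EPS_BCE)
  -mean(x * log(xh) + (1 - x) * log(1 - xh))
}

## Forward pass. training = TRUE uses batch statistics for batchnorm (and
## returns them for backprop); otherwise the running statistics in `bn`.
mmae_forward <- function(par, x_de, x_nd, merge, bn = NULL, training = FALSE) {
  cache <- list(x = list(de = x_de, nd = x_nd))
  lat <- list()
  for (m in c("de", "nd")) {
    x <- cache$x[[m]]
    h <- sigmoid(affine(x, par[[paste0("W1_", m)]], par[[paste0("b1_", m)]]))
    if (training) {
      mu <- colMeans(h)
      v <- colMeans(sweep(h, 2L, mu, "-")^2)
    } else {
      mu <- bn[[m]]$mean
      v <- bn[[m]]$var
    }
    hn <- sweep(sweep(h, 2L, mu, "-"), 2L, sqrt(v + EPS_BN), "/")
    hb <- sweep(sweep(hn, 2L, par[[paste0("gamma_", m)]], "*"), 2L,
                par[[paste0("beta_", m)]], "+")
    l <- sigmoid(affine(hb, par[[paste0("W2_", m)]], par[[paste0("b2_", m)]]))
    lat[[m]] <- l
    cache[[m]] <- list(h = h, mu = mu, v = v, hn = hn, hb = hb, l = l)
  }
  if (merge == "concat") {
    cc <- cbind(lat$de, lat$nd)
    z <- sigmoid(affine(cc, par$W3, par$b3))
    cache$cc <- cc
  } else {
    z <- (lat$de + lat$nd) / 2
  }
  cache$z <- z
  for (m in c("de", "nd")) {
    d <- sigmoid(affine(z, par[[paste0("W4_", m)]], par[[paste0("b4_", m)]]))
    xh <- sigmoid(affine(d, par[[paste0("W5_", m)]], par[[paste0("b5_", m)]]))
    cache[[m]]$d <- d
    cache[[m]]$xhat <- xh
  }
  cache
}

#' Mixture-weighted reconstruction loss
#'
#' Total training objective of the multi-modal autoencoder:
#' `alpha * E_de + (1 - alpha) * E_nd + beta * sum(w^2)`, where each branch
#' loss is the mean binary cross-entropy between that modality's input and
#' its reconstruction and the quadratic penalty runs over the encoding
#' weights only.
#'
#' @param x_de,x_nd Input matrices with entries in `[0, 1]`.
#' @param xhat_de,xhat_nd Reconstructions with entries in `(0, 1)`.
#' @param alpha Mixture weight in `[0, 1]` for the deleterious branch.
#' @param enc_weights List (possibly empty) of encoding weight matrices.
#' @param beta Non-negative L2 coefficient.
#' @return List with `total`, `de`, `nd`, `penalty`.
#' @export
loss_total <- function(x_de, x_nd, xhat_de, xhat_nd, alpha,
                       enc_weights = list(), beta = 0) {
  if (alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  e_de <- bce_mean(x_de, xhat_de)
  e_nd <- bce_mean(x_nd, xhat_nd)
  pen <- if (beta > 0 && length(enc_weights))
    beta * sum(vapply(enc_weights, function(w) sum(w^2), 0)) else 0
  list(total = alpha * e_de + (1 - alpha) * e_nd + pen,
       de = e_de, nd = e_nd, penalty = pen)
}

## Loss + analytic gradients for one (mini-)batch in training mode.
## Returns list(loss = list(...), grads = named list matching par).
mmae_loss_grad <- function(par, x_de, x_nd, alpha, beta, merge = "concat") {
  f <- mmae_forward(par, x_de, x_nd, merge, training = TRUE)
  b <- nrow(x_de)
  loss <- loss_total(x_de, x_nd, f$de$xhat, f$nd$xhat, alpha,
                     par[enc_weight_names(par)], beta)
  g <- list()
  w_mod <- c(de = alpha, nd = 1 - alpha)
  dz <- matrix(0, b, ncol(f$z))
  for (m in c("de", "nd")) {
    n <- ncol(x_de)
    cm <- f[[m]]
    x <- f$x[[m]]
    ## clamped-output BCE + sigmoid: use (xhat - x)/cells on the logit
    dA5 <- w_mod[[m]] * (cm$xhat - x) / (b * n)
    g[[paste0("W5_", m)]] <- crossprod(cm$d, dA5)
    g[[paste0("b5_", m)]] <- colSums(dA5)
    dD <- dA5 %*% t(par[[paste0("W5_", m)]])
    dA4 <- dD * cm$d * (1 - cm$d)
    g[[paste0("W4_", m)]] <- crossprod(f$z, dA4)
    g[[paste0("b4_", m)]] <- colSums(dA4)
    dz <- dz + dA4 %*% t(par[[paste0("W4_", m)]])
  }
  if (merge == "concat") {
    dA3 <- dz * f$z * (1 - f$z)
    g$W3 <- crossprod(f$cc, dA3) + 2 * beta * par$W3
    g$b3 <- colSums(dA3)
    dcc <- dA3 %*% t(par$W3)
    branch <- ncol(f$de$l)
    dlat <- list(de = dcc[, seq_len(branch), drop = FALSE],
                 nd = dcc[, branch + seq_len(branch), drop = FALSE])
  } else {
    dlat <- list(de = dz / 2, nd = dz / 2)
  }
  for (m in c("de", "nd")) {
    cm <- f[[m]]
    dA2 <- dlat[[m]] * cm$l * (1 - cm$l)
    g[[paste0("W2_", m)]] <- crossprod(cm$hb, dA2) +
      2 * beta * par[[paste0("W2_", m)]]
    g[[paste0("b2_", m)]] <- colSums(dA2)
    dHb <- dA2 %*% t(par[[paste0("W2_", m)]])
    g[[paste0("gamma_", m)]] <- colSums(dHb * cm$hn)
    g[[paste0("beta_", m)]] <- colSums(dHb)
    dHn <- sweep(dHb, 2L, par[[paste0("gamma_", m)]], "*")
    ## batchnorm backward (batch statistics)
    inv_sd <- 1 / sqrt(cm$v + EPS_BN)
    s1 <- colSums(dHn)
    s2 <- colSums(dHn * cm$hn)
    dH <- sweep(
      b * dHn - matrix(s1, b, length(s1), byrow = TRUE) -
        cm$hn * matrix(s2, b, length(s2), byrow = TRUE),
      2L, inv_sd / b, "*")
    dA1 <- dH * cm$h * (1 - cm$h)
    g[[paste0("W1_", m)]] <- crossprod(f$x[[m]], dA1) +
      2 * beta * par[[paste0("W1_", m)]]
    g[[paste0("b1_", m)]] <- colSums(dA1)
  }
  list(loss = loss, grads = g, cache = f)
}

#' Fit a multi-modal autoencoder to paired mutation matrices
#'
#' Trains an autoencoder with one encoder/decoder branch per mutation
#' modality. Each branch encodes its zero-one-normalized profile through a
#' sigmoid hidden layer (followed by batch normalization) into a branch
#' latent layer; the two branch latents are merged — concatenated and
#' projected, by default — into a shared latent space of dimension
#' `latent_dim`, from which each branch decodes its own reconstruction. The
#' objective is the mixture-weighted binary cross-entropy
#' `alpha * E_de + (1 - alpha) * E_nd` plus an L2 penalty `beta` on all
#' encoding weights, minimized by Adam with mini-batches. Training stops at
#' `epochs` or as soon as the improvement in validation loss between
#' consecutive epochs falls below `early_stop_delta`.
#'
#' @param x_de,x_nd Samples-by-genes matrices with entries in `[0, 1]`
#'   (deleterious / non-deleterious modality), or a
#'   `"mutation_matrix_pair"` passed as `x_de`.
#' @param latent_dim Dimension L of the shared latent space (default 50).
#' @param hidden_dim Width of the encoder/decoder hidden layers (default 400).
#' @param branch_dim Dimension of each branch latent layer before merging
#'   (default `latent_dim`).
#' @param alpha Mixture weight of the deleterious branch loss, in `[0, 1]`.
#' @param beta L2 coefficient on encoding weights (default 2e-5).
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs Maximum number of epochs (default 50).
#' @param batch_size Mini-batch size (default 128).
#' @param early_stop_delta Minimum per-epoch improvement of the monitored
#'   loss below which training stops (default 1e-4). Set to `-Inf` to
#'   disable early stopping.
#' @param patience Number of consecutive below-threshold epochs tolerated
#'   before stopping (default 1, i.e. stop at the first one).
#' @param val_rows Optional integer row indices used as the validation set
#'   for the stopping rule and the validation curve; these rows are excluded
#'   from gradient updates. If `NULL` the training loss is monitored.
#' @param merge `"concat"` (concatenate branch latents, then a dense
#'   projection to `latent_dim`) or `"average"` (element-wise mean; requires
#'   `branch_dim == latent_dim`).
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @param verbose Print a line per epoch.
#'
#' @return An object of class `"mmae"`: list with the learned `parameters`,
#'   batchnorm running statistics `bn`, a per-epoch `history` data.frame
#'   (columns `epoch`, `train_total`, `train_de`, `train_nd`, `val_total`,
#'   `val_de`, `val_nd`), the gene names seen at fit time, and the call
#'   configuration. Use [predict.mmae()] / [encode()] to embed samples.
#' @examples
#' set.seed(1)
#' x1 <- matrix(runif(40 * 12), 40)
#' x2 <- matrix(runif(40 * 12), 40)
#' fit <- mmae(x1, x2, latent_dim = 3, hidden_dim = 8, epochs = 3,
#'             batch_size = 20, seed = 1)
#' dim(predict(fit, list(de = x1, nd = x2)))
#' @export
mmae <- function(x_de, x_nd = NULL, latent_dim = 50, hidden_dim = 400,
                 branch_dim = latent_dim, alpha = 0.5, beta = 2e-5,
                 learning_rate = 1e-3, epochs = 50, batch_size = 128,
                 early_stop_delta = 1e-4, patience = 1L, val_rows = NULL,
                 merge = c("concat", "average"), seed = 1L,
                 verbose = FALSE) {
  merge <- match.arg(merge)
  if (inherits(x_de, "mutation_matrix_pair")) {
    pair <- x_de
    x_de <- pair$x_de
    x_nd <- pair$x_nd
  }
  if (is.null(x_nd)) stop("x_nd is required", call. = FALSE)
  if (!all(dim(x_de) == dim(x_nd)))
    stop("x_de and x_nd must have identical dimensions", call. = FALSE)
  if (min(x_de, x_nd) < 0 || max(x_de, x_nd) > 1)
    stop("inputs must be zero-one normalized (entries in [0, 1])",
         call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (merge == "average" && branch_dim != latent_dim)
    stop("merge = 'average' requires branch_dim == latent_dim", call. = FALSE)
  if (!(branch_dim <= hidden_dim))
    stop("branch_dim must not exceed hidden_dim", call. = FALSE)
  n <- ncol(x_de)
  m_all <- nrow(x_de)

  train_rows <- if (is.null(val_rows)) seq_len(m_all)
                else setdiff(seq_len(m_all), val_rows)
  if (length(train_rows) < 2L)
    stop("need at least 2 training rows", call. = FALSE)
  xt_de <- x_de[train_rows, , drop = FALSE]
  xt_nd <- x_nd[train_rows, , drop = FALSE]

  set.seed(seed)
  par <- mmae_init(n, hidden_dim, branch_dim, latent_dim, merge)
  adam_m <- lapply(par, function(p) p * 0)
  adam_v <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; t_step <- 0L
  run_bn <- list(de = list(mean = numeric(hidden_dim),
                           var = rep(1, hidden_dim)),
                 nd = list(mean = numeric(hidden_dim),
                           var = rep(1, hidden_dim)))
  momentum <- 0.9

  m_tr <- nrow(xt_de)
  bs <- min(batch_size, m_tr)
  hist_rows <- vector("list", epochs)
  prev_monitor <- Inf
  stall <- 0L

  eval_loss <- function(xd, xn) {
    f <- mmae_forward(par, xd, xn, merge, bn = run_bn, training = FALSE)
    loss_total(xd, xn, f$de$xhat, f$nd$xhat, alpha,
               par[enc_weight_names(par)], beta)
  }

  n_epochs_run <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(m_tr)
    starts <- seq(1L, m_tr, by = bs)
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1L, m_tr)]
      if (length(idx) < 2L) next  # batchnorm needs batch statistics
      lg <- mmae_loss_grad(par, xt_de[idx, , drop = FALSE],
                           xt_nd[idx, , drop = FALSE], alpha, beta, merge)
      if (!is.finite(lg$loss$total))
        stop(sprintf("training loss diverged (NaN/Inf) at epoch %d", ep),
             call. = FALSE)
      for (m in c("de", "nd")) {
        cm <- lg$cache[[m]]
        run_bn[[m]]$mean <- momentum * run_bn[[m]]$mean +
          (1 - momentum) * cm$mu
        run_bn[[m]]$var <- momentum * run_bn[[m]]$var + (1 - momentum) * cm$v
      }
      t_step <- t_step + 1L
      for (nm in names(par)) {
        gnm <- lg$grads[[nm]]
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * gnm
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * gnm^2
        mhat <- adam_m[[nm]] / (1 - b1^t_step)
        vhat <- adam_v[[nm]] / (1 - b2^t_step)
        par[[nm]] <- par[[nm]] - learning_rate * mhat /
          (sqrt(vhat) + adam_eps)
      }
    }
    tr <- eval_loss(xt_de, xt_nd)
    if (!is.finite(tr$total))
      stop(sprintf("training loss diverged (NaN/Inf) at epoch %d", ep),
           call. = FALSE)
    if (!is.null(val_rows)) {
      va <- eval_loss(x_de[val_rows, , drop = FALSE],
                      x_nd[val_rows, , drop = FALSE])
    } else {
      va <- list(total = NA_real_, de = NA_real_, nd = NA_real_)
    }
    hist_rows[[ep]] <- data.frame(
      epoch = ep, train_total = tr$total, train_de = tr$de,
      train_nd = tr$nd, val_total = va$total, val_de = va$de,
      val_nd = va$nd)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %s", ep, tr$total,
                      if (is.na(va$total)) "-" else sprintf("%.5f", va$total)))
    n_epochs_run <- ep
    monitor <- if (!is.null(val_rows)) va$total else tr$total
    if (ep >= 2L && (prev_monitor - monitor) < early_stop_delta) {
      stall <- stall + 1L
      if (stall >= patience) break
    } else stall <- 0L
    prev_monitor <- monitor
  }

  structure(
    list(parameters = par, bn = run_bn,
         history = do.call(rbind, hist_rows[seq_len(n_epochs_run)]),
         genes = colnames(x_de),
         config = list(latent_dim = latent_dim, hidden_dim = hidden_dim,
                       branch_dim = branch_dim, alpha = alpha, beta = beta,
                       learning_rate = learning_rate, epochs = epochs,
                       batch_size = batch_size,
                       early_stop_delta = early_stop_delta,
                       patience = patience, merge = merge,
                       seed = seed, n_genes = n,
                       n_train = length(train_rows),
                       n_val = length(val_rows))),
    class = "mmae"
  )
}

resolve_pair_input <- function(object, newdata) {
  if (inherits(newdata, "mutation_matrix_pair")) {
    if (!is.null(object$genes) && !is.null(newdata$genes)) {
      missing <- setdiff(object$genes, newdata$genes)
      if (length(missing))
        stop("newdata is missing gene(s) seen at fit time: ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) sprintf(" (and %d more)",
                                              length(missing) - 5) else "",
             call. = FALSE)
      x_de <- newdata$x_de[, object$genes, drop = FALSE]
      x_nd <- newdata$x_nd[, object$genes, drop = FALSE]
    } else {
      x_de <- newdata$x_de
      x_nd <- newdata$x_nd
    }
    list(de = x_de, nd = x_nd,
         y_type = newdata$y_type, y_subtype = newdata$y_subtype,
         sample_ids = newdata$sample_ids)
  } else if (is.list(newdata) && all(c("de", "nd") %in% names(newdata))) {
    list(de = newdata$de, nd = newdata$nd,
         y_type = NULL, y_subtype = NULL, sample_ids = rownames(newdata$de))
  } else {
    stop("newdata must be a mutation_matrix_pair or list(de = , nd = )",
         call. = FALSE)
  }
}

#' Predict from a fitted multi-modal autoencoder
#'
#' `type = "latent"` returns the samples-by-L latent coordinates;
#' `type = "response"` returns the per-modality reconstructions (entries in
#' `(0, 1)`). The forward pass uses the running batch-normalization
#' statistics, so it is deterministic.
#'
#' @param object A fitted `"mmae"`.
#' @param newdata A `"mutation_matrix_pair"` or `list(de = , nd = )` of
#'   zero-one matrices with the fit-time gene set.
#' @param type `"latent"` or `"response"`.
#' @param ... Unused.
#' @return A matrix (`"latent"`) or `list(de = , nd = )` (`"response"`).
#' @export
predict.mmae <- function(object, newdata, type = c("latent", "response"),
                         ...) {
  type <- match.arg(type)
  inp <- resolve_pair_input(object, newdata)
  if (ncol(inp$de) != object$config$n_genes)
    stop(sprintf("newdata has %d genes but the model was fit with %d",
                 ncol(inp$de), object$config$n_genes), call. = FALSE)
  f <- mmae_forward(object$parameters, inp$de, inp$nd, object$config$merge,
                    bn = object$bn, training = FALSE)
  if (type == "latent") {
    z <- f$z
    rownames(z) <- inp$sample_ids
    colnames(z) <- sprintf("L%02d", seq_len(ncol(z)))
    z
  } else {
    list(de = f$de$xhat, nd = f$nd$xhat)
  }
}

#' Embed samples into the learned latent space
#'
#' Convenience wrapper around [predict.mmae()] that keeps the tumor labels
#' alongside the coordinates.
#'
#' @param object A fitted `"mmae"`.
#' @param pair A `"mutation_matrix_pair"` with the fit-time gene set.
#' @return A `"latent_embedding"`: list with matrix `z` (samples x L),
#'   `sample_ids`, `y_type`, `y_subtype`.
#' @export
encode <- function(object, pair) {
  stopifnot(inherits(object, "mmae"))
  z <- predict(object, pair, type = "latent")
  structure(list(z = z,
                 sample_ids = rownames(z),
                 y_type = pair$y_type, y_subtype = pair$y_subtype),
            class = "latent_embedding")
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat(sprintf("Latent embedding: %d samples x %d dimensions\n",
              nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' @export
print.mmae <- function(x, ...) {
  cfg <- x$config
  cat("Multi-modal autoencoder\n")
  cat(sprintf("  %d genes -> %d hidden -> %d branch latent -> %d shared latent (%s merge)\n",
              cfg$n_genes, cfg$hidden_dim, cfg$branch_dim, cfg$latent_dim,
              cfg$merge))
  cat(sprintf("  alpha = %.2f, beta = %g, lr = %g, trained %d epoch(s)\n",
              cfg$alpha, cfg$beta, cfg$learning_rate, nrow(x$history)))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final loss: train %.5f%s\n", last$train_total,
              if (is.na(last$val_total)) ""
              else sprintf(", validation %.5f", last$val_total)))
  invisible(x)
}

#' @export
summary.mmae <- function(object, ...) {
  cfg <- object$config
  npar <- sum(vapply(object$parameters, length, 0L))
  out <- list(config = cfg, n_parameters = npar,
              epochs_run = nrow(object$history),
              history = object$history,
              compression_ratio = compression_ratio(cfg$n_genes,
                                                    cfg$latent_dim))
  class(out) <- "summary.mmae"
  out
}

#' @export
print.summary.mmae <- function(x, ...) {
  cfg <- x$config
  cat("Multi-modal autoencoder fit\n")
  cat(sprintf("  input genes: %d; latent dimension: %d (compression ratio %d)\n",
              cfg$n_genes, cfg$latent_dim, x$compression_ratio))
  cat(sprintf("  trainable parameters: %d\n", x$n_parameters))
  cat(sprintf("  mixture weight alpha = %.2f; L2 beta = %g; Adam lr = %g\n",
              cfg$alpha, cfg$beta, cfg$learning_rate))
  cat(sprintf("  epochs run: %d (max %d, early-stop delta %g)\n",
              x$epochs_run, cfg$epochs, cfg$early_stop_delta))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final losses: train E_tot %.5f (de %.5f, nd %.5f)%s\n",
              last$train_total, last$train_de, last$train_nd,
              if (is.na(last$val_total)) ""
              else sprintf("; val E_tot %.5f", last$val_total)))
  invisible(x)
}

#' @export
coef.mmae <- function(object, ...) object$parameters

#' @export
fitted.mmae <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    stop("pass the training pair as 'newdata' (the fit does not store it)",
         call. = FALSE)
  predict(object, newdata, type = "response")
}

#' Reconstruction residuals of a multi-modal autoencoder
#'
#' @param object A fitted `"mmae"`.
#' @param newdata The `"mutation_matrix_pair"` (or `list(de=, nd=)`) to
#'   reconstruct.
#' @param ... Unused.
#' @return `list(de = , nd = )` of `x - xhat` matrices.
#' @export
residuals.mmae <- function(object, newdata, ...) {
  inp <- resolve_pair_input(object, newdata)
  xh <- predict(object, newdata, type = "response")
  list(de = inp$de - xh$de, nd = inp$nd - xh$nd)
}

#' Plot training and validation loss curves
#'
#' @param x A fitted `"mmae"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mmae <- function(x, ...) {
  h <- x$history
  has_val <- !all(is.na(h$val_total))
  y <- if (has_val) cbind(h$train_total, h$val_total)
       else cbind(h$train_total)
  graphics::matplot(h$epoch, y, type = "l", lty = 1, lwd = 2,
                    col = c("steelblue", "firebrick")[seq_len(ncol(y))],
                    xlab = "epoch", ylab = "loss (E_tot)",
                    main = "Autoencoder convergence", ...)
  graphics::legend("topright",
                   legend = c("train", "validation")[seq_len(ncol(y))],
                   col = c("steelblue", "firebrick")[seq_len(ncol(y))],
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' Number of trainable parameters of an architecture
#'
#' Closed-form count for the default architecture; useful for comparing
#' latent dimensionalities before training.
#'
#' @param n_genes Input dimension per branch.
#' @param hidden_dim,branch_dim,latent_dim Layer widths.
#' @param merge `"concat"` or `"average"`.
#' @return Integer parameter count (weights + biases + batchnorm scales).
#' @export
mmae_parameter_count <- function(n_genes, hidden_dim = 400,
                                 branch_dim = latent_dim, latent_dim = 50,
                                 merge = "concat") {
  per_branch <- n_genes * hidden_dim + hidden_dim +   # W1, b1
    2 * hidden_dim +                                  # gamma, beta
    hidden_dim * branch_dim + branch_dim +            # W2, b2
    latent_dim * hidden_dim + hidden_dim +            # W4, b4
    hidden_dim * n_genes + n_genes                    # W5, b5
  merge_par <- if (merge == "concat")
    2 * branch_dim * latent_dim + latent_dim else 0
  as.integer(2 * per_branch + merge_par)
}
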