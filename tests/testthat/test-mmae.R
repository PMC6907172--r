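# Brute-force numerical gradient used as the oracle for backpropagation.
numeric_grad <- function(par, name, idx, x_de, x_nd, alpha, beta,
                         eps = 1e-5) {
  f <- function(v) {
    p2 <- par
    p2[[name]][idx] <- v
    mutembed:::mmae_loss_grad(p2, x_de, x_nd, alpha, beta)$loss$total
  }
  v0 <- par[[name]][idx]
  (f(v0 + eps) - f(v0 - eps)) / (2 * eps)
}

test_that("backpropagation matches numerical differentiation", {
  set.seed(7)
  n <- 7; h <- 5; b <- 3; l <- 4; m <- 6
  par <- mutembed:::mmae_init(n, h, b, l, "concat")
  x_de <- matrix(runif(m * n), m)
  x_nd <- matrix(runif(m * n), m)
  lg <- mutembed:::mmae_loss_grad(par, x_de, x_nd, alpha = 0.3,
                                  beta = 1e-3)
  for (name in names(par)) {
    set.seed(nchar(name))
    picks <- sample(length(par[[name]]), min(4, length(par[[name]])))
    for (idx in picks) {
      ng <- numeric_grad(par, name, idx, x_de, x_nd, alpha = 0.3,
                         beta = 1e-3)
      ag <- lg$grads[[name]][idx]
      expect_lt(abs(ag - ng) / max(1e-6, abs(ng) + abs(ag)), 1e-4,
                label = sprintf("gradient of %s[%d]", name, idx))
    }
  }
})

test_that("total loss combines branch cross-entropies and the L2 penalty", {
  x <- matrix(c(1, 0, 1, 0), 2)
  xh_perfect <- x
  # perfect binary reconstruction, no penalty -> zero loss
  l0 <- loss_total(x, x, xh_perfect, xh_perfect, alpha = 0.5)
  expect_equal(l0$total, 0, tolerance = 1e-5)
  # single-cell hand computation: x = 1, xhat = 0.5 -> -ln(0.5)
  l1 <- loss_total(matrix(1), matrix(0), matrix(0.5), matrix(0.999999),
                   alpha = 1)
  expect_equal(l1$total, -log(0.5), tolerance = 1e-5)
  # alpha = 1 ignores the non-deleterious branch
  xh_bad <- matrix(0.25, 2, 2)
  la <- loss_total(x, x, xh_perfect, xh_bad, alpha = 1)
  expect_equal(la$total, la$de, tolerance = 1e-6)
  # linearity in alpha for fixed reconstructions
  alphas <- c(0.1, 0.4, 0.8)
  tot <- vapply(alphas, function(a)
    loss_total(x, x, xh_bad, xh_perfect, alpha = a)$total, 0)
  slopes <- diff(tot) / diff(alphas)
  expect_equal(slopes[1], slopes[2], tolerance = 1e-10)
  # penalty counts encoding weights only
  w <- matrix(2, 2, 2)
  lp <- loss_total(x, x, xh_perfect, xh_perfect, alpha = 0.5,
                   enc_weights = list(w), beta = 0.01)
  expect_equal(lp$penalty, 0.01 * sum(w^2))
  expect_error(loss_total(x, x, xh_perfect, xh_perfect, alpha = 1.2),
               "alpha")
})

test_that("architecture has the closed-form parameter count and shapes", {
  n <- 33; hd <- 10; bd <- 4; l <- 4
  par <- mutembed:::mmae_init(n, hd, bd, l, "concat")
  expect_equal(sum(vapply(par, length, 0L)),
               mmae_parameter_count(n, hd, bd, l))
  # reference architecture arithmetic: 12424 genes, 400 hidden, 50 latent
  expect_equal(
    mmae_parameter_count(12424, 400, 50, 50),
    2 * (12424 * 400 + 400 + 800 + 400 * 50 + 50 + 50 * 400 + 400 +
           400 * 12424 + 12424) + 100 * 50 + 50)
  # encoding any input yields a latent of length exactly L
  set.seed(1)
  x1 <- matrix(runif(10 * n), 10)
  fit <- mmae(x1, x1, latent_dim = l, hidden_dim = hd, branch_dim = bd,
              epochs = 2, batch_size = 5, seed = 1)
  z <- predict(fit, list(de = x1, nd = x1))
  expect_equal(dim(z), c(10, l))
  xh <- predict(fit, list(de = x1, nd = x1), type = "response")
  expect_true(all(xh$de > 0 & xh$de < 1))
  expect_true(all(xh$nd > 0 & xh$nd < 1))
})

test_that("training reduces loss and records both curves", {
  setup <- small_training_setup(seed = 21)
  pair <- setup$pair
  split <- setup$split
  val <- split$folds[[1]]
  rows <- c(setdiff(split$train_idx, val), val)
  sub <- subset_rows(pair, rows)
  fit <- mmae(sub, latent_dim = 8, hidden_dim = 32, epochs = 30,
              batch_size = 16, seed = 2, learning_rate = 2e-3,
              val_rows = length(rows) - length(val) + seq_along(val),
              early_stop_delta = -Inf)
  h <- fit$history
  expect_equal(nrow(h), 30)
  expect_lt(h$val_total[nrow(h)], h$val_total[1])
  expect_lt(h$train_total[nrow(h)], h$train_total[1])
  # smoothed training curve non-increasing over 5-epoch windows
  sm <- stats::filter(h$train_total, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 1e-3))
})

test_that("early stopping obeys its threshold semantics", {
  set.seed(3)
  x <- matrix(runif(30 * 10), 30)
  # a huge threshold stops at the first comparison (epoch 2)
  fit <- mmae(x, x, latent_dim = 2, hidden_dim = 4, epochs = 20,
              batch_size = 15, early_stop_delta = 1e6, seed = 1)
  expect_equal(nrow(fit$history), 2)
  # disabled stopping runs to the epoch budget
  fit2 <- mmae(x, x, latent_dim = 2, hidden_dim = 4, epochs = 5,
               batch_size = 15, early_stop_delta = -Inf, seed = 1)
  expect_equal(nrow(fit2$history), 5)
})

test_that("encoding is deterministic, row-aligned and validates genes", {
  setup <- small_training_setup(seed = 8)
  pair <- setup$pair
  fit <- mmae(pair, latent_dim = 6, hidden_dim = 16, epochs = 3,
              batch_size = 32, seed = 5)
  emb1 <- encode(fit, pair)
  emb2 <- encode(fit, pair)
  expect_identical(emb1$z, emb2$z)
  expect_equal(nrow(emb1$z), length(pair$sample_ids))
  expect_identical(emb1$y_subtype, pair$y_subtype)
  # duplicated input row gives a duplicated latent row
  dup <- subset_rows(pair, c(1, 1, 2))
  zd <- predict(fit, dup)
  expect_equal(zd[1, ], zd[2, ])
  # gene-set mismatch errors, naming the missing genes
  bad <- pair
  bad$x_de <- bad$x_de[, -1]
  bad$x_nd <- bad$x_nd[, -1]
  bad$genes <- bad$genes[-1]
  expect_error(predict(fit, bad), "missing gene")
})

test_that("model methods expose the fit the standard way", {
  setup <- small_training_setup(seed = 12)
  pair <- setup$pair
  fit <- mmae(pair, latent_dim = 4, hidden_dim = 8, epochs = 2,
              batch_size = 32, seed = 1)
  expect_output(print(fit), "Multi-modal autoencoder")
  s <- summary(fit)
  expect_s3_class(s, "summary.mmae")
  expect_output(print(s), "compression ratio")
  expect_named(coef(fit)["W3"], "W3")
  r <- residuals(fit, pair)
  expect_equal(dim(r$de), dim(pair$x_de))
  xh <- fitted(fit, pair)
  expect_equal(r$de, pair$x_de - xh$de)
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf)
  expect_silent(plot(fit))
  grDevices::dev.off()
  unlink(tf)
})

test_that("divergent training reports the epoch", {
  set.seed(4)
  x <- matrix(runif(20 * 8), 20)
  expect_error(
    mmae(x, x, latent_dim = 2, hidden_dim = 4, epochs = 5, batch_size = 10,
         learning_rate = 1e300, seed = 1),
    "epoch")
})
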