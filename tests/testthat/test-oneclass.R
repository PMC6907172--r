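# Pairwise brute-force AUC oracle with the 1/2-credit tie convention.
auc_oracle <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("nu bounds hold for support vectors and margin violators", {
  for (nu in c(0.1, 0.3, 0.6)) {
    bl <- blob_matrix(n_per = 60, k = 1, p = 4, sep = 0, sd = 1, seed = 13)
    m <- fit_one_class(bl$x, nu = nu, sigma = 2, subtype = "a")
    sv_frac <- m$fit$tot.nSV / nrow(bl$x)
    viol_frac <- mean(decision_scores(m, bl$x) < 0)
    expect_gte(sv_frac, nu - 0.05)
    expect_lte(viol_frac, nu + 0.05)
  }
  # small nu on a tight cluster: at most nu (+ solver tolerance) of the
  # training points fall outside the boundary
  tight <- blob_matrix(n_per = 50, k = 1, p = 3, sep = 0, sd = 0.3,
                       seed = 14)
  m01 <- fit_one_class(tight$x, nu = 0.1, sigma = 1, subtype = "a")
  expect_gte(mean(decision_scores(m01, tight$x) >= 0), 1 - 0.1 - 0.05)
  # nu near 1: almost every training point becomes a margin violator
  m9 <- fit_one_class(tight$x, nu = 0.95, sigma = 1, subtype = "a")
  expect_gte(mean(decision_scores(m9, tight$x) < 0), 0.9)
  expect_error(fit_one_class(tight$x, nu = 0), "nu")
  expect_error(fit_one_class(tight$x[1, , drop = FALSE]), "at least 2")
})

test_that("decision scores are inside-positive, outside-negative", {
  tight <- blob_matrix(n_per = 40, k = 1, p = 3, sep = 0, sd = 0.5,
                       seed = 15)
  m <- fit_one_class(tight$x, nu = 0.1, sigma = 2, subtype = "a")
  centroid <- matrix(colMeans(tight$x), 1)
  expect_gt(decision_scores(m, centroid), 0)
  outlier <- centroid + 100 * 0.5
  expect_lt(decision_scores(m, outlier), 0)
  # permutation equivariance in rows
  set.seed(16)
  X <- matrix(rnorm(10 * 3), 10)
  perm <- sample(10)
  expect_equal(decision_scores(m, X)[perm], decision_scores(m, X[perm, ]))
  # duplicating the training set leaves the decision geometry unchanged:
  # the solver scales scores with n, so ranking and signs are preserved
  m_dup <- fit_one_class(rbind(tight$x, tight$x), nu = 0.1, sigma = 2,
                         subtype = "a")
  s1 <- decision_scores(m, X)
  s2 <- decision_scores(m_dup, X)
  expect_equal(s2, 2 * s1, tolerance = 1e-3)
  expect_identical(rank(s2), rank(s1))
  expect_error(decision_scores(m, X[, 1:2]), "features")
})

test_that("AUC matches the brute-force pairwise formula", {
  # hand example: scores .9 .8 .3 .1 labels + - + - -> AUC .75
  expect_equal(mutembed:::auc_from_scores(c(0.9, 0.8, 0.3, 0.1),
                                          c(TRUE, FALSE, TRUE, FALSE)),
               0.75)
  set.seed(17)
  for (rep in 1:20) {
    scores <- sample(round(rnorm(30), 1))  # rounding forces ties
    positive <- sample(c(TRUE, FALSE), 30, replace = TRUE,
                       prob = c(0.4, 0.6))
    if (!any(positive) || all(positive)) next
    expect_lt(abs(mutembed:::auc_from_scores(scores, positive) -
                    auc_oracle(scores, positive)), 1e-10)
  }
  # perfect ranking -> 1
  expect_equal(mutembed:::auc_from_scores(c(5, 4, 1, 0),
                                          c(TRUE, TRUE, FALSE, FALSE)), 1)
})

test_that("evaluate_auc uses the model subtype and handles degenerate tests", {
  bl <- blob_matrix(n_per = 30, k = 2, p = 4, sep = 6, sd = 0.5, seed = 18)
  m <- fit_one_class(bl$x[bl$labels == 1, ], nu = 0.1, sigma = 2,
                     subtype = "c1")
  y <- c("c1", "c2")[bl$labels]
  auc <- evaluate_auc(m, bl$x, y)
  expect_gt(auc, 0.95)
  expect_true(is.na(evaluate_auc(m, bl$x[bl$labels == 2, ],
                                 y[bl$labels == 2])))
  # random scores on shuffled labels hover near 1/2
  set.seed(19)
  y_perm <- sample(y)
  auc_null <- evaluate_auc(m, bl$x[sample(nrow(bl$x)), ], y_perm)
  expect_gt(auc_null, 0.3)
  expect_lt(auc_null, 0.7)
})

test_that("space benchmark builds a full AUC table with improvement count", {
  setup <- small_training_setup(seed = 23)
  pair <- setup$pair
  split <- setup$split
  fit <- mmae(pair, latent_dim = 8, hidden_dim = 32, epochs = 20,
              batch_size = 16, seed = 2, early_stop_delta = -Inf)
  emb <- encode(fit, pair)
  tab <- benchmark_spaces(emb, pair, split, nu = 0.1,
                          grid = sigma_grid(0.1, 20, 8))
  expect_s3_class(tab, "auc_table")
  expect_setequal(tab$subtype, unique(pair$y_subtype))
  expect_true(all(tab$n_test >= 1))
  aucs <- unlist(tab[, c("auc_latent", "auc_de", "auc_nd")])
  expect_true(all(aucs >= 0 & aucs <= 1, na.rm = TRUE))
  # the improvement count is the brute-force count over table rows
  ok <- stats::complete.cases(tab[, c("auc_latent", "auc_de", "auc_nd")])
  expect_equal(attr(tab, "improved"),
               sum(tab$auc_latent[ok] > tab$auc_de[ok] &
                     tab$auc_latent[ok] > tab$auc_nd[ok]))
  expect_output(print(tab), "subtypes")
  # a subtype below the size floor is skipped with a warning, not an error
  pair_small <- pair
  drop <- which(pair_small$y_subtype == pair_small$y_subtype[1])[-1]
  keep <- setdiff(seq_along(pair_small$sample_ids), drop)
  pair_small <- subset_rows(pair_small, keep)
  emb_small <- encode(fit, pair_small)
  split_small <- make_split(length(keep), 0.8, 5, seed = 1,
                            strata = pair_small$y_subtype)
  expect_warning(
    benchmark_spaces(emb_small, pair_small, split_small,
                     grid = sigma_grid(0.5, 5, 3)),
    "skipped")
})
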