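#' Hierarchical clustering of a sample space
#'
#' Agglomerative clustering with the Ward criterion on Euclidean distances
#' (`stats::hclust(method = "ward.D2")`), cut at `k` clusters.
#' Deterministic.
#'
#' @param X Numeric samples-by-features matrix.
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @return Integer vector of cluster assignments in `1..k`, with attribute
#'   `k`.
#' @export
hierarchical_cluster <- function(X, k) {
  X <- as.matrix(X)
  if (k < 1 || k > nrow(X))
    stop("k must lie between 1 and the number of samples", call. = FALSE)
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  attr(cl, "k") <- as.integer(k)
  unname_keep_attr(cl)
}

unname_keep_attr <- function(x) {
  a <- attributes(x)
  x <- unname(x)
  attr(x, "k") <- a$k
  x
}

#' Mutual information between a clustering and ground-truth labels
#'
#' Plug-in mutual information from the empirical contingency table,
#' `MI = sum_kj p_kj log(p_kj / (p_k p_j))` in nats. Because the raw value
#' is unbounded above, the reported score is normalized by the arithmetic
#' mean of the two marginal entropies so that identical partitions score
#' exactly 1 and independent ones 0; the raw value is returned as an
#' attribute (and by `normalized = FALSE`). Symmetric in its arguments and
#' invariant to relabeling.
#'
#' @param labels_a,labels_b Equal-length assignment vectors (cluster labels
#'   and ground-truth classes, in either order).
#' @param normalized Return the normalized score (default) or the raw MI.
#' @return Scalar; normalized MI lies in `[0, 1]`. Attribute `"raw"` holds
#'   the unnormalized value in nats.
#' @export
mutual_information <- function(labels_a, labels_b, normalized = TRUE) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length", call. = FALSE)
  if (length(labels_a) == 0L) stop("empty label vectors", call. = FALSE)
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p)
  pb <- colSums(p)
  pos <- p > 0
  mi <- sum(p[pos] * log(p[pos] / outer(pa, pb)[pos]))
  mi <- max(mi, 0)  # guard tiny negative rounding
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  denom <- (ha + hb) / 2
  ## equivalent partitions (one non-zero cell per row and column): the
  ## score is exactly 1, free of floating-point residue
  one_to_one <- all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
  nmi <- if (denom == 0 || one_to_one) 1 else mi / denom
  out <- if (normalized) nmi else mi
  attr(out, "raw") <- mi
  out
}

#' Compare clustering quality across latent and input spaces
#'
#' Clusters the latent space and both input modalities at each `k` and
#' scores every clustering against the tumor-type labels by normalized
#' mutual information. A well-learned latent space shows `mi_latent` at or
#' above both input-space scores.
#'
#' @param embedding A `"latent_embedding"` (see [encode()]).
#' @param pair The matching `"mutation_matrix_pair"` (same rows).
#' @param k_grid Integer vector of cluster counts.
#' @param labels Ground-truth labels (default: the embedding's tumor types).
#' @return data.frame with columns `k`, `mi_latent`, `mi_de`, `mi_nd` and
#'   their raw (unnormalized) counterparts.
#' @export
compare_spaces <- function(embedding, pair, k_grid,
                           labels = embedding$y_type) {
  stopifnot(inherits(embedding, "latent_embedding"),
            inherits(pair, "mutation_matrix_pair"))
  if (nrow(embedding$z) != nrow(pair$x_de))
    stop("embedding and pair must share sample rows", call. = FALSE)
  rows <- lapply(k_grid, function(k) {
    mi_of <- function(X) {
      cl <- hierarchical_cluster(X, k)
      mutual_information(cl, labels)
    }
    mz <- mi_of(embedding$z)
    md <- mi_of(pair$x_de)
    mn <- mi_of(pair$x_nd)
    data.frame(k = k,
               mi_latent = as.numeric(mz), mi_de = as.numeric(md),
               mi_nd = as.numeric(mn),
               mi_latent_raw = attr(mz, "raw"), mi_de_raw = attr(md, "raw"),
               mi_nd_raw = attr(mn, "raw"))
  })
  do.call(rbind, rows)
}
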