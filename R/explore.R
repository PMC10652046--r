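# Unsupervised structure discovery: correlation matrices with hierarchical
# ordering, PCA on z-scored data, and silhouette-guided k-means clustering.

#' Pearson correlation matrix with rank-based significance
#'
#' Pairwise-complete Pearson correlations between variables, with per-pair
#' p-values from the Spearman rank-correlation test (the screen's reported
#' pairing of a Pearson effect size with a rank-based significance level; a
#' Pearson t-test alternative is available). Variables are ordered by
#' average-linkage hierarchical clustering on the distance `1 - r` so related
#' variables sit together in heatmaps. Constant variables yield `NA`
#' correlations (undefined, not zero).
#'
#' @param data Numeric matrix or data.frame, samples x variables.
#' @param p_method `"spearman"` (default) or `"pearson"` for the p-values.
#' @return A `correlation_matrix` object: list with `r`, `p` (symmetric
#'   matrices), `ordering` (permutation of variables), `variables`,
#'   `p_method`, `linkage`.
#' @export
correlation_matrix <- function(data, p_method = c("spearman", "pearson")) {
  p_method <- match.arg(p_method)
  M <- as.matrix(data)
  stopifnot(is.numeric(M), ncol(M) >= 2)
  vars <- colnames(M)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(M)))
  colnames(M) <- vars
  q <- ncol(M)
  r <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs",
                                   method = "pearson"))
  pmat <- matrix(NA_real_, q, q, dimnames = list(vars, vars))
  diag(pmat) <- 0
  for (i in seq_len(q - 1)) {
    for (j in (i + 1):q) {
      ok <- stats::complete.cases(M[, i], M[, j])
      if (sum(ok) < 3 || stats::sd(M[ok, i]) == 0 || stats::sd(M[ok, j]) == 0) {
        r[i, j] <- r[j, i] <- NA_real_
        next
      }
      pv <- suppressWarnings(
        stats::cor.test(M[ok, i], M[ok, j], method = p_method, exact = FALSE)$p.value
      )
      pmat[i, j] <- pmat[j, i] <- pv
    }
  }
  d_r <- r
  d_r[is.na(d_r)] <- 0
  ordering <- if (q > 2) {
    stats::hclust(stats::as.dist(1 - d_r), method = "average")$order
  } else {
    seq_len(q)
  }
  structure(
    list(r = r, p = pmat, ordering = ordering, variables = vars,
         p_method = p_method, linkage = "average"),
    class = "correlation_matrix"
  )
}

#' PCA of a z-scored data matrix
#'
#' Columns are standardised to mean 0, SD 1, then decomposed by SVD.
#' Constant columns are dropped with a warning. Component signs are fixed so
#' the largest-magnitude loading of each component is positive, making the
#' result deterministic.
#'
#' @param data Numeric matrix or data.frame, samples x variables; rows with
#'   any missing value are dropped (count reported via attribute
#'   `n_dropped`).
#' @return List with `scores` (samples x components), `loadings`
#'   (variables x components), `variance_explained` (fractions, sum to 1 over
#'   all returned components), `dropped_columns`.
#' @export
pca_zscore <- function(data) {
  M <- as.matrix(data)
  keep_rows <- stats::complete.cases(M)
  n_dropped <- sum(!keep_rows)
  M <- M[keep_rows, , drop = FALSE]
  if (nrow(M) < 2) stop("need at least 2 complete samples for PCA", call. = FALSE)
  sds <- apply(M, 2, stats::sd)
  dropped <- colnames(M)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    M <- M[, sds > 0, drop = FALSE]
  }
  Z <- scale(M)
  sv <- svd(Z)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  U <- sv$u[, seq_len(ncomp), drop = FALSE]
  V <- sv$v[, seq_len(ncomp), drop = FALSE]
  # sign convention: the largest-|loading| entry of each component is positive
  for (j in seq_len(ncomp)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  scores <- U %*% diag(d, ncomp)
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(ncomp))
  rownames(V) <- colnames(M)
  ve <- d^2 / sum(sv$d^2)
  out <- list(scores = scores, loadings = V, variance_explained = ve,
              dropped_columns = dropped)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Mean silhouette across candidate cluster numbers
#'
#' For each k in `k_range`, runs k-means and computes the mean silhouette
#' width over samples (Euclidean distances). Values of k that are not below
#' the sample count are skipped with a warning. The k maximising the mean
#' silhouette is the supported cluster number.
#'
#' @param data Numeric matrix, samples x variables (z-score beforehand if
#'   variables are on different scales).
#' @param k_range Integer vector of candidate k (>= 2).
#' @param n_starts,seed Passed to [kmeans_cluster()].
#' @return Named numeric vector, mean silhouette per k.
#' @export
silhouette_scan <- function(data, k_range = 2:6, n_starts = 25, seed = 1L) {
  M <- as.matrix(data)
  n <- nrow(M)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 2))
  usable <- k_range[k_range < n]
  if (length(usable) < length(k_range)) {
    warning("skipping k >= number of samples: ",
            paste(setdiff(k_range, usable), collapse = ", "))
  }
  d <- stats::dist(M)
  out <- vapply(usable, function(k) {
    cl <- kmeans_cluster(M, k, n_starts = n_starts, seed = derive_seed(seed, k))
    mean(cluster::silhouette(cl$assignments, d)[, "sil_width"])
  }, numeric(1))
  stats::setNames(out, usable)
}

#' K-means clustering with multiple random starts
#'
#' Lloyd-style k-means (via `stats::kmeans`), keeping the best of `n_starts`
#' random initialisations by within-cluster sum of squares; deterministic
#' given `seed`. A degenerate start that would empty a cluster is re-seeded
#' by the underlying implementation (additional random restarts), so every
#' returned cluster is non-empty.
#'
#' @param data Numeric matrix, samples x variables.
#' @param k Number of centres (>= 2).
#' @param n_starts Random starts (the screen's convention: 25).
#' @param seed Integer seed.
#' @return List with `k`, `assignments`, `centers`, `withinss_total`,
#'   `silhouette` (per-sample widths), `mean_silhouette`.
#' @export
kmeans_cluster <- function(data, k, n_starts = 25, seed = 1L) {
  M <- as.matrix(data)
  stopifnot(k >= 2, k < nrow(M), n_starts >= 1)
  set.seed(seed)
  km <- stats::kmeans(M, centers = k, nstart = n_starts, iter.max = 100)
  sil <- cluster::silhouette(km$cluster, stats::dist(M))
  list(
    k = k,
    assignments = unname(km$cluster),
    centers = km$centers,
    withinss_total = km$tot.withinss,
    silhouette = sil[, "sil_width"],
    mean_silhouette = mean(sil[, "sil_width"])
  )
}

#' Silhouette-guided clustering
#'
#' Scans k over `k_range`, picks the k with the highest mean silhouette, and
#' returns the final clustering at that k together with the scan.
#'
#' @inheritParams silhouette_scan
#' @return List with `chosen_k`, `silhouette_by_k`, and the fields of
#'   [kmeans_cluster()] at the chosen k.
#' @export
cluster_with_silhouette <- function(data, k_range = 2:6, n_starts = 25, seed = 1L) {
  scan <- silhouette_scan(data, k_range, n_starts = n_starts, seed = seed)
  chosen_k <- as.integer(names(scan)[which.max(scan)])
  cl <- kmeans_cluster(as.matrix(data), chosen_k, n_starts = n_starts,
                       seed = derive_seed(seed, chosen_k))
  c(list(chosen_k = chosen_k, silhouette_by_k = scan), cl)
}
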