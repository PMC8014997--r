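#' @title Clustering of the integrated proteome
#' @description PCA of the batch-corrected matrix (or of its per-condition
#'   geometric means), k-means clustering with k-means++ seeding, and
#'   cluster-count selection by x-means: centroids are recursively split in
#'   two and a split is kept when it improves the Bayesian Information
#'   Criterion under a spherical-Gaussian model with a shared per-dimension
#'   variance.
#' @name clustering
NULL

#' Collapse replicate columns to per-(participant, condition) geomeans
#'
#' @param matrix a batch-corrected `protein_matrix`.
#' @return a `protein_matrix` (same state) with one column per
#'   (participant, condition) pair, each protein value the geometric mean
#'   over that pair's replicate columns. Reference pools collapse to one
#'   `unstimulated` column per participant.
#' @export
condition_geomeans <- function(matrix) {
  stopifnot(inherits(matrix, "protein_matrix"))
  cols <- matrix$columns
  keep <- cols$condition != "empty"
  vals <- matrix$values[, keep, drop = FALSE]
  cols <- cols[keep, , drop = FALSE]
  key <- paste(cols$participant, cols$condition, sep = "|")
  groups <- unique(key)
  out <- vapply(groups, function(g) {
    j <- which(key == g)
    exp(rowMeans(log(vals[, j, drop = FALSE])))
  }, numeric(nrow(vals)))
  out <- matrix(out, nrow = nrow(vals),
                dimnames = list(rownames(matrix$values), NULL))
  parts <- do.call(rbind, strsplit(groups, "|", fixed = TRUE))
  columns <- data.frame(batch_id = "all", channel = groups,
                        sample_id = groups,
                        participant = parts[, 1], condition = parts[, 2],
                        concentration_ppm = NA_real_,
                        is_reference_pool = parts[, 2] == "unstimulated",
                        stringsAsFactors = FALSE)
  new_protein_matrix(out, columns, state = matrix$state)
}

#' PCA of the integrated matrix
#'
#' Same projection as [per_batch_pca()] (log2, mean-centered per protein)
#' but applied to the concatenated or batch-corrected matrix.
#'
#' @param matrix a `protein_matrix` (any state; typically
#'   `combat_corrected`).
#' @param n_components retained score dimensions.
#' @return list with `scores`, non-increasing `explained_variance`
#'   fractions, and the column annotation.
#' @export
global_pca <- function(matrix, n_components = 2) {
  stopifnot(inherits(matrix, "protein_matrix"))
  out <- pca_scores(matrix$values, n_components)
  out$columns <- matrix$columns
  out
}

# k-means++ seeding: first centre uniform, later centres with probability
# proportional to squared distance to the nearest chosen centre.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k == 1) return(centers)
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

lloyd <- function(x, centers, max_iter = 100L) {
  n <- nrow(x); k <- nrow(centers)
  labels <- integer(n)
  wcss_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(k), function(j)
      rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2),
      numeric(n))
    d2 <- matrix(d2, nrow = n)
    new_labels <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters with the point farthest from its centre
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        far <- which.max(d2[cbind(seq_len(n), new_labels)])
        new_labels[far] <- j
        centers[j, ] <- x[far, ]
      }
    }
    wcss_trace <- c(wcss_trace, sum(d2[cbind(seq_len(n), new_labels)]))
    if (it > 1 && identical(new_labels, labels)) break
    labels <- new_labels
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
  }
  d2 <- vapply(seq_len(k), function(j)
    rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2), numeric(n))
  d2 <- matrix(d2, nrow = n)
  wcss <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, wcss = wcss,
       wcss_trace = wcss_trace)
}

#' k-means clustering (Lloyd's algorithm, k-means++ seeding)
#'
#' Runs `n_restarts` independently seeded replicates and keeps the one
#' with the smallest within-cluster sum of squares. Deterministic given
#' `seed`.
#'
#' @param x numeric matrix, points in rows.
#' @param k number of clusters (`k <= nrow(x)`).
#' @param seed RNG seed.
#' @param n_restarts independent k-means++ restarts.
#' @return list with `labels` (1-based), `centers`, `wcss`, and the
#'   per-iteration `wcss_trace` of the winning restart (non-increasing).
#' @export
kmeans_cluster <- function(x, k, seed = 1, n_restarts = 10) {
  x <- as.matrix(x)
  if (k > nrow(x)) stopf("k = %d exceeds the number of points (%d)", k, nrow(x))
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd(x, kmeanspp_init(x, k))
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  best
}

# BIC of a k-cluster spherical-Gaussian model with shared per-dimension
# variance (larger is better). sigma2 is the ML pooled variance with the
# R - K small-sample correction of the x-means formulation.
spherical_bic <- function(x, labels, centers) {
  x <- as.matrix(x)
  R <- nrow(x); M <- ncol(x); K <- nrow(centers)
  rss <- sum((x - centers[labels, , drop = FALSE])^2)
  if (R <= K) return(-Inf)
  sigma2 <- rss / (M * (R - K))
  if (sigma2 < 1e-12) return(Inf)
  R_n <- tabulate(labels, nbins = K)
  loglik <- sum(R_n[R_n > 0] * log(R_n[R_n > 0])) - R * log(R) -
    (R * M / 2) * log(2 * pi * sigma2) - (M * (R - K)) / 2
  n_params <- (K - 1) + M * K + 1
  loglik - (n_params / 2) * log(R)
}

#' x-means: choose the number of clusters by BIC-scored splitting
#'
#' Starts from a `k_min`-means solution and repeatedly attempts to split
#' each centroid in two (a local 2-means on the cluster's points). A split
#' is accepted when it improves the spherical-Gaussian BIC on those
#' points; splitting continues until no split helps or `k_max` is reached.
#' With `k_min == k_max` this reduces exactly to [kmeans_cluster()].
#'
#' @param x numeric matrix, points in rows.
#' @param k_min,k_max cluster-count search range.
#' @param seed RNG seed (threaded into every k-means call).
#' @param n_restarts restarts per k-means invocation.
#' @return list with chosen `k`, `labels`, `centers`, `wcss`, and the
#'   global `bic` of the final model.
#' @export
xmeans_cluster <- function(x, k_min = 1, k_max, seed = 1, n_restarts = 10) {
  x <- as.matrix(x)
  if (k_min < 1) stopf("k_min must be >= 1")
  if (k_max > nrow(x)) stopf("k_max = %d exceeds the number of points (%d)",
                             k_max, nrow(x))
  if (k_min > k_max) stopf("k_min must be <= k_max")
  fit <- kmeans_cluster(x, k_min, seed = seed, n_restarts = n_restarts)
  labels <- fit$labels
  centers <- fit$centers
  k <- k_min
  # the search records every visited configuration; the returned model is
  # the one with the best global BIC, which guards against locally
  # attractive splits of a genuine single Gaussian
  snapshots <- list(list(k = k, labels = labels, centers = centers,
                         wcss = fit$wcss,
                         bic = spherical_bic(x, labels, centers)))
  round <- 0L
  while (k < k_max) {
    round <- round + 1L
    improvements <- data.frame(cluster = integer(0), gain = numeric(0))
    children <- list()
    for (j in seq_len(k)) {
      pts <- which(labels == j)
      if (length(pts) < 3) next              # a 2-way split needs R - K >= 1
      xj <- x[pts, , drop = FALSE]
      parent_bic <- spherical_bic(xj, rep(1L, length(pts)),
                                  matrix(colMeans(xj), nrow = 1))
      child <- kmeans_cluster(xj, 2,
                              seed = stage_seed(seed, "cluster") + 97L * round + j,
                              n_restarts = n_restarts)
      child_bic <- spherical_bic(xj, child$labels, child$centers)
      if (child_bic > parent_bic) {
        improvements <- rbind(improvements,
                              data.frame(cluster = j, gain = child_bic - parent_bic))
        children[[as.character(j)]] <- child
      }
    }
    if (nrow(improvements) == 0) break
    improvements <- improvements[order(-improvements$gain), , drop = FALSE]
    split_any <- FALSE
    for (j in improvements$cluster) {
      if (k >= k_max) break
      child <- children[[as.character(j)]]
      pts <- which(labels == j)
      k <- k + 1L
      labels[pts[child$labels == 2]] <- k
      centers[j, ] <- child$centers[1, ]
      centers <- rbind(centers, child$centers[2, ])
      split_any <- TRUE
    }
    if (!split_any) break
    # polish the full configuration from the current centroids
    polished <- lloyd(x, centers)
    labels <- polished$labels
    centers <- polished$centers
    snapshots[[length(snapshots) + 1L]] <-
      list(k = nrow(centers), labels = labels, centers = centers,
           wcss = polished$wcss, bic = spherical_bic(x, labels, centers))
  }
  best <- snapshots[[which.max(vapply(snapshots, `[[`, numeric(1), "bic"))]]
  list(k = best$k, labels = best$labels, centers = best$centers,
       wcss = best$wcss, bic = best$bic)
}

#' Per-group agreement with the modal cluster
#'
#' For each group (e.g. participant), the fraction of its members assigned
#' to the group's most frequent cluster. Ties between equally frequent
#' clusters break toward the lowest cluster index.
#'
#' @param labels integer cluster labels.
#' @param groups group membership vector of the same length.
#' @return named numeric vector of per-group fractions in \[0, 1\].
#' @export
cluster_agreement <- function(labels, groups) {
  if (length(labels) != length(groups))
    stopf("labels and groups must have equal length")
  vapply(split(labels, groups), function(l) {
    lev <- sort(unique(l))
    counts <- vapply(lev, function(v) sum(l == v), numeric(1))
    modal <- lev[which.max(counts)]             # which.max: first max = lowest id
    mean(l == modal)
  }, numeric(1))
}
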