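#' @title Pool-normalized cross-batch distance statistic
#' @description The empirical-Bayes correction can only integrate proteins
#'   observed in every batch, discarding most of the proteome. This module
#'   implements the complementary statistic that needs no intersection:
#'   PCA is run on each uncorrected batch separately, each sample's
#'   Euclidean distance to its own participant's unstimulated pool is
#'   measured in score space, and that distance is divided by the distance
#'   between the two pools of the same batch — which, carrying the same
#'   pooled material everywhere, should vary to the same degree in every
#'   batch. The ratio is comparable across batches.
#' @name crossbatch_variability
NULL

# PCA of a linear-scale intensity matrix: columns (samples) are the
# observations, proteins the variables; log2 then mean-centered per protein.
pca_scores <- function(values, n_components) {
  keep <- !apply(values, 1, anyNA)
  values <- values[keep, , drop = FALSE]
  n_samples <- ncol(values)
  max_comp <- min(n_samples - 1L, nrow(values))
  if (n_components > max_comp)
    stopf("n_components = %d exceeds min(samples - 1, proteins) = %d",
          n_components, max_comp)
  obs <- t(log2(values))                       # samples x proteins
  pc <- stats::prcomp(obs, center = TRUE, scale. = FALSE)
  scores <- pc$x
  ev <- pc$sdev^2
  list(scores = scores, explained_variance = ev / sum(ev),
       n_components = n_components, n_proteins_used = nrow(values),
       dropped = sum(!keep))
}

#' Per-batch PCA of an uncorrected protein matrix
#'
#' Projects one batch's samples onto the principal components of the
#' mean-centered log2 protein intensities. The input must be
#' reference-normalized but NOT batch-corrected: the statistic built on
#' these scores is precisely the alternative to batch correction.
#'
#' @param matrix a single-batch `protein_matrix` in state `"ref_normalized"`.
#'   Proteins with any missing value in the batch are dropped.
#' @param n_components number of score dimensions retained downstream.
#' @return list with `scores` (samples x components), monotone
#'   non-increasing `explained_variance` fractions, the column annotation,
#'   and bookkeeping counts.
#' @export
per_batch_pca <- function(matrix, n_components = 2) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (matrix$state %in% c("concatenated", "combat_corrected"))
    stopf("per-batch PCA requires an uncorrected (ref_normalized) single-batch matrix, not state '%s'",
          matrix$state)
  if (length(unique(matrix$columns$batch_id)) != 1)
    stopf("per_batch_pca expects a single-batch matrix")
  out <- pca_scores(matrix$values, n_components)
  out$columns <- matrix$columns
  out$batch_id <- matrix$columns$batch_id[1]
  out
}

#' Pool-relative Euclidean distances of one batch
#'
#' For every non-pool sample of the batch, computes the Euclidean distance
#' in the first `n_components` PCA score dimensions to the reference pool
#' of the same participant, and expresses it relative to the distance
#' between the batch's two pools.
#'
#' @param pca result of [per_batch_pca()].
#' @param n_components score dimensions used (defaults to the value the
#'   PCA was asked for).
#' @return a `distance_report` data frame with columns `batch_id`,
#'   `sample_id`, `participant`, `condition`, `raw_distance`,
#'   `relative_distance`, plus attributes `pool_pool_distance` and
#'   `n_components`.
#' @export
relative_distance <- function(pca, n_components = pca$n_components) {
  scores <- pca$scores[, seq_len(n_components), drop = FALSE]
  cols <- pca$columns
  pool_idx <- which(cols$is_reference_pool)
  if (length(pool_idx) != 2)
    stopf("batch %s: expected exactly 2 reference pools, found %d",
          pca$batch_id %||% "?", length(pool_idx))
  pp <- sqrt(sum((scores[pool_idx[1], ] - scores[pool_idx[2], ])^2))
  if (pp < 1e-12)
    stopf("batch %s: the two reference pools are coincident in score space; relative distances undefined",
          pca$batch_id %||% "?")
  sample_idx <- which(!cols$is_reference_pool)
  pool_of <- function(participant) {
    i <- pool_idx[cols$participant[pool_idx] == participant]
    if (length(i) != 1)
      stopf("no unique reference pool for participant %s", participant)
    i
  }
  raw <- vapply(sample_idx, function(i) {
    p <- pool_of(cols$participant[i])
    sqrt(sum((scores[i, ] - scores[p, ])^2))
  }, numeric(1))
  out <- data.frame(batch_id = cols$batch_id[sample_idx],
                    sample_id = cols$sample_id[sample_idx],
                    participant = cols$participant[sample_idx],
                    condition = cols$condition[sample_idx],
                    raw_distance = raw,
                    relative_distance = raw / pp,
                    stringsAsFactors = FALSE)
  attr(out, "pool_pool_distance") <- pp
  attr(out, "n_components") <- n_components
  class(out) <- c("distance_report", "data.frame")
  out
}

#' Pool-relative distances for every batch
#'
#' @param matrices named list of per-batch ref-normalized
#'   `protein_matrix` objects.
#' @param n_components score dimensions (2 by default, the plotted PCA
#'   plane).
#' @return a single `distance_report` stacking all batches; per-batch
#'   pool-pool distances in attribute `"pool_pool_distance"`.
#' @export
batch_relative_distances <- function(matrices, n_components = 2) {
  reports <- lapply(matrices, function(m)
    relative_distance(per_batch_pca(m, n_components)))
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  attr(out, "pool_pool_distance") <-
    vapply(reports, attr, numeric(1), "pool_pool_distance")
  attr(out, "n_components") <- n_components
  class(out) <- c("distance_report", "data.frame")
  out
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("distance_report: %d samples, %d batch(es), %d PCA component(s)\n",
              nrow(x), length(unique(x$batch_id)),
              attr(x, "n_components") %||% NA_integer_))
  NextMethod()
  invisible(x)
}

#' Summarize relative distances by participant and condition
#'
#' Mean and standard error (sd / sqrt(n)) of the pool-relative distance
#' over replicates; the SE is reported missing for single replicates.
#'
#' @param report a `distance_report` (typically over all batches).
#' @return data frame with columns `participant`, `condition`, `n`,
#'   `mean_relative_distance`, `se`.
#' @export
summarize_by_condition <- function(report) {
  key <- interaction(report$participant, report$condition, drop = TRUE)
  groups <- split(report$relative_distance, key)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    parts <- strsplit(g, ".", fixed = TRUE)[[1]]
    data.frame(participant = parts[1],
               condition = paste(parts[-1], collapse = "."),
               n = length(v),
               mean_relative_distance = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out[order(out$participant, out$condition), ]
}
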