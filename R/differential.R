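#' @title Differential protein abundance vs unstimulated reference
#' @description Because every peptide is normalized to the geometric mean
#'   of its batch's two unstimulated pools, the unstimulated level is 1 by
#'   construction. A condition's fold change is the geometric mean of its
#'   normalized sample values across both participants, and significance is
#'   a two-sided one-sample t-test of the log2 values against 0, pooling
#'   both participants' replicates.
#' @name differential
NULL

# columns of a protein matrix belonging to a condition (both participants)
condition_columns <- function(matrix, condition) {
  which(matrix$columns$condition == condition &
          !matrix$columns$is_reference_pool)
}

#' Fold change of a condition vs the unstimulated pools
#'
#' Computed as the ratio of two geometric means: the condition's sample
#' columns over all reference-pool columns. On reference-normalized data
#' the pool geomean is 1 per batch, so the ratio reduces to the geomean of
#' the normalized sample values; both forms are available (the reduced
#' form is the attribute `"geomean_form"`).
#'
#' @param matrix a `protein_matrix` (ref-normalized, concatenated or
#'   batch-corrected).
#' @param condition condition label with >= 1 sample column per participant.
#' @return named numeric vector of per-protein linear fold changes.
#' @export
fold_change <- function(matrix, condition) {
  j <- condition_columns(matrix, condition)
  if (length(j) == 0) stopf("condition %s has no sample columns", condition)
  pools <- which(matrix$columns$is_reference_pool)
  if (length(pools) == 0) stopf("matrix has no reference-pool columns")
  num <- exp(rowMeans(log(matrix$values[, j, drop = FALSE])))
  den <- exp(rowMeans(log(matrix$values[, pools, drop = FALSE])))
  fc <- num / den
  attr(fc, "geomean_form") <- num
  fc
}

#' One-sample t-test of a condition against the reference level
#'
#' Two-sided t-test of the log2 normalized values of the condition's
#' replicate columns (both participants pooled) against 0, with exact
#' p-values from the t distribution on n - 1 degrees of freedom. Proteins
#' with zero variance across replicates get a missing p-value (counted in
#' attribute `"zero_variance"`).
#'
#' @param matrix a `protein_matrix`.
#' @param condition condition label with >= 2 replicate columns.
#' @return data frame with columns `protein`, `n`, `mean_log2`, `t`, `p`.
#' @export
test_regulation <- function(matrix, condition) {
  j <- condition_columns(matrix, condition)
  if (length(j) < 2)
    stopf("condition %s has %d replicate column(s); t-test needs >= 2",
          condition, length(j))
  x <- log2(matrix$values[, j, drop = FALSE])
  n <- ncol(x)
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  out <- data.frame(protein = rownames(matrix$values), n = n,
                    mean_log2 = m, t = t_stat, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "zero_variance") <- out$protein[s == 0]
  out
}

#' Call up/down regulation from fold changes and p-values
#'
#' A protein is called `up` when p < alpha and its fold change reaches
#' `up_threshold`, `down` when p < alpha and the fold change is at or
#' below `down_threshold`, otherwise `none`. Benjamini-Hochberg adjusted
#' p-values are reported alongside but do not gate the call by default.
#'
#' @param fold_changes named numeric vector (linear scale) from
#'   [fold_change()].
#' @param tests data frame from [test_regulation()].
#' @param condition condition label recorded on the result.
#' @param alpha raw-p significance gate.
#' @param up_threshold,down_threshold linear fold-change cutoffs
#'   (`up_threshold > 1`, `0 < down_threshold < 1`).
#' @return a `differential_result` data frame: `protein`, `condition`,
#'   `fold_change`, `p`, `adjusted_p`, `call`, `n`.
#' @export
call_regulation <- function(fold_changes, tests, condition,
                            alpha = 0.05, up_threshold = 1.5,
                            down_threshold = 0.667) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (up_threshold <= 1) stopf("up_threshold must be > 1")
  if (down_threshold <= 0 || down_threshold >= 1)
    stopf("down_threshold must lie in (0, 1)")
  fc <- unname(fold_changes[tests$protein])
  p <- tests$p
  call <- rep("none", nrow(tests))
  sig <- !is.na(p) & p < alpha
  call[sig & fc >= up_threshold] <- "up"
  call[sig & fc <= down_threshold] <- "down"
  out <- data.frame(protein = tests$protein,
                    condition = condition,
                    fold_change = fc,
                    p = p,
                    adjusted_p = stats::p.adjust(p, method = "BH"),
                    call = call,
                    n = tests$n,
                    stringsAsFactors = FALSE)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("differential_result: %d proteins x %d condition(s); %d up, %d down\n",
              length(unique(x$protein)), length(unique(x$condition)),
              sum(x$call == "up"), sum(x$call == "down")))
  NextMethod()
  invisible(x)
}

#' Differential table over all conditions
#'
#' @param matrix a `protein_matrix`.
#' @param conditions condition labels to test; defaults to every non-pool,
#'   non-empty condition in the matrix with >= 2 replicates.
#' @param ... thresholds passed to [call_regulation()].
#' @return a `differential_result` stacking all conditions.
#' @export
differential_table <- function(matrix, conditions = NULL, ...) {
  if (is.null(conditions)) {
    cand <- setdiff(unique(matrix$columns$condition), c("unstimulated", "empty"))
    conditions <- cand[vapply(cand, function(cc)
      length(condition_columns(matrix, cc)) >= 2, logical(1))]
  }
  out <- do.call(rbind, lapply(conditions, function(cc) {
    call_regulation(fold_change(matrix, cc), test_regulation(matrix, cc), cc, ...)
  }))
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  out
}

#' GO-style over-representation by one-sided Fisher test
#'
#' For each term, tests over-representation of the term's proteins in the
#' foreground against the background (hypergeometric upper tail including
#' the observed overlap), with Benjamini-Hochberg adjustment over the
#' tested terms.
#'
#' @param foreground protein id set (must be a subset of `background`).
#' @param background protein id universe.
#' @param annotation named list: term -> character vector of protein ids.
#' @return data frame with `term`, `overlap`, `term_size`, `p`,
#'   `adjusted_p`, sorted by p.
#' @export
go_enrichment <- function(foreground, background, annotation) {
  if (length(annotation) == 0) stopf("annotation is empty")
  if (!all(foreground %in% background))
    stopf("foreground contains ids absent from the background")
  bg <- unique(background)
  fg <- unique(foreground)
  N <- length(bg); n <- length(fg)
  out <- do.call(rbind, lapply(names(annotation), function(term) {
    ann <- intersect(unique(annotation[[term]]), bg)
    K <- length(ann)
    k <- length(intersect(ann, fg))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = k, term_size = K, p = p,
               stringsAsFactors = FALSE)
  }))
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Read a GMT-style annotation file
#'
#' Tab-delimited lines: term, description, then protein ids.
#'
#' @param path file path.
#' @return named list term -> protein id vector.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  out <- lapply(lines, function(f) f[-(1:2)])
  names(out) <- vapply(lines, `[[`, character(1), 1)
  out
}
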