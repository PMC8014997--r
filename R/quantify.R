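#' @title Quantification core: filtering, normalization, roll-up
#' @description PSMs are filtered (unassigned, missing or zero channel
#'   intensities, q-value above threshold), reporter intensities are
#'   normalized per batch by sum scaling (equalizing channel totals) and to
#'   the geometric mean of the two reference-pool channels of each peptide,
#'   then rolled up to one intensity per primary accession by geometric
#'   mean over peptides. Normalization runs at peptide level because the
#'   pool reference is defined per peptide.
#' @name quantify
NULL

#' Filter peptide-spectrum matches
#'
#' Removes records that are unassigned (no accession), have a missing or
#' zero intensity in any channel their batch declares, or exceed the
#' q-value threshold. Zero intensities are treated as missing because both
#' the geometric mean and the log transform are undefined at zero. Each
#' removed record is counted once, under the first matching rule in the
#' order unassigned, missing-channel, zero-intensity, q-value.
#'
#' @param psms a `psm_table`.
#' @param design the `batch_design` declaring each batch's channels.
#' @param q_threshold records with `q_value` above this are removed;
#'   records with no q-value (pre-filtered upstream) pass this rule.
#' @return the filtered `psm_table`; the per-rule removal counts are
#'   attached as attribute `"filter_log"` (see [filter_log()]).
#' @export
filter_psms <- function(psms, design, q_threshold = 0.05) {
  stopifnot(inherits(psms, "psm_table"))
  if (q_threshold <= 0 || q_threshold > 1)
    stopf("q_threshold must lie in (0, 1]")
  n <- nrow(psms)
  prim <- primary_accession(psms)
  unassigned <- is.na(prim)

  missing_ch <- logical(n)
  zero_ch <- logical(n)
  for (b in unique(psms$batch_id)) {
    rows <- which(psms$batch_id == b)
    chans <- batch_channels(design, b)
    vals <- as.matrix(psms[rows, chans, drop = FALSE])
    missing_ch[rows] <- apply(vals, 1, anyNA)
    zero_ch[rows] <- apply(vals, 1, function(v) any(!is.na(v) & v == 0))
  }
  high_q <- !is.na(psms$q_value) & psms$q_value > q_threshold

  rule <- rep(NA_character_, n)
  rule[high_q] <- "q-value"
  rule[zero_ch] <- "zero-intensity"
  rule[missing_ch] <- "missing-channel"
  rule[unassigned] <- "unassigned"

  keep <- is.na(rule)
  log <- list(input = n,
              unassigned = sum(rule == "unassigned", na.rm = TRUE),
              `missing-channel` = sum(rule == "missing-channel", na.rm = TRUE),
              `zero-intensity` = sum(rule == "zero-intensity", na.rm = TRUE),
              `q-value` = sum(rule == "q-value", na.rm = TRUE),
              retained = sum(keep))
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_psm_table(out, attr(psms, "batch_ids"))
  attr(out, "filter_log") <- log
  out
}

#' Filter log of a filtered PSM table
#'
#' @param psms a `psm_table` returned by [filter_psms()].
#' @return named list of removal counts per rule.
#' @export
filter_log <- function(psms) attr(psms, "filter_log")

#' Build the peptide-level intensity matrix of one batch
#'
#' Rows are the batch's (filtered) PSMs, columns its non-empty channels.
#' All values must be present and positive, which [filter_psms()]
#' guarantees.
#'
#' @param psms a filtered `psm_table`.
#' @param design the `batch_design`.
#' @param batch_id which batch to extract.
#' @return a `peptide_matrix` in state `"raw"`.
#' @export
peptide_matrix <- function(psms, design, batch_id) {
  rows <- which(psms$batch_id == batch_id)
  if (length(rows) == 0) stopf("batch %s has no PSMs", batch_id)
  cols <- design[design$batch_id == batch_id & design$condition != "empty", ]
  vals <- as.matrix(psms[rows, cols$channel, drop = FALSE])
  rownames(vals) <- NULL
  structure(list(values = vals,
                 peptide = psms$peptide[rows],
                 accession = primary_accession(psms[rows, , drop = FALSE]),
                 batch_id = batch_id,
                 columns = cols,
                 state = "raw"),
            class = "peptide_matrix")
}

#' @export
print.peptide_matrix <- function(x, ...) {
  cat(sprintf("peptide_matrix [%s]: batch %s, %d PSMs x %d channels\n",
              x$state, x$batch_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Sum scaling: equalize channel totals within a batch
#'
#' Multiplies each channel by (mean column total) / (that channel's
#' total), the standard loading correction for reporter-ion channels.
#' Afterwards all column totals equal the mean of the input totals; the
#' operation is idempotent.
#'
#' @param mat a `peptide_matrix` (state `"raw"` or `"sum_scaled"`).
#' @return the matrix with state `"sum_scaled"`.
#' @export
sum_scale <- function(mat) {
  stopifnot(inherits(mat, "peptide_matrix"))
  check_state_transition(mat$state, "sum_scaled")
  totals <- colSums(mat$values)
  if (any(totals == 0))
    stopf("channel %s has zero total intensity; cannot sum-scale",
          mat$columns$channel[which(totals == 0)[1]])
  mat$values <- sweep(mat$values, 2, mean(totals) / totals, `*`)
  mat$state <- "sum_scaled"
  mat
}

#' Normalize each peptide to its reference-pool geometric mean
#'
#' Divides every peptide row by the geometric mean of its two
#' reference-pool channel values, so that each row's pool geomean becomes
#' exactly 1 and intensities are expressed relative to pooled unstimulated
#' saliva. Peptides with a zero pool value cannot be normalized and are
#' dropped (counted in attribute `"norm_log"`).
#'
#' @param mat a sum-scaled `peptide_matrix`.
#' @param design unused; pool channels come from the matrix's own column
#'   annotation (argument kept for pipeline symmetry).
#' @return the matrix with state `"ref_normalized"`.
#' @export
normalize_to_reference <- function(mat, design = NULL) {
  stopifnot(inherits(mat, "peptide_matrix"))
  check_state_transition(mat$state, "ref_normalized")
  pool_idx <- which(mat$columns$is_reference_pool)
  if (length(pool_idx) != 2)
    stopf("batch %s has %d reference-pool channels; exactly 2 required",
          mat$batch_id, length(pool_idx))
  pools <- mat$values[, pool_idx, drop = FALSE]
  bad <- which(apply(pools, 1, function(v) any(v == 0)))
  if (length(bad) > 0) {
    mat$values <- mat$values[-bad, , drop = FALSE]
    mat$peptide <- mat$peptide[-bad]
    mat$accession <- mat$accession[-bad]
    pools <- pools[-bad, , drop = FALSE]
  }
  ref <- sqrt(pools[, 1] * pools[, 2])
  mat$values <- mat$values / ref
  mat$state <- "ref_normalized"
  attr(mat, "norm_log") <- list(zero_pool_dropped = length(bad))
  mat
}

#' Roll peptides up to protein intensities
#'
#' Groups PSMs by primary accession and takes the geometric mean of the
#' peptide intensities per channel as the protein intensity value. Records
#' the peptide (PSM) count per protein.
#'
#' @param mat a `peptide_matrix` whose rows all carry a primary accession.
#' @return a `protein_matrix` for the batch, inheriting the peptide
#'   matrix's normalization state.
#' @export
rollup_proteins <- function(mat) {
  stopifnot(inherits(mat, "peptide_matrix"))
  if (anyNA(mat$accession))
    stopf("peptide matrix contains rows without a primary accession; filter first")
  acc <- mat$accession
  proteins <- sort(unique(acc))
  logv <- log(mat$values)
  grouped <- rowsum(logv, group = acc)            # sums of logs per protein
  counts <- as.vector(table(acc)[rownames(grouped)])
  vals <- exp(grouped / counts)
  vals <- vals[proteins, , drop = FALSE]
  np <- counts[match(proteins, rownames(grouped))]
  names(np) <- proteins
  new_protein_matrix(vals, mat$columns, state = mat$state, n_peptides = np)
}

#' Quantify all batches of a PSM table
#'
#' Convenience wrapper running the canonical per-batch chain
#' filter -> sum_scale -> normalize_to_reference -> rollup_proteins.
#'
#' @param psms a `psm_table` (unfiltered).
#' @param design the `batch_design`.
#' @param q_threshold passed to [filter_psms()].
#' @param sum_scaling apply the channel-total equalization step. Sum
#'   scaling corrects loading differences but also absorbs genuine total
#'   abundance shifts caused by regulated proteins, slightly compressing
#'   fold changes (negligible when regulated proteins are a small fraction
#'   of total signal); set `FALSE` to normalize to the reference pools only.
#' @return list with `matrices` (named list of per-batch ref-normalized
#'   `protein_matrix` objects) and `filter_log`.
#' @export
quantify_batches <- function(psms, design, q_threshold = 0.05,
                             sum_scaling = TRUE) {
  filtered <- filter_psms(psms, design, q_threshold)
  batches <- intersect(unique(design$batch_id), unique(filtered$batch_id))
  mats <- lapply(batches, function(b) {
    pm <- peptide_matrix(filtered, design, b)
    if (sum_scaling) pm <- sum_scale(pm)
    pm <- normalize_to_reference(pm)
    rollup_proteins(pm)
  })
  names(mats) <- batches
  list(matrices = mats, filter_log = filter_log(filtered))
}
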