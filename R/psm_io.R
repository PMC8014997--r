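#' @title PSM tables, batch designs and protein matrices on disk
#' @description All three interchange formats are tab-delimited text.
#'   PSM tables have one row per peptide-spectrum match with one intensity
#'   column per reporter channel; protein matrices carry `batch:channel`
#'   column headers plus `#`-prefixed metadata lines recording the
#'   normalization state and a design fingerprint. Readers reject malformed
#'   rows with row numbers rather than coercing silently.
#' @name psm_io
NULL

new_psm_table <- function(df, batch_ids) {
  stopifnot(all(c("peptide", "accessions", "q_value", "batch_id") %in% names(df)))
  if (!all(df$batch_id %in% batch_ids))
    stopf("psm table contains batch ids outside the declared set")
  attr(df, "batch_ids") <- batch_ids
  class(df) <- c("psm_table", "data.frame")
  df
}

# intensity column names of a psm_table
psm_channel_cols <- function(psms) {
  setdiff(names(psms), c("peptide", "accessions", "q_value", "batch_id"))
}

#' Split a semicolon-joined accession field
#'
#' The first listed accession is the primary one under which peptides are
#' grouped at roll-up.
#'
#' @param x character vector of accession fields (possibly "").
#' @return list of character vectors (possibly empty).
#' @export
split_accessions <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(a) a[nzchar(a)])
}

#' Primary accession of each PSM
#'
#' @param psms a `psm_table`.
#' @return character vector; `NA` where a record carries no accession.
#' @export
primary_accession <- function(psms) {
  acc <- split_accessions(psms$accessions)
  vapply(acc, function(a) if (length(a) == 0) NA_character_ else a[[1]],
         character(1))
}

#' @export
print.psm_table <- function(x, ...) {
  cat(sprintf("psm_table: %d PSMs, %d batches, %d channels\n",
              nrow(x), length(unique(x$batch_id)),
              length(psm_channel_cols(x))))
  invisible(x)
}

#' Read a PSM table
#'
#' Expects a tab-delimited file with header columns `peptide`,
#' `accessions` (semicolon-joined, primary first), `q_value`, `batch`,
#' then one column per reporter channel. Empty intensity fields are parsed
#' as missing; rows are kept verbatim (filtering happens in
#' [filter_psms()]).
#'
#' @param path file path.
#' @param design the `batch_design` the table must conform to.
#' @return a `psm_table`.
#' @export
read_psm_table <- function(path, design) {
  if (!file.exists(path)) stopf("PSM table not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", comment.char = "")
  fixed <- c("peptide", "accessions", "q_value", "batch")
  if (!all(fixed %in% names(df)))
    stopf("PSM table header must contain: %s", paste(fixed, collapse = ", "))
  chan_cols <- setdiff(names(df), fixed)
  known_channels <- unique(design$channel)
  bad <- setdiff(chan_cols, known_channels)
  if (length(bad) > 0)
    stopf("PSM table declares channel(s) absent from the design: %s",
          paste(bad, collapse = ", "))
  batch_ids <- unique(design$batch_id)
  bad_batch <- which(!(df$batch %in% batch_ids))
  if (length(bad_batch) > 0)
    stopf("row %d: unknown batch id '%s'", bad_batch[1], df$batch[bad_batch[1]])

  out <- data.frame(peptide = df$peptide,
                    accessions = df$accessions,
                    q_value = suppressWarnings(as.numeric(df$q_value)),
                    batch_id = df$batch,
                    stringsAsFactors = FALSE)
  for (ch in chan_cols) {
    raw <- df[[ch]]
    v <- suppressWarnings(as.numeric(raw))
    v[!nzchar(raw)] <- NA_real_
    unparsed <- which(nzchar(raw) & is.na(v) & raw != "NA")
    if (length(unparsed) > 0)
      stopf("row %d: non-numeric intensity '%s' in channel %s",
            unparsed[1], raw[unparsed[1]], ch)
    neg <- which(!is.na(v) & v < 0)
    if (length(neg) > 0)
      stopf("row %d: negative intensity %g in channel %s", neg[1], v[neg[1]], ch)
    out[[ch]] <- v
  }
  # every record must carry exactly the channels its batch declares
  for (b in unique(out$batch_id)) {
    declared <- batch_channels(design, b)
    miss <- setdiff(declared, chan_cols)
    if (length(miss) > 0)
      stopf("batch %s declares channel(s) absent from the table: %s",
            b, paste(miss, collapse = ", "))
  }
  new_psm_table(out, batch_ids)
}

#' Write a PSM table
#'
#' @param psms a `psm_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  df <- as.data.frame(psms)
  names(df)[names(df) == "batch_id"] <- "batch"
  chan <- psm_channel_cols(psms)
  for (ch in chan) df[[ch]] <- ifelse(is.na(df[[ch]]), "",
                                      format(df[[ch]], digits = 15, trim = TRUE,
                                             scientific = FALSE))
  df$q_value <- ifelse(is.na(df$q_value), "",
                       format(df$q_value, digits = 15, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a batch design
#'
#' Tab-delimited with columns `batch_id`, `channel`, `sample_id`,
#' `participant`, `condition`, `concentration_ppm`, `is_reference_pool`.
#' Reference pools may alternatively be flagged by the `.P` sample-id
#' suffix if the flag column is absent.
#'
#' @param path file path.
#' @return a validated `batch_design`.
#' @export
read_batch_design <- function(path) {
  if (!file.exists(path)) stopf("batch design not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "character", na.strings = "NA",
                          quote = "", comment.char = "#")
  if (!"is_reference_pool" %in% names(df))
    df$is_reference_pool <- grepl("\\.P$", df$sample_id)
  else
    df$is_reference_pool <- df$is_reference_pool %in% c("TRUE", "true", "1")
  if (!"concentration_ppm" %in% names(df)) df$concentration_ppm <- NA_real_
  df$concentration_ppm <- suppressWarnings(as.numeric(df$concentration_ppm))
  df$condition[is.na(df$condition)] <- ""
  new_batch_design(df)
}

#' Write a batch design
#'
#' @param design a `batch_design`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_batch_design <- function(design, path) {
  df <- as.data.frame(design)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- protein / peptide intensity matrices ---------------------------------

MATRIX_STATES <- c("raw", "sum_scaled", "ref_normalized", "concatenated",
                   "combat_corrected")

# state may only move forward through the normalization pipeline
check_state_transition <- function(from, to) {
  i <- match(from, MATRIX_STATES)
  j <- match(to, MATRIX_STATES)
  if (is.na(i) || is.na(j)) stopf("unknown matrix state: %s", if (is.na(i)) from else to)
  if (j < i)
    stopf("illegal state transition %s -> %s: states only move forward", from, to)
  invisible(TRUE)
}

new_protein_matrix <- function(values, columns, state, n_peptides = NULL) {
  stopifnot(is.matrix(values), nrow(columns) == ncol(values))
  if (!state %in% MATRIX_STATES) stopf("unknown matrix state: %s", state)
  colnames(values) <- paste0(columns$batch_id, ":", columns$channel)
  structure(list(values = values, columns = columns, state = state,
                 n_peptides = n_peptides),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix [%s]: %d proteins x %d columns (%d batches)\n",
              x$state, nrow(x$values), ncol(x$values),
              length(unique(x$columns$batch_id))))
  invisible(x)
}

#' Write a protein matrix
#'
#' Tab-delimited, proteins as rows and `batch:channel` column headers,
#' preceded by `#`-prefixed metadata lines recording the normalization
#' state and a design fingerprint. Missing values serialize as `NA`.
#' Round-trips to 12 significant digits.
#'
#' @param matrix a `protein_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_protein_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# state: %s", matrix$state), con)
  writeLines(sprintf("# design_hash: %s", fnv1a_hash(matrix$columns)), con)
  meta <- matrix$columns
  writeLines(sprintf("# column %s\t%s\t%s\t%s\t%s\t%s", meta$batch_id,
                     meta$channel, meta$sample_id, meta$participant,
                     meta$condition, meta$is_reference_pool), con)
  header <- paste(c("protein", colnames(matrix$values)), collapse = "\t")
  writeLines(header, con)
  vals <- format(matrix$values, digits = 15, trim = TRUE, scientific = TRUE)
  vals[is.na(matrix$values)] <- "NA"
  body <- apply(cbind(rownames(matrix$values), vals), 1, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a protein matrix
#'
#' @param path a file written by [write_protein_matrix()].
#' @return a `protein_matrix` with its recorded state and column annotation.
#' @export
read_protein_matrix <- function(path) {
  if (!file.exists(path)) stopf("protein matrix not found: %s", path)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  state_line <- grep("^# state: ", meta, value = TRUE)
  if (length(state_line) != 1)
    stopf("protein matrix %s: missing '# state:' header line", path)
  state <- sub("^# state: ", "", state_line)
  if (!state %in% MATRIX_STATES)
    stopf("protein matrix %s: unknown state '%s'", path, state)
  col_lines <- grep("^# column ", meta, value = TRUE)
  cols <- do.call(rbind, strsplit(sub("^# column ", "", col_lines), "\t"))
  columns <- data.frame(batch_id = cols[, 1], channel = cols[, 2],
                        sample_id = cols[, 3], participant = cols[, 4],
                        condition = cols[, 5],
                        concentration_ppm = NA_real_,
                        is_reference_pool = cols[, 6] == "TRUE",
                        stringsAsFactors = FALSE)
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = "NA")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  if (ncol(vals) != nrow(columns))
    stopf("protein matrix %s: column annotation does not match data columns", path)
  new_protein_matrix(vals, columns, state)
}
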