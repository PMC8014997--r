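#' @title Batch designs for TMT10plex experiments
#' @description A batch design maps every TMT channel of every batch to a
#'   sample: which participant it came from, which stimulation condition it
#'   carries, and whether it is one of the pooled unstimulated reference
#'   channels that bridge batches. Reference pools are participant-specific:
#'   each batch carries exactly one pool channel per participant.
#' @name batch_design
NULL

# TMT10plex reporter channel labels, low to high mass.
TMT10_CHANNELS <- c("126", "127_N", "127_C", "128_N", "128_C",
                    "129_N", "129_C", "130_N", "130_C", "131")

new_batch_design <- function(df) {
  needed <- c("batch_id", "channel", "sample_id", "participant",
              "condition", "concentration_ppm", "is_reference_pool")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stopf("batch design lacks columns: %s", paste(missing_cols, collapse = ", "))
  df <- df[needed]
  df$batch_id <- as.character(df$batch_id)
  df$channel <- as.character(df$channel)
  df$sample_id <- as.character(df$sample_id)
  df$participant <- as.character(df$participant)
  df$condition <- as.character(df$condition)
  df$concentration_ppm <- as.numeric(df$concentration_ppm)
  df$is_reference_pool <- as.logical(df$is_reference_pool)
  rownames(df) <- NULL
  class(df) <- c("batch_design", "data.frame")
  validate_design(df)
  df
}

#' Validate a batch design
#'
#' Checks the structural contract: unique channel labels within each batch
#' and exactly one reference-pool channel per participant per batch.
#' Channels marked `condition == "empty"` are spare slots and are ignored
#' by all downstream stages.
#'
#' @param design a `batch_design`.
#' @return the design, invisibly, or an error describing the violation.
#' @export
validate_design <- function(design) {
  for (b in unique(design$batch_id)) {
    sub <- design[design$batch_id == b, ]
    if (anyDuplicated(sub$channel))
      stopf("batch %s declares duplicate channel labels", b)
    pools <- sub[sub$is_reference_pool, ]
    participants <- unique(sub$participant[sub$condition != "empty"])
    if (anyDuplicated(pools$participant))
      stopf("batch %s has more than one reference pool for participant %s",
            b, pools$participant[duplicated(pools$participant)][1])
    absent <- setdiff(participants, pools$participant)
    if (length(absent) > 0)
      stopf("batch %s lacks a reference pool for participant %s", b, absent[1])
  }
  invisible(design)
}

#' Generate a randomized multi-batch TMT design
#'
#' Lays out `participants * length(conditions) * repeats` experimental
#' samples across `n_batches` TMT runs. The first `participants` channels of
#' every batch carry the pooled unstimulated reference of each participant
#' (sample ids `"1.P"`, `"2.P"`, ...); the remaining channels receive the
#' experimental samples in an order randomized by `seed`. Channels left over
#' in undersized designs are flagged `condition = "empty"` and excluded by
#' every downstream stage.
#'
#' Whenever every condition can be given its own dedicated channel(s) —
#' as in the canonical 10plex layout, where each condition owns one
#' channel across all batches — that balanced assignment is used, so
#' replicates of a condition never share a batch (they would otherwise
#' share that batch's pool reference and be correlated after
#' normalization). The condition-to-channel mapping and the dealing of
#' samples to batches are both randomized by `seed`. If the balanced
#' layout does not fit, samples are scattered freely over the
#' experimental channels.
#'
#' @param n_batches number of TMT batches (plexes).
#' @param participants number of participants, each contributing one pooled
#'   reference channel per batch.
#' @param conditions character vector of condition labels; optionally named
#'   by label in `concentrations`.
#' @param repeats replicate collections per (participant, condition).
#' @param channels_per_batch channels per TMT run (10 for TMT10plex).
#' @param concentrations optional named numeric of agonist concentrations
#'   (ppm) per condition label.
#' @param seed integer seed controlling the randomized layout.
#' @return a `batch_design` data frame.
#' @examples
#' d <- generate_design(n_batches = 6, participants = 2,
#'                      conditions = paste0("cond", 1:8), repeats = 3, seed = 1)
#' table(d$is_reference_pool)
#' @export
generate_design <- function(n_batches = 6, participants = 2, conditions,
                            repeats = 3, channels_per_batch = 10,
                            concentrations = NULL, seed = 1) {
  if (n_batches < 1) stopf("n_batches must be >= 1")
  if (channels_per_batch < participants + 1)
    stopf("channels_per_batch must exceed the number of reference pools")
  n_samples <- participants * length(conditions) * repeats
  capacity <- n_batches * (channels_per_batch - participants)
  if (n_samples > capacity)
    stopf("design infeasible: %d samples exceed capacity %d (%d batches x %d experimental channels)",
          n_samples, capacity, n_batches, channels_per_batch - participants)

  channels <- if (channels_per_batch <= 10) {
    TMT10_CHANNELS[seq_len(channels_per_batch)]
  } else {
    sprintf("ch%02d", seq_len(channels_per_batch))
  }

  set.seed(as.integer(seed))
  exp_channels <- channels[-seq_len(participants)]
  n_cond <- length(conditions)
  per_cond <- participants * repeats
  chans_per_cond <- ceiling(per_cond / n_batches)
  balanced <- n_cond * chans_per_cond <= length(exp_channels)

  # (batch, channel) -> sample assignment table, filled below
  grid <- expand.grid(batch = seq_len(n_batches), channel = exp_channels,
                      stringsAsFactors = FALSE)
  grid$sample_id <- ""
  grid$participant <- ""
  grid$condition <- "empty"

  if (balanced) {
    cond_order <- sample(conditions)
    for (ci in seq_along(cond_order)) {
      cond <- cond_order[ci]
      own <- exp_channels[seq((ci - 1) * chans_per_cond + 1, ci * chans_per_cond)]
      slots <- which(grid$channel %in% own)
      slots <- slots[sample.int(length(slots))]
      samples <- expand.grid(participant = as.character(seq_len(participants)),
                             rep = seq_len(repeats), stringsAsFactors = FALSE)
      samples <- samples[sample.int(nrow(samples)), , drop = FALSE]
      take <- slots[seq_len(nrow(samples))]
      grid$sample_id[take] <- paste0(samples$participant, ".", samples$rep)
      grid$participant[take] <- samples$participant
      grid$condition[take] <- cond
    }
  } else {
    samples <- expand.grid(participant = as.character(seq_len(participants)),
                           condition = conditions,
                           rep = seq_len(repeats),
                           stringsAsFactors = FALSE)
    samples <- samples[sample.int(nrow(samples)), , drop = FALSE]
    slots <- order(grid$batch)[seq_len(nrow(samples))]
    grid$sample_id[slots] <- paste0(samples$participant, ".", samples$rep)
    grid$participant[slots] <- samples$participant
    grid$condition[slots] <- samples$condition
  }

  rows <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    batch_id <- paste0("batch", b)
    pool <- data.frame(batch_id = batch_id,
                       channel = channels[seq_len(participants)],
                       sample_id = paste0(seq_len(participants), ".P"),
                       participant = as.character(seq_len(participants)),
                       condition = "unstimulated",
                       concentration_ppm = NA_real_,
                       is_reference_pool = TRUE,
                       stringsAsFactors = FALSE)
    gb <- grid[grid$batch == b, , drop = FALSE]
    gb <- gb[match(exp_channels, gb$channel), , drop = FALSE]
    expr <- data.frame(batch_id = batch_id,
                       channel = gb$channel,
                       sample_id = gb$sample_id,
                       participant = gb$participant,
                       condition = gb$condition,
                       concentration_ppm = if (is.null(concentrations))
                         NA_real_ else unname(concentrations[gb$condition]),
                       is_reference_pool = FALSE,
                       stringsAsFactors = FALSE)
    rows[[b]] <- rbind(pool, expr)
  }
  new_batch_design(do.call(rbind, rows))
}

#' The canonical 6-batch TMT10plex saliva design
#'
#' The study layout this package emulates: six TMT10plex batches, two
#' participants, channels 126 and 127_N carrying each participant's pooled
#' unstimulated reference in every batch, and eight mouth-rinse conditions
#' (vehicle at two concentrations plus three TRP-channel agonists at two
#' concentrations each) distributed over the remaining eight channels.
#' Sample ids are `participant.repeat`.
#'
#' @return a `batch_design` with 60 rows (6 batches x 10 channels).
#' @export
tmt10_saliva_design <- function() {
  conds <- list(
    c("127_C", "cinnamaldehyde", 180,   "2.2", "1.2", "1.3", "2.1", "1.1", "2.3"),
    c("128_N", "nonivamide",     0.6,   "1.2", "2.1", "1.1", "2.2", "2.3", "1.3"),
    c("128_C", "cinnamaldehyde", 300,   "1.1", "1.3", "2.1", "2.2", "1.2", "2.3"),
    c("129_N", "pg",             30000, "1.1", "2.2", "2.3", "1.2", "1.3", "2.1"),
    c("129_C", "menthol",        500,   "2.3", "1.2", "1.3", "2.2", "2.1", "1.1"),
    c("130_N", "pg",             18000, "2.2", "2.1", "1.3", "1.1", "2.3", "2.1"),
    c("130_C", "menthol",        300,   "2.2", "1.2", "2.1", "1.3", "1.1", "2.3"),
    c("131",   "nonivamide",     1,     "1.2", "2.1", "1.3", "2.2", "1.1", "2.3")
  )
  rows <- list()
  for (b in 1:6) {
    batch_id <- paste0("batch", b)
    rows[[length(rows) + 1L]] <- data.frame(
      batch_id = batch_id, channel = c("126", "127_N"),
      sample_id = c("1.P", "2.P"), participant = c("1", "2"),
      condition = "unstimulated", concentration_ppm = NA_real_,
      is_reference_pool = TRUE, stringsAsFactors = FALSE)
    for (cc in conds) {
      sid <- cc[[3 + b]]
      rows[[length(rows) + 1L]] <- data.frame(
        batch_id = batch_id, channel = cc[[1]],
        sample_id = sid, participant = substr(sid, 1, 1),
        condition = paste0(cc[[2]], "_", cc[[3]]),
        concentration_ppm = as.numeric(cc[[3]]),
        is_reference_pool = FALSE, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(match(df$batch_id, unique(df$batch_id)),
                 match(df$channel, TMT10_CHANNELS)), ]
  new_batch_design(df)
}

#' @export
print.batch_design <- function(x, ...) {
  cat(sprintf("TMT batch design: %d batches, %d channels/batch, %d reference pools\n",
              length(unique(x$batch_id)),
              max(table(x$batch_id)),
              sum(x$is_reference_pool)))
  conds <- setdiff(unique(x$condition), c("unstimulated", "empty"))
  cat(" conditions:", paste(conds, collapse = ", "), "\n")
  NextMethod()
  invisible(x)
}

# Channels a batch declares, in design order.
batch_channels <- function(design, batch_id) {
  design$channel[design$batch_id == batch_id]
}

# Non-empty channels of a batch (spare slots excluded downstream).
active_channels <- function(design, batch_id) {
  sub <- design[design$batch_id == batch_id & design$condition != "empty", ]
  sub$channel
}
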