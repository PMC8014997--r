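#' Simulation configuration for synthetic PSM tables
#'
#' Defines the ground-truth generative model for a multi-batch TMT
#' experiment. Reporter intensities are generated multiplicatively on the
#' log2 scale and exponentiated: for protein p with baseline log2 abundance
#' b_p, peptide ionization offset o_k, condition fold change f_pc, batch
#' location shift gamma_bp and scale multiplier delta_bp,
#'
#'   log2 I = b_p + o_k + log2(f_pc) + gamma_bp + e,  e ~ N(0, noise_sd^2 * delta_bp)
#'
#' Reference-pool channels receive the unregulated state (f = 1) of their
#' participant, mirroring pooled unstimulated saliva.
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein length-2 integer (min, max); each protein's
#'   peptide count is drawn uniformly from this range.
#' @param conditions named list; each element is
#'   `list(regulated = <protein indices>, fold_change = <linear-scale fold changes>)`.
#'   Defaults to [default_conditions()], eight mouth-rinse conditions with
#'   spikes spanning the 0.4-2.2 fold-change range.
#' @param n_batches,channels_per_batch,participants design geometry the
#'   config expects (validated against the design at simulation time).
#' @param baseline_log2_mean,baseline_log2_sd distribution of protein
#'   baseline log2 intensities.
#' @param peptide_log2_sd sd of per-peptide ionization offsets (log2).
#' @param batch_location_sd sd of per-batch per-protein additive shifts (log2).
#' @param batch_scale_range length-2 range of per-batch variance multipliers.
#' @param noise_sd within-channel log2 measurement noise sd.
#' @param missing_channel_rate probability a PSM row has >= 1 blanked channel.
#' @param unassigned_rate probability a PSM row carries no accession.
#' @param protein_dropout_rate probability a protein goes undetected in a
#'   given batch (no PSMs), emulating run-to-run identification differences.
#' @param flagged_q_rate fraction of PSMs drawing a q-value above 0.05.
#' @param seed RNG seed; part of the config so that identical configs give
#'   byte-identical tables.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_proteins = 200,
                       peptides_per_protein = c(1L, 8L),
                       conditions = default_conditions(n_proteins),
                       n_batches = 6,
                       channels_per_batch = 10,
                       participants = 2,
                       baseline_log2_mean = 16,
                       baseline_log2_sd = 1.5,
                       peptide_log2_sd = 0.7,
                       batch_location_sd = 0.5,
                       batch_scale_range = c(0.8, 1.25),
                       noise_sd = 0.25,
                       missing_channel_rate = 0.05,
                       unassigned_rate = 0.02,
                       protein_dropout_rate = 0.17,
                       flagged_q_rate = 0.02,
                       seed = 1) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              conditions = conditions,
              n_batches = as.integer(n_batches),
              channels_per_batch = as.integer(channels_per_batch),
              participants = as.integer(participants),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              peptide_log2_sd = peptide_log2_sd,
              batch_location_sd = batch_location_sd,
              batch_scale_range = as.numeric(batch_scale_range),
              noise_sd = noise_sd,
              missing_channel_rate = missing_channel_rate,
              unassigned_rate = unassigned_rate,
              protein_dropout_rate = protein_dropout_rate,
              flagged_q_rate = flagged_q_rate,
              seed = as.integer(seed))
  rates <- c(cfg$missing_channel_rate, cfg$unassigned_rate,
             cfg$protein_dropout_rate, cfg$flagged_q_rate)
  if (any(rates < 0 | rates > 1)) stopf("all rates must lie in [0, 1]")
  sds <- c(cfg$baseline_log2_sd, cfg$peptide_log2_sd,
           cfg$batch_location_sd, cfg$noise_sd)
  if (any(sds < 0)) stopf("all standard deviations must be >= 0")
  if (cfg$n_batches < 2) stopf("n_batches must be >= 2")
  if (cfg$channels_per_batch < 4)
    stopf("channels_per_batch must be >= 4 (>= 2 pools and >= 2 samples)")
  if (length(cfg$peptides_per_protein) != 2 ||
      cfg$peptides_per_protein[1] < 1 ||
      cfg$peptides_per_protein[1] > cfg$peptides_per_protein[2])
    stopf("peptides_per_protein must be an increasing (min, max) pair >= 1")
  if (any(cfg$batch_scale_range <= 0) ||
      cfg$batch_scale_range[1] > cfg$batch_scale_range[2])
    stopf("batch_scale_range must be a positive (lo, hi) pair")
  for (nm in names(cfg$conditions)) {
    cn <- cfg$conditions[[nm]]
    if (length(cn$regulated) != length(cn$fold_change))
      stopf("condition %s: regulated and fold_change lengths differ", nm)
    if (any(cn$regulated < 1 | cn$regulated > cfg$n_proteins))
      stopf("condition %s: regulated protein index out of range", nm)
    if (any(cn$fold_change <= 0))
      stopf("condition %s: fold changes must be > 0", nm)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default condition set with study-scale spikes
#'
#' Eight mouth-rinse conditions (vehicle at two concentrations, three
#' TRP-channel agonists at two concentrations each). Each condition
#' regulates five distinct proteins at linear fold changes
#' 1.52, 1.72, 1.81, 2.15 and 0.52 — magnitudes spanning the regulated
#' range observed for salivary cystatins and immunoglobulins.
#'
#' @param n_proteins total protein count (spike indices stay in range).
#' @return a named list suitable for the `conditions` field of [sim_config()].
#' @export
default_conditions <- function(n_proteins = 200) {
  labels <- c("pg_18000", "pg_30000", "cinnamaldehyde_180", "cinnamaldehyde_300",
              "menthol_300", "menthol_500", "nonivamide_0.6", "nonivamide_1")
  spikes <- c(1.52, 1.72, 1.81, 2.15, 0.52)
  n_spike <- length(spikes)
  if (n_proteins < length(labels) * n_spike)
    stopf("n_proteins too small for the default condition set (need >= %d)",
          length(labels) * n_spike)
  out <- list()
  for (i in seq_along(labels)) {
    idx <- ((i - 1) * n_spike + 1):(i * n_spike)
    out[[labels[i]]] <- list(regulated = as.integer(idx), fold_change = spikes)
  }
  out
}

#' Simulate a PSM table with known ground truth
#'
#' Generates one peptide-spectrum match per detected (protein, peptide,
#' batch) triple, with reporter intensities for every channel the batch
#' declares, then applies the configured contamination processes:
#' accession-less rows, rows with blanked channel intensities, and PSMs
#' with elevated q-values.
#'
#' @param config a [sim_config()].
#' @param design a `batch_design`; its condition labels (other than
#'   `unstimulated`/`empty`) must appear in `config$conditions`.
#' @return list with elements `psms` (a `psm_table`) and `truth` (a
#'   `ground_truth`: protein x condition linear fold-change matrix,
#'   batch x protein location shifts `batch_gamma` and scale multipliers
#'   `batch_delta`, per-condition regulated sets, baselines, and the
#'   batch x protein detection mask).
#' @export
simulate_psm_table <- function(config, design) {
  stopifnot(inherits(config, "sim_config"))
  validate_design(design)
  design_conds <- setdiff(unique(design$condition), c("unstimulated", "empty"))
  unknown <- setdiff(design_conds, names(config$conditions))
  if (length(unknown) > 0)
    stopf("design conditions missing from config: %s", paste(unknown, collapse = ", "))

  set.seed(config$seed)
  P <- config$n_proteins
  protein_ids <- sprintf("PROT%04d", seq_len(P))
  cond_labels <- names(config$conditions)

  fc <- matrix(1, nrow = P, ncol = length(cond_labels),
               dimnames = list(protein_ids, cond_labels))
  regulated_set <- list()
  for (nm in cond_labels) {
    cn <- config$conditions[[nm]]
    fc[cn$regulated, nm] <- cn$fold_change
    regulated_set[[nm]] <- protein_ids[cn$regulated]
  }

  baseline <- stats::rnorm(P, config$baseline_log2_mean, config$baseline_log2_sd)
  names(baseline) <- protein_ids

  n_pep <- if (config$peptides_per_protein[1] == config$peptides_per_protein[2]) {
    rep(config$peptides_per_protein[1], P)
  } else {
    sample(seq(config$peptides_per_protein[1], config$peptides_per_protein[2]),
           P, replace = TRUE)
  }
  pep_protein <- rep(seq_len(P), n_pep)
  n_pep_total <- length(pep_protein)
  pep_len <- sample(8:15, n_pep_total, replace = TRUE)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pep_seq <- vapply(pep_len, function(l) paste(sample(aa, l, replace = TRUE),
                                               collapse = ""), character(1))
  # disambiguate rare collisions so peptide ids are unique
  pep_seq <- make.unique(pep_seq, sep = "")
  pep_offset <- stats::rnorm(n_pep_total, 0, config$peptide_log2_sd)

  batch_ids <- unique(design$batch_id)
  B <- length(batch_ids)
  gamma <- matrix(stats::rnorm(B * P, 0, config$batch_location_sd),
                  nrow = B, dimnames = list(batch_ids, protein_ids))
  delta <- matrix(stats::runif(B * P, config$batch_scale_range[1],
                               config$batch_scale_range[2]),
                  nrow = B, dimnames = list(batch_ids, protein_ids))
  detected <- matrix(stats::runif(B * P) >= config$protein_dropout_rate,
                     nrow = B, dimnames = list(batch_ids, protein_ids))

  all_channels <- unique(design$channel)
  blocks <- vector("list", B)
  for (bi in seq_len(B)) {
    b <- batch_ids[bi]
    sub <- design[design$batch_id == b, ]
    chans <- sub$channel
    ch_fc_col <- match(sub$condition, cond_labels)  # NA for pools/empty -> f = 1
    keep <- detected[bi, pep_protein]
    rows <- which(keep)
    if (length(rows) == 0) next
    p_idx <- pep_protein[rows]
    base_part <- baseline[p_idx] + pep_offset[rows] + gamma[bi, p_idx]
    log2fc <- matrix(0, nrow = length(rows), ncol = length(chans))
    for (ci in seq_along(chans)) {
      if (!is.na(ch_fc_col[ci]))
        log2fc[, ci] <- log2(fc[cbind(p_idx, ch_fc_col[ci])])
    }
    noise_sd_row <- config$noise_sd * sqrt(delta[bi, p_idx])
    noise <- matrix(stats::rnorm(length(rows) * length(chans)),
                    nrow = length(rows)) * noise_sd_row
    log2_mat <- base_part + log2fc + noise
    intens <- 2^log2_mat
    colnames(intens) <- chans

    wide <- matrix(NA_real_, nrow = length(rows), ncol = length(all_channels),
                   dimnames = list(NULL, all_channels))
    wide[, chans] <- intens
    blocks[[bi]] <- data.frame(peptide = pep_seq[rows],
                               accessions = protein_ids[p_idx],
                               q_value = NA_real_,
                               batch_id = b,
                               wide,
                               check.names = FALSE,
                               stringsAsFactors = FALSE)
  }
  psms <- do.call(rbind, blocks)
  rownames(psms) <- NULL
  n <- nrow(psms)

  # a small fraction of peptides report a second (non-primary) accession,
  # emulating shared-peptide ambiguity in search-engine exports
  second <- stats::runif(n) < 0.05
  if (any(second)) {
    alt <- protein_ids[sample.int(P, sum(second), replace = TRUE)]
    psms$accessions[second] <- paste(psms$accessions[second], alt, sep = ";")
  }

  unassigned <- stats::runif(n) < config$unassigned_rate
  psms$accessions[unassigned] <- ""

  hi_q <- stats::runif(n) < config$flagged_q_rate
  psms$q_value <- stats::runif(n, 0, 0.05)
  psms$q_value[hi_q] <- stats::runif(sum(hi_q), 0.05, 1)

  miss_row <- stats::runif(n) < config$missing_channel_rate
  if (any(miss_row)) {
    for (i in which(miss_row)) {
      chans <- batch_channels(design, psms$batch_id[i])
      forced <- sample(chans, 1)
      extra <- chans[stats::runif(length(chans)) < 0.15]
      psms[i, unique(c(forced, extra))] <- NA_real_
    }
  }

  psms <- new_psm_table(psms, batch_ids)
  truth <- structure(list(true_fold_change = fc,
                          batch_gamma = gamma,
                          batch_delta = delta,
                          regulated_set = regulated_set,
                          baseline_log2 = baseline,
                          detected = detected),
                     class = "ground_truth")
  list(psms = psms, truth = truth)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d proteins (%d-%d peptides), %d batches x %d channels, %d participants\n",
              x$n_proteins, x$peptides_per_protein[1], x$peptides_per_protein[2],
              x$n_batches, x$channels_per_batch, x$participants))
  cat(sprintf(" noise_sd=%.3g log2, batch_location_sd=%.3g, scale range [%.3g, %.3g]\n",
              x$noise_sd, x$batch_location_sd,
              x$batch_scale_range[1], x$batch_scale_range[2]))
  cat(sprintf(" rates: missing=%.3g unassigned=%.3g dropout=%.3g; seed=%d\n",
              x$missing_channel_rate, x$unassigned_rate,
              x$protein_dropout_rate, x$seed))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  n_reg <- length(unique(unlist(x$regulated_set)))
  cat(sprintf("ground_truth: %d proteins x %d conditions, %d batches, %d regulated proteins\n",
              nrow(x$true_fold_change), ncol(x$true_fold_change),
              nrow(x$batch_gamma), n_reg))
  invisible(x)
}

#' Write ground-truth tables
#'
#' Serializes the fold-change truth as a tab-delimited long table
#' (protein, condition, true_fold_change) and the batch effects as a
#' second table (batch, protein, gamma_log2, delta).
#'
#' @param truth a `ground_truth`.
#' @param fc_path,batch_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_ground_truth <- function(truth, fc_path, batch_path) {
  fcm <- truth$true_fold_change
  long <- data.frame(protein = rep(rownames(fcm), ncol(fcm)),
                     condition = rep(colnames(fcm), each = nrow(fcm)),
                     true_fold_change = as.vector(fcm))
  utils::write.table(long, fc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- truth$batch_gamma
  d <- truth$batch_delta
  be <- data.frame(batch = rep(rownames(g), ncol(g)),
                   protein = rep(colnames(g), each = nrow(g)),
                   gamma_log2 = as.vector(g),
                   delta = as.vector(d))
  utils::write.table(be, batch_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fc_path, batch_path))
}
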