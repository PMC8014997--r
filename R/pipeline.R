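#' @title End-to-end pipeline
#' @description Runs simulate (or load) -> quantify -> integrate ->
#'   distances -> cluster -> diffexp from a single configuration, writing
#'   every intermediate matrix with its normalization state, a
#'   machine-readable run manifest and a log. A single global seed is
#'   expanded into per-stage substreams so any stage can be re-run in
#'   isolation reproducibly.
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' The default emulates the study geometry: 6 TMT10plex batches, two
#' participants, eight mouth-rinse conditions with three repeats, 200
#' proteins with per-batch dropout, and spiked fold changes spanning
#' 0.52-2.15.
#'
#' @param out_dir artifact directory.
#' @param seed global seed.
#' @return a nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir, seed = 1) {
  list(out_dir = out_dir,
       seed = seed,
       simulation = list(n_proteins = 200, repeats = 3),
       quantify = list(q_threshold = 0.05),
       distances = list(n_components = 2),
       cluster = list(n_components = 2, k_min = 1, k_max = 8),
       diffexp = list(alpha = 0.05, up_threshold = 1.5, down_threshold = 0.667))
}

#' Run the full analysis pipeline
#'
#' @param config a configuration list (see [default_pipeline_config()]) or
#'   the path of a YAML file holding one. Inputs are either simulated
#'   (`simulation:` block) or loaded (`psm_table:` and `design:` paths).
#'   Any stage error aborts with the stage name attached.
#' @param out_dir,seed optional overrides of the config fields.
#' @return invisibly, a list with the key result objects and the artifact
#'   paths (`manifest` names every written file and its matrix state).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$out_dir)) stopf("config must name an out_dir")
  seed <- as.integer(config$seed %||% 1)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  log_path <- file.path(config$out_dir, "pipeline.log")
  cat("", file = log_path)
  logmsg <- function(level, fmt, ...) {
    line <- sprintf("[%s] %s %s", level,
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  run_stage <- function(name, expr) {
    logmsg("INFO", "stage %s: start", name)
    tryCatch(expr, error = function(e)
      stopf("stage %s: %s", name, conditionMessage(e)))
  }
  artifacts <- list()
  put <- function(name, path, state = NA_character_) {
    artifacts[[name]] <<- list(path = basename(path), state = state)
    path
  }

  # --- simulate / load ----------------------------------------------------
  sim <- run_stage("simulate", {
    if (!is.null(config$psm_table)) {
      design <- read_batch_design(config$design)
      psms <- read_psm_table(config$psm_table, design)
      list(psms = psms, design = design, truth = NULL)
    } else {
      sim_args <- config$simulation %||% list()
      repeats <- sim_args$repeats %||% 3
      sim_args$repeats <- NULL
      sim_args$seed <- stage_seed(seed, "simulate")
      cfg <- do.call(sim_config, sim_args)
      design <- if (!is.null(config$design)) read_batch_design(config$design)
      else generate_design(n_batches = cfg$n_batches,
                           participants = cfg$participants,
                           conditions = names(cfg$conditions),
                           repeats = repeats,
                           channels_per_batch = cfg$channels_per_batch,
                           seed = sim_args$seed)
      out <- simulate_psm_table(cfg, design)
      write_batch_design(design, put("design", file.path(config$out_dir, "design.tsv")))
      write_psm_table(out$psms, put("psms", file.path(config$out_dir, "psms.tsv")))
      write_ground_truth(out$truth,
                         put("truth_fold_changes",
                             file.path(config$out_dir, "truth_fold_changes.tsv")),
                         put("truth_batch_effects",
                             file.path(config$out_dir, "truth_batch_effects.tsv")))
      list(psms = out$psms, design = design, truth = out$truth)
    }
  })

  # --- quantify -----------------------------------------------------------
  quant <- run_stage("quantify", {
    q <- config$quantify$q_threshold %||% 0.05
    res <- quantify_batches(sim$psms, sim$design, q_threshold = q)
    for (b in names(res$matrices))
      write_protein_matrix(res$matrices[[b]],
                           put(paste0("protein_matrix_", b),
                               file.path(config$out_dir,
                                         sprintf("protein_matrix_%s.tsv", b)),
                               state = "ref_normalized"))
    jsonlite::write_json(res$filter_log,
                         put("filter_log", file.path(config$out_dir, "filter_log.json")),
                         auto_unbox = TRUE)
    logmsg("INFO", "quantify: %d/%d PSMs retained", res$filter_log$retained,
           res$filter_log$input)
    res
  })

  # --- integrate ----------------------------------------------------------
  integ <- run_stage("integrate", {
    concat <- intersect_proteins(quant$matrices)
    write_protein_matrix(concat,
                         put("concatenated", file.path(config$out_dir, "concatenated.tsv"),
                             state = "concatenated"))
    cc <- combat_correct(concat)
    if (!cc$model$converged)
      logmsg("WARN", "integrate: EB iteration hit the cap (%d iterations)",
             cc$model$iterations)
    write_protein_matrix(cc$matrix,
                         put("combat_corrected", file.path(config$out_dir, "combat_corrected.tsv"),
                             state = "combat_corrected"))
    write_combat_model(cc$model,
                       put("combat_model", file.path(config$out_dir, "combat_model.tsv")))
    logmsg("INFO", "integrate: %d proteins common to all %d batches",
           nrow(concat$values), length(quant$matrices))
    cc
  })

  # --- distances ----------------------------------------------------------
  dist_report <- run_stage("distances", {
    nc <- config$distances$n_components %||% 2
    rep <- batch_relative_distances(quant$matrices, n_components = nc)
    utils::write.table(as.data.frame(rep),
                       put("distance_report", file.path(config$out_dir, "distance_report.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summarize_by_condition(rep),
                       put("condition_summary", file.path(config$out_dir, "condition_summary.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep
  })

  # --- cluster ------------------------------------------------------------
  clust <- run_stage("cluster", {
    geo <- condition_geomeans(integ$matrix)
    nc <- config$cluster$n_components %||% 2
    pca <- global_pca(geo, n_components = nc)
    pts <- pca$scores[, seq_len(nc), drop = FALSE]
    k_max <- min(config$cluster$k_max %||% 8, nrow(pts))
    xm <- xmeans_cluster(pts, k_min = config$cluster$k_min %||% 1,
                         k_max = k_max, seed = stage_seed(seed, "cluster"))
    agreement <- cluster_agreement(xm$labels, geo$columns$participant)
    scores_df <- data.frame(sample = geo$columns$sample_id,
                            participant = geo$columns$participant,
                            condition = geo$columns$condition,
                            pts, cluster = xm$labels,
                            stringsAsFactors = FALSE)
    utils::write.table(scores_df,
                       put("cluster_scores", file.path(config$out_dir, "cluster_scores.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ev_df <- data.frame(component = seq_along(pca$explained_variance),
                        explained_variance = pca$explained_variance)
    utils::write.table(ev_df,
                       put("explained_variance", file.path(config$out_dir, "explained_variance.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(k = xm$k, wcss = xm$wcss,
                              agreement = as.list(agreement)),
                         put("cluster_summary", file.path(config$out_dir, "cluster_summary.json")),
                         auto_unbox = TRUE, digits = NA)
    logmsg("INFO", "cluster: x-means chose k = %d", xm$k)
    list(pca = pca, xmeans = xm, agreement = agreement, geomeans = geo)
  })

  # --- diffexp ------------------------------------------------------------
  diff <- run_stage("diffexp", {
    dd <- differential_table(integ$matrix,
                             alpha = config$diffexp$alpha %||% 0.05,
                             up_threshold = config$diffexp$up_threshold %||% 1.5,
                             down_threshold = config$diffexp$down_threshold %||% 0.667)
    utils::write.table(as.data.frame(dd),
                       put("differential", file.path(config$out_dir, "differential.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(config$annotation)) {
      ann <- read_gmt(config$annotation)
      fg <- unique(dd$protein[dd$call != "none"])
      bg <- unique(dd$protein)
      if (length(fg) > 0) {
        go <- go_enrichment(fg, bg, ann)
        utils::write.table(go,
                           put("go_enrichment", file.path(config$out_dir, "go_enrichment.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    logmsg("INFO", "diffexp: %d up / %d down calls",
           sum(dd$call == "up"), sum(dd$call == "down"))
    dd
  })

  manifest <- list(package = "tmtbridge",
                   version = as.character(utils::packageVersion("tmtbridge")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = seed,
                   config_hash = fnv1a_hash(config[setdiff(names(config), "out_dir")]),
                   stages = c("simulate", "quantify", "integrate",
                              "distances", "cluster", "diffexp"),
                   artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logmsg("INFO", "pipeline complete: %d artifacts in %s",
         length(artifacts), config$out_dir)
  invisible(list(design = sim$design, truth = sim$truth,
                 matrices = quant$matrices, filter_log = quant$filter_log,
                 corrected = integ$matrix, combat_model = integ$model,
                 distances = dist_report, clustering = clust,
                 differential = diff, manifest = manifest,
                 out_dir = config$out_dir))
}
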