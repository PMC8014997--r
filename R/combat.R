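#' @title Batch integration: concatenation and empirical-Bayes correction
#' @description Per-batch protein matrices are concatenated on their common
#'   protein set (the location/scale model needs every protein observed in
#'   every batch) and corrected with a parametric empirical-Bayes
#'   location/scale adjustment: per-batch additive shifts (gamma) and
#'   variance multipliers (delta) are estimated on standardized log2 data,
#'   shrunk toward batch-level normal / inverse-gamma priors fit by the
#'   method of moments, and removed.
#' @name batch_integration
NULL

#' Concatenate batches on their common protein set
#'
#' @param matrices list of per-batch `protein_matrix` objects in the same
#'   normalization state.
#' @return a `protein_matrix` in state `"concatenated"` restricted to
#'   proteins quantified in every batch; the proteins dropped from each
#'   batch are recorded in attribute `"dropped_proteins"`.
#' @export
intersect_proteins <- function(matrices) {
  if (length(matrices) < 2) stopf("need >= 2 batches to concatenate")
  sets <- lapply(matrices, function(m) rownames(m$values))
  common <- Reduce(intersect, sets)
  if (length(common) == 0)
    stopf("no protein is present in all %d batches", length(matrices))
  common <- sort(common)
  vals <- do.call(cbind, lapply(matrices, function(m)
    m$values[common, , drop = FALSE]))
  columns <- do.call(rbind, lapply(matrices, function(m) m$columns))
  rownames(columns) <- NULL
  for (m in matrices) check_state_transition(m$state, "concatenated")
  out <- new_protein_matrix(vals, columns, state = "concatenated")
  attr(out, "dropped_proteins") <- lapply(sets, function(s) setdiff(s, common))
  out
}

#' Parametric empirical-Bayes batch correction
#'
#' Implements the parametric ComBat-style adjustment on log2 intensities:
#' per-protein standardization by grand mean and pooled variance, per-batch
#' location (`gamma_hat`) and scale (`delta_hat`) estimates, method-of-moments
#' hyperpriors (normal on gamma, inverse-gamma on delta), iterated
#' conditional posterior means to convergence, and de-standardization.
#' Matrices are stored on the linear scale; the log2 conversion is internal.
#'
#' Proteins with zero variance within some batch (or zero pooled variance)
#' are excluded from the empirical-Bayes machinery and corrected by
#' location only; they are listed in the model's `location_only` field.
#'
#' @param matrix a concatenated `protein_matrix` with strictly positive
#'   values.
#' @param batch_labels per-column batch labels; defaults to the matrix's
#'   own column annotation.
#' @param conv convergence threshold on the absolute change of the
#'   posterior estimates.
#' @param max_iter iteration cap; non-convergence is flagged on the model,
#'   not an error.
#' @return list with `matrix` (state `"combat_corrected"`, linear scale)
#'   and `model` (a `combat_model` holding grand means, pooled variances,
#'   `gamma_hat`/`delta_hat`, their shrunk versions `gamma_star`/`delta_star`,
#'   and the per-batch prior parameters).
#' @export
combat_correct <- function(matrix, batch_labels = NULL, conv = 1e-6,
                           max_iter = 500L) {
  stopifnot(inherits(matrix, "protein_matrix"))
  check_state_transition(matrix$state, "combat_corrected")
  if (any(matrix$values <= 0, na.rm = TRUE))
    stopf("batch correction requires strictly positive intensities")
  if (anyNA(matrix$values))
    stopf("batch correction does not handle missing values; intersect first")
  batch_labels <- batch_labels %||% matrix$columns$batch_id
  if (length(batch_labels) != ncol(matrix$values))
    stopf("batch_labels length does not match the number of columns")
  batches <- unique(batch_labels)
  B <- length(batches)
  X <- log2(matrix$values)
  G <- nrow(X); n <- ncol(X)

  if (B == 1) {
    out <- matrix
    out$state <- "combat_corrected"
    model <- structure(list(batches = batches, converged = TRUE, iterations = 0L,
                            location_only = character(0)),
                       class = "combat_model")
    return(list(matrix = out, model = model))
  }
  idx <- lapply(batches, function(b) which(batch_labels == b))
  n_i <- vapply(idx, length, integer(1))
  if (any(n_i < 2)) stopf("every batch needs >= 2 columns for scale estimation")

  batch_means <- matrix(vapply(idx, function(j) rowMeans(X[, j, drop = FALSE]),
                               numeric(G)), nrow = G)     # G x B
  grand_mean <- as.vector(batch_means %*% (n_i / n))
  resid <- X - batch_means[, match(batch_labels, batches), drop = FALSE]
  var_pooled <- rowSums(resid^2) / n

  # proteins the EB machinery can handle: positive pooled variance and
  # positive within-batch variance everywhere
  within_var <- matrix(vapply(idx, function(j)
    apply(X[, j, drop = FALSE], 1, stats::var), numeric(G)), nrow = G)  # G x B
  eb_ok <- var_pooled > 0 & apply(within_var > 0, 1, all)
  location_only <- rownames(X)[!eb_ok]

  X_adj <- X
  gamma_hat <- gamma_star <- matrix(NA_real_, nrow = B, ncol = G,
                                    dimnames = list(batches, rownames(X)))
  delta_hat <- delta_star <- gamma_hat
  prior_params <- data.frame(batch = batches, gamma_bar = NA_real_,
                             t2 = NA_real_, a_prior = NA_real_,
                             b_prior = NA_real_)
  iterations <- 0L
  converged <- TRUE

  if (any(eb_ok)) {
    sel <- which(eb_ok)
    Z <- (X[sel, , drop = FALSE] - grand_mean[sel]) / sqrt(var_pooled[sel])
    Z_adj <- Z
    for (bi in seq_len(B)) {
      j <- idx[[bi]]
      Zi <- Z[, j, drop = FALSE]
      g_hat <- rowMeans(Zi)
      d_hat <- apply(Zi, 1, stats::var)
      gamma_hat[bi, sel] <- g_hat
      delta_hat[bi, sel] <- d_hat

      g_bar <- mean(g_hat)
      t2 <- stats::var(g_hat)
      m <- mean(d_hat); s2 <- stats::var(d_hat)
      a <- (2 * s2 + m^2) / s2
      b <- (m * s2 + m^3) / s2
      prior_params[bi, 2:5] <- c(g_bar, t2, a, b)

      if (!is.finite(a) || !is.finite(b)) {
        # degenerate inverse-gamma prior (all delta_hat identical): the
        # prior is a point mass at d_hat, leaving only the gamma posterior
        d_old <- d_hat
        g_old <- (n_i[bi] * t2 * g_hat + d_hat * g_bar) / (n_i[bi] * t2 + d_hat)
        gamma_star[bi, sel] <- g_old
        delta_star[bi, sel] <- d_old
        Z_adj[, j] <- (Zi - g_old) / sqrt(d_old)
        next
      }

      g_old <- g_hat
      d_old <- d_hat
      it <- 0L
      repeat {
        it <- it + 1L
        g_new <- (n_i[bi] * t2 * g_hat + d_old * g_bar) / (n_i[bi] * t2 + d_old)
        sum2 <- rowSums((Zi - g_new)^2)
        d_new <- (0.5 * sum2 + b) / (n_i[bi] / 2 + a - 1)
        change <- max(abs(g_new - g_old), abs(d_new - d_old))
        g_old <- g_new
        d_old <- d_new
        if (change < conv) break
        if (it >= max_iter) { converged <- FALSE; break }
      }
      iterations <- max(iterations, it)
      gamma_star[bi, sel] <- g_old
      delta_star[bi, sel] <- d_old
      Z_adj[, j] <- (Zi - g_old) / sqrt(d_old)
    }
    X_adj[sel, ] <- Z_adj * sqrt(var_pooled[sel]) + grand_mean[sel]
  }

  # location-only proteins: remove batch means, keep grand mean
  if (length(location_only) > 0) {
    sel <- which(!eb_ok)
    for (bi in seq_len(B)) {
      j <- idx[[bi]]
      gamma_hat[bi, sel] <- gamma_star[bi, sel] <-
        batch_means[sel, bi] - grand_mean[sel]
      X_adj[sel, j] <- X[sel, j, drop = FALSE] -
        (batch_means[sel, bi] - grand_mean[sel])
    }
  }

  out <- matrix
  out$values <- 2^X_adj
  colnames(out$values) <- colnames(matrix$values)
  out$state <- "combat_corrected"
  model <- structure(list(batches = batches,
                          grand_mean = grand_mean,
                          pooled_var = var_pooled,
                          gamma_hat = gamma_hat, delta_hat = delta_hat,
                          gamma_star = gamma_star, delta_star = delta_star,
                          prior_params = prior_params,
                          location_only = location_only,
                          converged = converged,
                          iterations = iterations),
                     class = "combat_model")
  list(matrix = out, model = model)
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("combat_model: %d batches, %d proteins%s\n",
              length(x$batches),
              if (is.null(x$gamma_hat)) 0L else ncol(x$gamma_hat),
              if (isTRUE(x$converged)) ""
              else sprintf(" [NOT converged after %d iterations]", x$iterations)))
  if (length(x$location_only) > 0)
    cat(sprintf(" %d protein(s) corrected by location only\n",
                length(x$location_only)))
  invisible(x)
}

#' Write the estimated batch-effect parameters
#'
#' @param model a `combat_model`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_combat_model <- function(model, path) {
  if (is.null(model$gamma_hat)) {
    utils::write.table(data.frame(batch = model$batches), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  g <- model$gamma_hat
  long <- data.frame(batch = rep(rownames(g), ncol(g)),
                     protein = rep(colnames(g), each = nrow(g)),
                     gamma_hat = as.vector(g),
                     delta_hat = as.vector(model$delta_hat),
                     gamma_star = as.vector(model$gamma_star),
                     delta_star = as.vector(model$delta_star))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
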