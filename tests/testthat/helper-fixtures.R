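# Small in-code fixtures shared across the suite.

# A minimal design: one or more batches, two participants, pools on the
# first two channels, conditions on the rest.
tiny_design <- function(n_batches = 1, conditions = c("condA", "condB"),
                        repeats = 1, channels_per_batch = 2 + length(conditions) * 2,
                        seed = 42) {
  generate_design(n_batches = n_batches, participants = 2,
                  conditions = conditions, repeats = repeats,
                  channels_per_batch = channels_per_batch, seed = seed)
}

# Construct a peptide_matrix directly from a numeric matrix; the first two
# columns are the participant pools.
make_pepmat <- function(values, batch_id = "batch1", state = "raw",
                        accession = NULL, conditions = NULL) {
  n_ch <- ncol(values)
  conds <- conditions %||% c("unstimulated", "unstimulated",
                             rep("condA", n_ch - 2))
  columns <- data.frame(
    batch_id = batch_id,
    channel = tmtbridge:::TMT10_CHANNELS[seq_len(n_ch)],
    sample_id = c("1.P", "2.P",
                  if (n_ch > 2) paste0(rep(1:2, length.out = n_ch - 2), ".1")),
    participant = c("1", "2", rep(c("1", "2"), length.out = n_ch - 2)),
    condition = conds,
    concentration_ppm = NA_real_,
    is_reference_pool = c(TRUE, TRUE, rep(FALSE, n_ch - 2)),
    stringsAsFactors = FALSE)
  structure(list(values = values,
                 peptide = sprintf("PEP%03d", seq_len(nrow(values))),
                 accession = accession %||% sprintf("PROT%03d", seq_len(nrow(values))),
                 batch_id = batch_id, columns = columns, state = state),
            class = "peptide_matrix")
}

make_protmat <- function(values, columns, state = "ref_normalized") {
  tmtbridge:::new_protein_matrix(values, columns, state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent reference implementation of the parametric empirical-Bayes
# batch adjustment, written as explicit per-protein scalar loops (vs the
# package's vectorized path). Takes and returns log2 matrices.
combat_oracle <- function(X, batches, conv = 1e-6, max_iter = 500) {
  batch_levels <- unique(batches)
  B <- length(batch_levels)
  G <- nrow(X)
  n <- ncol(X)
  n_i <- sapply(batch_levels, function(b) sum(batches == b))

  grand <- numeric(G); pooled <- numeric(G)
  bmeans <- matrix(0, G, B)
  for (g in seq_len(G)) {
    for (bi in seq_len(B)) {
      bmeans[g, bi] <- mean(X[g, batches == batch_levels[bi]])
    }
    grand[g] <- sum(n_i / n * bmeans[g, ])
    resid <- X[g, ] - bmeans[g, match(batches, batch_levels)]
    pooled[g] <- sum(resid^2) / n
  }
  Z <- (X - grand) / sqrt(pooled)

  Xa <- X
  for (bi in seq_len(B)) {
    cols <- which(batches == batch_levels[bi])
    g_hat <- numeric(G); d_hat <- numeric(G)
    for (g in seq_len(G)) {
      zi <- Z[g, cols]
      g_hat[g] <- mean(zi)
      d_hat[g] <- var(zi)
    }
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    m <- mean(d_hat); s2 <- var(d_hat)
    a <- (2 * s2 + m^2) / s2
    b <- (m * s2 + m^3) / s2
    for (g in seq_len(G)) {
      zi <- Z[g, cols]
      g_old <- g_hat[g]; d_old <- d_hat[g]
      for (it in seq_len(max_iter)) {
        g_new <- (n_i[bi] * t2 * g_hat[g] + d_old * g_bar) / (n_i[bi] * t2 + d_old)
        d_new <- (0.5 * sum((zi - g_new)^2) + b) / (n_i[bi] / 2 + a - 1)
        done <- max(abs(g_new - g_old), abs(d_new - d_old)) < conv
        g_old <- g_new; d_old <- d_new
        if (done) break
      }
      Xa[g, cols] <- (zi - g_old) / sqrt(d_old) * sqrt(pooled[g]) + grand[g]
    }
  }
  Xa
}

# Synthetic concatenated protein matrix with injected batch effects, on
# the linear scale, for integration tests.
make_batched_matrix <- function(n_proteins = 50, n_batches = 6,
                                per_batch = 10, gamma_sd = 0.8,
                                noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  base <- rnorm(n_proteins, 4, 1)
  cols <- list(); vals <- list()
  for (b in seq_len(n_batches)) {
    gamma <- rnorm(n_proteins, 0, gamma_sd)
    block <- base + gamma +
      matrix(rnorm(n_proteins * per_batch, 0, noise_sd), n_proteins)
    vals[[b]] <- block
    cols[[b]] <- data.frame(
      batch_id = paste0("batch", b),
      channel = tmtbridge:::TMT10_CHANNELS[seq_len(per_batch)],
      sample_id = paste0("s", seq_len(per_batch)),
      participant = rep(c("1", "2"), length.out = per_batch),
      condition = c("unstimulated", "unstimulated",
                    rep("condA", per_batch - 2)),
      concentration_ppm = NA_real_,
      is_reference_pool = c(TRUE, TRUE, rep(FALSE, per_batch - 2)),
      stringsAsFactors = FALSE)
  }
  values <- 2^do.call(cbind, vals)
  rownames(values) <- sprintf("PROT%03d", seq_len(n_proteins))
  make_protmat(values, do.call(rbind, cols), state = "concatenated")
}

# Gaussian point clouds around deterministic centers spaced `sep` apart
# (separation / within-cloud sd = sep / sd).
planted_clouds <- function(k = 3, n_per = 20, sep = 10, sd = 1, seed = 1,
                           dim = 2) {
  set.seed(seed)
  base <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(2, 0))
  centers <- base[seq_len(k), , drop = FALSE] * sep
  if (dim > 2) centers <- cbind(centers, matrix(0, k, dim - 2))
  x <- do.call(rbind, lapply(seq_len(k), function(j)
    matrix(rnorm(n_per * dim, 0, sd), n_per, dim) +
      matrix(centers[j, ], n_per, dim, byrow = TRUE)))
  list(x = x, truth = rep(seq_len(k), each = n_per))
}

# Per-protein eta-squared of a one-way batch decomposition, averaged:
# fraction of variance explained by batch membership.
mean_batch_eta_sq <- function(values, batches) {
  X <- log2(values)
  mean(apply(X, 1, function(x) {
    fit <- stats::aov(x ~ factor(batches))
    ss <- summary(fit)[[1]][["Sum Sq"]]
    ss[1] / sum(ss)
  }))
}
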