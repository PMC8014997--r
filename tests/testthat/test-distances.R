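# PCA scores fixture with hand-placed geometry: pools for participants 1
# and 2 plus samples at known coordinates.
fake_pca <- function(scores, participants, pools = c(1, 2),
                     batch_id = "batch1") {
  n <- nrow(scores)
  is_pool <- seq_len(n) %in% pools
  cols <- data.frame(batch_id = batch_id,
                     channel = paste0("ch", seq_len(n)),
                     sample_id = ifelse(is_pool, paste0(participants, ".P"),
                                        paste0(participants, ".1")),
                     participant = participants,
                     condition = ifelse(is_pool, "unstimulated", "condA"),
                     concentration_ppm = NA_real_,
                     is_reference_pool = is_pool,
                     stringsAsFactors = FALSE)
  list(scores = scores, explained_variance = rep(1 / ncol(scores), ncol(scores)),
       n_components = ncol(scores), columns = cols, batch_id = batch_id)
}

test_that("relative distances follow 3-4-5 arithmetic against the right pool", {
  # pools at (0,0) and (0,2.5): pool-pool distance 2.5; participant-1
  # sample at (3,4) is 5 from its pool -> relative 2.0
  scores <- rbind(c(0, 0), c(0, 2.5), c(3, 4), c(0, 2.5))
  pca <- fake_pca(scores, participants = c("1", "2", "1", "2"))
  rep <- relative_distance(pca)
  expect_equal(attr(rep, "pool_pool_distance"), 2.5)
  expect_equal(rep$raw_distance[1], 5.0)
  expect_equal(rep$relative_distance[1], 2.0)
  # the participant-2 sample coincides with its own pool -> distance 0
  expect_equal(rep$relative_distance[2], 0)
})

test_that("pools expressed relative to each other give exactly 1", {
  set.seed(31)
  for (i in 1:5) {
    scores <- matrix(rnorm(12), 6, 2)
    pca <- fake_pca(scores, participants = c("1", "2", "1", "2", "1", "2"))
    pp <- sqrt(sum((scores[1, ] - scores[2, ])^2))
    rep <- relative_distance(pca)
    # a hypothetical sample placed exactly at the other pool's position
    # would score raw = pool-pool distance, i.e. relative exactly 1
    expect_equal(attr(rep, "pool_pool_distance") / pp, 1)
    expect_true(all(rep$relative_distance > 0))
  }
})

test_that("coincident pools raise a degenerate-reference error", {
  scores <- rbind(c(1, 1), c(1, 1), c(3, 4))
  pca <- fake_pca(scores, participants = c("1", "2", "1"))
  expect_error(relative_distance(pca), "coincident")
})

test_that("per-batch PCA matches a brute-force eigendecomposition", {
  set.seed(33)
  vals <- 2^matrix(rnorm(300, 4, 1), 30, 10)
  rownames(vals) <- sprintf("P%03d", 1:30)
  m <- make_protmat(vals, tiny_design(conditions = c("a", "b", "c", "d"),
                                      channels_per_batch = 10),
                    state = "ref_normalized")
  pca <- per_batch_pca(m, n_components = 3)
  # oracle: eigendecomposition of the covariance of the centered log2 data
  X <- t(log2(vals))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(cov(Xc), symmetric = TRUE)
  oracle_scores <- Xc %*% ev$vectors
  for (j in 1:3) {
    # sign ambiguity: compare up to sign
    s <- sign(sum(oracle_scores[, j] * pca$scores[, j]))
    expect_equal(unname(pca$scores[, j]), unname(s * oracle_scores[, j]),
                 tolerance = 1e-8)
  }
  # distances are invariant to the rotation/sign ambiguity
  expect_equal(as.matrix(dist(pca$scores)), as.matrix(dist(oracle_scores)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # explained-variance fractions: non-increasing, sum <= 1
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  expect_lte(sum(pca$explained_variance), 1 + 1e-12)
})

test_that("duplicate columns land on identical scores, at distance zero", {
  set.seed(34)
  vals <- 2^matrix(rnorm(80, 4, 1), 20, 4)
  vals[, 2] <- vals[, 1]
  rownames(vals) <- sprintf("P%03d", 1:20)
  m <- make_protmat(vals, tiny_design(conditions = "a", channels_per_batch = 4),
                    state = "ref_normalized")
  pca <- per_batch_pca(m, n_components = 2)
  expect_equal(pca$scores[1, ], pca$scores[2, ], tolerance = 1e-10)
})

test_that("batch-corrected matrices are rejected; dimension bounds enforced", {
  set.seed(35)
  vals <- 2^matrix(rnorm(40, 4, 1), 10, 4,
                   dimnames = list(sprintf("P%02d", 1:10), NULL))
  m <- make_protmat(vals, tiny_design(conditions = "a", channels_per_batch = 4),
                    state = "combat_corrected")
  expect_error(per_batch_pca(m, 2), "uncorrected")
  m2 <- make_protmat(vals, tiny_design(conditions = "a", channels_per_batch = 4),
                     state = "ref_normalized")
  expect_error(per_batch_pca(m2, 4), "exceeds")
})

test_that("relative distances are invariant to global scaling of the log2 matrix", {
  d <- tiny_design(n_batches = 2, conditions = c("a", "b"))
  conds <- list(a = list(regulated = 1L, fold_change = 1.8),
                b = list(regulated = integer(0), fold_change = numeric(0)))
  cfg <- sim_config(n_proteins = 40, conditions = conds,
                    protein_dropout_rate = 0, missing_channel_rate = 0,
                    unassigned_rate = 0, seed = 37)
  s <- simulate_psm_table(cfg, d)
  q <- quantify_batches(s$psms, d)
  m <- q$matrices[[1]]
  rep1 <- relative_distance(per_batch_pca(m, 2))
  m_scaled <- m
  m_scaled$values <- 2^(3.7 * log2(m$values))   # scale the whole log2 matrix
  rep2 <- relative_distance(per_batch_pca(m_scaled, 2))
  expect_false(isTRUE(all.equal(rep1$raw_distance, rep2$raw_distance)))
  expect_equal(rep1$relative_distance, rep2$relative_distance, tolerance = 1e-9)
})

test_that("mean relative distance grows with the injected condition shift", {
  mean_dist <- function(shift, seeds = 1:12) {
    vals <- vapply(seeds, function(sd) {
      d <- tiny_design(n_batches = 2, conditions = c("a", "b"), repeats = 2)
      conds <- list(a = list(regulated = 1:10,
                             fold_change = rep(2^shift, 10)),
                    b = list(regulated = integer(0), fold_change = numeric(0)))
      cfg <- sim_config(n_proteins = 40, conditions = conds,
                        protein_dropout_rate = 0, missing_channel_rate = 0,
                        unassigned_rate = 0, noise_sd = 0.25, seed = 1000 + sd)
      s <- simulate_psm_table(cfg, d)
      q <- quantify_batches(s$psms, d)
      rep <- batch_relative_distances(q$matrices, 2)
      mean(rep$relative_distance[rep$condition == "a"])
    }, numeric(1))
    mean(vals)
  }
  dists <- vapply(c(0, 1, 2), mean_dist, numeric(1))
  expect_true(all(diff(dists) > 0))
})

test_that("condition summaries report mean and standard error correctly", {
  rep <- structure(data.frame(batch_id = "b1",
                              sample_id = c("1.1", "1.2", "1.3", "2.1"),
                              participant = c("1", "1", "1", "2"),
                              condition = c("x", "x", "x", "x"),
                              raw_distance = 1,
                              relative_distance = c(1, 2, 3, 5)),
                   class = c("distance_report", "data.frame"))
  s <- summarize_by_condition(rep)
  p1 <- s[s$participant == "1", ]
  expect_equal(p1$mean_relative_distance, 2)
  expect_equal(p1$se, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(p1$se, 0.5774, tolerance = 1e-4)
  # single replicate: SE missing
  p2 <- s[s$participant == "2", ]
  expect_equal(p2$mean_relative_distance, 5)
  expect_true(is.na(p2$se))
  # all replicates equal: SE 0
  rep$relative_distance <- c(2, 2, 2, 5)
  s2 <- summarize_by_condition(rep)
  expect_equal(s2$se[s2$participant == "1"], 0)
})
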