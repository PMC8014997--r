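test_that("protein intersection keeps exactly the proteins present in all batches", {
  cols <- function(b) data.frame(batch_id = b, channel = c("126", "127_N"),
                                 sample_id = c("1.P", "2.P"),
                                 participant = c("1", "2"),
                                 condition = "unstimulated",
                                 concentration_ppm = NA_real_,
                                 is_reference_pool = TRUE,
                                 stringsAsFactors = FALSE)
  m1 <- make_protmat(matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), NULL)),
                     cols("b1"))
  m2 <- make_protmat(matrix(1:6, 3, 2, dimnames = list(c("B", "C", "D"), NULL)),
                     cols("b2"))
  out <- intersect_proteins(list(m1, m2))
  expect_equal(rownames(out$values), c("B", "C"))
  expect_equal(out$state, "concatenated")
  expect_equal(attr(out, "dropped_proteins")[[1]], "A")

  # identical protein sets: everything retained
  out2 <- intersect_proteins(list(m1, m1, m1))
  expect_equal(rownames(out2$values), c("A", "B", "C"))
  expect_equal(ncol(out2$values), 6)

  m3 <- make_protmat(matrix(1:4, 2, 2, dimnames = list(c("X", "Y"), NULL)),
                     cols("b3"))
  expect_error(intersect_proteins(list(m1, m3)), "no protein is present")
})

test_that("intersection count on synthetic 6-batch data matches brute force", {
  d <- generate_design(6, 2, paste0("c", 1:8), 3, seed = 3)
  conds <- setNames(lapply(1:8, function(i)
    list(regulated = integer(0), fold_change = numeric(0))), paste0("c", 1:8))
  cfg <- sim_config(n_proteins = 200, conditions = conds,
                    protein_dropout_rate = 0.17, seed = 19)
  s <- simulate_psm_table(cfg, d)
  q <- quantify_batches(s$psms, d)
  sets <- lapply(q$matrices, function(m) rownames(m$values))
  brute <- sort(Reduce(intersect, sets))
  out <- intersect_proteins(q$matrices)
  expect_equal(rownames(out$values), brute)
  # the dropout default targets the study geometry: roughly a third of
  # proteins survive all six batches
  expect_gt(length(brute), 40)
  expect_lt(length(brute), 100)
})

test_that("a single batch passes through the correction unchanged", {
  m <- make_batched_matrix(n_batches = 1, n_proteins = 10, seed = 4)
  out <- combat_correct(m)
  expect_equal(out$matrix$values, m$values, tolerance = 1e-9)
  expect_equal(out$matrix$state, "combat_corrected")
})

test_that("a pure additive batch shift is removed exactly in the zero-noise limit", {
  set.seed(5)
  base <- rnorm(200, 4, 1)
  spread <- seq(-0.5, 0.5, length.out = 10)   # within-batch structure, no noise
  b1 <- outer(base, spread, `+`)
  b2 <- b1 + 1.7                              # additive gamma on batch 2
  cols <- rbind(
    data.frame(batch_id = "b1", channel = paste0("ch", 1:10),
               sample_id = paste0("s", 1:10), participant = "1",
               condition = "condA", concentration_ppm = NA_real_,
               is_reference_pool = FALSE, stringsAsFactors = FALSE),
    data.frame(batch_id = "b2", channel = paste0("ch", 1:10),
               sample_id = paste0("t", 1:10), participant = "1",
               condition = "condA", concentration_ppm = NA_real_,
               is_reference_pool = FALSE, stringsAsFactors = FALSE))
  vals <- 2^cbind(b1, b2)
  rownames(vals) <- sprintf("P%03d", 1:200)
  m <- make_protmat(vals, cols, state = "concatenated")
  out <- combat_correct(m)
  X <- log2(out$matrix$values)
  means1 <- rowMeans(X[, 1:10])
  means2 <- rowMeans(X[, 11:20])
  expect_lt(max(abs(means1 - means2)), 1e-6)
})

test_that("corrected values match the independent per-protein EB oracle", {
  m <- make_batched_matrix(n_proteins = 50, n_batches = 6, per_batch = 10,
                           seed = 6)
  out <- combat_correct(m)
  oracle <- combat_oracle(log2(m$values), m$columns$batch_id)
  expect_lt(max(abs(log2(out$matrix$values) - oracle)), 1e-6)
})

test_that("corrected values agree with the reference library implementation", {
  library(sva)
  m <- make_batched_matrix(n_proteins = 50, n_batches = 6, per_batch = 10,
                           seed = 7)
  out <- combat_correct(m)
  ref <- suppressMessages(
    sva::ComBat(dat = log2(m$values), batch = factor(m$columns$batch_id),
                mod = NULL, par.prior = TRUE, prior.plots = FALSE))
  # sva stops its EB solver at a looser internal tolerance; agreement is
  # asserted at that scale
  expect_lt(max(abs(log2(out$matrix$values) - ref)), 2e-3)
})

test_that("EB shrinkage contracts gamma toward the batch prior mean", {
  m <- make_batched_matrix(n_proteins = 60, n_batches = 4, seed = 8)
  model <- combat_correct(m)$model
  expect_true(all(model$delta_hat > 0))
  expect_true(all(model$delta_star > 0))
  for (bi in seq_along(model$batches)) {
    g_bar <- model$prior_params$gamma_bar[bi]
    expect_true(all(abs(model$gamma_star[bi, ] - g_bar) <=
                      abs(model$gamma_hat[bi, ] - g_bar) + 1e-12))
  }
})

test_that("correction reduces the variance explained by batch", {
  d <- generate_design(6, 2, paste0("c", 1:4), 3, seed = 9,
                       channels_per_batch = 6)
  conds <- setNames(lapply(1:4, function(i)
    list(regulated = integer(0), fold_change = numeric(0))), paste0("c", 1:4))
  cfg <- sim_config(n_proteins = 80, channels_per_batch = 6,
                    conditions = conds, batch_location_sd = 0.8,
                    protein_dropout_rate = 0, seed = 23)
  s <- simulate_psm_table(cfg, d)
  # skip reference normalization here: it already removes the location
  # shift, which is exactly what this test must leave in place
  f <- filter_psms(s$psms, d)
  mats <- lapply(unique(d$batch_id), function(b)
    rollup_proteins(sum_scale(peptide_matrix(f, d, b))))
  concat <- intersect_proteins(mats)
  out <- combat_correct(concat)
  before <- mean_batch_eta_sq(concat$values, concat$columns$batch_id)
  after <- mean_batch_eta_sq(out$matrix$values, concat$columns$batch_id)
  expect_lt(after, before)
  # shape and identity preserved
  expect_equal(dim(out$matrix$values), dim(concat$values))
  expect_equal(rownames(out$matrix$values), rownames(concat$values))
  expect_equal(colnames(out$matrix$values), colnames(concat$values))
})

test_that("zero-variance proteins fall back to location-only correction", {
  set.seed(10)
  vals <- matrix(2^rnorm(40, 4), 4, 10,
                 dimnames = list(paste0("P", 1:4), NULL))
  vals[1, ] <- rep(c(2, 8), each = 5)   # constant within each batch
  cols <- data.frame(batch_id = rep(c("b1", "b2"), each = 5),
                     channel = paste0("ch", rep(1:5, 2)),
                     sample_id = paste0("s", 1:10), participant = "1",
                     condition = "condA", concentration_ppm = NA_real_,
                     is_reference_pool = FALSE, stringsAsFactors = FALSE)
  m <- make_protmat(vals, cols, state = "concatenated")
  out <- combat_correct(m)
  expect_equal(out$model$location_only, "P1")
  # the flat protein ends up with equal values everywhere (batch means removed)
  expect_equal(unname(out$matrix$values[1, ]), rep(4, 10), tolerance = 1e-9)
})
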