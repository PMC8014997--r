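# A reference-normalized-style matrix: pools at 1, samples as given.
diff_matrix <- function(sample_values, pools_per_participant = 2,
                        pool_value = 1) {
  n_samp <- ncol(sample_values)
  n_pool <- pools_per_participant
  vals <- cbind(matrix(pool_value, nrow(sample_values), n_pool), sample_values)
  rownames(vals) <- rownames(sample_values) %||% sprintf("P%03d", seq_len(nrow(vals)))
  cols <- data.frame(batch_id = "b1",
                     channel = paste0("ch", seq_len(ncol(vals))),
                     sample_id = c(paste0(seq_len(n_pool), ".P"),
                                   paste0(rep(1:2, length.out = n_samp), ".1")),
                     participant = c(as.character(seq_len(n_pool)),
                                     rep(c("1", "2"), length.out = n_samp)),
                     condition = c(rep("unstimulated", n_pool),
                                   rep("condA", n_samp)),
                     concentration_ppm = NA_real_,
                     is_reference_pool = c(rep(TRUE, n_pool), rep(FALSE, n_samp)),
                     stringsAsFactors = FALSE)
  make_protmat(vals, cols, state = "ref_normalized")
}

test_that("fold changes are geomean ratios against the pools", {
  # all normalized sample values 2.0 -> fold change 2.0
  m <- diff_matrix(matrix(2, 1, 6))
  expect_equal(unname(fold_change(m, "condA")), 2.0, ignore_attr = TRUE)
  # values {1.5, 2.0} -> geomean sqrt(3)
  m2 <- diff_matrix(matrix(c(1.5, 2.0), 1, 2))
  expect_equal(unname(fold_change(m2, "condA")), sqrt(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # the two computational forms coincide when pools sit exactly at 1
  fc <- fold_change(m2, "condA")
  expect_equal(as.numeric(fc), as.numeric(attr(fc, "geomean_form")),
               tolerance = 1e-12)
  # fold change of the pools against themselves is exactly 1
  pool_m <- diff_matrix(matrix(c(3, 5), 1, 2))
  num <- exp(rowMeans(log(pool_m$values[, 1:2, drop = FALSE])))
  den <- exp(rowMeans(log(pool_m$values[, 1:2, drop = FALSE])))
  expect_equal(unname(num / den), 1)
})

test_that("zero-noise spiked proteins come back at exactly the spiked ratio", {
  d <- tiny_design(n_batches = 2, conditions = c("condA", "condB"), repeats = 2)
  cfg <- sim_config(n_proteins = 10, peptides_per_protein = c(2, 2),
                    batch_location_sd = 0, noise_sd = 0,
                    missing_channel_rate = 0, unassigned_rate = 0,
                    protein_dropout_rate = 0, flagged_q_rate = 0, seed = 47,
                    conditions = list(condA = list(regulated = 3L, fold_change = 1.72),
                                      condB = list(regulated = integer(0),
                                                   fold_change = numeric(0))))
  s <- simulate_psm_table(cfg, d)
  q <- quantify_batches(s$psms, d, sum_scaling = FALSE)
  concat <- intersect_proteins(q$matrices)
  fc <- fold_change(concat, "condA")
  expect_equal(unname(fc["PROT0003"]), 1.72, tolerance = 1e-12)
  expect_equal(unname(fc[setdiff(names(fc), "PROT0003")]),
               rep(1, 9), tolerance = 1e-12)
})

test_that("the one-sample t-test matches the textbook formula and stats::t.test", {
  vals <- 2^matrix(c(0.5, 1.0, 1.5,
                     0, 0, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("P1", "P2"), NULL))
  m <- diff_matrix(vals)
  tt <- test_regulation(m, "condA")
  x <- c(0.5, 1.0, 1.5)
  t_manual <- mean(x) / (sd(x) / sqrt(3))
  p_manual <- 2 * pt(-abs(t_manual), df = 2)
  expect_equal(tt$t[1], t_manual, tolerance = 1e-12)
  expect_equal(tt$p[1], p_manual, tolerance = 1e-12)
  ref <- t.test(x, mu = 0)
  expect_equal(tt$p[1], ref$p.value, tolerance = 1e-12)
  # zero variance: p missing and logged
  expect_true(is.na(tt$p[2]))
  expect_equal(attr(tt, "zero_variance"), "P2")
})

test_that("type-I error under the null sits near the nominal level", {
  set.seed(51)
  null_vals <- 2^matrix(rnorm(2000 * 6, 0, 0.25), 2000, 6,
                        dimnames = list(sprintf("P%04d", 1:2000), NULL))
  m <- diff_matrix(null_vals)
  tt <- test_regulation(m, "condA")
  frac <- mean(tt$p < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("regulation calls follow the threshold and significance gates", {
  fc <- c(A = 1.81, B = 0.52, C = 1.2, D = 1.6, E = 0.5)
  tests <- data.frame(protein = names(fc), n = 6,
                      mean_log2 = log2(fc), t = 3,
                      p = c(0.01, 0.01, 0.001, 0.2, NA),
                      stringsAsFactors = FALSE)
  out <- call_regulation(fc, tests, "condA", alpha = 0.05,
                         up_threshold = 1.5, down_threshold = 0.667)
  expect_equal(out$call, c("up", "down", "none", "none", "none"))
  expect_s3_class(out, "differential_result")
  expect_error(call_regulation(fc, tests, "condA", up_threshold = 0.9),
               "up_threshold")
  expect_error(call_regulation(fc, tests, "condA", alpha = 1.5), "alpha")
})

test_that("median estimated log2 fold change recovers the truth within 0.15", {
  set.seed(53)
  est <- replicate(50, {
    vals <- 2^matrix(log2(1.8) + rnorm(6, 0, 0.25), 1, 6)
    unname(fold_change(diff_matrix(vals), "condA"))
  })
  expect_lt(abs(median(log2(est)) - log2(1.8)), 0.15)
})

test_that("enrichment p-values match brute-force hypergeometric summation", {
  bg <- sprintf("P%03d", 1:100)
  fg <- bg[1:10]
  ann <- list(term1 = bg[c(1:5, 50:54)],     # 5 of 10 in foreground
              term2 = bg[60:69],             # zero overlap
              term3 = bg[1:3])
  out <- go_enrichment(fg, bg, ann)
  # brute force: P(X >= k) by explicit summation over the tail
  brute <- function(k, K, N, n) sum(dhyper(k:min(K, n), K, N - K, n))
  expect_equal(out$p[out$term == "term1"], brute(5, 10, 100, 10),
               tolerance = 1e-10)
  expect_equal(out$p[out$term == "term3"], brute(3, 3, 100, 10),
               tolerance = 1e-10)
  # zero overlap: upper tail including 0 is 1
  expect_equal(out$p[out$term == "term2"], 1)
  expect_error(go_enrichment(c(fg, "PXXX"), bg, ann), "absent from the background")
})

test_that("BH adjustment matches the direct step-up formula", {
  bg <- sprintf("P%03d", 1:60)
  # three nested terms engineered to give raw p of increasing size
  ann <- list(t1 = bg[1:10], t2 = bg[c(1:5, 31:35)], t3 = bg[c(1, 31:39)])
  out <- go_enrichment(bg[1:10], bg, ann)
  ps <- sort(out$p)
  k <- length(ps)
  direct <- pmin(rev(cummin(rev(ps * k / seq_len(k)))), 1)
  expect_equal(sort(out$adjusted_p), direct, tolerance = 1e-12)
  # the textbook example: p = {0.01, 0.02, 0.03} -> all adjusted to 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})

test_that("differential_table stacks conditions and flags spiked proteins", {
  d <- tiny_design(n_batches = 2, conditions = c("condA", "condB"), repeats = 3,
                   channels_per_batch = 8)
  cfg <- sim_config(n_proteins = 30, peptides_per_protein = c(2, 4),
                    channels_per_batch = 8,
                    protein_dropout_rate = 0, missing_channel_rate = 0,
                    unassigned_rate = 0, noise_sd = 0.2, seed = 59,
                    conditions = list(condA = list(regulated = 5L, fold_change = 2.15),
                                      condB = list(regulated = 7L, fold_change = 0.52)))
  s <- simulate_psm_table(cfg, d)
  q <- quantify_batches(s$psms, d)
  concat <- intersect_proteins(q$matrices)
  cc <- combat_correct(concat)
  dd <- differential_table(cc$matrix)
  expect_setequal(unique(dd$condition), c("condA", "condB"))
  a5 <- dd[dd$protein == "PROT0005" & dd$condition == "condA", ]
  expect_equal(a5$call, "up")
  b7 <- dd[dd$protein == "PROT0007" & dd$condition == "condB", ]
  expect_equal(b7$call, "down")
})
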