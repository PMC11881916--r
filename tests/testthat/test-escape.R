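test_that("escape proportion follows its defining ratio", {
  expect_equal(escape_proportion(0, 100), 0)
  expect_equal(escape_proportion(50, 50), 0.5)
  # the dataset-level X split: 8.3% castaneus / 91.7% musculus
  expect_equal(escape_proportion(8.3, 91.7), 0.083)
  expect_true(is.na(escape_proportion(0, 0)))
})

test_that("autosomal bias ratio is the castaneus/musculus total ratio", {
  pb <- data.frame(gene_id = rep(c("a1", "x1"), each = 2),
                   allele = rep(c("xa_strain", "xi_strain"), 2),
                   cell_type = "T", age_group = "young",
                   value = c(56, 44, 10, 1))
  genes <- data.frame(gene_id = c("a1", "x1"), chromosome = c("1", "X"))
  br <- autosomal_bias_ratio(pb, genes)
  expect_equal(br$ratio, 11 / 14)   # X rows excluded
  # scale invariance
  pb2 <- pb; pb2$value <- pb2$value * 2
  expect_equal(autosomal_bias_ratio(pb2, genes)$ratio, br$ratio)
  # balanced autosomes give 1
  pb$value <- c(50, 50, 0, 0)
  expect_equal(autosomal_bias_ratio(pb, genes)$ratio, 1)
  # zero reference total is an error
  pb$value <- c(0, 50, 0, 0)
  expect_error(autosomal_bias_ratio(pb, genes), "zero")
})

test_that("bias adjustment evaluates its formula and is identity at ratio 1", {
  expect_equal(adjust_escape(0.5, 11 / 14), 14 / 25)
  expect_equal(adjust_escape(0, 5), 0)
  set.seed(1)
  p <- runif(1000)
  expect_equal(adjust_escape(p, 1), p)
})

test_that("bias adjustment is monotone in both arguments", {
  p <- seq(0, 1, by = 0.01)
  for (r in c(0.5, 11 / 14, 1, 2)) {
    adj <- adjust_escape(p, r)
    expect_true(all(diff(adj) >= 0), label = paste("monotone in p at ratio", r))
  }
  for (pp in c(0.1, 0.5, 0.9)) {
    adj <- adjust_escape(pp, c(0.5, 0.8, 1, 1.5))
    expect_true(all(diff(adj) <= 0), label = paste("antitone in ratio at p", pp))
  }
})

test_that("the 99% interval evaluates exactly and behaves at its limits", {
  expect_equal(as.vector(escape_interval(0, 50)), c(0, 0))
  expect_equal(as.vector(escape_interval(0.5, 100)), c(0.37125, 0.62875))
  expect_equal(as.vector(escape_interval(0.2, 1e4)), c(0.1897, 0.2103))
  expect_error(escape_interval(0.5, 0), "positive")
  # contains the estimate; width shrinks to 0 with depth
  for (p in c(0.01, 0.2, 0.9)) {
    ci <- escape_interval(p, 10^(1:6))
    expect_true(all(ci[, "lower"] <= p & p <= ci[, "upper"]))
    w <- ci[, "upper"] - ci[, "lower"]
    expect_true(all(diff(w) < 0))
    expect_lt(w[6], 0.01)
  }
  # clamped to [0, 1]
  ci <- escape_interval(0.99, 10)
  expect_lte(ci[, "upper"], 1)
})

test_that("depth threshold is the pooled 5th percentile with interpolation", {
  genes <- data.frame(gene_id = c("x1", "x2", "a1"), chromosome = c("X", "X", "1"))
  pb <- data.frame(gene_id = rep(c("x1", "x2", "a1"), each = 2),
                   allele = rep(c("xa_strain", "xi_strain"), 3),
                   cell_type = "T", age_group = "young",
                   value = c(7, 7, 7, 7, 99, 99))
  expect_equal(depth_threshold(pb, genes), 7)    # constant distribution
  pb$value <- c(0, 100, 0, 0, 5, 5)              # autosomal rows ignored
  # pooled X values {0, 100, 0, 0}: 5th percentile by linear interpolation
  expect_equal(depth_threshold(pb, genes),
               unname(quantile(c(0, 100, 0, 0), 0.05)))
  pbx <- pb[pb$gene_id == "x1", ]
  expect_equal(depth_threshold(pbx, genes), 5)   # {0, 100} -> 5
  # adding large values leaves a low percentile within the original range
  pb2 <- rbind(pb, data.frame(gene_id = "x2", allele = "xa_strain",
                              cell_type = "T2", age_group = "young",
                              value = 1e6))
  expect_lte(depth_threshold(pb2, genes), 100)
  expect_error(depth_threshold(pb[pb$gene_id == "a1", ], genes), "no X-linked")
})

test_that("escapee status rule applies its strict thresholds", {
  # escapee: CI lower > 0, adjusted value > 0.05, depths at/above threshold
  expect_equal(call_escape_status(0.10, 0.01, 50, 450, threshold = 10), "escapee")
  # CI lower exactly 0 (after clamping) is not an escapee
  expect_equal(call_escape_status(0.30, 0, 60, 140, threshold = 10), "inactive")
  # adjusted value exactly 0.05 is not an escapee
  expect_equal(call_escape_status(0.05, 0.01, 50, 950, threshold = 10), "inactive")
  # ties at the depth threshold pass ("lower than" is strict)
  expect_equal(call_escape_status(0.10, 0.01, 10, 10, threshold = 10), "escapee")
  # low Xa: not assessable; low Xi only: inactive
  expect_equal(call_escape_status(0.10, 0.01, 50, 9, threshold = 10), "not_assessable")
  expect_equal(call_escape_status(0.10, 0.01, 9, 50, threshold = 10), "inactive")
  # nothing detected
  expect_equal(call_escape_status(NA, NA, 0, 0, threshold = 0), "not_detected")
})

test_that("escape calls are invariant to the normalization scale", {
  sim <- simulate_study(quick_config())
  c1 <- call_escape(sim$dataset, target_sum = 1e4)
  c2 <- call_escape(sim$dataset, target_sum = 5e4)
  expect_equal(c1$p_esc, c2$p_esc)
  expect_equal(c1$p_escadj, c2$p_escadj)
  expect_equal(c1$status, c2$status)
  expect_false(isTRUE(all.equal(c1$ci_lower, c2$ci_lower)))  # widths do change
})

test_that("adjusted escape recovers planted truth within 0.02 at deep counts", {
  cfg <- sim_config(n_cell_types = 1, cells_per_type_per_sample = 500,
                    n_samples_per_age = 2, n_autosomal_genes = 50,
                    n_x_genes = 20, baseline_escape_fraction = 0.2,
                    escape_prob_range = c(0.1, 0.3), mapping_bias = 0.12,
                    rate_sdlog = 0, celltype_sdlog = 0,
                    mean_depth_per_cell = 4000, seed = 9)
  sim <- simulate_study(cfg)
  calls <- call_escape(sim$dataset, include_all = FALSE)
  truth <- sim$truth$params
  esc <- truth[truth$gene_id %in% sim$truth$escapees & truth$age_group == "young", ]
  got <- calls[match(paste(esc$gene_id, "young"),
                     paste(calls$gene_id, calls$age_group)), ]
  expect_true(all(abs(got$p_escadj - esc$p_cast) <= 0.02))
  # and they are called escapees
  expect_true(all(got$status == "escapee"))
})

test_that("per-group bias scope is exposed and close to the global ratio here", {
  sim <- simulate_study(quick_config())
  cg <- call_escape(sim$dataset, bias_scope = "global")
  cp <- call_escape(sim$dataset, bias_scope = "per_group")
  ct_rows <- cg$cell_type != "all"
  expect_equal(cg$p_escadj[ct_rows], cp$p_escadj[ct_rows], tolerance = 0.05)
})
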