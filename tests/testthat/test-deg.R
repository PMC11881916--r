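# Independent Pearson chi-squared oracle on a 2x2 table.
oracle_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  sum((o - e)^2 / e)
}

test_that("DE feature filter matches brute-force rule application", {
  expect_false(filter_de_features(rbind(c(3, 3, 3))))          # total 9
  expect_true(filter_de_features(rbind(c(12, 0))))             # total 12, max 12
  expect_false(filter_de_features(rbind(c(6, 6))))             # max 6 < 10
  expect_true(filter_de_features(rbind(c(6, 6)), mode = "every_sample") == FALSE)
  expect_true(filter_de_features(rbind(c(10, 10)), mode = "every_sample"))

  # boundary grid vs independent rule
  grid <- expand.grid(s1 = c(0, 5, 9, 10, 11), s2 = c(0, 5, 9, 10, 11))
  m <- as.matrix(grid)
  got <- filter_de_features(m)
  want <- apply(m, 1, function(r) sum(r) >= 10 && max(r) >= 10)
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("significance rule matches brute-force enumeration at its boundaries", {
  grid <- expand.grid(p_adjusted = c(0.049, 0.05, 0.051),
                      log2fc = c(-0.11, -0.1, 0, 0.1, 0.11))
  got <- call_significant(grid)
  want <- apply(grid, 1, function(r)
    r["p_adjusted"] < 0.05 && (r["log2fc"] > 0.1 || r["log2fc"] < -0.1))
  expect_equal(got, unname(want))
  # published rule examples
  expect_true(call_significant(data.frame(p_adjusted = 0.049, log2fc = 0.11)))
  expect_false(call_significant(data.frame(p_adjusted = 0.05, log2fc = 0.5)))
  expect_false(call_significant(data.frame(p_adjusted = 0.01, log2fc = 0.1)))
  expect_false(call_significant(data.frame(p_adjusted = NA, log2fc = 2)))
})

test_that("chromosome enrichment equals the independent chi-squared oracle", {
  genes <- data.frame(gene_id = c(paste0("x", 1:100), paste0("a", 1:1000)),
                      chromosome = c(rep("X", 100), rep("1", 1000)))
  expressed <- genes$gene_id
  sig <- c(paste0("x", 1:20), paste0("a", 1:100))
  e <- chromosome_enrichment(sig, expressed, genes)
  expect_equal(e$chi2, 9.354, tolerance = 1e-4)
  expect_equal(e$chi2, oracle_chi2(20, 80, 100, 900), tolerance = 1e-12)
  expect_equal(e$n_sig_focal, 20); expect_equal(e$n_expressed_focal, 100)

  # equal proportions give exactly 0
  e0 <- chromosome_enrichment(c(paste0("x", 1:10), paste0("a", 1:100)),
                              expressed, genes)
  expect_equal(e0$chi2, 0)

  # swapping focal and comparison leaves the statistic unchanged
  esw <- chromosome_enrichment(sig, expressed, genes, focal = "1", comparison = "X")
  expect_equal(esw$chi2, e$chi2)
  expect_equal(esw$p_value, e$p_value)

  # 1000 random 2x2 tables against the oracle
  set.seed(7)
  for (i in 1:1000) {
    ne_f <- sample(5:200, 1); ne_c <- sample(5:2000, 1)
    ns_f <- sample(1:(ne_f - 1), 1); ns_c <- sample(1:(ne_c - 1), 1)
    g2 <- data.frame(gene_id = c(paste0("x", seq_len(ne_f)),
                                 paste0("a", seq_len(ne_c))),
                     chromosome = c(rep("X", ne_f), rep("2", ne_c)))
    s2 <- c(paste0("x", seq_len(ns_f)), paste0("a", seq_len(ns_c)))
    got <- chromosome_enrichment(s2, g2$gene_id, g2)$chi2
    expect_equal(got, oracle_chi2(ns_f, ne_f - ns_f, ns_c, ne_c - ns_c),
                 tolerance = 1e-9)
  }
  expect_error(chromosome_enrichment(sig, paste0("x", 1:100), genes),
               "empty margin")
})

test_that("mirrored age groups give zero log fold change", {
  set.seed(3)
  y <- matrix(rnbinom(40 * 3, mu = 50, size = 5), 40, 3)
  counts <- cbind(y, y)  # old samples identical to young samples
  rownames(counts) <- paste0("g", 1:40, "::xa_strain")
  colnames(counts) <- c(paste0("young_", 1:3), paste0("old_", 1:3))
  keep <- filter_de_features(counts)
  de <- fit_pseudobulk_de(counts[keep, ], rep(c("young", "old"), each = 3))
  expect_true(all(abs(de$log2fc) < 1e-4))
  expect_false(any(de$significant))
})

test_that("degenerate designs are rejected", {
  counts <- matrix(50L, 5, 4,
                   dimnames = list(paste0("g", 1:5, "::xa_strain"), paste0("s", 1:4)))
  expect_error(fit_pseudobulk_de(counts, rep("young", 4)), "degenerate")
  expect_error(fit_pseudobulk_de(counts, c("young", "old", "old", "old")),
               "2 samples per age")
})

test_that("null pseudobulk DE keeps raw p values near uniform", {
  set.seed(21)
  counts <- matrix(rnbinom(300 * 8, mu = 200, size = 8), 300, 8)
  rownames(counts) <- paste0("g", 1:300, "::xa_strain")
  colnames(counts) <- paste0("s", 1:8)
  de <- fit_pseudobulk_de(counts, rep(c("young", "old"), each = 4))
  frac <- mean(de$p_value < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.12)
  # BH monotonicity: adjusted p never reorders raw p
  ord <- order(de$p_value)
  expect_true(all(diff(de$p_adjusted[ord]) >= -1e-12))
})

test_that("a planted 4-fold allele effect is recovered with correct sign", {
  set.seed(8)
  mu <- matrix(300, 60, 8)
  mu[1, 5:8] <- 1200  # 4-fold increase in old samples for feature 1
  counts <- matrix(rnbinom(60 * 8, mu = mu, size = 20), 60, 8)
  rownames(counts) <- paste0("g", 1:60, "::xi_strain")
  colnames(counts) <- paste0("s", 1:8)
  de <- fit_pseudobulk_de(counts, rep(c("young", "old"), each = 4))
  hit <- de[de$gene_id == "g1", ]
  expect_true(hit$significant)
  expect_lt(abs(hit$log2fc - 2), 0.5)
})

test_that("cell-type categories follow the neuronal/glial rules", {
  # >= 2 neuronal, <= 1 glial
  expect_equal(classify_deg_category(c("CA1", "DG"), c(1, 1))$category, "neuronal")
  # >= 2 glial, <= 1 neuronal (a neuronal member is allowed)
  expect_equal(classify_deg_category(c("Astro", "Oligo", "CA1"), c(1, 1, 1))$category,
               "glial")
  # 2 cell types, neither class rule met, opposite directions -> excluded
  expect_equal(classify_deg_category(c("CA1", "Astro"), c(1, -1))$category,
               "excluded_discordant")
  expect_equal(classify_deg_category(c("CA1", "Astro"), c(1, 1))$category,
               "multiple")
  expect_equal(classify_deg_category("OPC", -1)$category, "cell_type_specific")
  expect_error(classify_deg_category("Unknown", 1), "missing from class map")
})

test_that("run_de covers all cell types and supports enrichment end-to-end", {
  sim <- simulate_study(quick_config())
  deg <- run_de(sim$dataset)
  expect_setequal(unique(deg$cell_type), c("all", "CA1", "CA3"))
  # planted autosomal xa fold change is significant with positive sign everywhere
  hit <- deg[deg$gene_id == "geneA0001" & deg$allele == "xa_strain", ]
  expect_true(all(hit$significant))
  expect_true(all(hit$log2fc > 0))
  # its xi allele is untouched
  miss <- deg[deg$gene_id == "geneA0001" & deg$allele == "xi_strain", ]
  expect_true(all(abs(miss$log2fc) < 1))

  expressed <- attr(deg, "expressed")
  d <- deg[deg$cell_type == "all", ]
  e <- chromosome_enrichment(paste(d$gene_id, d$allele, sep = "::")[d$significant],
                             expressed[["all"]], sim$dataset$genes)
  expect_gte(e$n_sig_focal, 1)  # the planted new-escape xi allele is X-linked DE
})
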