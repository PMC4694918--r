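test_that("probe-to-TSS linking matches the all-pairs distance oracle", {
  set.seed(7)
  for (rep in 1:5) {
    probes <- data.frame(
      probe_id = sprintf("cg%03d", 1:50),
      chrom = sample(c("chr1", "chr2", "chr3"), 50, replace = TRUE),
      position = sample.int(50000, 50), stringsAsFactors = FALSE)
    features <- data.frame(
      feature_id = sprintf("f%02d", 1:10),
      chrom = sample(c("chr1", "chr2", "chr3"), 10, replace = TRUE),
      tss = sample.int(50000, 10),
      strand = sample(c("+", "-"), 10, replace = TRUE),
      stringsAsFactors = FALSE)
    got <- annotate_probes_to_features(probes, features, window = 2000)
    want <- annotate_oracle(probes, features, 2000)
    got <- got[order(got$linked_feature, got$probe_id),
               c("probe_id", "linked_feature", "tss_distance")]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("linking is inclusive at the window and signed by strand", {
  features <- data.frame(feature_id = c("plus", "minus"),
                         chrom = "chr1", tss = c(10000, 50000),
                         strand = c("+", "-"), stringsAsFactors = FALSE)
  probes <- data.frame(
    probe_id = c("at_tss", "at_edge", "past_edge", "down_minus"),
    chrom = "chr1",
    position = c(10000, 12000, 12001, 49000), stringsAsFactors = FALSE)
  ann <- annotate_probes_to_features(probes, features, window = 2000)
  expect_equal(ann$tss_distance[ann$probe_id == "at_tss"], 0L)
  expect_true("at_edge" %in% ann$probe_id)      # |d| == window stays linked
  expect_false("past_edge" %in% ann$probe_id)   # window + 1 bp is out
  # 1 kb before a minus-strand TSS in genomic coordinates is downstream (+)
  expect_equal(ann$tss_distance[ann$probe_id == "down_minus"], 1000L)
})

test_that("probes on unknown chromosomes are skipped with a warning", {
  features <- data.frame(feature_id = "f", chrom = "chr1", tss = 100,
                         strand = "+", stringsAsFactors = FALSE)
  probes <- data.frame(probe_id = c("a", "b"), chrom = c("chr1", "chrX"),
                       position = c(100, 100), stringsAsFactors = FALSE)
  expect_warning(ann <- annotate_probes_to_features(probes, features, 500),
                 "skipped")
  expect_identical(ann$probe_id, "a")
})

test_that("student t matches the closed form and its degenerate rules", {
  a <- c(0.1, 0.2, 0.15); b <- c(0.8, 0.9, 0.85)
  got <- group_test(a, b, method = "student_t")
  want <- student_t_oracle(a, b)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  expect_lt(got$p_value, 0.01)
  expect_equal(got$delta, mean(a) - mean(b))
  # identical constant vectors: delta 0, p 1
  same <- group_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$p_value, 1)
  expect_equal(same$delta, 0)
  # zero variance with unequal means: p 0, flagged degenerate
  deg <- group_test(c(1, 1, 1), c(2, 2, 2))
  expect_equal(deg$p_value, 0)
  expect_true(deg$degenerate)
  expect_error(group_test(1, c(1, 2)), "at least 2")
})

test_that("group tests are symmetric and t is affine invariant", {
  set.seed(31)
  for (rep in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    for (m in c("student_t", "mann_whitney_u")) {
      ab <- group_test(a, b, method = m); ba <- group_test(b, a, method = m)
      expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
      expect_equal(ab$delta, -ba$delta, tolerance = 1e-12)
    }
    sc <- group_test(3 * a + 5, 3 * b + 5, method = "student_t")
    expect_equal(sc$p_value, group_test(a, b)$p_value, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney agrees with exact enumeration for groups up to 5", {
  got <- group_test(c(1, 2, 3), c(4, 5, 6), method = "mann_whitney_u")
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 0.1)   # 2/20 assignments are as extreme
  set.seed(17)
  for (rep in 1:15) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    pooled <- sample(100, na + nb)   # distinct values, exact test applies
    a <- pooled[1:na]; b <- pooled[-(1:na)]
    expect_equal(group_test(a, b, method = "mann_whitney_u")$p_value,
                 mwu_exact_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("methylation comparison tests each linked probe and each region", {
  sim <- gen_methylation_cohort(30, 9, n_tumor = 17, n_normal = 5, seed = 3)
  probe_res <- compare_methylation(sim$betas, sim$annotation, level = "probe")
  expect_equal(nrow(probe_res), nrow(sim$annotation))
  expect_true(all(probe_res$p_value >= 0 & probe_res$p_value <= 1))
  expect_equal(probe_res$delta,
               probe_res$mean_beta_tumor - probe_res$mean_beta_normal,
               tolerance = 1e-12)
  expect_true(all(probe_res$delta[probe_res$probe_id %in% sim$candidates] > 0))
  region_res <- compare_methylation(sim$betas, sim$annotation, level = "region")
  expect_equal(nrow(region_res), length(unique(sim$annotation$linked_feature)))
  expect_true(all(region_res$n_probes == 3))
  # region mean equals the mean of its probes' group means
  f1 <- sim$annotation$probe_id[sim$annotation$linked_feature == region_res$feature[1]]
  tum <- sim$betas$samples$sample_id[sim$betas$samples$group == "tumor"]
  expect_equal(region_res$mean_beta_tumor[1],
               mean(colMeans(sim$betas$values[f1, tum])), tolerance = 1e-12)
})

test_that("duplicating the normal group as tumor gives null p-values", {
  sim <- gen_methylation_cohort(20, 5, n_tumor = 5, n_normal = 5,
                                noise_sd = 0, seed = 5)
  vals <- sim$betas$values
  vals[, sim$betas$samples$group == "tumor"] <-
    vals[, sim$betas$samples$group == "normal"]
  nullbetas <- beta_matrix(vals, sim$betas$samples)
  res <- compare_methylation(nullbetas, sim$annotation)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$delta == 0))
})

test_that("BH adjustment is a monotone add-on column", {
  sim <- gen_methylation_cohort(30, 9, seed = 6)
  res <- compare_methylation(sim$betas, sim$annotation, adjust = "BH")
  expect_true(all(res$adj_p_value >= res$p_value - 1e-15))
  expect_equal(res$adj_p_value, p.adjust(res$p_value, "BH"))
})

test_that("five-number summary uses min/max whiskers and type-7 quartiles", {
  s <- summarize_beta_distribution(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(unname(s), c(0.1, 0.2, 0.3, 0.4, 0.5))
  const <- summarize_beta_distribution(rep(0.42, 7))
  expect_true(all(const == 0.42))
  set.seed(9)
  x <- runif(23)
  s2 <- summarize_beta_distribution(x)
  expect_equal(unname(s2[c(1, 5)]), range(x))
  expect_equal(unname(s2[2:4]), unname(quantile(x, c(0.25, 0.5, 0.75), type = 7)))
  expect_error(summarize_beta_distribution(numeric(0)), "non-empty")
})
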