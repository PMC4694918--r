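test_that("generators are deterministic under a fixed seed", {
  a <- gen_unmasking_experiment(30, 4, seed = 7)
  b <- gen_unmasking_experiment(30, 4, seed = 7)
  expect_identical(a, b)

  m1 <- gen_methylation_cohort(24, 6, seed = 7)
  m2 <- gen_methylation_cohort(24, 6, seed = 7)
  expect_identical(m1, m2)

  tt <- list(m1 = c("g1", "g2"), m2 = "g3")
  p1 <- gen_prediction_tensor(c("m1", "m2"), paste0("g", 1:5), tt, seed = 7)
  p2 <- gen_prediction_tensor(c("m1", "m2"), paste0("g", 1:5), tt, seed = 7)
  expect_identical(p1, p2)

  tr <- survival_truth("g1", "g2")
  s1 <- gen_survival_cohort(40, 5, tr, genes = paste0("g", 1:5), seed = 7)
  s2 <- gen_survival_cohort(40, 5, tr, genes = paste0("g", 1:5), seed = 7)
  expect_identical(s1, s2)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(gen_unmasking_experiment(10, 2, seed = 99))
  expect_identical(runif(1), before)
})

test_that("zero-noise unmasking experiment plants exact fold effects", {
  sim <- gen_unmasking_experiment(40, 5, noise_sd = 0,
                                  effect_range = c(4, 4), seed = 3)
  fold <- sim$treated$values / sim$control$values
  eff <- sim$truth$per_line_effect
  expect_equal(unname(fold), unname(eff), tolerance = 1e-12)
  affected <- rowSums(eff > 1) > 0
  expect_setequal(rownames(eff)[affected], sim$truth$silenced_mirnas)
  expect_true(all(rowSums(eff[sim$truth$silenced_mirnas, , drop = FALSE] > 1) >= 2))
})

test_that("unmasking generator validates its parameters", {
  expect_error(gen_unmasking_experiment(0, 0), "n_mirna")
  expect_error(gen_unmasking_experiment(10, 11), "n_silenced")
  expect_error(gen_unmasking_experiment(10, 2, effect_range = c(0.5, 2)),
               "effect_range")
})

test_that("methylation cohort keeps betas in range and plants the shift", {
  for (db in c(0.2, 0.5, 0.99)) {
    sim <- gen_methylation_cohort(30, 9, delta_beta = db, seed = 11)
    expect_true(all(sim$betas$values >= 0 & sim$betas$values <= 1))
  }
  # saturation: near-zero baseline, huge shift -> tumor ~1, normal ~0
  sat <- gen_methylation_cohort(12, 6, delta_beta = 0.99,
                                baseline_range = c(0, 0.005),
                                noise_sd = 0, seed = 2)
  tum <- sat$betas$samples$group == "tumor"
  expect_true(all(sat$betas$values[1:6, tum] > 0.98))
  expect_true(all(sat$betas$values[1:6, !tum] < 0.01))
  expect_error(gen_methylation_cohort(10, 2, delta_beta = 1.2), "delta_beta")
})

test_that("study-design cohort (17 tumor vs 5 normal) recovers the planted shift", {
  deltas <- vapply(1:10, function(s) {
    sim <- gen_methylation_cohort(30, 9, n_tumor = 17, n_normal = 5,
                                  delta_beta = 0.3, seed = s)
    res <- compare_methylation(sim$betas, sim$annotation, level = "probe")
    mean(res$delta[res$probe_id %in% sim$candidates])
  }, numeric(1))
  expect_true(all(deltas > 0))
  expect_lt(abs(mean(deltas) - 0.3), 0.05)
})

test_that("prediction tensor masks unavailable cells instead of zeroing them", {
  tt <- list(m1 = c("g1", "g2"), m2 = "g3")
  sim <- gen_prediction_tensor(c("m1", "m2"), paste0("g", 1:5), tt,
                               n_algorithms = 4, sensitivity = 1, fpr = 0,
                               availability = c(1, 1, 1, 0), seed = 5)
  expect_true(all(sim$available[4, ] == 0))
  expect_true(all(is.na(sim$calls[4, , ])))
  # the dead algorithm contributes to no denominator: removing it changes nothing
  trimmed <- prediction_tensor(sim$calls[1:3, , , drop = FALSE],
                               sim$available[1:3, , drop = FALSE])
  expect_identical(consensus_targets(sim)$per_mirna,
                   consensus_targets(trimmed)$per_mirna)
  expect_error(gen_prediction_tensor(character(0), "g1", list()), "non-empty")
})

test_that("noiseless prediction tensor reproduces true targets through voting", {
  tt <- list(m1 = c("g1", "g4"), m2 = c("g2", "g3", "g5"))
  sim <- gen_prediction_tensor(c("m1", "m2"), paste0("g", 1:6), tt,
                               sensitivity = 1, fpr = 0, availability = 1,
                               seed = 9)
  got <- consensus_targets(sim)$per_mirna
  expect_identical(got, lapply(tt, sort))
})

test_that("consensus recall on noisy tensors stays high (Monte Carlo)", {
  genes <- sprintf("g%02d", 1:50)
  tt <- list(m1 = genes[1:10], m2 = genes[11:25])
  recalls <- vapply(3:22, function(s) {
    sim <- gen_prediction_tensor(c("m1", "m2"), genes, tt, n_algorithms = 12,
                                 sensitivity = 0.9, fpr = 0.05, seed = s)
    got <- consensus_targets(sim)$per_mirna
    truth <- attr(sim, "true_targets")
    mean(unlist(Map(function(g, t) t %in% g, got[names(truth)], truth)))
  }, numeric(1))
  expect_gte(mean(recalls), 0.95)
})

test_that("survival cohort output is valid and hits the censoring rate", {
  tr <- survival_truth(paste0("g", 1:5), paste0("g", 6:10), beta_rs = 0.7,
                       censor_rate = 0.3)
  coh <- gen_survival_cohort(600, 20, tr, genes = paste0("g", 1:20), seed = 11)
  expect_true(all(coh$survival$time > 0))
  expect_true(all(coh$survival$event %in% c(0, 1)))
  expect_lt(abs(mean(coh$survival$event == 0) - 0.3), 0.08)
  # RS truth matches the signature formula applied to the planted lists
  sig <- signature_from_lists(tr$planted_cpos, tr$planted_cneg)
  rs <- compute_risk_scores(coh$expr, sig)
  expect_equal(unname(coh$true_rs), rs$rs, tolerance = 1e-12)
  expect_error(survival_truth("a", "b", censor_rate = 1.5), "censor_rate")
  expect_error(survival_truth(c("a", "b"), c("b", "c")), "disjoint")
})

test_that("null survival cohort yields hazard ratio near 1", {
  tr <- survival_truth(paste0("g", 1:5), paste0("g", 6:10), beta_rs = 0)
  coh <- gen_survival_cohort(500, 20, tr, genes = paste0("g", 1:20), seed = 13)
  sig <- signature_from_lists(tr$planted_cpos, tr$planted_cneg)
  sc <- bin_risk_levels(compute_risk_scores(coh$expr, sig), 4)
  fit <- survival_association(sc$level, coh$survival)
  expect_true(fit$ci_low <= 1 && 1 <= fit$ci_high)
})

test_that("planted survival signal is recovered within 25% of the oracle fit", {
  tr <- survival_truth(paste0("g", 1:10), paste0("g", 11:20), beta_rs = 0.7,
                       censor_rate = 0.3)
  coh <- gen_survival_cohort(1000, 40, tr, genes = paste0("g", 1:40), seed = 11)
  oracle <- univariate_cox(unname(coh$true_rs), coh$survival)
  sig <- signature_from_lists(tr$planted_cpos, tr$planted_cneg)
  rs <- compute_risk_scores(coh$expr, sig)
  fit <- univariate_cox(rs$rs, coh$survival)
  expect_lt(abs(fit$coefficient - oracle$coefficient),
            0.25 * abs(oracle$coefficient))
})
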