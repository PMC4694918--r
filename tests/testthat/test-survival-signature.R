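test_that("single-covariate Cox matches the brute-force Breslow oracle", {
  # binary covariates are interleaved with the death order: a covariate that
  # perfectly separates early from late deaths has a monotone partial
  # likelihood with no finite maximizer
  toys <- list(
    list(time = 1:8, event = rep(1, 8), x = c(0, 1, 0, 1, 0, 1, 1, 0)),
    list(time = c(2, 2, 3, 5, 6, 7, 9), event = c(1, 1, 0, 1, 1, 0, 1),
         x = c(0.2, -1, 0.5, 2, -0.3, 1, 0.1)),
    list(time = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5), event = rep(1, 10),
         x = c(5, 2, 1, 6, 2, 4, 3, 5, 4, 1)),
    list(time = c(4, 1, 6, 3, 8, 2, 9, 5), event = c(1, 0, 1, 1, 0, 1, 1, 1),
         x = c(-2, 1, 0, 3, -1, 2, 0.5, -0.5)))
  for (toy in toys) {
    fit <- univariate_cox(toy$x, toy_surv(toy$time, toy$event))
    oracle <- breslow_fit_oracle(toy$time, toy$event, toy$x)
    expect_lt(abs(fit$coefficient - oracle), 1e-4)
    expect_equal(fit$hazard_ratio, exp(fit$coefficient))
    expect_true(fit$ci_low <= fit$hazard_ratio &&
                  fit$hazard_ratio <= fit$ci_high)
  }
})

test_that("Cox coefficient is antisymmetric in the covariate sign", {
  x <- c(0, 1, 0, 1, 0, 1, 1, 0)
  surv <- toy_surv(1:8)
  expect_equal(univariate_cox(x, surv)$coefficient,
               -univariate_cox(-x, surv)$coefficient, tolerance = 1e-9)
})

test_that("Cox fit rejects degenerate inputs", {
  expect_error(univariate_cox(rep(1, 5), toy_surv(1:5)), "constant")
  expect_error(univariate_cox(1:5, toy_surv(1:5, event = 0)), "events")
  expect_error(univariate_cox(1:3, toy_surv(c(-1, 1, 2))), "positive")
})

test_that("signature construction splits significant genes by sign", {
  fits <- data.frame(gene = c("A", "B", "C"),
                     coefficient = c(0.2, -0.3, 0.5),
                     p_value = c(0.01, 0.04, 0.2), stringsAsFactors = FALSE)
  sig <- build_signature(fits, alpha = 0.05)
  expect_identical(sig$c_plus, "A")
  expect_identical(sig$c_minus, "B")
  empty <- build_signature(fits, alpha = 0)
  expect_length(empty$c_plus, 0)
  expect_length(empty$c_minus, 0)
  zero <- rbind(fits, data.frame(gene = "Z", coefficient = 0, p_value = 0.001))
  expect_warning(sigz <- build_signature(zero), "undefined sign")
  expect_false("Z" %in% c(sigz$c_plus, sigz$c_minus))
})

test_that("risk score is the difference of group medians", {
  vals <- matrix(c(2, 4, 6, 1, 3), 5, 1,
                 dimnames = list(c("p1", "p2", "p3", "n1", "n2"), "s1"))
  sig <- signature_from_lists(c("p1", "p2", "p3"), c("n1", "n2"))
  rs <- compute_risk_scores(expr_matrix(vals), sig)
  expect_equal(rs$u, 4); expect_equal(rs$d, 2); expect_equal(rs$rs, 2)
  expect_equal(rs$rs, rs$u - rs$d)
  # all genes at a common value -> RS 0
  flat <- expr_matrix(matrix(7, 5, 2, dimnames = list(rownames(vals),
                                                      c("s1", "s2"))))
  expect_equal(compute_risk_scores(flat, sig)$rs, c(0, 0))
})

test_that("risk score is translation equivariant and order invariant", {
  set.seed(19)
  for (rep in 1:10) {
    genes <- sprintf("g%02d", 1:12)
    v <- matrix(rnorm(12 * 6), 12, 6,
                dimnames = list(genes, sprintf("s%d", 1:6)))
    sig <- signature_from_lists(genes[1:5], genes[6:12])
    rs0 <- compute_risk_scores(expr_matrix(v, log2 = TRUE), sig)
    cshift <- runif(1, -3, 3)
    v2 <- v; v2[genes[1:5], 2] <- v2[genes[1:5], 2] + cshift
    rs2 <- compute_risk_scores(expr_matrix(v2, log2 = TRUE), sig)
    expect_equal(rs2$rs[2], rs0$rs[2] + cshift, tolerance = 1e-12)
    expect_equal(rs2$rs[-2], rs0$rs[-2], tolerance = 1e-12)
    # shuffling gene order inside each group changes nothing
    shuf <- signature_from_lists(sample(genes[1:5]), sample(genes[6:12]))
    expect_equal(compute_risk_scores(expr_matrix(v, log2 = TRUE), shuf)$rs,
                 rs0$rs, tolerance = 1e-12)
  }
})

test_that("missing signature genes are dropped; empty groups handled", {
  v <- matrix(rnorm(8), 4, 2,
              dimnames = list(c("a", "b", "c", "d"), c("s1", "s2")))
  ex <- expr_matrix(v, log2 = TRUE)
  sig <- signature_from_lists(c("a", "zz"), c("c", "d"))
  expect_message(rs <- compute_risk_scores(ex, sig), "dropped")
  expect_equal(rs$u, unname(v["a", ]))
  lone <- signature_from_lists(c("a", "b"), "qq")
  expect_warning(rs2 <- compute_risk_scores(ex, lone), "empty")
  expect_equal(rs2$d, c(0, 0))
  expect_error(compute_risk_scores(ex, signature_from_lists(character(0),
                                                            character(0))),
               "no genes")
})

test_that("equal-width binning covers the range with a right-closed last bin", {
  sc <- data.frame(sample_id = letters[1:4], rs = c(0, 1, 2, 3))
  expect_identical(bin_risk_levels(sc, 4)$level, 1:4)
  set.seed(29)
  for (rep in 1:10) {
    rs <- rnorm(50)
    sc <- data.frame(sample_id = seq_along(rs), rs = rs)
    lev <- bin_risk_levels(sc, 4)$level
    expect_true(all(lev %in% 1:4))
    expect_equal(lev[which.max(rs)], 4L)   # max always lands in the top bin
    expect_equal(lev[which.min(rs)], 1L)
    # affine transforms leave equal-width assignments unchanged
    aff <- data.frame(sample_id = seq_along(rs), rs = 2.5 * rs - 7)
    expect_identical(bin_risk_levels(aff, 4)$level, lev)
    # width boundaries: every bin's scores sit inside [lo + (k-1)w, lo + kw]
    w <- diff(range(rs)) / 4
    for (k in 1:4) {
      in_k <- rs[lev == k]
      expect_true(all(in_k >= min(rs) + (k - 1) * w - 1e-12))
      expect_true(all(in_k <= min(rs) + k * w + 1e-12))
    }
  }
  expect_warning(one <- bin_risk_levels(data.frame(rs = c(1, 1, 1)), 4),
                 "identical")
  expect_true(all(one$level == 1L))
})

test_that("quantile binning balances group sizes", {
  sc <- data.frame(sample_id = 1:100, rs = rnorm(100))
  lev <- bin_risk_levels(sc, 4, method = "quantile")$level
  expect_equal(as.vector(table(lev)), rep(25L, 4))
})

test_that("risk-level association matches the Breslow oracle on a toy", {
  levels <- c(1, 1, 2, 2, 3, 3, 4, 4)
  surv <- toy_surv(c(5, 8, 3, 7, 2, 6, 1, 4))
  fit <- survival_association(levels, surv)
  oracle <- breslow_fit_oracle(surv$time, surv$event, levels)
  expect_lt(abs(fit$coefficient - oracle), 1e-4)
  expect_gt(fit$coefficient, 0)
  cat_fit <- survival_association(levels, surv, categorical = TRUE)
  expect_true(is.finite(cat_fit$coefficient))
  expect_error(survival_association(rep(1, 8), surv), "distinct")
})

test_that("Kaplan-Meier steps follow the product-limit formula", {
  km <- km_curves(rep(1, 3), toy_surv(c(1, 2, 3)))
  expect_equal(km$surv, c(1, 2 / 3, 1 / 3, 0))
  allc <- km_curves(rep(1, 4), toy_surv(c(1, 2, 3, 4), event = 0))
  expect_true(all(allc$surv == 1))
  # with censoring: hand product-limit on times 1+, 2, 3 (censored at 1)
  km2 <- km_curves(rep(1, 3), data.frame(time = c(1, 2, 3), event = c(0, 1, 1)))
  expect_equal(km2$surv[km2$time == 2], 1 / 2)
  expect_equal(km2$surv[km2$time == 3], 0)
  set.seed(37)
  surv <- toy_surv(rexp(30, 0.2), event = rbinom(30, 1, 0.7))
  lev <- sample(1:3, 30, replace = TRUE)
  km3 <- km_curves(lev, surv)
  for (l in unique(lev)) {
    s <- km3$surv[km3$level == l]
    expect_true(all(diff(s) <= 1e-12))       # non-increasing
    expect_equal(km3$surv[km3$level == l][1], 1)  # anchored at S(0) = 1
  }
})

test_that("probeset collapsing takes per-sample medians", {
  v <- matrix(c(1, 3, 5, 2, 4, 6), 3, 2,
              dimnames = list(c("ps1", "ps2", "ps3"), c("s1", "s2")))
  map <- data.frame(probeset = c("ps1", "ps2", "ps3"),
                    gene = c("G", "G", "H"), stringsAsFactors = FALSE)
  coll <- collapse_probesets(expr_matrix(v, log2 = TRUE), map)
  expect_equal(unname(coll$values["G", ]), c(2, 3))
  expect_equal(unname(coll$values["H", ]), c(5, 6))
})
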