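#' Single-covariate Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling) for one
#' continuous covariate and returns the Wald summary: log hazard ratio,
#' standard error, hazard ratio with 95% confidence interval, and p-value.
#'
#' @param x numeric covariate, one value per sample; must be finite and
#'   non-constant.
#' @param survival data.frame with columns `time` (> 0) and `event`
#'   (0 = censored, 1 = death), rows aligned with `x`.
#' @return A `cox_fit` one-row data.frame: `coefficient`, `se`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p_value`, `n`, `n_events`.
#' @examples
#' surv <- data.frame(time = 1:8, event = 1)
#' univariate_cox(c(0, 0, 0, 0, 1, 1, 1, 1), surv)
#' @export
univariate_cox <- function(x, survival) {
  check_survival_table(survival)
  if (length(x) != nrow(survival)) {
    stop_invalid("covariate and survival table lengths differ")
  }
  if (any(!is.finite(x))) stop_invalid("covariate must be finite")
  if (sum(survival$event) < 2) stop_invalid("need at least 2 events")
  if (sd(x) == 0) stop_invalid("degenerate covariate: constant across samples")
  fit <- survival::coxph(survival::Surv(survival$time, survival$event) ~ x,
                         ties = "breslow")
  s <- summary(fit)
  coef <- unname(s$coefficients[1, "coef"])
  se <- unname(s$coefficients[1, "se(coef)"])
  structure(data.frame(
    coefficient = coef, se = se, hazard_ratio = exp(coef),
    ci_low = exp(coef - 1.96 * se), ci_high = exp(coef + 1.96 * se),
    p_value = unname(s$coefficients[1, "Pr(>|z|)"]),
    n = nrow(survival), n_events = sum(survival$event)),
    class = c("cox_fit", "data.frame"))
}

check_survival_table <- function(survival) {
  stopifnot(is.data.frame(survival))
  if (!all(c("time", "event") %in% names(survival))) {
    stop_invalid("survival table needs time and event columns")
  }
  if (any(!is.finite(survival$time)) || any(survival$time <= 0)) {
    stop_invalid("survival times must be positive and finite")
  }
  if (!all(survival$event %in% c(0, 1))) {
    stop_invalid("event must be 0 (censored) or 1 (death)")
  }
  invisible(survival)
}

#' Univariate Cox screen over genes
#'
#' Fits [univariate_cox()] for each gene of an expression matrix against a
#' common survival table.
#'
#' @param expr an [expr_matrix] (typically log-scale cohort expression).
#' @param survival data.frame with `sample_id`, `time`, `event`; matched to
#'   the matrix columns by `sample_id`.
#' @param genes optional subset of genes to screen (default: all rows).
#' @return data.frame with one row per screened gene: `gene` plus the
#'   `cox_fit` columns. Genes absent from the matrix or constant are skipped
#'   with a warning.
#' @export
cox_screen <- function(expr, survival, genes = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  check_survival_table(survival)
  if (!"sample_id" %in% names(survival)) {
    stop_invalid("survival table needs a sample_id column")
  }
  if (!setequal(survival$sample_id, colnames(expr$values))) {
    stop_invalid("survival table samples must match the expression columns")
  }
  survival <- survival[match(colnames(expr$values), survival$sample_id), ]
  if (is.null(genes)) genes <- rownames(expr$values)
  missing <- setdiff(genes, rownames(expr$values))
  if (length(missing)) {
    warning(sprintf("%d gene(s) absent from the expression matrix were skipped",
                    length(missing)), call. = FALSE)
    genes <- setdiff(genes, missing)
  }
  keep <- genes[apply(expr$values[genes, , drop = FALSE], 1, sd) > 0]
  if (length(keep) < length(genes)) {
    warning(sprintf("%d constant gene(s) skipped", length(genes) - length(keep)),
            call. = FALSE)
  }
  rows <- lapply(keep, function(g) {
    fit <- univariate_cox(expr$values[g, ], survival)
    cbind(data.frame(gene = g, stringsAsFactors = FALSE), fit)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a C+/C- survival signature from per-gene Cox fits
#'
#' Splits survival-associated genes by the sign of their log hazard ratio:
#' genes with `p < alpha` and a positive coefficient form the C+ group
#' (higher expression, higher risk), those with a negative coefficient the
#' C- group.
#'
#' @param gene_fits data.frame with columns `gene`, `coefficient`,
#'   `p_value` (e.g. [cox_screen()] output).
#' @param alpha significance level (default 0.05).
#' @return An `mm_signature`: list with sorted character vectors `c_plus`
#'   and `c_minus`. A gene with `p < alpha` but coefficient exactly 0 has no
#'   defined sign and is dropped with a warning.
#' @export
build_signature <- function(gene_fits, alpha = 0.05) {
  stopifnot(is.data.frame(gene_fits),
            all(c("gene", "coefficient", "p_value") %in% names(gene_fits)))
  check_prob(alpha, "alpha")
  if (anyDuplicated(gene_fits$gene)) stop_invalid("duplicate gene ids in fits")
  sig <- gene_fits$p_value < alpha
  zero <- sig & gene_fits$coefficient == 0
  if (any(zero)) {
    warning(sprintf("%d significant gene(s) with coefficient exactly 0 dropped (undefined sign)",
                    sum(zero)), call. = FALSE)
  }
  structure(list(
    c_plus = sort(gene_fits$gene[sig & gene_fits$coefficient > 0]),
    c_minus = sort(gene_fits$gene[sig & gene_fits$coefficient < 0]),
    alpha = alpha), class = "mm_signature")
}

#' @export
print.mm_signature <- function(x, ...) {
  cat(sprintf("survival signature: %d C+ gene(s), %d C- gene(s) (alpha = %g)\n",
              length(x$c_plus), length(x$c_minus), x$alpha))
  invisible(x)
}

#' Construct a signature from explicit gene lists
#'
#' @param c_plus,c_minus disjoint character vectors of gene ids.
#' @param alpha significance level to record (informational).
#' @return An `mm_signature`.
#' @export
signature_from_lists <- function(c_plus, c_minus, alpha = NA_real_) {
  c_plus <- sort(as.character(c_plus)); c_minus <- sort(as.character(c_minus))
  if (length(intersect(c_plus, c_minus))) {
    stop_invalid("C+ and C- gene lists must be disjoint")
  }
  structure(list(c_plus = c_plus, c_minus = c_minus, alpha = alpha),
            class = "mm_signature")
}

#' Median-difference risk scores
#'
#' The per-sample risk score of the signature: `RS = U - D`, where `U` is
#' the median expression of the C+ genes and `D` the median expression of
#' the C- genes in that sample. Signature genes absent from the matrix are
#' dropped from their group with a logged count (needed when applying a
#' signature across array platforms).
#'
#' @param expr an [expr_matrix]; rows must cover the signature genes
#'   (after dropping missing ones).
#' @param sig an `mm_signature`.
#' @return A `risk_scores` data.frame: `sample_id`, `u`, `d`, `rs`.
#' @examples
#' m <- matrix(c(2, 4, 6, 1, 3), 5, 1,
#'             dimnames = list(c("a", "b", "c", "d", "e"), "s1"))
#' sig <- signature_from_lists(c("a", "b", "c"), c("d", "e"))
#' compute_risk_scores(expr_matrix(m), sig)  # RS = 4 - 2 = 2
#' @export
compute_risk_scores <- function(expr, sig) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(sig, "mm_signature"))
  if (!length(sig$c_plus) && !length(sig$c_minus)) {
    stop_invalid("signature has no genes in either group")
  }
  use_plus <- intersect(sig$c_plus, rownames(expr$values))
  use_minus <- intersect(sig$c_minus, rownames(expr$values))
  n_drop <- (length(sig$c_plus) - length(use_plus)) +
    (length(sig$c_minus) - length(use_minus))
  if (n_drop > 0) {
    message(sprintf("compute_risk_scores: %d signature gene(s) absent from the matrix were dropped",
                    n_drop))
  }
  if (!length(use_plus) && !length(use_minus)) {
    stop_invalid("no signature gene present in the expression matrix")
  }
  med <- function(genes) {
    if (!length(genes)) return(rep(0, ncol(expr$values)))
    apply(expr$values[genes, , drop = FALSE], 2, median)
  }
  if (!length(use_plus) || !length(use_minus)) {
    warning("one signature group is empty after matching; its median is taken as 0",
            call. = FALSE)
  }
  u <- med(use_plus); d <- med(use_minus)
  out <- data.frame(sample_id = colnames(expr$values), u = u, d = d,
                    rs = u - d, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("risk_scores", "data.frame")
  out
}

#' Bin risk scores into equally-spaced levels
#'
#' Splits the observed risk-score range `[min RS, max RS]` into `n_levels`
#' equal-width bins; level k covers `[min + (k-1)w, min + kw)` with the last
#' bin closed on the right (`w = range / n_levels`). Equal-width binning
#' describes the score scale, not the group sizes; a quantile mode is
#' offered for sensitivity analysis.
#'
#' @param scores a `risk_scores` data.frame (or any data.frame with `rs`).
#' @param n_levels number of levels (>= 2, default 4).
#' @param method `"width"` (default) or `"quantile"` (equal-count bins).
#' @return `scores` with an integer `level` column in `1..n_levels`. If all
#'   scores are identical a single-level output is returned with a warning.
#' @examples
#' sc <- data.frame(sample_id = letters[1:4], rs = 0:3)
#' bin_risk_levels(sc, 4)$level  # 1 2 3 4
#' @export
bin_risk_levels <- function(scores, n_levels = 4,
                            method = c("width", "quantile")) {
  stopifnot(is.data.frame(scores), "rs" %in% names(scores))
  method <- match.arg(method)
  n_levels <- check_count(n_levels, "n_levels", min = 2L)
  rs <- scores$rs
  if (any(!is.finite(rs))) stop_invalid("risk scores must be finite")
  lo <- min(rs); hi <- max(rs)
  if (lo == hi) {
    warning("all risk scores identical; single-level output", call. = FALSE)
    scores$level <- 1L
    return(scores)
  }
  if (method == "width") {
    w <- (hi - lo) / n_levels
    lev <- pmin(floor((rs - lo) / w) + 1L, n_levels)
  } else {
    br <- quantile(rs, probs = seq(0, 1, length.out = n_levels + 1),
                   names = FALSE, type = 7)
    br <- unique(br)
    lev <- as.integer(cut(rs, breaks = br, include.lowest = TRUE,
                          labels = FALSE))
  }
  scores$level <- as.integer(lev)
  scores
}

#' Survival association of risk levels
#'
#' Cox proportional-hazards fit of survival on the risk level. By default
#' the level enters as a single numeric (ordinal-trend) covariate, so the
#' reported hazard ratio is per one-level increase — matching a single HR
#' per cohort; a categorical mode fits level-versus-reference contrasts.
#'
#' @param levels integer risk level per sample.
#' @param survival data.frame with `time` and `event`, rows aligned with
#'   `levels`.
#' @param categorical fit level as a factor instead (returns the fit of the
#'   highest level versus the lowest as its summary row).
#' @return A `cox_fit` data.frame (see [univariate_cox()]).
#' @export
survival_association <- function(levels, survival, categorical = FALSE) {
  if (length(unique(levels)) < 2) stop_invalid("need >= 2 distinct levels")
  if (!categorical) return(univariate_cox(as.numeric(levels), survival))
  check_survival_table(survival)
  f <- factor(levels)
  fit <- survival::coxph(survival::Surv(survival$time, survival$event) ~ f,
                         ties = "breslow")
  s <- summary(fit)
  i <- nrow(s$coefficients)
  coef <- unname(s$coefficients[i, "coef"])
  se <- unname(s$coefficients[i, "se(coef)"])
  structure(data.frame(
    coefficient = coef, se = se, hazard_ratio = exp(coef),
    ci_low = exp(coef - 1.96 * se), ci_high = exp(coef + 1.96 * se),
    p_value = unname(s$coefficients[i, "Pr(>|z|)"]),
    n = nrow(survival), n_events = sum(survival$event)),
    class = c("cox_fit", "data.frame"))
}

#' Kaplan-Meier curves per risk level
#'
#' Product-limit survival estimate for each risk level:
#' `S(t) = prod_(t_i <= t) (1 - d_i / n_i)`.
#'
#' @param levels integer risk level per sample.
#' @param survival data.frame with `time` and `event`, aligned with
#'   `levels`.
#' @return data.frame of step-function coordinates: `level`, `time`,
#'   `n_risk`, `n_event`, `surv`, including the `time = 0, surv = 1` anchor
#'   for every level.
#' @examples
#' km <- km_curves(rep(1, 3), data.frame(time = 1:3, event = 1))
#' km$surv  # 1, 2/3, 1/3, 0
#' @export
km_curves <- function(levels, survival) {
  check_survival_table(survival)
  if (length(levels) != nrow(survival)) {
    stop_invalid("levels and survival table lengths differ")
  }
  fit <- survival::survfit(
    survival::Surv(survival$time, survival$event) ~ lev,
    data = data.frame(lev = factor(levels), time = survival$time,
                      event = survival$event))
  sm <- summary(fit, censored = TRUE)
  lev_of <- if (is.null(sm$strata)) rep(sort(unique(levels))[1], length(sm$time))
    else as.integer(sub("lev=", "", as.character(sm$strata)))
  out <- data.frame(level = lev_of, time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, surv = sm$surv)
  anchors <- data.frame(level = sort(unique(levels)), time = 0,
                        n_risk = as.vector(table(levels)[as.character(sort(unique(levels)))]),
                        n_event = 0, surv = 1)
  out <- rbind(anchors, out)
  out <- out[order(out$level, out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse probesets to genes by per-sample median
#'
#' When several probesets measure one gene, their per-sample median becomes
#' the gene's expression value.
#'
#' @param expr an [expr_matrix] whose rows are probesets.
#' @param probe_to_gene data.frame with columns `probeset` and `gene`.
#' @return An [expr_matrix] with one row per gene.
#' @export
collapse_probesets <- function(expr, probe_to_gene) {
  stopifnot(inherits(expr, "expr_matrix"), is.data.frame(probe_to_gene),
            all(c("probeset", "gene") %in% names(probe_to_gene)))
  map <- probe_to_gene[probe_to_gene$probeset %in% rownames(expr$values), ]
  if (!nrow(map)) stop_invalid("no probeset in the map matches the matrix")
  genes <- sort(unique(map$gene))
  v <- t(vapply(genes, function(g) {
    ps <- map$probeset[map$gene == g]
    apply(expr$values[ps, , drop = FALSE], 2, median)
  }, numeric(ncol(expr$values))))
  dimnames(v) <- list(genes, colnames(expr$values))
  expr_matrix(v, expr$samples, log2 = expr$log2)
}
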