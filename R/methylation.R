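#' Link CpG probes to nearby transcription start sites
#'
#' A probe is linked to a feature (pre-miRNA or host gene) when it lies
#' within `window` bp of the feature's TSS on the same chromosome, upstream
#' or downstream. The reported distance is signed relative to the feature's
#' strand: negative means upstream of the TSS.
#'
#' @param probes data.frame with columns `probe_id`, `chrom`, `position`
#'   (1-based); an optional `region_class` column is carried through.
#' @param features data.frame with columns `feature_id`, `chrom`, `tss`
#'   (1-based), `strand` (`"+"`/`"-"`).
#' @param window maximum absolute probe-to-TSS distance in bp (> 0);
#'   default 2000 bp, a promoter-scale neighborhood.
#' @return A `ProbeAnnotation` data.frame: `probe_id`, `chrom`, `position`,
#'   `linked_feature`, `tss_distance`, `region_class` — one row per
#'   (probe, feature) link; probes on chromosomes absent from `features` are
#'   skipped with a warning.
#' @examples
#' pr <- data.frame(probe_id = "cg1", chrom = "chr1", position = 1500)
#' ft <- data.frame(feature_id = "mir-a", chrom = "chr1", tss = 1000, strand = "+")
#' annotate_probes_to_features(pr, ft)
#' @export
annotate_probes_to_features <- function(probes, features, window = 2000) {
  stopifnot(is.data.frame(probes), is.data.frame(features))
  need_p <- c("probe_id", "chrom", "position")
  need_f <- c("feature_id", "chrom", "tss", "strand")
  if (!all(need_p %in% names(probes))) {
    stop_invalid("`probes` needs columns %s", paste(need_p, collapse = ", "))
  }
  if (!all(need_f %in% names(features))) {
    stop_invalid("`features` needs columns %s", paste(need_f, collapse = ", "))
  }
  if (!is.numeric(window) || window <= 0) stop_invalid("`window` must be > 0")
  if (any(probes$position <= 0) || any(features$tss <= 0)) {
    stop_invalid("coordinates are 1-based and must be positive")
  }
  unknown <- !(probes$chrom %in% unique(features$chrom))
  if (any(unknown)) {
    warning(sprintf("%d probe(s) on chromosomes absent from the feature table were skipped",
                    sum(unknown)), call. = FALSE)
    probes <- probes[!unknown, , drop = FALSE]
  }
  empty <- data.frame(probe_id = character(0), chrom = character(0),
                      position = integer(0), linked_feature = character(0),
                      tss_distance = integer(0), region_class = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(probes) || !nrow(features)) return(empty)

  pg <- GenomicRanges::GRanges(probes$chrom,
                               IRanges::IRanges(probes$position, width = 1))
  fg <- GenomicRanges::GRanges(features$chrom,
                               IRanges::IRanges(pmax(features$tss - window, 1),
                                                features$tss + window))
  hits <- GenomicRanges::findOverlaps(pg, fg)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) return(empty)
  raw_dist <- probes$position[qi] - features$tss[si]
  keep <- abs(raw_dist) <= window  # guard the clamp at chromosome start
  qi <- qi[keep]; si <- si[keep]; raw_dist <- raw_dist[keep]
  signed <- ifelse(features$strand[si] == "-", -raw_dist, raw_dist)
  out <- data.frame(
    probe_id = probes$probe_id[qi], chrom = probes$chrom[qi],
    position = probes$position[qi], linked_feature = features$feature_id[si],
    tss_distance = as.integer(signed),
    region_class = if ("region_class" %in% names(probes))
      probes$region_class[qi] else NA_character_,
    stringsAsFactors = FALSE)
  out <- out[order(out$linked_feature, out$position, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-group location test
#'
#' The study's two generic group comparisons: classic (pooled-variance)
#' Student's t-test, optionally Welch, or the two-sided Mann-Whitney U
#' (Wilcoxon rank-sum) test. Degenerate inputs are resolved before testing:
#' when both groups have zero variance, p is 1 if the means agree and 0
#' (flagged) if they differ.
#'
#' @param values_a,values_b numeric vectors (group A is reported first;
#'   `delta = mean(values_a) - mean(values_b)`). Student's t needs at least
#'   two values per group.
#' @param method `"student_t"` or `"mann_whitney_u"`.
#' @param welch use the Welch (unequal-variance) t statistic instead of the
#'   pooled one.
#' @return One-row data.frame: `mean_a`, `mean_b`, `delta`, `statistic`,
#'   `p_value`, `test_name`, `degenerate`.
#' @examples
#' group_test(c(0.1, 0.2, 0.15), c(0.8, 0.9, 0.85))
#' group_test(1:3, 4:6, method = "mann_whitney_u")
#' @export
group_test <- function(values_a, values_b,
                       method = c("student_t", "mann_whitney_u"),
                       welch = FALSE) {
  method <- match.arg(method)
  if (any(!is.finite(values_a)) || any(!is.finite(values_b))) {
    stop_invalid("group values must be finite")
  }
  min_n <- if (method == "student_t") 2L else 1L
  if (length(values_a) < min_n || length(values_b) < min_n) {
    stop_invalid("each group needs at least %d value(s) for %s", min_n, method)
  }
  ma <- mean(values_a); mb <- mean(values_b)
  test_name <- if (method == "student_t") {
    if (welch) "welch_t" else "student_t"
  } else "mann_whitney_u"
  res <- function(stat, p, degenerate = FALSE) {
    data.frame(mean_a = ma, mean_b = mb, delta = ma - mb, statistic = stat,
               p_value = p, test_name = test_name, degenerate = degenerate,
               stringsAsFactors = FALSE)
  }
  if (method == "student_t") {
    if (sd(values_a) == 0 && sd(values_b) == 0) {
      if (ma == mb) return(res(0, 1)) else return(res(Inf * sign(ma - mb), 0, TRUE))
    }
    tt <- t.test(values_a, values_b, var.equal = !welch)
    res(unname(tt$statistic), tt$p.value)
  } else {
    if (all(values_a %in% values_b) && all(values_b %in% values_a) &&
        length(unique(c(values_a, values_b))) == 1L) {
      return(res(length(values_a) * length(values_b) / 2, 1))
    }
    wt <- suppressWarnings(wilcox.test(values_a, values_b,
                                       alternative = "two.sided"))
    res(unname(wt$statistic), wt$p.value)
  }
}

#' Tumor-versus-normal methylation comparison
#'
#' Tests each TSS-linked CpG probe (or each feature, after averaging its
#' linked probes per sample) for a beta-value difference between tumor and
#' normal samples, the analysis behind per-miRNA methylation panels.
#'
#' @param betas a [beta_matrix].
#' @param annotation a probe annotation from [annotate_probes_to_features()]
#'   (or the synthetic generator); only annotated probes present in `betas`
#'   are tested.
#' @param level `"probe"` (one test per (probe, feature) link) or `"region"`
#'   (per feature, on per-sample means of its linked probes).
#' @param method,welch passed to [group_test()].
#' @param adjust `"none"` (default; the study reports raw p-values) or
#'   `"BH"` for Benjamini-Hochberg adjusted p-values in an extra column.
#' @return data.frame sorted by feature then position with columns `feature`,
#'   `probe_id` (NA at region level), `position`, `n_probes`,
#'   `mean_beta_tumor`, `mean_beta_normal`, `delta`, `statistic`, `p_value`,
#'   `test_name` (+ `adj_p_value` when `adjust = "BH"`). Features with no
#'   linked probe in the matrix are omitted with a warning.
#' @examples
#' sim <- gen_methylation_cohort(30, 9, seed = 4)
#' head(compare_methylation(sim$betas, sim$annotation))
#' @export
compare_methylation <- function(betas, annotation, level = c("probe", "region"),
                                method = "student_t", welch = FALSE,
                                adjust = c("none", "BH")) {
  stopifnot(inherits(betas, "beta_matrix"))
  level <- match.arg(level); adjust <- match.arg(adjust)
  tumor <- betas$samples$sample_id[betas$samples$group == "tumor"]
  normal <- betas$samples$sample_id[betas$samples$group == "normal"]
  if (method == "student_t" && (length(tumor) < 2 || length(normal) < 2)) {
    stop_invalid("t-testing needs >= 2 samples per group")
  }
  ann <- annotation[annotation$probe_id %in% rownames(betas$values), , drop = FALSE]
  missing_feat <- setdiff(annotation$linked_feature, ann$linked_feature)
  if (length(missing_feat)) {
    warning(sprintf("%d feature(s) have no linked probe in the matrix and were omitted",
                    length(missing_feat)), call. = FALSE)
  }
  if (!nrow(ann)) {
    return(data.frame(feature = character(0), probe_id = character(0),
                      position = integer(0), n_probes = integer(0),
                      mean_beta_tumor = numeric(0), mean_beta_normal = numeric(0),
                      delta = numeric(0), statistic = numeric(0),
                      p_value = numeric(0), test_name = character(0),
                      stringsAsFactors = FALSE))
  }

  one_test <- function(vals, feature, probe_id, position, n_probes) {
    gt <- group_test(vals[tumor], vals[normal], method = method, welch = welch)
    data.frame(feature = feature, probe_id = probe_id, position = position,
               n_probes = n_probes, mean_beta_tumor = gt$mean_a,
               mean_beta_normal = gt$mean_b, delta = gt$delta,
               statistic = gt$statistic, p_value = gt$p_value,
               test_name = gt$test_name, stringsAsFactors = FALSE)
  }

  if (level == "probe") {
    rows <- lapply(seq_len(nrow(ann)), function(i) {
      one_test(betas$values[ann$probe_id[i], ], ann$linked_feature[i],
               ann$probe_id[i], ann$position[i], 1L)
    })
  } else {
    feats <- unique(ann$linked_feature)
    rows <- lapply(feats, function(f) {
      pids <- unique(ann$probe_id[ann$linked_feature == f])
      vals <- colMeans(betas$values[pids, , drop = FALSE])
      one_test(vals, f, NA_character_,
               min(ann$position[ann$linked_feature == f]), length(pids))
    })
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$feature, out$position), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust == "BH") out$adj_p_value <- p.adjust(out$p_value, "BH")
  out
}

#' Five-number summary with min/max whiskers
#'
#' Box-plot coordinates in the convention where whiskers mark the data
#' minimum and maximum (not 1.5 IQR fences). Quartiles use linear
#' interpolation between order statistics (type 7).
#'
#' @param values non-empty finite numeric vector.
#' @return Named numeric: `min`, `q1`, `median`, `q3`, `max`.
#' @examples
#' summarize_beta_distribution(c(0.1, 0.2, 0.3, 0.4, 0.5))
#' @export
summarize_beta_distribution <- function(values) {
  if (!length(values) || any(!is.finite(values))) {
    stop_invalid("`values` must be a non-empty finite vector")
  }
  q <- quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                type = 7)
  setNames(q, c("min", "q1", "median", "q3", "max"))
}
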