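#' Per-cell-line fold changes from treated/control expression
#'
#' Computes, for every (miRNA, cell line) pair, the linear fold change of
#' treated over control intensity. A side whose intensity falls below
#' `detection_floor` is called not detected; when either arm is undetected
#' the pair is reported as `n.d.` with no numeric fold change, mirroring how
#' array screens report absent calls. Replicate samples within a cell line
#' and arm are averaged on the linear scale first.
#'
#' @param treated,control [expr_matrix] objects sharing the same feature set,
#'   with a `cell_line` column in their sample sheets; every cell line must
#'   appear in both arms.
#' @param detection_floor linear intensity below which a feature is not
#'   detected; the default 0 marks everything detected.
#' @return A `fold_change_table`: data.frame with columns `mirna`,
#'   `cell_line`, `fold_change` (NA for n.d.), `regulation`
#'   (`"up"`/`"down"`/`"n.d."`), `detected_treated`, `detected_control`.
#'   `regulation` is `"up"` exactly when both arms are detected and the fold
#'   change exceeds 1.
#' @examples
#' sim <- gen_unmasking_experiment(20, 3, noise_sd = 0, effect_range = c(4, 4))
#' fc <- compute_fold_changes(sim$treated, sim$control)
#' head(fc)
#' @export
compute_fold_changes <- function(treated, control, detection_floor = 0) {
  stopifnot(inherits(treated, "expr_matrix"), inherits(control, "expr_matrix"))
  if (treated$log2 || control$log2) {
    stop_invalid("fold changes are taken on linear intensities; supply linear matrices")
  }
  if (!setequal(rownames(treated$values), rownames(control$values))) {
    stop_invalid("treated and control must share the same feature set")
  }
  if (!"cell_line" %in% names(treated$samples) ||
      !"cell_line" %in% names(control$samples)) {
    stop_invalid("sample sheets must carry a cell_line column")
  }
  lines <- unique(treated$samples$cell_line)
  if (!setequal(lines, unique(control$samples$cell_line))) {
    stop_invalid("every cell line must be present in both arms")
  }
  mirnas <- rownames(treated$values)
  ctrl <- control$values[mirnas, , drop = FALSE]

  arm_mean <- function(em, values, line) {
    cols <- em$samples$sample_id[em$samples$cell_line == line]
    rowMeans(values[, cols, drop = FALSE])
  }

  rows <- lapply(lines, function(line) {
    ti <- arm_mean(treated, treated$values, line)
    ci <- arm_mean(control, ctrl, line)
    det_t <- ti >= detection_floor
    det_c <- ci >= detection_floor
    fold <- rep(NA_real_, length(mirnas))
    ok <- det_t & det_c
    zero_ctrl <- ok & ci == 0
    if (any(zero_ctrl)) {
      warning(sprintf("%d feature(s) in line %s have detected control intensity 0; reported as n.d.",
                      sum(zero_ctrl), line), call. = FALSE)
      ok <- ok & !zero_ctrl
    }
    fold[ok] <- ti[ok] / ci[ok]
    reg <- ifelse(!ok, "n.d.", ifelse(fold > 1, "up", "down"))
    data.frame(mirna = mirnas, cell_line = line, fold_change = fold,
               regulation = reg, detected_treated = det_t,
               detected_control = det_c, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna, out$cell_line), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fold_change_table", "data.frame")
  out
}

#' Select miRNAs unmasked by demethylating treatment
#'
#' Applies the screen's headline selection rule: a miRNA is a candidate when
#' it is upregulated by at least `fold_threshold` (inclusive) in at least
#' `min_lines` cell lines. `n.d.` entries are neutral — they never count
#' toward (or against) the line tally, since an absent call carries no fold
#' change.
#'
#' @param fc a `fold_change_table` from [compute_fold_changes()] (or any
#'   data.frame with `mirna`, `cell_line`, `fold_change`, `regulation`).
#' @param fold_threshold minimum linear fold change, > 1; the comparison is
#'   inclusive (`>=`).
#' @param min_lines minimum number of qualifying cell lines.
#' @return A `candidate_set`: list with `selected` (character vector, sorted)
#'   and `evidence` (per selected miRNA, a data.frame of its qualifying
#'   (cell_line, fold_change) rows), plus the thresholds applied.
#' @examples
#' tab <- candidate_mirna_folds()
#' select_unmasked(tab, fold_threshold = 1.5, min_lines = 2)$selected
#' @export
select_unmasked <- function(fc, fold_threshold = 1.5, min_lines = 2) {
  stopifnot(is.data.frame(fc))
  if (!is.numeric(fold_threshold) || fold_threshold <= 1) {
    stop_invalid("`fold_threshold` must be > 1")
  }
  min_lines <- check_count(min_lines, "min_lines")
  if (nrow(fc) == 0) {
    return(structure(list(selected = character(0), evidence = list(),
                          fold_threshold = fold_threshold,
                          min_lines = min_lines),
                     class = "candidate_set"))
  }
  qual <- fc$regulation == "up" & !is.na(fc$fold_change) &
    fc$fold_change >= fold_threshold
  counts <- tapply(qual, fc$mirna, sum)
  selected <- sort(names(counts)[counts >= min_lines])
  evidence <- lapply(setNames(selected, selected), function(m) {
    rows <- fc[qual & fc$mirna == m, c("cell_line", "fold_change")]
    rownames(rows) <- NULL
    rows
  })
  structure(list(selected = selected, evidence = evidence,
                 fold_threshold = fold_threshold, min_lines = min_lines),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d miRNA(s) upregulated >= %.3g-fold in >= %d line(s)\n",
              length(x$selected), x$fold_threshold, x$min_lines))
  if (length(x$selected)) cat(paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Comparative-Ct relative quantification
#'
#' The comparative Ct (delta-delta Ct) method for qPCR: the relative quantity
#' of the target in a sample against a calibrator, both normalized to a
#' reference gene, is 2^-ddCt with
#' ddCt = (Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,calibrator - Ct_ref,calibrator). Vectorized over its
#' arguments.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_calibrator,ct_ref_calibrator
#'   finite Ct values (threshold cycles).
#' @return Relative quantity (linear scale); 1 means no change against the
#'   calibrator.
#' @examples
#' ddct_relative_quantity(20, 18, 24, 19)  # 2^-(2 - 5) = 8
#' @export
ddct_relative_quantity <- function(ct_target_sample, ct_ref_sample,
                                   ct_target_calibrator, ct_ref_calibrator) {
  cts <- cbind(ct_target_sample, ct_ref_sample,
               ct_target_calibrator, ct_ref_calibrator)
  if (any(!is.finite(cts))) stop_invalid("all Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Upper-quartile normalization of a linear expression matrix
#'
#' Optional per-sample scaling used in place of upstream array
#' normalization: each sample is scaled so its 75th percentile equals the
#' geometric mean of all samples' 75th percentiles. The screen only consumes
#' treated/control ratios, so this simply removes per-sample intensity
#' offsets.
#'
#' @param expr a linear-scale [expr_matrix].
#' @return An [expr_matrix] with scaled values.
#' @export
normalize_upper_quartile <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$log2) stop_invalid("upper-quartile scaling applies to linear intensities")
  q75 <- apply(expr$values, 2, quantile, probs = 0.75, names = FALSE)
  if (any(q75 <= 0)) stop_invalid("each sample needs a positive 75th percentile")
  target <- exp(mean(log(q75)))
  expr_matrix(sweep(expr$values, 2, q75 / target, "/"), expr$samples)
}

#' Fold changes of the nine leading candidate miRNAs
#'
#' The published fold-change table for the nine leading tumor-suppressive
#' miRNA candidates after 5'azacytidine treatment of four human myeloma cell
#' lines (H929, MM1S, OPM2, 8226), in long format. `n.d.` cells (miRNA not
#' detected in at least one arm of the comparison) carry `NA` fold change.
#'
#' @return A `fold_change_table` data.frame with columns `mirna`,
#'   `cell_line`, `fold_change`, `regulation`.
#' @examples
#' tab <- candidate_mirna_folds()
#' subset(tab, mirna == "hsa-miR-155")
#' @export
candidate_mirna_folds <- function() {
  path <- system.file("extdata", "aza_candidate_fold_changes.tsv",
                      package = "mirunmask", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "character"))
  class(tab) <- c("fold_change_table", "data.frame")
  tab
}
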