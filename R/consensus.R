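#' Consensus miRNA targets by algorithm voting
#'
#' A gene is accepted as a target of a miRNA when it is called by at least
#' `rule_fraction` of the prediction algorithms available for that miRNA
#' (default: at least half). The comparison is `>=` on the exact rational
#' threshold, so with 7 available algorithms the bar is 3.5 — i.e. 4 calls.
#' Unavailable algorithms are masked out of both numerator and denominator.
#'
#' @param tensor a [prediction_tensor].
#' @param rule_fraction fraction of available algorithms required, in
#'   (0, 1\].
#' @param denominator `"per_mirna"` (default; the algorithms available for
#'   that miRNA) or `"global"` (every algorithm in the tensor, for
#'   sensitivity analysis).
#' @return A `target_set`: list with `per_mirna` (named list of sorted gene
#'   vectors), `union` (sorted deduplicated pooled gene list) and the rule
#'   parameters. miRNAs with zero available algorithms are excluded with a
#'   warning.
#' @examples
#' sim <- gen_prediction_tensor(c("m1", "m2"), paste0("g", 1:6),
#'   list(m1 = c("g1", "g2"), m2 = "g3"),
#'   sensitivity = 1, fpr = 0, availability = 1, seed = 5)
#' consensus_targets(sim)$per_mirna
#' @export
consensus_targets <- function(tensor, rule_fraction = 0.5,
                              denominator = c("per_mirna", "global")) {
  stopifnot(inherits(tensor, "prediction_tensor"))
  denominator <- match.arg(denominator)
  if (!is.numeric(rule_fraction) || length(rule_fraction) != 1L ||
      rule_fraction <= 0 || rule_fraction > 1) {
    stop_invalid("`rule_fraction` must lie in (0, 1]")
  }
  n_avail <- colSums(tensor$available)
  dead <- names(n_avail)[n_avail == 0]
  if (length(dead)) {
    warning(sprintf("miRNA(s) with no available algorithm excluded: %s",
                    paste(dead, collapse = ", ")), call. = FALSE)
  }
  keep <- setdiff(tensor$mirnas, dead)
  per_mirna <- lapply(setNames(keep, keep), function(m) {
    denom <- if (denominator == "per_mirna") n_avail[[m]] else
      length(tensor$algorithms)
    votes <- apply(tensor$calls[, m, , drop = FALSE], 3, sum, na.rm = TRUE)
    sort(names(votes)[votes >= rule_fraction * denom])
  })
  structure(list(per_mirna = per_mirna,
                 union = sort(unique(unlist(per_mirna, use.names = FALSE))),
                 rule_fraction = rule_fraction, denominator = denominator),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("target_set: %d miRNA(s), %d unique pooled target gene(s) (rule >= %.3g of %s algorithms)\n",
              length(x$per_mirna), length(x$union), x$rule_fraction,
              if (x$denominator == "per_mirna") "available" else "all"))
  invisible(x)
}

#' Pooled target gene list
#'
#' Sorted, deduplicated union of the per-miRNA consensus target sets.
#'
#' @param targets a `target_set` from [consensus_targets()], or a named list
#'   of per-miRNA gene vectors.
#' @return character vector of unique gene ids, sorted.
#' @export
union_target_genes <- function(targets) {
  per <- if (inherits(targets, "target_set")) targets$per_mirna else targets
  sort(unique(unlist(per, use.names = FALSE)))
}

#' Genes upregulated in tumor versus normal samples
#'
#' Per-gene differential upregulation in the convention of large myeloma
#' expression-profile cohorts: linear fold change of group means, two-sample
#' t-test on log2 values, Benjamini-Hochberg correction, and a flag for
#' genes passing both the fold gate (inclusive, `>=`) and the adjusted-p
#' gate (strict, `<`).
#'
#' @param expr an [expr_matrix] whose sample sheet carries a `group` column
#'   with values `"tumor"`/`"normal"`; linear intensities must be positive
#'   (log2 matrices are used as-is for testing, with fold = 2^(mean
#'   difference)).
#' @param fold_cutoff minimum linear fold change (default 1.5).
#' @param adj_p_cutoff adjusted-p threshold (default 0.005).
#' @param adjust_method a [stats::p.adjust] method, default `"BH"`.
#' @param welch use the Welch t statistic.
#' @return A `DEResult` data.frame: `gene`, `fold_change` (linear,
#'   tumor/normal), `direction`, `p_value`, `adj_p_value`, `upregulated`.
#' @examples
#' ex <- gen_tumor_normal_expr(paste0("g", 1:20), paste0("g", 1:4), seed = 6)
#' head(differential_upregulation(ex))
#' @export
differential_upregulation <- function(expr, fold_cutoff = 1.5,
                                      adj_p_cutoff = 0.005,
                                      adjust_method = "BH", welch = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!"group" %in% names(expr$samples) ||
      !all(expr$samples$group %in% c("tumor", "normal"))) {
    stop_invalid("sample sheet needs a group column with tumor/normal labels")
  }
  tumor <- expr$samples$sample_id[expr$samples$group == "tumor"]
  normal <- expr$samples$sample_id[expr$samples$group == "normal"]
  if (length(tumor) < 2 || length(normal) < 2) {
    stop_invalid("need >= 2 samples per group")
  }
  if (fold_cutoff <= 0) stop_invalid("`fold_cutoff` must be > 0")
  check_prob(adj_p_cutoff, "adj_p_cutoff")

  if (expr$log2) {
    logv <- expr$values
  } else {
    if (any(expr$values <= 0)) {
      stop_invalid("linear intensities must be > 0 to take logs; offset upstream")
    }
    logv <- log2(expr$values)
  }
  genes <- rownames(logv)
  rows <- lapply(genes, function(g) {
    gt <- group_test(logv[g, tumor], logv[g, normal], method = "student_t",
                     welch = welch)
    fold <- 2^(gt$delta)
    if (!expr$log2) {
      # fold of linear group means (the reported scale); test stays on log2
      fold <- mean(expr$values[g, tumor]) / mean(expr$values[g, normal])
    }
    data.frame(gene = g, fold_change = fold,
               direction = ifelse(fold >= 1, "up", "down"),
               p_value = gt$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p_value <- p.adjust(out$p_value, adjust_method)
  out$upregulated <- out$fold_change >= fold_cutoff &
    out$adj_p_value < adj_p_cutoff
  rownames(out) <- NULL
  out
}

#' Intersect pooled targets with tumor-upregulated genes
#'
#' The in-silico filter joining the two evidence streams: predicted targets
#' of the candidate miRNAs that are also upregulated in tumor samples.
#'
#' @param targets character vector of gene ids (e.g.
#'   [union_target_genes()] output) or a `target_set`.
#' @param de a `DEResult` from [differential_upregulation()].
#' @return Sorted character vector of genes in both lists.
#' @export
intersect_targets_with_upregulated <- function(targets, de) {
  if (inherits(targets, "target_set")) targets <- targets$union
  targets <- as.character(targets)
  stopifnot(is.data.frame(de), all(c("gene", "upregulated") %in% names(de)))
  if (anyDuplicated(de$gene)) {
    stop_invalid("duplicate gene ids in the differential-expression table")
  }
  sort(intersect(targets, de$gene[de$upregulated]))
}
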