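#' Expression matrix with sample metadata
#'
#' Lightweight container for a features-by-samples numeric matrix plus a
#' per-sample metadata table, in the style of microarray expression sets.
#' Values are either nonnegative linear intensities (default) or log2
#' intensities (`log2 = TRUE`, negative values allowed).
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param sample_meta data.frame with one row per sample and a `sample_id`
#'   column; typical extra columns are `cell_line`, `condition`
#'   (`"treated"`/`"control"`/`"none"`) or `group` (`"tumor"`/`"normal"`).
#'   Defaults to a bare sheet holding only the sample ids.
#' @param log2 logical; are values on the log2 scale?
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `samples` and `log2`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("miR-1", "miR-2"), c("s1", "s2", "s3")))
#' expr_matrix(m)
#' @export
expr_matrix <- function(values, sample_meta = NULL, log2 = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_invalid("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_invalid("`values` must carry feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop_invalid("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop_invalid("duplicate sample ids")
  if (any(!is.finite(values))) stop_invalid("expression values must be finite")
  if (!log2 && any(values < 0)) {
    stop_invalid("linear intensities must be >= 0 (use log2 = TRUE for log-scale data)")
  }
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
  }
  if (!is.data.frame(sample_meta) || !"sample_id" %in% names(sample_meta)) {
    stop_invalid("`sample_meta` must be a data.frame with a sample_id column")
  }
  if (!setequal(sample_meta$sample_id, colnames(values)) ||
      nrow(sample_meta) != ncol(values)) {
    stop_invalid("`sample_meta$sample_id` must match the matrix columns exactly")
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, samples = sample_meta, log2 = isTRUE(log2)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), if (x$log2) "log2" else "linear"))
  extra <- setdiff(names(x$samples), "sample_id")
  if (length(extra)) cat("sample metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Methylation beta-value matrix with group labels
#'
#' Container for CpG probe beta values (fraction methylated, in \[0, 1\])
#' across tumor and normal samples.
#'
#' @param values numeric matrix of beta values, probes in rows, samples in
#'   columns, all entries in \[0, 1\].
#' @param sample_meta data.frame with columns `sample_id` and `group`; every
#'   group label must be `"tumor"` or `"normal"`.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_invalid("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_invalid("`values` must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop_invalid("duplicate probe ids")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    stop_invalid("beta values must lie in [0, 1]")
  }
  if (!is.data.frame(sample_meta) ||
      !all(c("sample_id", "group") %in% names(sample_meta))) {
    stop_invalid("`sample_meta` needs sample_id and group columns")
  }
  if (!all(sample_meta$group %in% c("tumor", "normal"))) {
    stop_invalid("group labels must be 'tumor' or 'normal'")
  }
  if (!setequal(sample_meta$sample_id, colnames(values)) ||
      nrow(sample_meta) != ncol(values)) {
    stop_invalid("`sample_meta$sample_id` must match the matrix columns exactly")
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, samples = sample_meta), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$samples$group == "tumor"), sum(x$samples$group == "normal")))
  invisible(x)
}

#' Binary target-prediction tensor with availability mask
#'
#' Holds per-(algorithm, miRNA, gene) binary prediction calls together with a
#' per-(algorithm, miRNA) availability mask. Target-prediction databases
#' expose different algorithm panels for different miRNAs, so an unavailable
#' cell is `NA` (masked), never an implicit zero; masked cells contribute to
#' no consensus denominator.
#'
#' @param calls 3-d 0/1 array `algorithms x mirnas x genes`, with `NA` where
#'   the algorithm is unavailable for the miRNA; dimnames required.
#' @param available 0/1 matrix `algorithms x mirnas`.
#' @return An object of class `prediction_tensor`.
#' @export
prediction_tensor <- function(calls, available) {
  if (!is.array(calls) || length(dim(calls)) != 3L) {
    stop_invalid("`calls` must be a 3-d array (algorithm x mirna x gene)")
  }
  dn <- dimnames(calls)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1)))) {
    stop_invalid("`calls` must have full dimnames")
  }
  if (!is.matrix(available) ||
      !identical(dim(available), dim(calls)[1:2])) {
    stop_invalid("`available` must be an algorithms x mirnas matrix matching `calls`")
  }
  if (!all(available %in% c(0, 1))) stop_invalid("`available` must be 0/1")
  av3 <- array(rep(available, times = dim(calls)[3]), dim = dim(calls))
  if (any(calls[av3 == 1] %in% NA) || !all(calls[av3 == 1] %in% c(0, 1))) {
    stop_invalid("available cells must carry 0/1 calls")
  }
  if (!all(is.na(calls[av3 == 0]))) {
    stop_invalid("unavailable cells must be NA (masked), not 0")
  }
  dimnames(available) <- dn[1:2]
  structure(list(calls = calls, available = available,
                 algorithms = dn[[1]], mirnas = dn[[2]], genes = dn[[3]]),
            class = "prediction_tensor")
}

#' @export
print.prediction_tensor <- function(x, ...) {
  cat(sprintf("prediction_tensor: %d algorithms x %d miRNAs x %d genes (%.0f%% cells available)\n",
              length(x$algorithms), length(x$mirnas), length(x$genes),
              100 * mean(x$available)))
  invisible(x)
}
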