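# Shared TSV/BED readers and writers. Interchange format is tab-separated
# UTF-8 with a header row and '.' decimals; BED probe files are 0-based
# half-open and converted to 1-based positions on read.

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_file <- function(path, required = character(0)) {
  if (!file.exists(path)) stop_invalid("input file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_invalid("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", "))
  }
  df
}

#' Read an expression matrix from TSV
#'
#' Features in rows (first column `feature_id`), samples in columns. An
#' optional sample sheet TSV (`sample_id` plus metadata such as `cell_line`,
#' `condition`, `group`) supplies the sample metadata.
#'
#' @param path expression TSV path.
#' @param samples_path optional sample-sheet TSV path.
#' @param log2 is the matrix on the log2 scale?
#' @return An [expr_matrix].
#' @export
read_expr_tsv <- function(path, samples_path = NULL, log2 = FALSE) {
  df <- read_tsv_file(path, "feature_id")
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- df$feature_id
  meta <- if (!is.null(samples_path)) read_sample_sheet(samples_path) else NULL
  if (!is.null(meta)) meta <- meta[meta$sample_id %in% colnames(v), , drop = FALSE]
  expr_matrix(v, meta, log2 = log2)
}

#' Write an expression matrix (and its sample sheet) to TSV
#'
#' @param expr an [expr_matrix].
#' @param path expression TSV path.
#' @param samples_path optional path for the sample sheet.
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(expr, path, samples_path = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- data.frame(feature_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path)
  if (!is.null(samples_path)) write_tsv_file(expr$samples, samples_path)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' @param path TSV with a `sample_id` column plus arbitrary metadata.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_file(path, "sample_id")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read a methylation beta matrix from TSV
#'
#' @param path TSV with `probe_id` first column and one column per sample.
#' @param samples_path sample sheet with `sample_id` and `group`
#'   (tumor/normal).
#' @return A [beta_matrix].
#' @export
read_beta_tsv <- function(path, samples_path) {
  df <- read_tsv_file(path, "probe_id")
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- df$probe_id
  beta_matrix(v, read_tsv_file(samples_path, c("sample_id", "group")))
}

#' Read CpG probe coordinates from a BED-like file
#'
#' Columns chrom, start, end, probe_id (0-based half-open, BED convention,
#' no header); single-base probes have `end = start + 1`. Positions are
#' converted to 1-based.
#'
#' @param path BED file path.
#' @return data.frame with `probe_id`, `chrom`, `position` (1-based).
#' @export
read_probe_bed <- function(path) {
  if (!file.exists(path)) stop_invalid("input file not found: %s", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop_invalid("%s: BED probe file needs chrom/start/end/probe_id", path)
  names(df)[1:4] <- c("chrom", "start", "end", "probe_id")
  data.frame(probe_id = as.character(df$probe_id), chrom = df$chrom,
             position = as.integer(df$start) + 1L, stringsAsFactors = FALSE)
}

#' Read feature TSS coordinates from TSV
#'
#' @param path TSV with columns `feature_id`, `chrom`, `tss` (1-based),
#'   `strand`.
#' @return data.frame.
#' @export
read_feature_tsv <- function(path) {
  read_tsv_file(path, c("feature_id", "chrom", "tss", "strand"))
}

#' Read a survival table from TSV
#'
#' @param path TSV with columns `sample_id`, `time`, `event`.
#' @return data.frame, validated (positive times, 0/1 events).
#' @export
read_survival_tsv <- function(path) {
  df <- read_tsv_file(path, c("sample_id", "time", "event"))
  df$sample_id <- as.character(df$sample_id)
  check_survival_table(df)
}

#' Assemble a prediction tensor from long-format TSVs
#'
#' @param calls data.frame with columns `algorithm`, `mirna`, `gene`,
#'   `call` (0/1), listing available cells (rows absent from an available
#'   (algorithm, miRNA) block default to call 0).
#' @param availability data.frame with columns `algorithm`, `mirna` listing
#'   available (algorithm, miRNA) pairs.
#' @param genes optional gene universe (default: genes seen in `calls`).
#' @return A [prediction_tensor].
#' @export
predictions_to_tensor <- function(calls, availability, genes = NULL) {
  stopifnot(is.data.frame(calls),
            all(c("algorithm", "mirna", "gene", "call") %in% names(calls)),
            is.data.frame(availability),
            all(c("algorithm", "mirna") %in% names(availability)))
  algs <- sort(unique(c(calls$algorithm, availability$algorithm)))
  mirnas <- sort(unique(c(calls$mirna, availability$mirna)))
  if (is.null(genes)) genes <- sort(unique(calls$gene))
  genes <- as.character(genes)
  av <- matrix(0L, length(algs), length(mirnas), dimnames = list(algs, mirnas))
  av[cbind(match(availability$algorithm, algs),
           match(availability$mirna, mirnas))] <- 1L
  arr <- array(NA_real_, dim = c(length(algs), length(mirnas), length(genes)),
               dimnames = list(algs, mirnas, genes))
  open <- which(av == 1L, arr.ind = TRUE)
  arr[cbind(rep(open[, 1], each = length(genes)),
            rep(open[, 2], each = length(genes)),
            rep(seq_along(genes), times = nrow(open)))] <- 0
  ok <- calls$call == 1
  if (any(ok)) {
    idx <- cbind(match(calls$algorithm[ok], algs),
                 match(calls$mirna[ok], mirnas),
                 match(calls$gene[ok], genes))
    if (any(!complete.cases(idx))) {
      stop_invalid("calls reference genes outside the gene universe")
    }
    if (any(av[idx[, 1:2, drop = FALSE]] == 0)) {
      stop_invalid("calls present for unavailable (algorithm, miRNA) cells")
    }
    arr[idx] <- 1
  }
  prediction_tensor(arr, av)
}

#' Read prediction calls and availability TSVs into a tensor
#'
#' @param calls_path long-format TSV (`algorithm`, `mirna`, `gene`, `call`).
#' @param availability_path TSV (`algorithm`, `mirna`).
#' @param genes optional gene universe.
#' @return A [prediction_tensor].
#' @export
read_predictions_tsv <- function(calls_path, availability_path, genes = NULL) {
  predictions_to_tensor(
    read_tsv_file(calls_path, c("algorithm", "mirna", "gene", "call")),
    read_tsv_file(availability_path, c("algorithm", "mirna")),
    genes = genes)
}

#' Read a C+/C- signature from TSV
#'
#' @param path TSV with columns `gene`, `group` (`C+` or `C-`).
#' @return An `mm_signature`.
#' @export
read_signature_tsv <- function(path) {
  df <- read_tsv_file(path, c("gene", "group"))
  if (!all(df$group %in% c("C+", "C-"))) {
    stop_invalid("%s: signature group must be 'C+' or 'C-'", path)
  }
  signature_from_lists(df$gene[df$group == "C+"], df$gene[df$group == "C-"])
}
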