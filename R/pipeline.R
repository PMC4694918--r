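#' Declarative pipeline configuration
#'
#' Collects every stage toggle, threshold and file path the pipeline uses.
#' Thresholds default to the published analysis settings: 1.5-fold in at
#' least 2 cell lines for the unmasking screen; at least half of available
#' prediction algorithms; 1.5-fold and adjusted p < 0.005 for tumor
#' upregulation; p < 0.05 for the univariate Cox screen; 4 equally-spaced
#' risk levels; a 2 kb TSS window.
#'
#' @param inputs named list of input paths (see [run_pipeline()]).
#' @param output_dir run directory for stage outputs.
#' @param stages character subset of
#'   `c("screen", "methylation", "targets", "signature")`.
#' @param fold_threshold,min_lines,detection_floor unmasking-screen settings.
#' @param tss_window methylation probe-to-TSS window (bp).
#' @param rule_fraction consensus voting fraction in (0, 1].
#' @param fold_cutoff,adj_p_cutoff differential-upregulation gates.
#' @param alpha Cox screen significance level.
#' @param n_levels number of equally-spaced risk levels.
#' @param cohort_log2 is the survival-cohort expression matrix log2 scale?
#' @param seed integer seed recorded with the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = list(), output_dir = "run",
                            stages = c("screen", "methylation", "targets",
                                       "signature"),
                            fold_threshold = 1.5, min_lines = 2,
                            detection_floor = 0, tss_window = 2000,
                            rule_fraction = 0.5, fold_cutoff = 1.5,
                            adj_p_cutoff = 0.005, alpha = 0.05,
                            n_levels = 4, cohort_log2 = TRUE, seed = 1) {
  stages <- if (length(stages)) match.arg(stages, several.ok = TRUE) else character(0)
  cfg <- list(inputs = lapply(inputs, as.character),
              output_dir = output_dir, stages = stages,
              fold_threshold = fold_threshold, min_lines = as.integer(min_lines),
              detection_floor = detection_floor, tss_window = tss_window,
              rule_fraction = rule_fraction, fold_cutoff = fold_cutoff,
              adj_p_cutoff = adj_p_cutoff, alpha = alpha,
              n_levels = as.integer(n_levels),
              cohort_log2 = isTRUE(cohort_log2), seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (cfg$fold_threshold <= 1) stop_invalid("fold_threshold must be > 1")
  check_count(cfg$min_lines, "min_lines")
  if (cfg$tss_window <= 0) stop_invalid("tss_window must be > 0")
  if (cfg$rule_fraction <= 0 || cfg$rule_fraction > 1) {
    stop_invalid("rule_fraction must lie in (0, 1]")
  }
  if (cfg$fold_cutoff <= 0) stop_invalid("fold_cutoff must be > 0")
  check_prob(cfg$adj_p_cutoff, "adj_p_cutoff")
  check_prob(cfg$alpha, "alpha")
  check_count(cfg$n_levels, "n_levels", min = 2L)
  invisible(cfg)
}

#' Read / write a pipeline configuration (YAML)
#'
#' The configuration round-trips losslessly through its YAML serialization.
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate pipeline input files
#'
#' Report-only schema check of the pipeline's TSV inputs: header presence,
#' identifier uniqueness, beta-value range, survival-time positivity and
#' binary event codes. Inputs are never mutated.
#'
#' @param paths named list of file paths; recognized names are those of
#'   [run_pipeline()] inputs (`screen_expr`, `screen_samples`, `betas`,
#'   `beta_samples`, `probes`, `features`, `predictions`, `availability`,
#'   `de_expr`, `de_samples`, `cohort_expr`, `survival`).
#' @return data.frame with columns `file`, `role`, `record`, `message`;
#'   zero rows for clean inputs.
#' @export
validate_inputs <- function(paths) {
  report <- list()
  note <- function(role, record, message) {
    report[[length(report) + 1L]] <<- data.frame(
      file = as.character(paths[[role]]), role = role, record = record,
      message = message, stringsAsFactors = FALSE)
  }
  try_read <- function(role, fun) {
    if (is.null(paths[[role]])) return(NULL)
    tryCatch(fun(paths[[role]]),
             error = function(e) { note(role, NA, conditionMessage(e)); NULL })
  }
  check_matrix_tsv <- function(role, id_col) {
    df <- try_read(role, function(p) read_tsv_file(p, id_col))
    if (is.null(df)) return(NULL)
    ids <- df[[id_col]]
    dup <- unique(ids[duplicated(ids)])
    for (d in dup) note(role, d, sprintf("duplicate %s", id_col))
    vals <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "double")
    if (any(is.na(vals))) note(role, NA, "non-numeric or missing values")
    df
  }
  for (role in intersect(c("screen_expr", "de_expr", "cohort_expr"), names(paths))) {
    check_matrix_tsv(role, "feature_id")
  }
  for (role in intersect(c("screen_samples", "de_samples", "beta_samples"),
                         names(paths))) {
    df <- try_read(role, function(p) read_tsv_file(p, "sample_id"))
    if (!is.null(df)) {
      for (d in unique(df$sample_id[duplicated(df$sample_id)])) {
        note(role, d, "duplicate sample_id")
      }
    }
  }
  if ("betas" %in% names(paths)) {
    df <- check_matrix_tsv("betas", "probe_id")
    if (!is.null(df)) {
      vals <- as.matrix(df[, setdiff(names(df), "probe_id"), drop = FALSE])
      suppressWarnings(storage.mode(vals) <- "double")
      bad <- which(rowSums(vals < 0 | vals > 1, na.rm = TRUE) > 0)
      for (i in bad) note("betas", df$probe_id[i], "beta value outside [0, 1]")
    }
  }
  if ("survival" %in% names(paths)) {
    df <- try_read("survival", function(p)
      read_tsv_file(p, c("sample_id", "time", "event")))
    if (!is.null(df)) {
      for (i in which(!is.finite(df$time) | df$time <= 0)) {
        note("survival", df$sample_id[i], "non-positive survival time")
      }
      for (i in which(!df$event %in% c(0, 1))) {
        note("survival", df$sample_id[i], "event not in {0, 1}")
      }
      for (d in unique(df$sample_id[duplicated(df$sample_id)])) {
        note("survival", d, "duplicate sample_id")
      }
    }
  }
  if ("predictions" %in% names(paths)) {
    df <- try_read("predictions", function(p)
      read_tsv_file(p, c("algorithm", "mirna", "gene", "call")))
    if (!is.null(df) && !all(df$call %in% c(0, 1))) {
      note("predictions", NA, "call values must be 0/1")
    }
  }
  if ("features" %in% names(paths)) {
    df <- try_read("features", read_feature_tsv)
    if (!is.null(df)) {
      for (i in which(df$tss <= 0)) {
        note("features", df$feature_id[i], "TSS must be positive (1-based)")
      }
    }
  }
  if (!length(report)) {
    return(data.frame(file = character(0), role = character(0),
                      record = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, report)
  rownames(out) <- NULL
  out
}

#' Run the unmasking pipeline end to end
#'
#' Executes the enabled stages in order — unmasking screen, methylation
#' comparison, target consensus with tumor-upregulation intersection,
#' survival signature — writing each stage's TSV outputs into the run
#' directory plus a machine-readable `summary.json` recording every
#' threshold applied and the count at every filter. The run is deterministic
#' for a fixed configuration.
#'
#' Recognized `inputs` entries: `screen_expr` + `screen_samples` (expression
#' TSV + sheet with `cell_line`, `condition`); `betas` + `beta_samples` +
#' `probes` (BED) + `features`; `predictions` + `availability`; `de_expr` +
#' `de_samples`; `cohort_expr` + `survival`.
#'
#' @param config a `pipeline_config`.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- config$inputs
  need <- function(role) {
    if (is.null(inp[[role]])) stop_invalid("config input '%s' is required for this stage", role)
    inp[[role]]
  }
  out_path <- function(name) file.path(config$output_dir, name)
  summary <- list(seed = config$seed,
                  thresholds = config[c("fold_threshold", "min_lines",
                                        "detection_floor", "tss_window",
                                        "rule_fraction", "fold_cutoff",
                                        "adj_p_cutoff", "alpha", "n_levels")])
  candidates <- NULL

  if ("screen" %in% config$stages) {
    expr <- read_expr_tsv(need("screen_expr"), need("screen_samples"))
    treated_ids <- expr$samples$sample_id[expr$samples$condition == "treated"]
    control_ids <- expr$samples$sample_id[expr$samples$condition == "control"]
    split_arm <- function(ids) {
      expr_matrix(expr$values[, ids, drop = FALSE],
                  expr$samples[expr$samples$sample_id %in% ids, , drop = FALSE])
    }
    fc <- compute_fold_changes(split_arm(treated_ids), split_arm(control_ids),
                               detection_floor = config$detection_floor)
    cand <- select_unmasked(fc, config$fold_threshold, config$min_lines)
    candidates <- cand$selected
    write_tsv_file(fc, out_path("fold_changes.tsv"))
    write_tsv_file(data.frame(mirna = cand$selected, stringsAsFactors = FALSE),
                   out_path("candidates.tsv"))
    summary$screen <- list(n_mirna = nrow(expr$values),
                           n_fold_change_rows = nrow(fc),
                           n_nd_rows = sum(fc$regulation == "n.d."),
                           n_candidates = length(cand$selected),
                           candidates = cand$selected)
  }

  if ("methylation" %in% config$stages) {
    betas <- read_beta_tsv(need("betas"), need("beta_samples"))
    ann <- annotate_probes_to_features(read_probe_bed(need("probes")),
                                       read_feature_tsv(need("features")),
                                       window = config$tss_window)
    probe_res <- compare_methylation(betas, ann, level = "probe")
    region_res <- compare_methylation(betas, ann, level = "region")
    write_tsv_file(ann, out_path("probe_annotation.tsv"))
    write_tsv_file(probe_res, out_path("methylation_probe_tests.tsv"))
    write_tsv_file(region_res, out_path("methylation_region_tests.tsv"))
    summary$methylation <- list(
      n_probes = nrow(betas$values), n_linked_probes = length(unique(ann$probe_id)),
      n_probe_tests = nrow(probe_res), n_region_tests = nrow(region_res),
      n_probe_hypermethylated_p05 = sum(probe_res$delta > 0 &
                                          probe_res$p_value < 0.05))
  }

  if ("targets" %in% config$stages) {
    tensor <- read_predictions_tsv(need("predictions"), need("availability"))
    voted_mirnas <- tensor$mirnas
    if (!is.null(candidates)) {
      voted_mirnas <- intersect(tensor$mirnas, candidates)
      if (!length(voted_mirnas)) {
        stop_invalid("no screen candidate has prediction calls")
      }
      keep <- match(voted_mirnas, tensor$mirnas)
      tensor <- prediction_tensor(
        tensor$calls[, keep, , drop = FALSE],
        tensor$available[, keep, drop = FALSE])
    }
    ts <- consensus_targets(tensor, rule_fraction = config$rule_fraction)
    de <- differential_upregulation(
      read_expr_tsv(need("de_expr"), need("de_samples")),
      fold_cutoff = config$fold_cutoff, adj_p_cutoff = config$adj_p_cutoff)
    final_genes <- intersect_targets_with_upregulated(ts, de)
    per <- do.call(rbind, lapply(names(ts$per_mirna), function(m) {
      if (!length(ts$per_mirna[[m]])) return(NULL)
      data.frame(mirna = m, gene = ts$per_mirna[[m]], stringsAsFactors = FALSE)
    }))
    write_tsv_file(per %||% data.frame(mirna = character(0), gene = character(0)),
                   out_path("targets_per_mirna.tsv"))
    write_tsv_file(data.frame(gene = ts$union), out_path("targets_union.tsv"))
    write_tsv_file(de, out_path("differential_upregulation.tsv"))
    write_tsv_file(data.frame(gene = final_genes),
                   out_path("targets_upregulated.tsv"))
    summary$targets <- list(n_mirnas_voted = length(ts$per_mirna),
                            n_union_targets = length(ts$union),
                            n_genes_tested = nrow(de),
                            n_upregulated = sum(de$upregulated),
                            n_intersect = length(final_genes))
    candidates_genes <- final_genes
  } else candidates_genes <- NULL

  if ("signature" %in% config$stages) {
    expr <- read_expr_tsv(need("cohort_expr"), log2 = config$cohort_log2)
    surv <- read_survival_tsv(need("survival"))
    pool <- candidates_genes %||% rownames(expr$values)
    fits <- cox_screen(expr, surv, genes = intersect(pool, rownames(expr$values)))
    sig <- build_signature(fits, alpha = config$alpha)
    scores <- compute_risk_scores(expr, sig)
    scores <- bin_risk_levels(scores, n_levels = config$n_levels)
    surv_m <- surv[match(scores$sample_id, surv$sample_id), ]
    assoc <- survival_association(scores$level, surv_m)
    km <- km_curves(scores$level, surv_m)
    write_tsv_file(fits, out_path("cox_screen.tsv"))
    write_tsv_file(data.frame(
      gene = c(sig$c_plus, sig$c_minus),
      group = rep(c("C+", "C-"), c(length(sig$c_plus), length(sig$c_minus)))),
      out_path("signature.tsv"))
    write_tsv_file(scores, out_path("risk_scores.tsv"))
    write_tsv_file(as.data.frame(assoc), out_path("association.tsv"))
    write_tsv_file(km, out_path("km_curves.tsv"))
    summary$signature <- list(
      n_genes_screened = nrow(fits),
      n_significant = sum(fits$p_value < config$alpha),
      n_cplus = length(sig$c_plus), n_cminus = length(sig$c_minus),
      c_plus = sig$c_plus, c_minus = sig$c_minus,
      n_levels_used = length(unique(scores$level)),
      hazard_ratio_per_level = assoc$hazard_ratio,
      ci_low = assoc$ci_low, ci_high = assoc$ci_high,
      p_value = assoc$p_value, n_events = assoc$n_events)
  }

  if (length(config$stages)) {
    jsonlite::write_json(summary, out_path("summary.json"), auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
  }
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a complete synthetic fixture directory
#'
#' Generates every pipeline input with the synthetic-data module, writes
#' them in the pipeline's TSV/BED formats together with a ready-to-run
#' `config.yaml` and a `truth_manifest.txt` (key-value text) recording the
#' planted ground truth. With `noiseless = TRUE` all stochastic noise is
#' switched off (fixed 4-fold unmasking effects, noise-free betas and
#' expression, perfect prediction calls), so every deterministic stage must
#' reproduce its planted truth exactly.
#'
#' @param dir output directory (created).
#' @param seed integer seed.
#' @param noiseless disable all measurement noise.
#' @param n_mirna,n_silenced screen dimensions.
#' @param n_samples survival-cohort size.
#' @param beta_rs planted log hazard ratio per unit risk score.
#' @return Invisibly, a list with the truth objects and the config path.
#' @export
simulate_fixture <- function(dir, seed = 1, noiseless = FALSE,
                             n_mirna = 100, n_silenced = 9, n_samples = 400,
                             beta_rs = 0.7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) file.path(dir, name)

  sim <- gen_unmasking_experiment(
    n_mirna, n_silenced,
    effect_range = if (noiseless) c(4, 4) else c(2, 8),
    noise_sd = if (noiseless) 0 else 0.2, seed = seed)
  silenced <- sim$truth$silenced_mirnas
  comb <- cbind(sim$treated$values, sim$control$values)
  write_tsv_file(data.frame(feature_id = rownames(comb), comb,
                            check.names = FALSE), p("screen_expr.tsv"))
  write_tsv_file(rbind(sim$treated$samples, sim$control$samples),
                 p("screen_samples.tsv"))

  meth <- gen_methylation_cohort(
    n_probes = 60, n_candidate = 27,
    noise_sd = if (noiseless) 0 else 0.05, seed = seed + 101)
  write_tsv_file(data.frame(probe_id = rownames(meth$betas$values),
                            meth$betas$values, check.names = FALSE),
                 p("betas.tsv"))
  write_tsv_file(meth$betas$samples, p("beta_samples.tsv"))
  ann <- meth$annotation
  write.table(data.frame(ann$chrom, ann$position - 1L, ann$position,
                         ann$probe_id),
              p("probes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  feats <- unique(ann[ann$tss_distance == 0,
                      c("linked_feature", "chrom", "position")])
  write_tsv_file(data.frame(feature_id = feats$linked_feature,
                            chrom = feats$chrom, tss = feats$position,
                            strand = "+"), p("features.tsv"))

  genes <- sprintf("gene%03d", 1:120)
  target_pool <- genes[1:50]
  tensor_mirnas <- c(silenced,
                     setdiff(sprintf("mir-%03d", seq_len(n_mirna)),
                             silenced)[1:6])
  truth_targets <- with_seed(seed + 202, {
    lapply(setNames(tensor_mirnas, tensor_mirnas), function(m) {
      if (m %in% silenced) sort(sample(target_pool, 12)) else
        sort(sample(genes, 8))
    })
  })
  tensor <- gen_prediction_tensor(
    tensor_mirnas, genes, truth_targets,
    sensitivity = if (noiseless) 1 else 0.9,
    fpr = if (noiseless) 0 else 0.05,
    availability = if (noiseless) 1 else 0.8, seed = seed + 303)
  av_idx <- which(tensor$available == 1, arr.ind = TRUE)
  avail_df <- data.frame(algorithm = rownames(tensor$available)[av_idx[, 1]],
                         mirna = colnames(tensor$available)[av_idx[, 2]])
  call_idx <- which(tensor$calls == 1, arr.ind = TRUE)
  calls_df <- data.frame(algorithm = tensor$algorithms[call_idx[, 1]],
                         mirna = tensor$mirnas[call_idx[, 2]],
                         gene = tensor$genes[call_idx[, 3]], call = 1L)
  write_tsv_file(calls_df, p("predictions.tsv"))
  write_tsv_file(avail_df, p("availability.tsv"))

  planted_union <- sort(unique(unlist(truth_targets[silenced],
                                      use.names = FALSE)))
  planted_up <- sort(c(intersect(planted_union, genes[1:30]), genes[101:110]))
  de <- gen_tumor_normal_expr(genes, planted_up, fold = 2,
                              noise_sd = if (noiseless) 0 else 0.3,
                              seed = seed + 404)
  write_expr_tsv(de, p("de_expr.tsv"), p("de_samples.tsv"))
  planted_intersect <- sort(intersect(planted_union, planted_up))

  sig_pool <- planted_intersect
  if (length(sig_pool) < 20) {
    stop_invalid("fixture geometry yielded <20 intersect genes; change seed")
  }
  tr <- survival_truth(sig_pool[1:10], sig_pool[11:20], beta_rs = beta_rs,
                       censor_rate = 0.3)
  coh <- gen_survival_cohort(n_samples, length(genes), tr, genes = genes,
                             seed = seed + 505)
  write_expr_tsv(coh$expr, p("cohort_expr.tsv"))
  write_tsv_file(coh$survival, p("survival.tsv"))

  cfg <- pipeline_config(
    inputs = list(screen_expr = p("screen_expr.tsv"),
                  screen_samples = p("screen_samples.tsv"),
                  betas = p("betas.tsv"), beta_samples = p("beta_samples.tsv"),
                  probes = p("probes.bed"), features = p("features.tsv"),
                  predictions = p("predictions.tsv"),
                  availability = p("availability.tsv"),
                  de_expr = p("de_expr.tsv"), de_samples = p("de_samples.tsv"),
                  cohort_expr = p("cohort_expr.tsv"),
                  survival = p("survival.tsv")),
    output_dir = file.path(dir, "run"), seed = seed)
  write_pipeline_config(cfg, p("config.yaml"))

  manifest <- c(
    seed = seed, noiseless = as.integer(noiseless), n_mirna = n_mirna,
    n_silenced = length(silenced),
    silenced_mirnas = paste(silenced, collapse = ","),
    n_candidate_probes = length(meth$candidates),
    n_planted_features = length(unique(
      ann$linked_feature[ann$probe_id %in% meth$candidates])),
    n_target_union = length(planted_union),
    n_planted_upregulated = length(planted_up),
    n_planted_intersect = length(planted_intersect),
    n_planted_cplus = length(tr$planted_cpos),
    n_planted_cminus = length(tr$planted_cneg),
    planted_cplus = paste(tr$planted_cpos, collapse = ","),
    planted_cminus = paste(tr$planted_cneg, collapse = ","),
    beta_rs = beta_rs, censor_rate = tr$censor_rate)
  writeLines(paste(names(manifest), manifest, sep = "\t"),
             p("truth_manifest.txt"))

  invisible(list(config_path = p("config.yaml"),
                 truth = list(screen = sim$truth,
                              methylation = meth[c("annotation", "candidates")],
                              targets = truth_targets, survival = tr),
                 manifest = as.list(manifest)))
}

#' Read a fixture truth manifest
#'
#' @param path `truth_manifest.txt` written by [simulate_fixture()].
#' @return Named list of character values.
#' @export
read_truth_manifest <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(kv, function(x) if (length(x) > 1) x[2] else ""),
           vapply(kv, `[`, "", 1))
}
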