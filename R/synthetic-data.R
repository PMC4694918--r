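#' Ground truth for a synthetic survival cohort
#'
#' Describes the planted survival signature of a simulated cohort: the gene
#' sets with positive (`planted_cpos`) and negative (`planted_cneg`)
#' log-hazard association, the log hazard ratio per unit of true risk score,
#' and the target censoring fraction.
#'
#' @param planted_cpos character vector of genes whose higher expression
#'   raises the hazard.
#' @param planted_cneg character vector of genes whose higher expression
#'   lowers the hazard; must be disjoint from `planted_cpos`.
#' @param beta_rs finite log hazard ratio per unit of true risk score.
#' @param censor_rate expected fraction of samples censored, in \[0, 1\].
#' @return An object of class `survival_truth`.
#' @export
survival_truth <- function(planted_cpos, planted_cneg, beta_rs = 0.7,
                           censor_rate = 0.3) {
  planted_cpos <- as.character(planted_cpos)
  planted_cneg <- as.character(planted_cneg)
  if (length(intersect(planted_cpos, planted_cneg))) {
    stop_invalid("planted C+ and C- gene sets must be disjoint")
  }
  if (!is.numeric(beta_rs) || length(beta_rs) != 1L || !is.finite(beta_rs)) {
    stop_invalid("`beta_rs` must be a single finite number")
  }
  check_prob(censor_rate, "censor_rate")
  structure(list(planted_cpos = planted_cpos, planted_cneg = planted_cneg,
                 beta_rs = beta_rs, censor_rate = censor_rate),
            class = "survival_truth")
}

#' Simulate a demethylating-agent unmasking experiment
#'
#' Generates paired treated/control miRNA expression matrices across several
#' myeloma cell lines, with a planted subset of epigenetically silenced
#' miRNAs that respond to the demethylating agent. Baseline log2 intensities
#' are normal (so linear intensities are log-normal, as on single-channel
#' arrays); each silenced miRNA is multiplied, in a random subset of at least
#' two cell lines, by a per-line linear effect drawn from `effect_range`.
#' Gaussian noise is applied on the log2 scale.
#'
#' @param n_mirna number of miRNA features.
#' @param n_silenced number of planted demethylation-responsive miRNAs
#'   (`<= n_mirna`).
#' @param n_lines number of cell lines; one treated and one control sample
#'   per line.
#' @param effect_range length-2 numeric, linear fold-effect interval; lower
#'   bound must be >= 1.
#' @param noise_sd standard deviation of log2-scale noise.
#' @param detection_floor linear intensity below which a feature counts as
#'   not detected downstream (recorded in the truth object).
#' @param baseline_log2 length-2 numeric: mean and sd of baseline log2
#'   intensities.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `treated` and `control` [expr_matrix] objects and
#'   `truth`, a list with `silenced_mirnas`, `per_line_effect` (miRNA x line
#'   matrix of linear effects, 1 where unaffected) and `detection_floor`.
#' @examples
#' sim <- gen_unmasking_experiment(50, 5, seed = 1)
#' sim$truth$silenced_mirnas
#' @export
gen_unmasking_experiment <- function(n_mirna, n_silenced, n_lines = 4,
                                     effect_range = c(2, 8), noise_sd = 0.2,
                                     detection_floor = 0,
                                     baseline_log2 = c(7, 1.5), seed = 1) {
  n_mirna <- check_count(n_mirna, "n_mirna")
  n_silenced <- check_count(n_silenced, "n_silenced", min = 0L)
  n_lines <- check_count(n_lines, "n_lines")
  if (n_silenced > n_mirna) stop_invalid("n_silenced must be <= n_mirna")
  if (length(effect_range) != 2L || effect_range[1] < 1 ||
      effect_range[2] < effect_range[1]) {
    stop_invalid("`effect_range` must be an interval with lower bound >= 1")
  }
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (detection_floor < 0) stop_invalid("`detection_floor` must be >= 0")

  mirnas <- sprintf("mir-%03d", seq_len(n_mirna))
  lines <- if (n_lines == 4) c("H929", "MM1S", "OPM2", "8226") else
    sprintf("line%02d", seq_len(n_lines))

  with_seed(seed, {
    base <- rnorm(n_mirna, baseline_log2[1], baseline_log2[2])
    silenced <- sort(sample(mirnas, n_silenced))
    effect <- matrix(1, n_mirna, n_lines, dimnames = list(mirnas, lines))
    min_affected <- min(2L, n_lines)
    for (m in silenced) {
      k <- if (n_lines == min_affected) n_lines else
        sample(seq(min_affected, n_lines), 1L)
      hit <- sample(lines, k)
      effect[m, hit] <- runif(k, effect_range[1], effect_range[2])
    }
    make_arm <- function(arm_effect, suffix, condition) {
      log2v <- base + log2(arm_effect) +
        matrix(rnorm(n_mirna * n_lines, 0, noise_sd), n_mirna, n_lines)
      v <- 2^log2v
      dimnames(v) <- list(mirnas, paste0(lines, suffix))
      expr_matrix(v, data.frame(sample_id = colnames(v), cell_line = lines,
                                condition = condition,
                                stringsAsFactors = FALSE))
    }
    treated <- make_arm(effect, "_aza", "treated")
    control <- make_arm(matrix(1, n_mirna, n_lines), "_dmso", "control")
    list(treated = treated, control = control,
         truth = list(silenced_mirnas = silenced, per_line_effect = effect,
                      detection_floor = detection_floor))
  })
}

#' Simulate a tumor/normal methylation cohort
#'
#' Generates a CpG beta-value matrix for a tumor-versus-normal design with a
#' planted hypermethylation shift: candidate probes are shifted upward by
#' `delta_beta` in tumor samples before clipping to \[0, 1\]. Probes are
#' grouped three per feature on a toy chromosome and annotated with position,
#' linked feature and signed TSS distance, mirroring CpG probes near miRNA
#' transcription start sites.
#'
#' @param n_probes total CpG probes.
#' @param n_candidate number of planted hypermethylated probes
#'   (`<= n_probes`); candidates fill whole features first, so planted
#'   features are those whose probes are all candidates.
#' @param n_tumor,n_normal group sizes (study design default 17 vs 5).
#' @param delta_beta planted beta shift in tumor samples, in (0, 1).
#' @param baseline_range interval for per-probe baseline (unmethylated)
#'   means.
#' @param noise_sd per-measurement Gaussian noise on the beta scale.
#' @param seed integer seed.
#' @return list with `betas` ([beta_matrix]), `annotation` (data.frame:
#'   probe_id, chrom, position, linked_feature, tss_distance, region_class)
#'   and `candidates` (character vector of planted probe ids).
#' @export
gen_methylation_cohort <- function(n_probes, n_candidate, n_tumor = 17,
                                   n_normal = 5, delta_beta = 0.3,
                                   baseline_range = c(0.05, 0.15),
                                   noise_sd = 0.05, seed = 1) {
  n_probes <- check_count(n_probes, "n_probes")
  n_candidate <- check_count(n_candidate, "n_candidate", min = 0L)
  n_tumor <- check_count(n_tumor, "n_tumor")
  n_normal <- check_count(n_normal, "n_normal")
  if (n_candidate > n_probes) stop_invalid("n_candidate must be <= n_probes")
  if (!is.numeric(delta_beta) || length(delta_beta) != 1L ||
      delta_beta <= 0 || delta_beta >= 1) {
    stop_invalid("`delta_beta` must lie in (0, 1)")
  }

  probes <- sprintf("cg%06d", seq_len(n_probes))
  n_feat <- ceiling(n_probes / 3)
  feat_of <- rep(sprintf("mir-feat-%03d", seq_len(n_feat)), each = 3)[seq_len(n_probes)]
  # one TSS per feature, probes at -500/0/+500 around it
  tss <- 10000L * seq_len(n_feat)
  offset <- rep(c(-500L, 0L, 500L), length.out = n_probes)
  pos <- tss[match(feat_of, unique(feat_of))] + offset
  classes <- c("island", "shore", "intragenic", "intergenic")

  samples <- c(sprintf("MM_%02d", seq_len(n_tumor)),
               sprintf("NPC_%02d", seq_len(n_normal)))
  groups <- rep(c("tumor", "normal"), c(n_tumor, n_normal))

  with_seed(seed, {
    region_class <- sample(classes, n_probes, replace = TRUE)
    baseline <- runif(n_probes, baseline_range[1], baseline_range[2])
    shift <- matrix(0, n_probes, length(samples))
    cand <- probes[seq_len(n_candidate)]
    shift[seq_len(n_candidate), groups == "tumor"] <- delta_beta
    b <- baseline + shift +
      matrix(rnorm(n_probes * length(samples), 0, noise_sd),
             n_probes, length(samples))
    b <- pmin(pmax(b, 0), 1)
    dimnames(b) <- list(probes, samples)
    betas <- beta_matrix(b, data.frame(sample_id = samples, group = groups,
                                       stringsAsFactors = FALSE))
    annotation <- data.frame(probe_id = probes, chrom = "chr1",
                             position = pos, linked_feature = feat_of,
                             tss_distance = offset,
                             region_class = region_class,
                             stringsAsFactors = FALSE)
    list(betas = betas, annotation = annotation, candidates = cand)
  })
}

#' Simulate a target-prediction tensor
#'
#' Emulates binary miRNA-to-gene calls from a panel of prediction algorithms.
#' Each (algorithm, miRNA) cell is available with probability `availability`
#' (scalar or per-algorithm vector); unavailable cells are masked (`NA`),
#' never zero. An available algorithm calls a true pair with probability
#' `sensitivity` and a false pair with probability `fpr`. Every miRNA is
#' guaranteed at least one available algorithm among algorithms whose
#' availability probability is positive.
#'
#' @param mirnas,genes non-empty character vectors of identifiers.
#' @param true_targets named list: for each miRNA, the character vector of
#'   its true target genes.
#' @param n_algorithms number of prediction algorithms (default 12, the size
#'   of a typical aggregated panel).
#' @param sensitivity,fpr per-algorithm call probabilities for true and
#'   false pairs.
#' @param availability probability that an (algorithm, miRNA) cell is
#'   available; scalar or length `n_algorithms`.
#' @param seed integer seed.
#' @return A [prediction_tensor], with the truth attached as attribute
#'   `true_targets`.
#' @export
gen_prediction_tensor <- function(mirnas, genes, true_targets,
                                  n_algorithms = 12, sensitivity = 0.9,
                                  fpr = 0.05, availability = 0.8, seed = 1) {
  mirnas <- as.character(mirnas); genes <- as.character(genes)
  if (!length(mirnas) || !length(genes)) {
    stop_invalid("miRNA and gene lists must be non-empty")
  }
  n_algorithms <- check_count(n_algorithms, "n_algorithms")
  check_prob(sensitivity, "sensitivity"); check_prob(fpr, "fpr")
  if (!length(availability) %in% c(1L, n_algorithms) ||
      any(availability < 0 | availability > 1)) {
    stop_invalid("`availability` must be probabilities, scalar or one per algorithm")
  }
  avail_p <- rep(availability, length.out = n_algorithms)
  algs <- sprintf("alg%02d", seq_len(n_algorithms))
  truth <- lapply(setNames(mirnas, mirnas),
                  function(m) intersect(as.character(true_targets[[m]]), genes))

  with_seed(seed, {
    available <- matrix(rbinom(n_algorithms * length(mirnas), 1,
                               rep(avail_p, times = length(mirnas))),
                        n_algorithms, length(mirnas),
                        dimnames = list(algs, mirnas))
    for (j in seq_along(mirnas)) {
      if (sum(available[, j]) == 0 && any(avail_p > 0)) {
        available[sample(which(avail_p > 0), 1L), j] <- 1L
      }
    }
    is_true <- array(0L, dim = c(length(mirnas), length(genes)),
                     dimnames = list(mirnas, genes))
    for (m in mirnas) is_true[m, truth[[m]]] <- 1L
    calls <- array(NA_real_,
                   dim = c(n_algorithms, length(mirnas), length(genes)),
                   dimnames = list(algs, mirnas, genes))
    p <- ifelse(is_true == 1L, sensitivity, fpr)
    for (a in seq_len(n_algorithms)) {
      on <- which(available[a, ] == 1)
      if (length(on)) {
        calls[a, on, ] <- rbinom(length(on) * length(genes), 1, p[on, ])
      }
    }
    out <- prediction_tensor(calls, available)
    attr(out, "true_targets") <- truth
    out
  })
}

#' Simulate an expression-plus-survival cohort
#'
#' Generates per-gene standard-normal (log-scale) expression for `n_samples`
#' patients and exponential survival times under a proportional-hazards model
#' whose linear predictor is `beta_rs` times the true median-difference risk
#' score computed from the planted C+/C- gene sets (RS = U - D, with U and D
#' the per-sample medians of C+ and C- gene expression). Censoring times are
#' uniform on (0, tau), with tau solved so the expected censored fraction
#' equals `truth$censor_rate`; censoring is independent of the event process.
#'
#' @param n_samples number of patients.
#' @param n_genes size of the gene universe; planted sets must be contained
#'   in `gene001 ... geneNNN` (or pass explicit `genes`).
#' @param truth a [survival_truth] object.
#' @param baseline_hazard baseline exponential event rate (> 0), per month.
#' @param genes optional character vector of gene ids (length `n_genes`).
#' @param seed integer seed.
#' @return list with `expr` (log-scale [expr_matrix]), `survival`
#'   (data.frame: sample_id, time, event) and `true_rs` (named numeric).
#' @examples
#' tr <- survival_truth(paste0("gene", 1:5), paste0("gene", 6:10))
#' coh <- gen_survival_cohort(100, 20, tr, genes = paste0("gene", 1:20), seed = 2)
#' head(coh$survival)
#' @export
gen_survival_cohort <- function(n_samples, n_genes, truth,
                                baseline_hazard = 0.05, genes = NULL,
                                seed = 1) {
  n_samples <- check_count(n_samples, "n_samples")
  n_genes <- check_count(n_genes, "n_genes")
  if (!inherits(truth, "survival_truth")) {
    stop_invalid("`truth` must be a survival_truth object")
  }
  if (baseline_hazard <= 0) stop_invalid("`baseline_hazard` must be > 0")
  if (is.null(genes)) genes <- sprintf("gene%03d", seq_len(n_genes))
  if (length(genes) != n_genes) stop_invalid("`genes` must have length n_genes")
  planted <- c(truth$planted_cpos, truth$planted_cneg)
  if (!all(planted %in% genes)) {
    stop_invalid("planted gene sets must be contained in the gene universe")
  }

  samples <- sprintf("pt%04d", seq_len(n_samples))
  with_seed(seed, {
    v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(genes, samples))
    u <- apply(v[truth$planted_cpos, , drop = FALSE], 2, median)
    d <- apply(v[truth$planted_cneg, , drop = FALSE], 2, median)
    rs <- u - d
    rate <- baseline_hazard * exp(truth$beta_rs * rs)
    t_event <- rexp(n_samples, rate)
    if (truth$censor_rate == 0) {
      time <- t_event; event <- rep(1L, n_samples)
    } else if (truth$censor_rate >= 1) {
      time <- t_event * runif(n_samples); event <- rep(0L, n_samples)
    } else {
      frac_cens <- function(tau) mean(pmin(t_event / tau, 1)) - truth$censor_rate
      tau <- uniroot(frac_cens, lower = min(t_event) * 1e-6,
                     upper = max(t_event) * 1e6, tol = 1e-10)$root
      cens <- runif(n_samples, 0, tau)
      event <- as.integer(t_event <= cens)
      time <- pmin(t_event, cens)
    }
    time <- pmax(time, .Machine$double.xmin)
    expr <- expr_matrix(v, data.frame(sample_id = samples,
                                      stringsAsFactors = FALSE), log2 = TRUE)
    list(expr = expr,
         survival = data.frame(sample_id = samples, time = time,
                               event = event, stringsAsFactors = FALSE),
         true_rs = setNames(rs, samples))
  })
}

#' Simulate tumor/normal gene expression with planted upregulation
#'
#' Companion generator for the differential-upregulation stage: log-normal
#' gene expression for a tumor-versus-normal design with a planted set of
#' genes upregulated by a fixed linear fold in tumor samples.
#'
#' @param genes character vector of gene ids.
#' @param upregulated subset of `genes` planted as tumor-upregulated.
#' @param fold planted linear fold change (>= 1).
#' @param n_tumor,n_normal group sizes.
#' @param noise_sd log2-scale noise standard deviation.
#' @param baseline_log2 mean/sd of baseline log2 intensities.
#' @param seed integer seed.
#' @return A linear-scale [expr_matrix] whose sample sheet carries a `group`
#'   column.
#' @export
gen_tumor_normal_expr <- function(genes, upregulated, fold = 2,
                                  n_tumor = 20, n_normal = 20,
                                  noise_sd = 0.3, baseline_log2 = c(7, 1),
                                  seed = 1) {
  genes <- as.character(genes)
  if (!all(upregulated %in% genes)) {
    stop_invalid("`upregulated` must be a subset of `genes`")
  }
  if (fold < 1) stop_invalid("`fold` must be >= 1")
  n_tumor <- check_count(n_tumor, "n_tumor")
  n_normal <- check_count(n_normal, "n_normal")
  samples <- c(sprintf("MM_%03d", seq_len(n_tumor)),
               sprintf("NPC_%03d", seq_len(n_normal)))
  groups <- rep(c("tumor", "normal"), c(n_tumor, n_normal))
  with_seed(seed, {
    base <- rnorm(length(genes), baseline_log2[1], baseline_log2[2])
    shift <- matrix(0, length(genes), length(samples))
    shift[genes %in% upregulated, groups == "tumor"] <- log2(fold)
    log2v <- base + shift +
      matrix(rnorm(length(genes) * length(samples), 0, noise_sd),
             length(genes), length(samples))
    v <- 2^log2v
    dimnames(v) <- list(genes, samples)
    expr_matrix(v, data.frame(sample_id = samples, group = groups,
                              stringsAsFactors = FALSE))
  })
}
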