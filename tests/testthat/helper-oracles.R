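# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and libraries) they verify.

# Breslow log partial likelihood for a single covariate, written from the
# definition: sum over event times of (beta * x_i - log(sum of exp(beta * x_j)
# over the risk set)), with tied events sharing the full risk set.
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Numerical maximization of the Breslow partial likelihood on a wide bracket.
breslow_fit_oracle <- function(time, event, x, interval = c(-20, 20)) {
  optimize(function(b) breslow_loglik(b, time, event, x),
           interval = interval, maximum = TRUE, tol = 1e-9)$maximum
}

# Exact two-sided Mann-Whitney p-value by enumerating every assignment of the
# pooled observations to the two groups (valid without ties).
mwu_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  u_stat <- function(ga, gb) sum(outer(ga, gb, ">"))
  u_obs <- u_stat(a, b)
  n <- length(a)
  combos <- combn(length(pooled), n)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- length(a) * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Per-row counting implementation of the unmasking selection rule.
select_unmasked_oracle <- function(fc, fold_threshold, min_lines) {
  mirnas <- unique(fc$mirna)
  sel <- character(0)
  for (m in mirnas) {
    rows <- fc[fc$mirna == m, ]
    n_up <- 0
    for (i in seq_len(nrow(rows))) {
      if (!is.na(rows$fold_change[i]) && rows$regulation[i] == "up" &&
          rows$fold_change[i] >= fold_threshold) {
        n_up <- n_up + 1
      }
    }
    if (n_up >= min_lines) sel <- c(sel, m)
  }
  sort(sel)
}

# Brute-force consensus voting: nested loops over miRNAs and genes.
consensus_oracle <- function(tensor, rule_fraction) {
  out <- list()
  for (m in tensor$mirnas) {
    avail <- which(tensor$available[, m] == 1)
    if (!length(avail)) next
    genes <- character(0)
    for (g in tensor$genes) {
      votes <- 0
      for (a in avail) if (isTRUE(tensor$calls[a, m, g] == 1)) votes <- votes + 1
      if (votes >= rule_fraction * length(avail)) genes <- c(genes, g)
    }
    out[[m]] <- sort(genes)
  }
  out
}

# All-pairs probe-to-TSS linking by direct distance comparison.
annotate_oracle <- function(probes, features, window) {
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    for (j in seq_len(nrow(features))) {
      if (probes$chrom[i] != features$chrom[j]) next
      d <- probes$position[i] - features$tss[j]
      if (abs(d) <= window) {
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = probes$probe_id[i],
          linked_feature = features$feature_id[j],
          tss_distance = if (features$strand[j] == "-") -d else d,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame(probe_id = character(0),
                                       linked_feature = character(0),
                                       tss_distance = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$linked_feature, out$probe_id), , drop = FALSE]
}

# Pooled-variance two-sample t-test from the closed form.
student_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = tstat, p = 2 * pt(-abs(tstat), na + nb - 2))
}

# A small survival table helper for toy fixtures.
toy_surv <- function(time, event = 1) {
  data.frame(time = time, event = rep(event, length.out = length(time)))
}
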