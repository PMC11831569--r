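# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each statistic from its definition with
# plain loops, sharing no code with the package internals.

# Weighted KS random-walk enrichment score, computed step by step.
oracle_es_walk <- function(z, set_idx, tau = 1, combine = "diff") {
  p <- nrow(z)
  vapply(seq_len(ncol(z)), function(j) {
    ord <- order(-z[, j], seq_len(p))
    rho <- p - seq_len(p) + 1          # top of the list gets rank p
    w <- abs(p / 2 - rho)^tau
    inset <- ord %in% set_idx
    wtot <- sum(w[inset])
    inc <- if (wtot > 0) w * inset / wtot else inset / sum(inset)
    dec <- (!inset) / (p - length(set_idx))
    nu <- cumsum(inc - dec)
    if (combine == "absmax") {
      # ties in magnitude resolve to the positive excursion
      if (max(nu) >= -min(nu)) max(nu) else min(nu)
    } else {
      max(0, max(nu)) + min(0, min(nu))
    }
  }, numeric(1))
}

# AUC by exhaustive pair counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Harrell's C by exhaustive pair enumeration.
oracle_harrell <- function(times, events, risks) {
  n <- length(times)
  num <- den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (times[i] < times[j] && events[i] == 1) {
      den <- den + 1
      num <- num + (risks[i] > risks[j]) + 0.5 * (risks[i] == risks[j])
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Mann-Whitney U (for group a) by pair counting.
oracle_u_stat <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + (x > y) + 0.5 * (x == y)
  tot
}

# Upper-tail hypergeometric / one-sided Fisher p by direct summation of
# table probabilities.
oracle_hyper_p <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Ridge-penalized logistic regression (no intercept penalty) fitted by
# Nelder-Mead/BFGS on the literal objective.
oracle_ridge_logistic <- function(X, y, C1) {
  nll <- function(par) {
    theta <- par[-length(par)]
    b <- par[length(par)]
    eta <- as.numeric(X %*% theta) + b
    sum(log1p(exp(eta)) - y * eta) + C1 / 2 * sum(theta^2)
  }
  opt <- optim(numeric(ncol(X) + 1), nll, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  list(theta = opt$par[-(ncol(X) + 1)], b = opt$par[ncol(X) + 1])
}

# Default-scale reference simulation, generated once per test run and
# shared across files.
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.sim_cache$sc)) {
    cfg <- sim_config(seed = 1)
    .sim_cache$cfg <- cfg
    .sim_cache$sc <- generate_sc_datasets(cfg)
    .sim_cache$bulk <- generate_bulk_cohorts(cfg)
    .sim_cache$screens <- generate_crispr_screens(cfg)
  }
  list(cfg = .sim_cache$cfg, sc = .sim_cache$sc, bulk = .sim_cache$bulk,
       screens = .sim_cache$screens)
}

# Per-dataset signatures for the reference simulation (QC + scoring +
# marker detection are the expensive part; computed once).
default_signatures <- function() {
  if (is.null(.sim_cache$sigs)) {
    sim <- default_sim()
    sen <- sim$sc[[1]]$truth$senescence_set_genes
    .sim_cache$qc <- lapply(sim$sc, function(x) qc_filter_cells(x$dataset))
    .sim_cache$sigs <- lapply(.sim_cache$qc, per_dataset_signature,
                              senescence_genes = sen)
  }
  list(qc = .sim_cache$qc, sigs = .sim_cache$sigs)
}
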