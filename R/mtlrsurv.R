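# Multi-task logistic regression (MTLR) survival model with
# differential-expression feature selection around the median survival
# time, plus concordance evaluation. The model places logistic "tasks"
# on a discretized time grid; a subject's likelihood sums over the
# monotone death-time sequences consistent with its (possibly censored)
# observation.

#' Select prognostic genes by differential expression around median OS
#'
#' Splits samples at the median observed time M: `poor` outcome is death
#' before M, `good` is surviving to at least M; samples censored before M
#' are excluded (their class is unknown). Each gene is tested with a
#' two-sided Wilcoxon rank-sum test and the `n_features` smallest-p genes
#' are returned (ties broken by larger absolute median difference, then
#' gene id).
#'
#' @param expr samples x genes expression matrix.
#' @param times,events Survival outcome per sample.
#' @param n_features Number of genes to return (default 10).
#' @return Character vector of selected gene ids.
#' @export
select_de_features <- function(expr, times, events, n_features = 10) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 20L) stop("need at least 20 samples with outcome")
  M <- median(times)
  poor <- times < M & events == 1
  good <- times >= M
  keep <- poor | good
  if (sum(poor) < 5L || sum(good) < 5L) {
    stop("fewer than 5 samples in the poor or good OS group")
  }
  sub <- expr[keep, , drop = FALSE]
  grp <- poor[keep]
  ws <- rowwise_ranksum(t(sub), grp)
  meddiff <- abs(apply(sub[grp, , drop = FALSE], 2L, median) -
                   apply(sub[!grp, , drop = FALSE], 2L, median))
  ord <- order(ws$p, -meddiff, colnames(expr))
  colnames(expr)[head(ord, n_features)]
}

#' Build a discretization grid from event times
#'
#' Uses `m = clamp(ceiling(sqrt(#events)), 2, 30)` boundaries placed at
#' evenly spaced interior quantiles of the event times, deduplicated.
#'
#' @param times,events Survival outcome.
#' @return Numeric vector of strictly increasing positive boundaries
#'   (class `mtlr_grid`).
#' @export
make_time_grid <- function(times, events) {
  ev <- times[events == 1]
  if (length(unique(ev)) < 2L) stop("need at least 2 distinct event times")
  m <- min(max(ceiling(sqrt(length(ev))), 2L), 30L)
  q <- unname(quantile(ev, probs = seq_len(m) / (m + 1)))
  q <- unique(q[q > 0])
  if (length(q) < 2L) stop("degenerate grid: fewer than 2 distinct boundaries")
  structure(q, class = "mtlr_grid")
}

# interval index of time x on grid t: i such that t_{i-1} < x <= t_i,
# with i = m+1 beyond the last boundary
interval_index <- function(x, grid) {
  findInterval(x, grid, left.open = TRUE) + 1L
}

row_logsumexp <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

# Sequence scores F (n x (m+1)): F[, j+1] = sum_{k > j} (theta_k . x + b_k),
# column m+1 is the all-survive sequence with score 0.
mtlr_seq_scores <- function(X, theta, b) {
  A <- X %*% t(theta) + matrix(b, nrow(X), length(b), byrow = TRUE)
  m <- length(b)
  if (m == 1L) return(cbind(A, 0))
  Frev <- t(apply(A[, m:1, drop = FALSE], 1L, cumsum))
  cbind(Frev[, m:1, drop = FALSE], 0)
}

mtlr_objective <- function(par, X, int_idx, events, m, C1, C2) {
  d <- ncol(X)
  theta <- matrix(par[seq_len(m * d)], m, d)
  b <- par[m * d + seq_len(m)]
  Fm <- mtlr_seq_scores(X, theta, b)
  logZ <- row_logsumexp(Fm)
  n <- nrow(X)
  ll <- numeric(n)
  unc <- events == 1
  if (any(unc)) ll[unc] <- Fm[cbind(which(unc), int_idx[unc])] - logZ[unc]
  if (any(!unc)) {
    for (i in which(!unc)) {
      cols <- int_idx[i]:(m + 1L)
      fi <- Fm[i, cols]
      mx <- max(fi)
      ll[i] <- mx + log(sum(exp(fi - mx))) - logZ[i]
    }
  }
  pen <- C1 / 2 * sum(theta^2)
  if (m > 1L && C2 > 0) {
    dtheta <- theta[-1L, , drop = FALSE] - theta[-m, , drop = FALSE]
    pen <- pen + C2 / 2 * sum(dtheta^2)
  }
  -sum(ll) + pen
}

mtlr_gradient <- function(par, X, int_idx, events, m, C1, C2) {
  d <- ncol(X)
  n <- nrow(X)
  theta <- matrix(par[seq_len(m * d)], m, d)
  b <- par[m * d + seq_len(m)]
  Fm <- mtlr_seq_scores(X, theta, b)
  P <- exp(Fm - row_logsumexp(Fm))
  # Q[, k] = E_P[ 1(death interval <= k) ] = cumulative sequence mass
  Q <- t(apply(P, 1L, cumsum))[, seq_len(m), drop = FALSE]
  Tm <- matrix(0, n, m)
  unc <- events == 1
  if (any(unc)) {
    Tm[unc, ] <- outer(int_idx[unc], seq_len(m),
                       function(i, k) as.numeric(k >= i))
  }
  if (any(!unc)) {
    for (i in which(!unc)) {
      cols <- int_idx[i]:(m + 1L)
      pt_ <- P[i, cols]
      pt_ <- pt_ / sum(pt_)
      full <- numeric(m + 1L)
      full[cols] <- pt_
      Tm[i, ] <- cumsum(full)[seq_len(m)]
    }
  }
  Gmat <- Q - Tm  # n x m, gradient of NLL wrt A[, k]
  grad_theta <- t(Gmat) %*% X + C1 * theta
  if (m > 1L && C2 > 0) {
    sm <- matrix(0, m, d)
    sm[1L, ] <- theta[1L, ] - theta[2L, ]
    if (m > 2L) {
      mid <- 2:(m - 1L)
      sm[mid, ] <- 2 * theta[mid, , drop = FALSE] -
        theta[mid - 1L, , drop = FALSE] - theta[mid + 1L, , drop = FALSE]
    }
    sm[m, ] <- theta[m, ] - theta[m - 1L, ]
    grad_theta <- grad_theta + C2 * sm
  }
  grad_b <- colSums(Gmat)
  c(as.numeric(grad_theta), grad_b)
}

#' Fit the MTLR survival model
#'
#' Minimizes the censored negative log-likelihood plus a ridge penalty
#' `C1/2 * sum ||theta_k||^2` and a temporal-smoothness penalty
#' `C2/2 * sum ||theta_{k+1} - theta_k||^2` by quasi-Newton (BFGS)
#' iteration from zero initialization (deterministic). Uncensored
#' subjects contribute the probability of their death-interval sequence;
#' censored subjects contribute the summed probability of every sequence
#' whose death interval is not excluded by the censoring time.
#'
#' @param X samples x features matrix, standardized (mean 0, sd 1 per
#'   feature).
#' @param times,events Survival outcome.
#' @param grid Boundaries from [make_time_grid()] (computed when NULL).
#' @param C1 Ridge strength (default 1).
#' @param C2 Smoothness strength (default 1).
#' @param tol Target gradient max-norm (default 1e-6).
#' @param max_iter BFGS iteration budget (default 2000).
#' @return Object of class `mtlr_fit`: `theta` (m x d), `b`, `grid`,
#'   penalties, and a convergence record.
#' @export
fit_mtlr <- function(X, times, events, grid = NULL, C1 = 1.0, C2 = 1.0,
                     tol = 1e-6, max_iter = 2000) {
  X <- as.matrix(X)
  if (sum(events) == 0) stop("no events observed: model is unidentifiable")
  if (is.null(grid)) grid <- make_time_grid(times, events)
  m <- length(grid)
  d <- ncol(X)
  int_idx <- interval_index(times, grid)
  par0 <- numeric(m * d + m)
  opt <- optim(par0, mtlr_objective, mtlr_gradient,
               X = X, int_idx = int_idx, events = events, m = m,
               C1 = C1, C2 = C2, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-15))
  if (!is.finite(opt$value)) {
    stop(sprintf("non-finite objective (%g) during MTLR fit", opt$value))
  }
  g <- mtlr_gradient(opt$par, X, int_idx, events, m, C1, C2)
  gnorm <- max(abs(g))
  if (gnorm > tol) {
    opt2 <- optim(opt$par, mtlr_objective, mtlr_gradient,
                  X = X, int_idx = int_idx, events = events, m = m,
                  C1 = C1, C2 = C2, method = "BFGS",
                  control = list(maxit = max_iter, reltol = 1e-15))
    if (opt2$value <= opt$value) opt <- opt2
    g <- mtlr_gradient(opt$par, X, int_idx, events, m, C1, C2)
    gnorm <- max(abs(g))
    if (gnorm > tol) {
      warning(sprintf("MTLR did not reach tol (gradient max-norm %.2e)",
                      gnorm))
    }
  }
  theta <- matrix(opt$par[seq_len(m * d)], m, d,
                  dimnames = list(NULL, colnames(X)))
  structure(list(theta = theta, b = opt$par[m * d + seq_len(m)],
                 grid = as.numeric(grid), C1 = C1, C2 = C2,
                 convergence = list(objective = opt$value,
                                    grad_norm = gnorm,
                                    counts = opt$counts)),
            class = "mtlr_fit")
}

#' @export
print.mtlr_fit <- function(x, ...) {
  cat(sprintf("mtlr_fit: %d intervals x %d features; objective %.4f, |grad| %.2e\n",
              length(x$b), ncol(x$theta), x$convergence$objective,
              x$convergence$grad_norm))
  invisible(x)
}

#' Predict survival curves and risk scores from an MTLR fit
#'
#' `S(t_k | x)` is the summed probability of the sequences that survive
#' past `t_k`; the risk score is `sum_k (1 - S(t_k))`, the expected
#' number of grid intervals died through (monotone in predicted death
#' mass).
#'
#' @param object An `mtlr_fit`.
#' @param newdata samples x features matrix with the model's features.
#' @param ... Unused.
#' @return List with `survival` (samples x m matrix of S(t_k)),
#'   `sequence_prob` (samples x (m+1)), and `risk`.
#' @export
predict.mtlr_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(object$theta))) {
    missing <- setdiff(colnames(object$theta), colnames(X))
    if (length(missing) > 0L) {
      stop(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")))
    }
    X <- X[, colnames(object$theta), drop = FALSE]
  }
  m <- length(object$b)
  Fm <- mtlr_seq_scores(X, object$theta, object$b)
  P <- exp(Fm - row_logsumexp(Fm))
  revcum <- t(apply(P[, (m + 1L):1L, drop = FALSE], 1L, cumsum))
  # revcum[, r] = sum_{jj >= m+2-r} P[, jj]; S(t_k) = sum_{jj >= k+1} P
  S <- revcum[, m:1L, drop = FALSE]
  colnames(S) <- paste0("t", seq_len(m))
  risk <- rowSums(1 - S)
  list(survival = S, sequence_prob = P, risk = unname(risk))
}

#' Concordance index between risk scores and survival outcome
#'
#' Harrell's C uses the comparable pairs `(i, j)` with `t_i < t_j` and an
#' event at `t_i`; a pair is concordant when the earlier-failing sample
#' has the higher risk, ties count 1/2. Uno's C weights each pair by the
#' inverse squared Kaplan-Meier estimate of the censoring survival at
#' `t_i` and restricts to `t_i < tau`.
#'
#' @param times,events Survival outcome.
#' @param risks Predicted risk scores (higher = worse).
#' @param method `"harrell"` (default) or `"uno"`.
#' @param tau Horizon for Uno's C (default: 90th percentile of observed
#'   times).
#' @return Concordance in [0, 1].
#' @export
concordance_index <- function(times, events, risks,
                              method = c("harrell", "uno"), tau = NULL) {
  method <- match.arg(method)
  n <- length(times)
  stopifnot(length(events) == n, length(risks) == n)
  if (method == "uno") {
    if (is.null(tau)) tau <- unname(quantile(times, 0.9))
    cens_km <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
    Gfun <- stats::stepfun(cens_km$time, c(1, cens_km$surv), right = FALSE)
    # left-continuous evaluation G(t-)
    Gminus <- function(t) Gfun(t - 1e-10)
  }
  num <- den <- 0
  for (i in which(events == 1)) {
    cmp <- times > times[i]
    if (!any(cmp)) next
    w <- 1
    if (method == "uno") {
      if (times[i] >= tau) next
      g <- Gminus(times[i])
      if (g <= 0) next
      w <- 1 / g^2
    }
    conc <- sum(risks[i] > risks[cmp]) + 0.5 * sum(risks[i] == risks[cmp])
    num <- num + w * conc
    den <- den + w * sum(cmp)
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}
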