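sim_exp_surv <- function(n, beta, censor_rate = 0.2, seed = 1) {
  set.seed(seed)
  d <- length(beta)
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("x", 1:d)))
  lp <- as.numeric(X %*% beta)
  death <- rexp(n, rate = exp(lp) / 500)
  cens <- rexp(n, censor_rate / 500)
  list(X = X, times = pmin(death, cens),
       events = as.integer(death <= cens), lp = lp)
}

test_that("DE feature selection classifies outcomes around the median and ranks planted genes", {
  set.seed(25)
  n <- 200
  risk <- rnorm(n)
  times <- rexp(n, exp(risk) / 100)
  events <- rbinom(n, 1, 0.8)
  expr <- cbind(matrix(rnorm(n * 50), n, 50),
                sig1 = risk + rnorm(n, 0, 0.5),
                sig2 = -risk + rnorm(n, 0, 0.5))
  colnames(expr)[1:50] <- sprintf("null%02d", 1:50)
  feats <- select_de_features(expr, times, events, n_features = 2)
  expect_setequal(feats, c("sig1", "sig2"))
  expect_error(select_de_features(expr[1:10, ], times[1:10], events[1:10]),
               "at least 20")
})

test_that("a constant gene is never selected ahead of differential ones", {
  set.seed(26)
  n <- 60
  times <- rexp(n, 1 / 100)
  events <- rep(1, n)
  expr <- cbind(flat = rep(1, n),
                good = (times < median(times)) + rnorm(n, 0, 0.2))
  feats <- select_de_features(expr, times, events, n_features = 1)
  expect_equal(feats, "good")
})

test_that("time grid follows the sqrt-of-events rule", {
  times <- seq_len(100)
  grid <- make_time_grid(times, rep(1, 100))
  expect_length(grid, 10)
  expect_true(all(diff(grid) > 0))
  g2 <- make_time_grid(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_true(all(diff(g2) > 0) && all(g2 > 0))
  expect_error(make_time_grid(c(5, 7), c(1, 0)), "2 distinct event")
})

test_that("with one interval the model reduces to ridge logistic regression", {
  set.seed(30)
  for (rep_i in 1:20) {
    n <- 40
    X <- matrix(rnorm(n * 3), n, 3)
    X <- scale(X)
    attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
    t1 <- 10
    times <- rexp(n, 1 / 12)
    events <- rep(1, n)
    fit <- fit_mtlr(X, times, events, grid = t1, C1 = 1, C2 = 0)
    orc <- oracle_ridge_logistic(X, as.numeric(times <= t1), C1 = 1)
    expect_equal(as.numeric(fit$theta), orc$theta, tolerance = 1e-4)
    expect_equal(fit$b, orc$b, tolerance = 1e-4)
    pred <- predict(fit, X)
    expect_equal(pred$risk,
                 plogis(as.numeric(X %*% orc$theta) + orc$b),
                 tolerance = 1e-4)
  }
})

test_that("predicted sequence probabilities are a proper, monotone distribution", {
  dat <- sim_exp_surv(120, c(0.8, -0.5), seed = 5)
  fit <- fit_mtlr(scale(dat$X), dat$times, dat$events, tol = 1e-5)
  pred <- predict(fit, scale(dat$X))
  expect_equal(rowSums(pred$sequence_prob), rep(1, 120), tolerance = 1e-12)
  expect_true(all(pred$survival >= -1e-12 & pred$survival <= 1 + 1e-12))
  expect_true(all(apply(pred$survival, 1, function(s) all(diff(s) <= 1e-12))))
  # identical inputs get identical curves
  X0 <- matrix(0, 5, 2, dimnames = list(NULL, colnames(dat$X)))
  p0 <- predict(fit, X0)
  expect_equal(max(apply(p0$survival, 2, function(col) diff(range(col)))), 0)
})

test_that("objective decreases with iteration count and C1 shrinks the weights", {
  dat <- sim_exp_surv(80, c(1, 0.5), seed = 8)
  Xs <- scale(dat$X)
  f_small <- fit_mtlr(Xs, dat$times, dat$events, C1 = 0.1, tol = 1e-5)
  f_big <- fit_mtlr(Xs, dat$times, dat$events, C1 = 10, tol = 1e-5)
  expect_lt(sum(f_big$theta^2), sum(f_small$theta^2))
  expect_lte(f_small$convergence$grad_norm, 1e-5)
  expect_error(fit_mtlr(Xs, dat$times, rep(0, 80)), "no events")
})

test_that("risk ordering recovers the generating hazard on exponential data", {
  dat <- sim_exp_surv(500, c(0.8, -0.6, 0.4), censor_rate = 0.15, seed = 2)
  true_c <- concordance_index(dat$times, dat$events, dat$lp)
  fit <- fit_mtlr(scale(dat$X), dat$times, dat$events, tol = 1e-5)
  pred <- predict(fit, scale(dat$X))
  model_c <- concordance_index(dat$times, dat$events, pred$risk)
  expect_lt(abs(model_c - true_c), 0.05)
})

test_that("Harrell concordance matches enumeration and the survival package", {
  set.seed(33)
  for (rep_i in 1:10) {
    n <- 20
    times <- sample(1:12, n, replace = TRUE)
    events <- rbinom(n, 1, 0.7)
    risks <- sample(1:6, n, replace = TRUE)
    if (sum(events) == 0) next
    mine <- concordance_index(times, events, risks)
    expect_equal(mine, oracle_harrell(times, events, risks),
                 tolerance = 1e-12)
    # cross-check against the survival package on tie-free times (its
    # convention for time-tied pairs differs from the pinned one)
    t2 <- times + runif(n, 0, 0.5)
    mine2 <- concordance_index(t2, events, risks)
    ref <- survival::concordance(survival::Surv(t2, events) ~ risks,
                                 reverse = TRUE)
    expect_equal(mine2, unname(ref$concordance), tolerance = 1e-10)
  }
})

test_that("concordance edge behavior: perfect ordering, random risks, Uno weighting", {
  times <- c(5, 3, 8, 1, 9, 2, 7)
  ev <- rep(1, 7)
  expect_equal(concordance_index(times, ev, -times), 1)
  set.seed(40)
  t2 <- rexp(200)
  e2 <- rbinom(200, 1, 0.8)
  r2 <- rnorm(200)
  expect_lt(abs(concordance_index(t2, e2, r2) - 0.5), 0.05)
  u <- concordance_index(t2, e2, -t2, method = "uno")
  expect_gt(u, 0.95)
  expect_error(concordance_index(c(1, 2), c(0, 1), c(1, 2)),
               "no comparable pairs")
})
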