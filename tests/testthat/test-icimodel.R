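test_that("per-cohort standardization zeroes means, fixes variances, preserves order", {
  set.seed(6)
  expr <- matrix(rnorm(60 * 5, mean = rep(c(0, 5), each = 30)), 60, 5,
                 dimnames = list(sprintf("s%02d", 1:60), letters[1:5]))
  cohort <- rep(c("x", "y"), each = 30)
  adj <- batch_standardize(expr, cohort)
  for (ch in c("x", "y")) {
    sub <- adj[cohort == ch, ]
    expect_equal(colMeans(sub), rep(0, 5), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(apply(sub, 2, sd), rep(1, 5), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(order(expr[cohort == ch, "a"]), order(sub[, "a"]))
  }
  # a cohort-separating mean shift carries no information afterwards
  expect_lt(abs(roc_auc(adj[, "a"], cohort == "y") - 0.5), 0.15)
  expect_error(batch_standardize(expr[1:31, ], c(rep("x", 30), "y")),
               "singleton")
})

test_that("8:2 partition reproduces the 657/164 arithmetic and stratification", {
  ids <- sprintf("p%03d", 1:821)
  labels <- rep(c("R", "NR"), c(250, 571))
  part <- partition_cohort(ids, labels, 0.8, seed = 2)
  expect_length(part$train, 657)
  expect_length(part$validation, 164)
  expect_length(intersect(part$train, part$validation), 0)
  expect_setequal(c(part$train, part$validation), ids)
  # class proportions preserved within one sample
  tr_r <- sum(labels[match(part$train, ids)] == "R")
  expect_lte(abs(tr_r - 250 * 657 / 821), 1)
  small <- partition_cohort(sprintf("q%02d", 1:10), train_frac = 0.8,
                            seed = 1)
  expect_length(small$train, 8)
  expect_length(small$validation, 2)
  p1 <- partition_cohort(ids, labels, seed = 5)
  p2 <- partition_cohort(ids, labels, seed = 5)
  p3 <- partition_cohort(ids, labels, seed = 6)
  expect_identical(p1, p2)
  expect_false(identical(p1$train, p3$train))
})

test_that("AUC has the worked values, tie rule, and matches pair counting", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(14)
  for (rep_i in 1:10) {
    sc <- sample(1:5, 30, replace = TRUE)
    y <- sample(c(0, 1), 30, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(sc, y), oracle_auc(sc, y), tolerance = 1e-12)
  }
  # invariant to strictly increasing transforms
  set.seed(15)
  sc <- rnorm(50)
  y <- rbinom(50, 1, 0.5)
  expect_equal(roc_auc(sc, y), roc_auc(exp(2 * sc), y), tolerance = 1e-12)
})

test_that("classifier separates separable data and flags single-class labels", {
  set.seed(3)
  X <- matrix(rnorm(80 * 4), 80, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- ifelse(X[, 1] > 0, "R", "NR")
  mod <- train_response_classifier(X, y, "logistic", k = 5, repeats = 1,
                                   seed = 4)
  expect_equal(roc_auc(predict(mod, X), y == "R"), 1)
  expect_error(train_response_classifier(X, rep("R", 80), "logistic"),
               "both response classes")
})

test_that("permuted labels give chance-level cross-validated AUC", {
  set.seed(19)
  n <- 400
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- sample(rep(c("R", "NR"), c(150, 250)))
  mod <- train_response_classifier(
    X, y, "gbm", k = 5, repeats = 2, seed = 7,
    grid = data.frame(nrounds = 50, max_depth = 2, eta = 0.1))
  expect_lt(abs(mod$cv_auc[mod$best] - 0.5), 0.08)
})

test_that("held-out AUC on planted response structure beats the permutation null", {
  cfg <- sim_config(bulk_n_samples = 800, response_coef = 6, seed = 17)
  bk <- generate_bulk_cohorts(cfg)
  clin <- bk$cohort$clinical
  feats <- bk$truth$planted_fss_genes
  es <- batch_standardize(bk$cohort$expr, clin$cohort)
  part <- partition_cohort(clin$sample_id, clin$response, 0.8, seed = 17)
  tr <- match(part$train, clin$sample_id)
  va <- match(part$validation, clin$sample_id)
  mod <- train_response_classifier(es[tr, feats], clin$response[tr],
                                   "logistic", k = 5, repeats = 1,
                                   seed = 17)
  obs <- roc_auc(predict(mod, es[va, feats]), clin$response[va] == "R")
  set.seed(18)
  null_auc <- replicate(199, {
    yp <- sample(clin$response[tr])
    m0 <- suppressWarnings(
      stats::glm(y ~ ., data.frame(y = yp == "R", es[tr, feats]),
                 family = stats::binomial()))
    sc0 <- suppressWarnings(predict(m0, data.frame(es[va, feats]),
                                    type = "response"))
    roc_auc(sc0, clin$response[va] == "R")
  })
  p_emp <- (1 + sum(null_auc >= obs)) / 200
  expect_lt(p_emp, 0.01)
})

test_that("Kaplan-Meier log-rank matches the hand-computed O-E table", {
  # times 1..4, all events, groups A,A,B,B:
  # O_A = 2, E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36
  # chi-square = (2 - 5/6)^2 / (17/36) = 49/17
  res <- kaplan_meier_logrank(c(1, 2, 3, 4), c(1, 1, 1, 1),
                              c("A", "A", "B", "B"))
  expect_equal(res$chisq, 49 / 17, tolerance = 1e-8)
  expect_equal(res$p, pchisq(49 / 17, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("identical groups give a null log-rank and KM equals the empirical survival", {
  t2 <- rep(c(1, 2, 3, 5), 2)
  g <- rep(c("A", "B"), each = 4)
  res <- kaplan_meier_logrank(t2, rep(1, 8), g)
  expect_lt(res$chisq, 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-6)
  # without censoring the product-limit estimate is the empirical S(t)
  km <- res$km
  sA <- summary(km)$surv[summary(km)$strata == "groups=A"]
  expect_equal(sA, c(0.75, 0.5, 0.25, 0), tolerance = 1e-12)
  expect_error(kaplan_meier_logrank(t2, rep(0, 8), g), "event")
})
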