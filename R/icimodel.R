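# Immunotherapy-response model harness: per-cohort standardization,
# stratified 8:2 partitioning, cross-validated gradient-boosted-tree (or
# logistic) training on signature-gene features, ROC/AUC, and
# Kaplan-Meier / log-rank risk-group comparison.

#' Per-cohort gene-wise standardization
#'
#' Centers and scales every gene to mean 0 / unit variance within each
#' cohort (a rank-preserving surrogate for cross-cohort batch removal).
#' Genes with zero within-cohort variance are set to 0.
#'
#' @param expr samples x genes matrix.
#' @param cohort Cohort label per sample.
#' @return Standardized matrix of the same shape.
#' @export
batch_standardize <- function(expr, cohort) {
  expr <- as.matrix(expr)
  cohort <- as.character(cohort)
  if (length(cohort) != nrow(expr)) stop("cohort must align to samples")
  sizes <- table(cohort)
  if (any(sizes < 2)) {
    stop(sprintf("singleton cohort(s): %s",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  out <- expr
  for (ch in names(sizes)) {
    sel <- cohort == ch
    sub <- expr[sel, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2L, sd)
    z <- sweep(sub, 2L, mu, "-")
    z <- sweep(z, 2L, ifelse(sdv > 0, sdv, 1), "/")
    z[, sdv == 0] <- 0
    out[sel, ] <- z
  }
  out
}

#' Stratified train/validation partition
#'
#' The training size is `floor(train_frac * n + 0.5)` (round half up;
#' 821 samples at 0.8 give 657). Per-class training quotas follow the
#' largest-remainder rule so class proportions match the global split
#' within one sample; allocation within class is a seeded shuffle.
#'
#' @param ids Sample identifiers.
#' @param labels Optional stratification labels (e.g. response). `NULL`
#'   for an unstratified split.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Seed for the shuffle.
#' @return List with `train` and `validation` id vectors (disjoint,
#'   exhaustive).
#' @export
partition_cohort <- function(ids, labels = NULL, train_frac = 0.8, seed = 1) {
  n <- length(ids)
  if (n < 5L) stop("need at least 5 samples to partition")
  n_train <- floor(train_frac * n + 0.5)
  set.seed(as.integer(seed))
  if (is.null(labels)) {
    train <- sample(ids, n_train)
    return(list(train = train, validation = setdiff(ids, train)))
  }
  labels <- as.character(labels)
  strata <- split(ids, labels)
  if (any(lengths(strata) == 0L)) {
    warning("empty stratum; falling back to unstratified split")
    return(partition_cohort(ids, NULL, train_frac, seed))
  }
  quota_raw <- lengths(strata) * n_train / n
  quota <- floor(quota_raw)
  rem <- n_train - sum(quota)
  if (rem > 0) {
    extra <- order(quota_raw - quota, names(strata), decreasing = TRUE)[seq_len(rem)]
    quota[extra] <- quota[extra] + 1L
  }
  # tiny strata can starve one side; fall back rather than emit an empty
  # class in either split
  if (any(quota == 0L) || any(lengths(strata) - quota == 0L)) {
    warning("a stratum would be empty in one split; unstratified fallback")
    return(partition_cohort(ids, NULL, train_frac, seed))
  }
  train <- unlist(lapply(names(strata), function(s) {
    sample(strata[[s]], quota[[s]])
  }), use.names = FALSE)
  list(train = train, validation = setdiff(ids, train))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs
#' where the positive scores higher, ties counted 1/2.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (logical, 0/1, or a two-level factor whose
#'   second level is positive).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  if (is.character(labels)) labels <- labels == sort(unique(labels))[2]
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

make_cv_folds <- function(y, k, repeats, seed) {
  set.seed(as.integer(seed))
  folds <- list()
  for (r in seq_len(repeats)) {
    assign_vec <- integer(length(y))
    for (cls in unique(y)) {
      ix <- which(y == cls)
      assign_vec[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
    for (f in seq_len(k)) {
      folds[[length(folds) + 1L]] <- which(assign_vec == f)
    }
  }
  folds
}

default_gbm_grid <- function() {
  expand.grid(nrounds = c(50, 100), max_depth = c(2, 3), eta = 0.1)
}

fit_gbm <- function(X, y01, pars) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y01)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   max_depth = pars$max_depth,
                                   eta = pars$eta, nthread = 1),
                     data = dtrain, nrounds = pars$nrounds, verbose = 0)
}

predict_gbm <- function(fit, X) {
  predict(fit, xgboost::xgb.DMatrix(as.matrix(X)))
}

#' Train an immunotherapy-response classifier with repeated CV
#'
#' Grid-searches a gradient-boosted-tree classifier (or fits a logistic
#' baseline) on signature-gene features, selecting hyperparameters by
#' mean AUC over stratified repeated k-fold cross-validation, then refits
#' on the full training set.
#'
#' @param X samples x features matrix (typically batch-standardized
#'   signature-gene expression).
#' @param y Response labels (`"R"`/`"NR"`, factor, or 0/1; responders are
#'   the positive class).
#' @param model `"gbm"` (gradient-boosted trees, default) or
#'   `"logistic"`.
#' @param k,repeats CV scheme (default 10-fold x 5 repeats).
#' @param seed Seed controlling folds and fitting.
#' @param grid Hyperparameter grid for `"gbm"` (data.frame with
#'   `nrounds`, `max_depth`, `eta`); a small default is used when NULL.
#' @return Object of class `response_model` with the fitted classifier,
#'   the CV record (`cv_auc` per grid row), and chosen hyperparameters.
#' @export
train_response_classifier <- function(X, y, model = c("gbm", "logistic"),
                                      k = 10, repeats = 5, seed = 1,
                                      grid = NULL) {
  model <- match.arg(model)
  X <- as.matrix(X)
  y01 <- response_to01(y)
  if (length(unique(y01)) < 2L) stop("both response classes must be present")
  folds <- make_cv_folds(y01, k, repeats, seed)
  cv_auc_for <- function(fit_fun, predict_fun) {
    aucs <- vapply(folds, function(test_ix) {
      if (length(unique(y01[-test_ix])) < 2L ||
          length(unique(y01[test_ix])) < 2L) return(NA_real_)
      fit <- fit_fun(X[-test_ix, , drop = FALSE], y01[-test_ix])
      roc_auc(predict_fun(fit, X[test_ix, , drop = FALSE]), y01[test_ix])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
  if (model == "gbm") {
    if (is.null(grid)) grid <- default_gbm_grid()
    set.seed(as.integer(seed))
    cv <- vapply(seq_len(nrow(grid)), function(i) {
      cv_auc_for(function(Xt, yt) fit_gbm(Xt, yt, grid[i, ]),
                 predict_gbm)
    }, numeric(1))
    best <- which.max(cv)
    set.seed(as.integer(seed))
    fit <- fit_gbm(X, y01, grid[best, ])
    pars <- grid[best, ]
  } else {
    df <- data.frame(y = y01, X)
    cv <- cv_auc_for(
      function(Xt, yt) {
        suppressWarnings(stats::glm(y ~ ., data.frame(y = yt, Xt),
                                    family = stats::binomial()))
      },
      function(fit, Xv) {
        suppressWarnings(predict(fit, data.frame(Xv), type = "response"))
      })
    fit <- suppressWarnings(stats::glm(y ~ ., df, family = stats::binomial()))
    best <- 1L
    grid <- data.frame(model = "logistic")
    pars <- grid
  }
  structure(list(model = model, fit = fit, features = colnames(X),
                 grid = grid, cv_auc = cv, best = best, pars = pars,
                 cv_scheme = list(k = k, repeats = repeats, seed = seed)),
            class = "response_model")
}

response_to01 <- function(y) {
  if (is.numeric(y)) return(as.integer(y))
  if (is.logical(y)) return(as.integer(y))
  y <- as.character(y)
  if (all(y %in% c("R", "NR"))) return(as.integer(y == "R"))
  as.integer(y == sort(unique(y))[2])
}

#' Predict response scores from a fitted classifier
#'
#' @param object A `response_model`.
#' @param newdata samples x features matrix containing the model's
#'   feature genes.
#' @param ... Unused.
#' @return Numeric response scores (probability of response).
#' @export
predict.response_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing) > 0L) {
    stop(sprintf("missing feature genes: %s",
                 paste(head(missing, 5), collapse = ", ")))
  }
  newdata <- newdata[, object$features, drop = FALSE]
  if (object$model == "gbm") {
    predict_gbm(object$fit, newdata)
  } else {
    suppressWarnings(predict(object$fit, data.frame(newdata),
                             type = "response"))
  }
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("response_model (%s): %d features, best CV AUC %.3f\n",
              x$model, length(x$features), max(x$cv_auc, na.rm = TRUE)))
  invisible(x)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group with the standard log-rank
#' chi-square (df = 1) via the survival package.
#'
#' @param times Follow-up times.
#' @param events Event indicators (1 = death).
#' @param groups Two-level group label (e.g. predicted high/low risk).
#' @return List of class `survival_comparison`: `km` (a
#'   `survival::survfit` object), `chisq`, `df`, `p`.
#' @export
kaplan_meier_logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("need exactly two groups")
  if (sum(events) == 0) stop("no events observed")
  if (any(tapply(events, groups, sum) == 0)) {
    stop("each group must contain at least one event")
  }
  df <- data.frame(times = times, events = events, groups = groups)
  km <- survival::survfit(survival::Surv(times, events) ~ groups, data = df)
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ groups, data = df)
  structure(list(km = km, chisq = unname(sd_$chisq), df = 1L,
                 p = pchisq(unname(sd_$chisq), df = 1, lower.tail = FALSE)),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.3f (df = %d), p = %.3g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}
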