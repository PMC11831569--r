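toy_cohort <- function(n = 40, p = 60, seed = 3) {
  set.seed(seed)
  expr <- matrix(rnorm(n * p), n, p,
                 dimnames = list(sprintf("s%03d", 1:n),
                                 sprintf("g%03d", 1:p)))
  expr
}

test_that("identical samples score identically and top-ranked sets maximize the score", {
  expr <- toy_cohort()
  expr[2, ] <- expr[1, ]
  sig <- colnames(expr)[1:10]
  sc <- score_cohort_fss(expr, sig)
  expect_equal(sc[1], sc[2], ignore_attr = TRUE)
  # a sample where the signature genes dominate every other gene
  expr2 <- toy_cohort()
  expr2[5, sig] <- 10
  expr2[5, setdiff(colnames(expr2), sig)] <- -10
  sc2 <- score_cohort_fss(expr2, sig)
  expect_equal(which.max(sc2), 5, ignore_attr = TRUE)
})

test_that("scoring warns on poor coverage and errors with none", {
  expr <- toy_cohort()
  expect_warning(score_cohort_fss(expr, c(colnames(expr)[1:3],
                                          sprintf("x%02d", 1:10))),
                 "signature genes present")
  expect_error(score_cohort_fss(expr, c("nope1", "nope2")), "no signature gene")
})

test_that("marker-mean immune scores reduce to the stated arithmetic", {
  expr <- toy_cohort()
  sets <- list(one = "g001", two = c("g002", "g003"))
  sc <- immune_scores(expr, sets)
  expect_equal(sc[, "one"], expr[, "g001"])
  expect_equal(sc[, "two"], rowMeans(expr[, c("g002", "g003")]))
  expr2 <- expr
  expr2[, "g010"] <- expr2[, "g010"] * 2   # non-member gene
  expect_equal(immune_scores(expr2, sets)[, "two"], sc[, "two"])
  expect_warning(immune_scores(expr, list(two = c("g002"), bad = "zz")),
                 "skipped")
})

test_that("pathway correlation is exact for self, signed, and NA for constants", {
  set.seed(4)
  fss <- runif(30)
  paths <- cbind(self = fss, anti = -fss, flat = rep(1, 30),
                 noise = rnorm(30))
  tab <- pathway_correlation(fss, paths)
  expect_equal(tab$r[tab$pathway == "self"], 1, tolerance = 1e-12)
  expect_lt(tab$r[tab$pathway == "anti"], 0)
  expect_true(is.na(tab$r[tab$pathway == "flat"]))
})

test_that("pathway correlation p-values are calibrated under permutation", {
  set.seed(12)
  fss <- runif(100)
  paths <- matrix(rnorm(100 * 50), 100,
                  dimnames = list(NULL, sprintf("p%02d", 1:50)))
  tab <- pathway_correlation(fss, paths)
  ks <- suppressWarnings(stats::ks.test(tab$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("median stratification yields the worked labels and a partition", {
  st <- stratify_fss_tmb(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(st$combined, c("LFHT", "LFHT", "HFLT", "HFLT"))
  set.seed(9)
  st2 <- stratify_fss_tmb(rnorm(101), rlnorm(101))
  expect_equal(sort(unique(st2$combined)),
               sort(unique(paste0(st2$fss_label, st2$tmb_label))))
  expect_equal(nrow(st2), 101)
  # odd n with distinct values: marginals split 50/51
  expect_equal(sort(table(st2$fss_label)), sort(c(LF = 51, HF = 50)),
               ignore_attr = TRUE)
  expect_error(stratify_fss_tmb(1:3, 1:3), "at least 4")
})

test_that("subgroup Mann-Whitney matches enumeration and handles extremes", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(6, 7, 8, 9)
  tab <- compare_subgroups(c(a, b), rep(c("A", "B"), c(5, 4)))
  expect_equal(tab$u, oracle_u_stat(a, b), tolerance = 1e-10)
  # identical groups: p near 1
  tab2 <- compare_subgroups(rep(c(1, 2, 3), 4),
                            rep(c("A", "B"), each = 6))
  expect_gt(tab2$p, 0.9)
  expect_warning(expect_warning(
    tab3 <- compare_subgroups(1:10, c(rep("A", 4), rep("B", 4), "C", "C")),
    "skipped"), "skipped")
  expect_equal(nrow(tab3), 1)  # only A vs B is testable
})

test_that("bulk cohort recovers latent burden and the cytotoxic ordering", {
  sim <- default_sim()
  bk <- sim$bulk
  fs <- score_cohort_fss(bk$cohort, bk$truth$planted_fss_genes)
  expect_gte(cor(fs, bk$truth$S, method = "spearman"), 0.6)
  imm <- immune_scores(bk$cohort, list(cyto = bk$truth$cytotoxic_genes))
  expect_lt(cor(imm[, 1], bk$truth$S, method = "spearman"), -0.3)
  st <- stratify_fss_tmb(fs, bk$cohort$clinical$tmb)
  mm <- tapply(imm[, 1], st$combined, mean)
  expect_true(mm[["LFHT"]] > mm[["LFLT"]])
  expect_true(mm[["LFLT"]] > mm[["HFHT"]])
  expect_true(mm[["HFHT"]] > mm[["HFLT"]])
  # high-FSS samples show significantly lower cytotoxic infiltration
  tests <- compare_subgroups(imm, st$fss_label)
  expect_lt(tests$fdr[1], 0.05)
  hf <- st$fss_label == "HF"
  expect_lt(mean(imm[hf, 1]), mean(imm[!hf, 1]))
})
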