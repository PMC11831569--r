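small_cfg <- function(...) {
  do.call(sim_config,
          utils::modifyList(list(n_datasets = 1, n_cells_per_dataset = 300,
                                 bulk_n_samples = 120, bulk_n_cohorts = 2,
                                 screen_n_datasets = 4),
                            list(...)))
}

test_that("config validation names the gene-budget deficit and bad knobs", {
  expect_error(sim_config(n_genes = 100), "deficit")
  expect_error(sim_config(censor_frac = 1), "censor_frac")
  expect_error(sim_config(screen_effect = -1), "delta")
  expect_error(sim_config(cell_type_props = c(fibroblast = 0.5,
                                              malignant = 0.4)),
               "sum to 1")
})

test_that("all three generators are bit-identical under a fixed seed", {
  cfg <- small_cfg(seed = 3)
  a <- generate_sc_datasets(cfg)
  b <- generate_sc_datasets(cfg)
  expect_identical(a[[1]]$dataset$counts, b[[1]]$dataset$counts)
  expect_identical(a[[1]]$truth$s, b[[1]]$truth$s)
  ba <- generate_bulk_cohorts(cfg)
  bb <- generate_bulk_cohorts(cfg)
  expect_identical(ba$cohort$expr, bb$cohort$expr)
  expect_identical(ba$cohort$clinical, bb$cohort$clinical)
  sa <- generate_crispr_screens(cfg)
  sb <- generate_crispr_screens(cfg)
  expect_identical(sa$screens, sb$screens)
})

test_that("latent senescence is fibroblast-shifted and planted sets are disjoint from foreign markers", {
  sim <- default_sim()
  for (x in sim$sc[1:3]) {
    s <- x$truth$s
    fib <- x$dataset$cell_meta$cell_type == "fibroblast"
    expect_gt(mean(s[fib]), max(vapply(
      setdiff(unique(x$dataset$cell_meta$cell_type), "fibroblast"),
      function(t) mean(s[x$dataset$cell_meta$cell_type == t]), numeric(1))))
    foreign <- unlist(x$truth$marker_genes[
      setdiff(names(x$truth$marker_genes), "fibroblast")])
    expect_length(intersect(x$truth$planted_fss_genes, foreign), 0)
  }
})

test_that("cell-type frequencies and mito fraction match the configured margins", {
  sim <- default_sim()
  cfg <- sim$cfg
  x <- sim$sc[[1]]
  tab <- table(x$dataset$cell_meta$cell_type)
  n <- ncol(x$dataset$counts)
  for (t in names(cfg$cell_type_props)) {
    pr <- cfg$cell_type_props[[t]]
    se <- sqrt(pr * (1 - pr) / n)
    expect_lt(abs(tab[[t]] / n - pr), 3 * se + 1e-9)
  }
  normal <- !colnames(x$dataset$counts) %in% x$truth$lowdepth_cells
  expect_lt(mean(x$dataset$cell_meta$pct_mito[normal]), 5)
})

test_that("a zero senescence slope yields null planted correlations", {
  cfg <- small_cfg(fss_effect = 0, n_cells_per_dataset = 500, seed = 9)
  x <- generate_sc_datasets(cfg)[[1]]
  norm <- lognormalize(x$dataset)
  fib <- x$dataset$cell_meta$cell_type == "fibroblast"
  s <- x$truth$s[fib]
  r <- vapply(x$truth$planted_fss_genes,
              function(g) cor(norm[g, fib], s, method = "spearman"),
              numeric(1))
  expect_lt(abs(mean(r)), 0.1)
})

test_that("planted senescence correlation is strong at reference settings", {
  sim <- default_sim()
  mean_r <- mean(vapply(sim$sc, function(x) {
    fib <- x$dataset$cell_meta$cell_type == "fibroblast"
    norm <- lognormalize(x$dataset)[x$truth$planted_fss_genes, fib]
    mean(vapply(seq_len(nrow(norm)),
                function(i) cor(norm[i, ], x$truth$s[fib],
                                method = "spearman"), numeric(1)))
  }, numeric(1)))
  expect_gt(mean_r, 0.3)
  # regression pin for the observed operating point
  expect_equal(mean_r, 0.35, tolerance = 0.05 / 0.35)
})

test_that("bulk survival is null when the hazard slope is zero", {
  cfg <- sim_config(bulk_n_samples = 500, hazard_coef = 0, seed = 21)
  bk <- generate_bulk_cohorts(cfg)
  cl <- bk$cohort$clinical
  cc <- concordance_index(cl$os_time, cl$os_event, bk$truth$S)
  expect_lt(abs(cc - 0.5), 0.05)
})

test_that("bulk clinical margins follow the configuration", {
  sim <- default_sim()
  bk <- sim$bulk
  cl <- bk$cohort$clinical
  expect_true(all(cl$os_time > 0))
  expect_lt(abs(mean(cl$os_event == 0) - sim$cfg$censor_frac), 0.08)
  expect_lt(abs(cor(log(cl$tmb), bk$truth$S)), 0.15)  # TMB independent of S
  expect_true(all(bk$truth$hazard ==
                    sim$cfg$baseline_hazard *
                    exp(sim$cfg$hazard_coef * bk$truth$S)))
})

test_that("screens plant depleted genes with dataset-specific location and scale", {
  sim <- default_sim()
  scr <- sim$screens
  expect_length(scr$screens, sim$cfg$screen_n_datasets)
  res <- scr$truth$planted_resistant_genes
  d1 <- scr$screens[[1]]
  expect_lt(mean(d1$logfc[d1$gene %in% res]),
            mean(d1$logfc[!d1$gene %in% res]))
  # null effect: delta = 0 leaves planted genes centered
  cfg0 <- small_cfg(screen_effect = 0, seed = 13)
  scr0 <- generate_crispr_screens(cfg0)
  z0 <- aggregate_rank(zscore_screens(scr0$screens))
  planted_z <- z0$z[z0$gene %in% scr0$truth$planted_resistant_genes]
  expect_lt(abs(mean(planted_z)), 0.5)
})

test_that("datasets and truth records round-trip through disk formats", {
  cfg <- small_cfg(n_cells_per_dataset = 50, seed = 4)
  x <- generate_sc_datasets(cfg)[[1]]
  dir <- withr::local_tempdir()
  write_sc_dataset(x$dataset, dir)
  back <- read_sc_dataset(dir)
  expect_equal(unname(as.matrix(back$counts)),
               unname(as.matrix(x$dataset$counts)))
  expect_equal(back$cell_meta$cell_type, x$dataset$cell_meta$cell_type)
  tf <- file.path(dir, "truth.json")
  write_truth(x$truth, tf)
  tr <- read_truth(tf)
  expect_equal(tr$planted_fss_genes, x$truth$planted_fss_genes)
  expect_equal(tr$s, x$truth$s, tolerance = 1e-12)
  expect_equal(tr$marker_genes$tcell, x$truth$marker_genes$tcell)
})
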