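test_that("change_t is the treated-vs-baseline t with the documented sign", {
  expect_equal(change_t(c(10, 10, 12), c(10, 10, 12)), 0)
  base <- c(9.8, 10.4, 11.0)
  trt <- c(12.1, 13.0, 12.4)
  expect_equal(change_t(base, trt), t_from_raw(base, trt)$t)
  expect_gt(change_t(base, trt), 0)
  expect_equal(change_t(trt, base), -change_t(base, trt))
})

test_that("d_statistic matches hand and brute-force arithmetic", {
  d <- d_statistic(c(0, 0), c(2, 2), c(0, 0), c(1, 1))
  expect_equal(unlist(d), c(d_spfj = 1, d_wt = 2, d_obs = -1))
  d <- d_statistic(c(3, 3), c(3, 3), c(3), c(3, 3, 3))
  expect_equal(d$d_obs, 0)
  expect_error(d_statistic(numeric(0), 1, 1, 1),
               class = "otcpanel_validation_error")
  set.seed(77)
  for (i in 1:100) {
    g <- lapply(1:4, function(j) rnorm(sample(1:6, 1)))
    d <- d_statistic(g[[1]], g[[2]], g[[3]], g[[4]])
    expect_equal(d$d_obs,
                 (mean(g[[4]]) - mean(g[[3]])) - (mean(g[[2]]) - mean(g[[1]])))
  }
})

test_that("d_obs is shift-invariant and antisymmetric in genotype", {
  set.seed(8)
  g <- lapply(1:4, function(j) rnorm(5, 10))
  d <- d_statistic(g[[1]], g[[2]], g[[3]], g[[4]])$d_obs
  shifted <- d_statistic(g[[1]] + 7, g[[2]] + 7, g[[3]] + 7, g[[4]] + 7)$d_obs
  expect_equal(shifted, d)
  swapped <- d_statistic(g[[3]], g[[4]], g[[1]], g[[2]])$d_obs
  expect_equal(swapped, -d)
})

test_that("degenerate all-equal data give p = 1 inclusive, p = 0 strict", {
  x <- rep(4, 2)
  res <- permutation_test(x, x, x, x)
  expect_true(res$exact)
  expect_equal(res$d_obs, 0)
  expect_equal(res$p, 1)
  expect_equal(permutation_test(x, x, x, x, tail = "lower")$p, 1)
  # the literal strict-inequality reading is anti-conservative here
  expect_equal(permutation_test(x, x, x, x, ties = "strict")$p, 0)
})

test_that("singleton groups enumerate all 24 assignments and match the oracle", {
  res <- permutation_test(0, 0, 0, 3, tail = "lower")
  expect_true(res$exact)
  expect_equal(res$B, 24L)
  vals <- c(0, 0, 0, 3)
  for (tail in c("lower", "upper", "two.sided")) {
    mine <- permutation_test(0, 0, 0, 3, tail = tail)
    expect_equal(mine$p, oracle_perm_p(vals, rep(1, 4), mine$d_obs, tail))
  }
  # by hand: D is +3 for 12 of 24 assignments and -3 for the other 12
  expect_equal(permutation_test(0, 0, 0, 3, tail = "upper")$p, 0.5)
  expect_equal(permutation_test(0, 0, 0, 3, tail = "two.sided")$p, 1)
})

test_that("exact enumeration agrees with the full-orderings oracle", {
  set.seed(5150)
  vals <- rnorm(8, 50, 8)
  g <- split(vals, rep(1:4, each = 2))
  for (tail in c("lower", "upper", "two.sided")) {
    mine <- permutation_test(g[[1]], g[[2]], g[[3]], g[[4]], tail = tail)
    expect_true(mine$exact)
    expect_equal(mine$B, 2520L)
    expect_equal(mine$p,
                 oracle_perm_p(vals, rep(2, 4), mine$d_obs, tail))
  }
})

test_that("Monte-Carlo sampling converges to the exact null", {
  set.seed(99)
  g <- lapply(1:4, function(j) rnorm(2, 20, 4))
  exact <- permutation_test(g[[1]], g[[2]], g[[3]], g[[4]])
  mc <- permutation_test(g[[1]], g[[2]], g[[3]], g[[4]], B = 20000,
                         seed = 12, exact_threshold = 0)
  expect_false(mc$exact)
  se <- sqrt(exact$p * (1 - exact$p) / mc$B)
  expect_lt(abs(mc$p - exact$p), 3 * se + 1e-9)
})

test_that("fixed seeds make Monte-Carlo results reproducible", {
  g <- lapply(1:4, function(j) (1:5) * j)
  a <- permutation_test(g[[1]], g[[2]], g[[3]], g[[4]], B = 2000, seed = 3,
                        exact_threshold = 0)
  b <- permutation_test(g[[1]], g[[2]], g[[3]], g[[4]], B = 2000, seed = 3,
                        exact_threshold = 0)
  expect_identical(a, b)
})

test_that("heat maps carry per-genotype change t in canonical panel order", {
  set.seed(21)
  cohort <- null_cohort(tissue = "CEREBRUM", n = 5)
  hm <- build_heatmap(cohort, "cerebrum")
  expect_s3_class(hm, "heatmap_matrix")
  expect_equal(dim(hm), c(20L, 2L))
  expect_equal(rownames(hm), panel_analytes("CEREBRUM"))
  expect_equal(colnames(hm), c("WT", "SPFJ"))
  # no-effect cohort: t statistics hover around zero
  expect_lt(max(abs(hm)), 4)
  expect_lt(abs(mean(hm)), 1)
})

test_that("constructed opposite responses show up as opposite column signs", {
  tab <- panel_fixture("cerebrum")
  spec <- generator_spec(tab)
  k <- 2.5 * pmax(tab$wt_sd, tab$spfj_sd)
  effects <- tibble::tibble(analyte = tab$analyte, treatment_effect = k,
                            interaction = -2 * k)
  cohort <- suppressWarnings(
    generate_cohort(apply_effects(spec, effects), seed = 14))
  hm <- build_heatmap(cohort, "cerebrum")
  expect_true(all(hm[, "WT"] > 0))
  expect_true(all(hm[, "SPFJ"] < 0))
})

test_that("sparse cohorts give explicit NA cells and 1x2 single-analyte maps", {
  cohort <- cohort_from_cells(
    list(WT.BASELINE = c(10, 11, 12), WT.POLYIC = c(14, 15, 16),
         SPFJ.BASELINE = c(10, 11, 12), SPFJ.POLYIC = c(8, 9, 10)),
    analyte = "Glycine", tissue = "LIVER")
  hm <- build_heatmap(cohort, "liver")
  expect_equal(dim(hm), c(1L, 2L))
  expect_gt(hm["Glycine", "WT"], 0)
  expect_lt(hm["Glycine", "SPFJ"], 0)
  # drop the mutant treated cell: its entry must be NA, not absent
  part <- cohort[cohort$genotype != "SPFJ" | cohort$treatment != "POLYIC", ]
  hm2 <- build_heatmap(part, "liver")
  expect_true(is.na(hm2["Glycine", "SPFJ"]))
  expect_false(is.na(hm2["Glycine", "WT"]))
})

test_that("heat-map TSV export is lossless", {
  set.seed(31)
  hm <- build_heatmap(null_cohort(tissue = "LIVER", n = 3), "liver")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_heatmap(hm, f)
  back <- readr::read_tsv(f, show_col_types = FALSE, progress = FALSE)
  expect_equal(back$analyte, rownames(hm))
  expect_equal(back$WT, unname(hm[, "WT"]))
  expect_equal(back$SPFJ, unname(hm[, "SPFJ"]))
})

test_that("panel-wide permutation p-values are analyte-order independent", {
  set.seed(61)
  cohort <- null_cohort(tissue = "LIVER", n = 3,
                        analytes = c("Glycine", "Alanine", "Taurine"))
  a <- panel_permutation(cohort, "liver", B = 500, seed = 42,
                         exact_threshold = 0)
  shuffled <- cohort[sample(nrow(cohort)), ]
  b <- panel_permutation(shuffled, "liver", B = 500, seed = 42,
                         exact_threshold = 0)
  b <- b[match(a$analyte, b$analyte), ]
  expect_equal(a$p, b$p)
  # and fully reproducible under the master seed
  c <- panel_permutation(cohort, "liver", B = 500, seed = 42,
                         exact_threshold = 0)
  expect_equal(a, c)
})

test_that("a planted interaction is the panel's smallest permutation p", {
  tab <- panel_fixture("cerebrum")
  spec <- generator_spec(tab)
  glysd <- tab$spfj_sd[tab$analyte == "Glycine"]
  effects <- tibble::tibble(analyte = "Glycine", interaction = 8 * glysd)
  cohort <- generate_cohort(apply_effects(spec, effects), seed = 20)
  res <- panel_permutation(cohort, "cerebrum", B = 1000, seed = 7,
                           exact_threshold = 0)
  expect_equal(res$analyte[which.min(res$p)], "Glycine")
  expect_lt(res$p[res$analyte == "Glycine"], 0.05)
  # null cohort: about alpha * 20 rejections, i.e. almost always <= 4
  null <- generate_cohort(spec, seed = 23)
  res0 <- panel_permutation(null, "cerebrum", B = 1000, seed = 7,
                            exact_threshold = 0)
  expect_lte(sum(res0$p <= 0.05), 4)
})
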