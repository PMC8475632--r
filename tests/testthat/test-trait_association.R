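test_that("dataset QC enforces the strict >5 animals rule", {
  ds <- phenotype_dataset(sprintf("S%02d", 1:10), rnorm(10), rep(1, 10),
                          c(rep(8L, 9), 5L))
  qc <- qc_dataset(ds)
  expect_false(qc$accept)
  expect_true("min_animals" %in% qc$reasons)
})

test_that("a strong simulated dataset is accepted and pure noise rejected", {
  carriers <- sprintf("S%02d", 1:8)
  cfg <- sim_config(n_groups = 1, strains_per_group = 20, n_snps = 20,
                    fst = 0, target_eta2 = 0.8, replicates_per_strain = 10,
                    within_strain_sd = 0.05, seed = 3,
                    planted_block = list(start_index = 5, snp_count = 4,
                                         carriers = carriers))
  sim <- simulate_structured_panel(cfg)
  ph <- simulate_phenotype(sim$truth, cfg)
  expect_true(qc_dataset(ph)$accept)

  ## replicate-free single-strain dataset is an error
  expect_error(qc_dataset(phenotype_dataset("A", 1, 0, 8)), "single strain")

  rejections <- vapply(1:100, function(s) {
    cfg0 <- sim_config(n_groups = 1, strains_per_group = 12, n_snps = 20,
                       fst = 0, target_eta2 = 0, replicates_per_strain = 8,
                       within_strain_sd = 1, strain_sd = 1e-4, seed = s)
    sim0 <- simulate_structured_panel(cfg0)
    ph0 <- simulate_phenotype(sim0$truth, cfg0)
    !qc_dataset(ph0)$accept
  }, logical(1))
  expect_gte(mean(rejections), 0.99)
})

test_that("perfect haplotype/phenotype separation gives p = 0 with unbounded F", {
  groups <- stats::setNames(c(rep(1L, 8), rep(2L, 21)), sprintf("S%02d", 1:29))
  retina <- phenotype_dataset(names(groups), c(rep(1, 8), rep(0, 21)),
                              rep(0, 29), rep(8L, 29), categorical = TRUE)
  res <- block_anova(groups, retina)
  expect_identical(res$p_hbcgm, 0)
  expect_true(res$F_unbounded)
  expect_identical(res$eta2, 1)
  expect_identical(res$k, 2L)
  expect_identical(res$n, 29L)
})

test_that("constant phenotype gives F = 0, p = 1 and degenerate grouping errors", {
  groups <- stats::setNames(rep(1:2, each = 5), sprintf("S%02d", 1:10))
  ds <- phenotype_dataset(names(groups), rep(3.7, 10), rep(0.1, 10), rep(8L, 10))
  res <- block_anova(groups, ds)
  expect_identical(res$F_statistic, 0)
  expect_identical(res$p_hbcgm, 1)
  expect_error(effect_size(res), "undefined")

  one_group <- stats::setNames(rep(1L, 10), names(groups))
  expect_error(block_anova(one_group, ds), "degenerate grouping")
})

test_that("block ANOVA matches stats::anova on plain and random groupings", {
  ## hand case: groups {1,2,3} and {4,5,6}
  groups <- stats::setNames(rep(1:2, each = 3), sprintf("S%02d", 1:6))
  ds <- phenotype_dataset(names(groups), c(1, 2, 3, 4, 5, 6), rep(0.5, 6),
                          rep(8L, 6))
  res <- block_anova(groups, ds)
  ref <- stats::anova(stats::lm(c(1, 2, 3, 4, 5, 6) ~ factor(rep(1:2, each = 3))))
  expect_equal(res$F_statistic, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p_hbcgm, ref$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(res$eta2, ref$`Sum Sq`[1] / sum(ref$`Sum Sq`), tolerance = 1e-12)

  for (seed in 1:5) {
    set.seed(seed)
    n <- 18
    y <- rnorm(n)
    g <- sample(1:3, n, replace = TRUE)
    g[1:3] <- 1:3
    ds <- phenotype_dataset(sprintf("S%02d", 1:n), y, rep(0.5, n), rep(8L, n))
    res <- block_anova(stats::setNames(g, ds$data$strain), ds)
    ref <- stats::anova(stats::lm(y ~ factor(g)))
    expect_equal(res$F_statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p_hbcgm, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("unassigned strains and unmeasured strains are excluded from the ANOVA", {
  groups <- stats::setNames(c(1L, 1L, NA, 2L, 2L, 2L), sprintf("S%02d", 1:6))
  ds <- phenotype_dataset(sprintf("S%02d", 1:5), c(1, 1.2, 9, 3, 3.1),
                          rep(0.2, 5), rep(8L, 5))
  res <- block_anova(groups, ds)   # S03 unassigned, S06 unmeasured
  expect_identical(res$n, 4L)
  ref <- stats::anova(stats::lm(c(1, 1.2, 3, 3.1) ~ factor(c(1, 1, 2, 2))))
  expect_equal(res$F_statistic, ref$`F value`[1], tolerance = 1e-10)
})

test_that("null permutation p-values of the block ANOVA are uniform", {
  set.seed(8)
  n <- 20
  groups <- stats::setNames(sample(rep(1:3, c(7, 7, 6))), sprintf("S%02d", 1:n))
  p <- vapply(1:2000, function(i) {
    y <- rnorm(n)
    ds <- phenotype_dataset(names(groups), y, rep(0.5, n), rep(8L, n))
    block_anova(groups, ds)$p_hbcgm
  }, numeric(1))
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("power obeys the null identity and the stated noncentrality", {
  for (alpha in c(0.01, 0.05, 0.1)) {
    for (n in c(10, 20, 40)) {
      for (k in c(2, 3, 5)) {
        expect_equal(anova_power(alpha, 0, n, k), alpha, tolerance = 1e-12)
      }
    }
  }
  ## lambda = n eta2 / (1 - eta2): at eta2 = 0.5, n = 20, k = 2 the power
  ## must equal the upper tail of F(1, 18, ncp = 20) beyond the central
  ## critical value, computed here from the definition
  lam <- 20 * 0.5 / (1 - 0.5)
  expect_equal(anova_power(0.05, 0.5, 20, 2),
               stats::pf(stats::qf(0.95, 1, 18), 1, 18, ncp = lam,
                         lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(anova_power(0.05, 0.3, n = 3, k = 3), "exceed")
})

test_that("power is nondecreasing in n, eta2 and alpha", {
  grid_n <- vapply(c(10, 15, 20, 30, 50), function(n)
    anova_power(0.05, 0.3, n, 2), numeric(1))
  grid_e <- vapply(c(0, 0.1, 0.3, 0.5, 0.7), function(e)
    anova_power(0.05, e, 20, 2), numeric(1))
  grid_a <- vapply(c(0.01, 0.05, 0.1, 0.2), function(a)
    anova_power(a, 0.3, 20, 2), numeric(1))
  expect_true(all(diff(grid_n) >= 0))
  expect_true(all(diff(grid_e) >= 0))
  expect_true(all(diff(grid_a) >= 0))
})

test_that("correlated-block selection is strict at the cutoff and best-per-gene", {
  mk <- function(p) structure(list(p_hbcgm = p, F_statistic = 1,
                                   F_unbounded = FALSE, eta2 = 0.1,
                                   ssb = 1, sst = 10, k = 2L, n = 10L,
                                   block = NULL), class = "block_association")
  res <- lapply(c(0.005, 0.01, 0.02), mk)
  kept <- select_correlated(res, cutoff = 0.01)
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$p_hbcgm, 0.005)
  expect_length(select_correlated(list(), 0.01), 0L)

  res2 <- lapply(c(0.003, 0.001, 0.002), mk)
  kept2 <- select_correlated(res2, cutoff = 0.01,
                             genes = c("Apoa2", "Apoa2", NA))
  expect_identical(sort(vapply(kept2, function(r) r$p_hbcgm, numeric(1))),
                   c(0.001, 0.002))
})
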