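test_that("simulated calls are complete and homozygously coded", {
  cfg <- sim_config(n_groups = 3, strains_per_group = c(5, 5, 5),
                    n_snps = 500, fst = 0.2, seed = 2)
  g <- simulate_structured_panel(cfg)$genotypes
  expect_true(all(g$calls %in% c(0L, 1L)))
  expect_identical(sum(is.na(g$calls)), 0L)
})

test_that("identical seeds reproduce the panel bit-for-bit; different seeds differ", {
  cfg <- sim_config(n_groups = 2, strains_per_group = c(8, 8), n_snps = 400,
                    fst = 0.3, seed = 9)
  g1 <- simulate_structured_panel(cfg)$genotypes
  g2 <- simulate_structured_panel(cfg)$genotypes
  expect_identical(g1$calls, g2$calls)
  cfg2 <- sim_config(n_groups = 2, strains_per_group = c(8, 8), n_snps = 400,
                     fst = 0.3, seed = 10)
  g3 <- simulate_structured_panel(cfg2)$genotypes
  expect_false(identical(g1$calls, g3$calls))
})

test_that("at fst = 0 between-group frequency differences reflect sampling alone", {
  ## |p1_hat - p2_hat| for groups of size n has mean sqrt(2 Var / pi) under
  ## normal approximation with Var = p(1-p) (1/n1 + 1/n2).
  cfg <- sim_config(n_groups = 2, strains_per_group = c(10, 10),
                    n_snps = 5000, fst = 0, seed = 4)
  sim <- simulate_structured_panel(cfg)
  g <- sim$genotypes
  grp <- sim$truth$group[g$strains]
  p1 <- colMeans(g$calls[grp == 1, ])
  p2 <- colMeans(g$calls[grp == 2, ])
  obs <- mean(abs(p1 - p2))
  p <- (p1 + p2) / 2
  v <- pmax(p * (1 - p), 1e-12) * (1 / 10 + 1 / 10)
  theo <- mean(sqrt(2 * v / pi))
  se <- stats::sd(abs(p1 - p2)) / sqrt(length(p1))
  expect_lt(abs(obs - theo), 3 * se)
})

test_that("fst outside [0,1) and degenerate configs are rejected", {
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(fst = -0.1), "fst")
  expect_error(sim_config(n_groups = 1, strains_per_group = 1), "2 strains")
  expect_error(sim_config(planted_block = list(snp_count = 3)), "snp_count")
})

test_that("a planted block creates exactly two haplotype strings and is found", {
  carriers <- sprintf("S%02d", sample(1:29, 8))
  cfg <- sim_config(n_groups = 1, strains_per_group = 29, n_snps = 60,
                    fst = 0, seed = 12,
                    planted_block = list(start_index = 30, snp_count = 4,
                                         carriers = carriers))
  sim <- simulate_structured_panel(cfg)
  idx <- 30:33
  strings <- apply(sim$genotypes$calls[, idx], 1, paste, collapse = "")
  expect_identical(length(unique(strings)), 2L)
  is_carrier <- sim$genotypes$strains %in% carriers
  expect_identical(length(unique(strings[is_carrier])), 1L)
  expect_identical(length(unique(strings[!is_carrier])), 1L)

  ## block construction emits a block covering the interval whose partition
  ## is exactly {carriers, non-carriers}
  blocks <- build_blocks(filter_variants(sim$genotypes, sim$genotypes$strains))
  covering <- Filter(function(b) b$snp_index_range[1] <= 30 &&
                       b$snp_index_range[2] >= 33, blocks)
  expect_gt(length(covering), 0)
  found <- any(vapply(covering, function(b) {
    lab <- b$strain_groups
    length(unique(lab[is_carrier])) == 1 &&
      length(unique(lab[!is_carrier])) == 1 &&
      lab[which(is_carrier)[1]] != lab[which(!is_carrier)[1]]
  }, logical(1)))
  expect_true(found)
})

test_that("planting requires a proper nonempty carrier subset", {
  cfg <- sim_config(n_groups = 1, strains_per_group = 10, n_snps = 20,
                    fst = 0, seed = 1)
  sim <- simulate_structured_panel(cfg)
  expect_error(plant_causal_block(sim$genotypes, sim$truth,
                                  carriers = character(), snp_count = 4),
               "nonempty")
  expect_error(plant_causal_block(sim$genotypes, sim$truth,
                                  carriers = sim$genotypes$strains,
                                  snp_count = 4),
               "proper subset")
  ## all-but-one carrier is a valid boundary: 2 haplotypes, singleton group
  res <- plant_causal_block(sim$genotypes, sim$truth,
                            carriers = sim$genotypes$strains[-1],
                            snp_count = 4, start_index = 5)
  strings <- apply(res$genotypes$calls[, 5:8], 1, paste, collapse = "")
  expect_identical(length(unique(strings)), 2L)
  expect_identical(sum(strings == strings[1]), 1L)
})

test_that("zero within-strain noise makes replicates equal their strain mean", {
  carriers <- sprintf("S%02d", 1:5)
  cfg <- sim_config(n_groups = 1, strains_per_group = 15, n_snps = 20,
                    fst = 0, target_eta2 = 0.5, replicates_per_strain = 6,
                    within_strain_sd = 0, seed = 21,
                    planted_block = list(start_index = 5, snp_count = 4,
                                         carriers = carriers))
  sim <- simulate_structured_panel(cfg)
  ph <- simulate_phenotype(sim$truth, cfg)
  for (s in ph$data$strain) {
    expect_true(all(ph$replicates[[s]] == ph$data$mean[ph$data$strain == s]))
  }
  expect_true(all(ph$data$sd == 0))
})

test_that("null phenotypes realize the null eta2 expectation (k-1)/(n-1)", {
  eta <- vapply(1:200, function(s) {
    cfg <- sim_config(n_groups = 1, strains_per_group = 30, n_snps = 20,
                      fst = 0, target_eta2 = 0, seed = s)
    sim <- simulate_structured_panel(cfg)
    ph <- simulate_phenotype(sim$truth, cfg)
    grp <- stats::setNames(rep(1:2, each = 15), ph$data$strain)
    block_anova(grp, ph)$eta2
  }, numeric(1))
  expect_lt(abs(mean(eta) - 1 / 29), 0.03)
})

test_that("stronger divergence increases the leading GRM eigenvalue share", {
  lead_share <- function(fst) {
    mean(vapply(1:5, function(s) {
      cfg <- sim_config(n_groups = 2, strains_per_group = c(10, 10),
                        n_snps = 800, fst = fst, seed = s)
      g <- simulate_structured_panel(cfg)$genotypes
      ev <- pca_coordinates(compute_grm(g), p = 2)$eigenvalues
      ev[1] / sum(pmax(ev, 0))
    }, numeric(1)))
  }
  shares <- vapply(c(0, 0.1, 0.3), lead_share, numeric(1))
  expect_true(all(diff(shares) > 0))
})
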