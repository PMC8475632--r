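test_that("GRM matches the per-entry standardization formula on a toy panel", {
  calls <- rbind(A = c(0L, 1L, 0L, 1L, 0L, 1L),
                 B = c(0L, 1L, 1L, 0L, 0L, 0L),
                 C = c(1L, 0L, 1L, 1L, 0L, 1L),
                 D = c(1L, 0L, 0L, 0L, 1L, 1L))
  g <- genotype_matrix(calls, chrom = rep("chr1", 6), pos = (1:6) * 10)
  grm <- compute_grm(g)
  p <- colMeans(calls)
  z <- sweep(sweep(calls, 2, p), 2, sqrt(p * (1 - p)), "/")
  ref <- tcrossprod(z) / ncol(calls)
  expect_equal(grm$values, ref, tolerance = 1e-12)
  expect_equal(grm$values, t(grm$values))

  ## identical strains have identical GRM rows
  calls2 <- rbind(calls, E = calls["A", ])
  g2 <- genotype_matrix(calls2, chrom = g$chrom, pos = g$pos)
  grm2 <- compute_grm(g2)
  expect_equal(grm2$values["A", ], grm2$values["E", ], tolerance = 1e-12)

  mono <- genotype_matrix(matrix(1L, 3, 4, dimnames = list(c("A", "B", "C"), NULL)),
                          chrom = rep("chr1", 4), pos = (1:4) * 10)
  expect_error(compute_grm(mono), "monomorphic")
})

test_that("GRM skips monomorphic sites and averages over co-observed pairs", {
  calls <- rbind(A = c(0L, 1L, 1L), B = c(0L, 0L, NA), C = c(1L, 1L, 0L),
                 D = c(1L, 0L, 1L))
  g <- genotype_matrix(calls, chrom = rep("chr1", 3), pos = (1:3) * 10)
  grm <- compute_grm(g)$values
  ## pair (A,B) co-observes sites 1 and 2 only
  p <- c(1 / 2, 1 / 2, 2 / 3)
  zf <- function(x, s) (x - p[s]) / sqrt(p[s] * (1 - p[s]))
  expect_equal(grm["A", "B"],
               (zf(0, 1) * zf(0, 1) + zf(1, 2) * zf(0, 2)) / 2,
               tolerance = 1e-12)
})

test_that("IBS matches hand-counted match fractions with unit diagonal", {
  calls <- rbind(A = c(0L, 1L, 1L, 0L), B = c(0L, 1L, 0L, 1L),
                 C = c(1L, 0L, 0L, 1L))
  g <- genotype_matrix(calls, chrom = rep("chr1", 4), pos = (1:4) * 10)
  ibs <- compute_ibs(g)$values
  expect_equal(unname(diag(ibs)), rep(1, 3))
  expect_equal(ibs["A", "B"], 2 / 4)
  expect_equal(ibs["A", "C"], 0)      # complementary strains
  expect_equal(ibs["B", "C"], 2 / 4)
  expect_true(all(ibs >= 0 & ibs <= 1))
})

test_that("uncentered PCA at p = n reconstructs the relationship matrix", {
  g <- random_panel(8, 200, seed = 17)
  grm <- compute_grm(g)
  coords <- pca_coordinates(grm, p = 8, center = FALSE)
  expect_equal(coords$scores %*% t(coords$scores), grm$values,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(coords$variance_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(coords$eigenvalues) <= 1e-12))
})

test_that("GRM, IBS and PCA are equivariant under strain reordering", {
  g <- random_panel(9, 150, seed = 23)
  perm <- sample(g$strains)
  gp <- genotype_matrix(g$calls[perm, ], chrom = g$chrom, pos = g$pos,
                        strains = perm)
  grm1 <- compute_grm(g)$values
  grm2 <- compute_grm(gp)$values
  expect_equal(grm2[g$strains, g$strains], grm1, tolerance = 1e-12)
  ibs1 <- compute_ibs(g)$values
  ibs2 <- compute_ibs(gp)$values
  expect_equal(ibs2[g$strains, g$strains], ibs1, tolerance = 1e-12)
})

test_that("PC1 separates two diverged sub-populations", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_groups = 2, strains_per_group = c(10, 10),
                      n_snps = 1000, fst = 0.3, seed = s)
    sim <- simulate_structured_panel(cfg)
    coords <- pca_coordinates(compute_grm(sim$genotypes), p = 4)
    grp <- sim$truth$group[rownames(coords$scores)]
    pc1 <- coords$scores[, 1]
    gap <- abs(mean(pc1[grp == 1]) - mean(pc1[grp == 2]))
    pooled <- sqrt((stats::var(pc1[grp == 1]) + stats::var(pc1[grp == 2])) / 2)
    gap > 4 * pooled
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("equal eigenvalues give no Tracy-Widom excess", {
  res <- tw_test(rep(1, 20), n_test = 1)
  expect_gt(res$p_value[1], 0.05)
  expect_error(tw_test(c(1, 0.5)), "3 positive eigenvalues")
})

test_that("hierarchical IBS clustering recovers trivial and planted structure", {
  g <- random_panel(6, 100, seed = 5)
  ibs <- compute_ibs(g)
  all_one <- hierarchical_subpopulations(ibs, k = 1)
  expect_identical(unname(all_one$labels), rep(1L, 6))
  expect_error(hierarchical_subpopulations(ibs, k = 7), "1..n")
  expect_error(hierarchical_subpopulations(compute_grm(g), k = 2), "IBS")

  ## identical strains co-cluster for every k < n
  calls <- g$calls
  calls["S02", ] <- calls["S01", ]
  g2 <- genotype_matrix(calls, chrom = g$chrom, pos = g$pos)
  ibs2 <- compute_ibs(g2)
  for (k in 2:5) {
    cl <- hierarchical_subpopulations(ibs2, k = k)
    expect_identical(cl$labels[["S01"]], cl$labels[["S02"]])
  }
})

test_that("supervised ANOVA on PCs separates true groups and is null on noise", {
  cfg <- sim_config(n_groups = 2, strains_per_group = c(10, 10),
                    n_snps = 1000, fst = 0.3, seed = 31)
  sim <- simulate_structured_panel(cfg)
  coords <- pca_coordinates(compute_grm(sim$genotypes), p = 4)
  res <- anova_on_pcs(coords, sim$truth$group)
  expect_lt(res$p_value[1], 0.001)

  ## degenerate: a single label errors; constant scores give p = 1
  expect_error(anova_on_pcs(coords, stats::setNames(rep(1L, 20),
                                                    rownames(coords$scores))),
               "2 sub-populations")
  flat <- as_coords(matrix(0, 10, 1))
  res0 <- anova_on_pcs(flat, stats::setNames(rep(1:2, 5), rownames(flat$scores)))
  expect_identical(res0$p_value, 1)
})

test_that("LD pruning removes duplicated columns and leaves no violating pair", {
  calls <- matrix(stats::rbinom(10 * 6, 1, 0.5), 10, 6,
                  dimnames = list(sprintf("S%02d", 1:10), NULL))
  calls[, 4] <- calls[, 2]            # identical pair 200 bp apart
  g <- genotype_matrix(calls, chrom = rep("chr1", 6),
                       pos = c(100, 200, 300, 400, 5000, 20000))
  pruned <- ld_prune(g, window_bp = 10000, r2_threshold = 0.99)
  expect_false(400L %in% pruned$pos)
  expect_true(200L %in% pruned$pos)

  ## exhaustive post-check on random fixtures
  for (seed in 1:5) {
    set.seed(seed)
    m <- 40
    calls <- matrix(stats::rbinom(12 * m, 1, 0.5), 12, m,
                    dimnames = list(sprintf("S%02d", 1:12), NULL))
    g <- genotype_matrix(calls, chrom = rep("chr1", m),
                         pos = sort(sample(1:20000, m)))
    for (preset in ld_presets()[c("10kb_r2_0.5", "50kb_r2_0.75")]) {
      pruned <- ld_prune(g, preset$window_bp, preset$r2_threshold)
      pos <- pruned$pos
      viol <- 0L
      starts <- seq(min(pos), max(pos), by = preset$window_bp %/% 2)
      for (w0 in starts) {
        w <- which(pos >= w0 & pos < w0 + preset$window_bp)
        if (length(w) < 2) next
        for (a in 1:(length(w) - 1)) {
          for (b in (a + 1):length(w)) {
            r <- suppressWarnings(stats::cor(pruned$calls[, w[a]],
                                             pruned$calls[, w[b]]))
            if (!is.na(r) && r^2 >= preset$r2_threshold) viol <- viol + 1L
          }
        }
      }
      expect_identical(viol, 0L)
    }
  }
})

test_that("clustering is unchanged by LD pruning under strong structure", {
  cfg <- sim_config(n_groups = 4, strains_per_group = c(8, 8, 8, 8),
                    n_snps = 1500, fst = 0.3, seed = 13)
  sim <- simulate_structured_panel(cfg)
  full <- hierarchical_subpopulations(compute_ibs(sim$genotypes), k = 4)
  pruned_g <- ld_prune(sim$genotypes, 10000, 0.5)
  expect_lt(n_variants(pruned_g), n_variants(sim$genotypes))
  pruned <- hierarchical_subpopulations(compute_ibs(pruned_g), k = 4)
  expect_identical(unname(full$labels), unname(pruned$labels))
})
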