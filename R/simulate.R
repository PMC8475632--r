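#' Configuration for simulated inbred-strain panels
#'
#' Collects the free parameters of the panel generator. The defaults describe
#' a panel modelled on the composition of the commonly sequenced laboratory
#' strains: 49 strains in four diverged sub-populations of sizes 7, 14, 23
#' and 5, with sub-population allele-frequency divergence `fst = 0.3`
#' (Balding-Nichols Beta model), a large planted genetic effect
#' (`target_eta2 = 0.6`, typical of inbred-strain mapping where effect sizes
#' usually exceed 0.3), and 8 animals measured per strain.
#'
#' @param n_groups number of sub-populations (1-4).
#' @param strains_per_group integer vector of length `n_groups`.
#' @param n_snps number of simulated SNP sites.
#' @param fst divergence parameter in `[0, 1)`: the variance of each group's
#'   allele frequency around the ancestral frequency `p` is `fst * p * (1-p)`.
#' @param ancestral_maf_range interval within `(0, 0.5]` from which ancestral
#'   allele frequencies are drawn uniformly.
#' @param planted_block optional list with elements `chrom`, `start_index`,
#'   `snp_count` (>= 4), `carriers` (strain names); `NULL` plants nothing at
#'   panel generation time (see [plant_causal_block()]).
#' @param target_eta2 genetic effect size eta-squared in `[0, 1)` planted into
#'   the phenotype (between-haplotype-group share of the strain-mean variance).
#' @param replicates_per_strain animals measured per strain, `>= 1`.
#' @param within_strain_sd SD of replicate values around their strain mean.
#' @param strain_sd SD of strain means around their haplotype-group mean
#'   (the residual between-strain variation).
#' @param seed integer RNG seed; every simulation is deterministic given it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_groups = 4,
                       strains_per_group = c(7, 14, 23, 5),
                       n_snps = 5000,
                       fst = 0.3,
                       ancestral_maf_range = c(0.1, 0.5),
                       planted_block = NULL,
                       target_eta2 = 0.6,
                       replicates_per_strain = 8,
                       within_strain_sd = 0.5,
                       strain_sd = 1,
                       seed = 1L) {
  n_groups <- as.integer(n_groups)
  strains_per_group <- as.integer(strains_per_group)
  if (n_groups < 1L || n_groups > 4L) stop("n_groups must be in 1..4")
  if (length(strains_per_group) != n_groups) {
    stop("strains_per_group must have length n_groups")
  }
  if (sum(strains_per_group) < 2L) stop("at least 2 strains are required")
  if (!is.numeric(fst) || fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (length(ancestral_maf_range) != 2 || ancestral_maf_range[1] <= 0 ||
      ancestral_maf_range[2] > 0.5 ||
      ancestral_maf_range[1] > ancestral_maf_range[2]) {
    stop("ancestral_maf_range must be an interval within (0, 0.5]")
  }
  if (target_eta2 < 0 || target_eta2 >= 1) stop("target_eta2 must lie in [0, 1)")
  if (replicates_per_strain < 1) stop("replicates_per_strain must be >= 1")
  if (within_strain_sd < 0) stop("within_strain_sd must be >= 0")
  if (strain_sd <= 0) stop("strain_sd must be > 0")
  if (!is.null(planted_block)) {
    if (is.null(planted_block$snp_count) || planted_block$snp_count < 4) {
      stop("planted_block$snp_count must be >= 4")
    }
  }
  structure(list(n_groups = n_groups, strains_per_group = strains_per_group,
                 n_snps = as.integer(n_snps), fst = fst,
                 ancestral_maf_range = ancestral_maf_range,
                 planted_block = planted_block, target_eta2 = target_eta2,
                 replicates_per_strain = as.integer(replicates_per_strain),
                 within_strain_sd = within_strain_sd, strain_sd = strain_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a structured panel of fully homozygous strains
#'
#' Balding-Nichols style generative model. For each site an ancestral
#' frequency `p` is drawn uniformly from `ancestral_maf_range`; each
#' sub-population's frequency is drawn from a Beta distribution with mean `p`
#' and variance `fst * p * (1-p)` (at `fst = 0` the ancestral frequency is
#' used directly); each strain's single allele is a Bernoulli draw from its
#' group frequency, so every call is 0/1 and none missing. Sites are placed
#' on one chromosome at 1 kb spacing. If `config$planted_block` is set, the
#' causative block is planted before returning.
#'
#' @param config a [sim_config()].
#' @return list with elements `genotypes` (a [genotype_matrix()]) and `truth`
#'   (class `sim_truth`: `group` per-strain labels, `planted` block interval
#'   and carrier set or `NULL`, `group_freq_seed` bookkeeping).
#' @export
simulate_structured_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- sum(config$strains_per_group)
  M <- config$n_snps
  group <- rep(seq_len(config$n_groups), config$strains_per_group)
  strains <- sprintf("S%02d", seq_len(n))
  p0 <- stats::runif(M, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  freq <- matrix(NA_real_, nrow = config$n_groups, ncol = M)
  if (config$fst == 0) {
    freq[] <- rep(p0, each = config$n_groups)
  } else {
    k <- (1 - config$fst) / config$fst
    for (gidx in seq_len(config$n_groups)) {
      freq[gidx, ] <- stats::rbeta(M, shape1 = p0 * k, shape2 = (1 - p0) * k)
    }
  }
  calls <- matrix(0L, nrow = n, ncol = M)
  for (i in seq_len(n)) {
    calls[i, ] <- stats::rbinom(M, 1L, freq[group[i], ])
  }
  g <- genotype_matrix(calls, chrom = rep("chr1", M),
                       pos = seq_len(M) * 1000L, strains = strains)
  truth <- structure(list(group = stats::setNames(group, strains),
                          planted = NULL, group_effects = NULL),
                     class = "sim_truth")
  if (!is.null(config$planted_block)) {
    pb <- config$planted_block
    carriers <- pb$carriers
    if (is.null(carriers)) stop("planted_block$carriers must name the carrier strains")
    res <- plant_causal_block(g, truth, carriers = carriers,
                              snp_count = pb$snp_count,
                              start_index = pb$start_index)
    g <- res$genotypes; truth <- res$truth
  }
  list(genotypes = g, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d strains in %d groups%s\n", length(x$group),
              length(unique(x$group)),
              if (is.null(x$planted)) "" else
                sprintf("; planted block of %d SNPs, %d carriers",
                        x$planted$snp_count, length(x$planted$carriers))))
  invisible(x)
}

#' Plant a causative haplotype block into a simulated panel
#'
#' Overwrites `snp_count` consecutive sites so that carrier strains share one
#' allele string (all alternate) and non-carriers another (all reference),
#' emulating a two-allele causative block such as a nonsense variant shared
#' by all affected strains.
#'
#' @param genotypes a [genotype_matrix()].
#' @param truth the matching `sim_truth`.
#' @param carriers character vector of carrier strain names; must be a proper
#'   nonempty subset of the panel.
#' @param snp_count number of consecutive sites to overwrite, `>= 4`.
#' @param start_index first overwritten variant column; defaults to the
#'   middle of the panel.
#' @return list `(genotypes, truth)` with the planted interval recorded in
#'   `truth$planted`.
#' @export
plant_causal_block <- function(genotypes, truth, carriers, snp_count = 4L,
                               start_index = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  snp_count <- as.integer(snp_count)
  if (snp_count < 4L) stop("snp_count must be >= 4")
  carriers <- as.character(carriers)
  if (!length(carriers)) stop("carriers must be nonempty")
  if (!all(carriers %in% genotypes$strains)) {
    stop("unknown carrier strains: ",
         paste(setdiff(carriers, genotypes$strains), collapse = ", "))
  }
  if (length(carriers) >= n_strains(genotypes)) {
    stop("carriers must be a proper subset of the panel")
  }
  M <- n_variants(genotypes)
  if (is.null(start_index)) start_index <- max(1L, (M - snp_count) %/% 2L)
  start_index <- as.integer(start_index)
  if (start_index < 1L || start_index + snp_count - 1L > M) {
    stop("planted interval exceeds the variant range")
  }
  idx <- start_index:(start_index + snp_count - 1L)
  if (length(unique(genotypes$chrom[idx])) > 1L) {
    stop("planted interval must lie on a single chromosome")
  }
  is_carrier <- genotypes$strains %in% carriers
  genotypes$calls[, idx] <- 0L
  genotypes$calls[is_carrier, idx] <- 1L
  truth$planted <- list(chrom = genotypes$chrom[start_index],
                        start_index = start_index,
                        snp_count = snp_count,
                        start_bp = genotypes$pos[start_index],
                        end_bp = genotypes$pos[idx[length(idx)]],
                        carriers = carriers)
  list(genotypes = genotypes, truth = truth)
}

#' Simulate an MPD-style phenotype with a controlled genetic effect size
#'
#' Strain means are drawn as `mu_i = delta * carrier_i + N(0, strain_sd^2)`.
#' The carrier offset `delta` is calibrated from the one-way ANOVA moment
#' identity so that the expected realized eta-squared across the reported
#' strain means equals `target_eta2`: with `k = 2` groups of sizes `n1`, `n0`
#' and effective per-strain variance
#' `s2 = strain_sd^2 + within_strain_sd^2 / replicates_per_strain`
#' (reported means carry replicate-mean noise),
#' `delta^2 * n1 * n0 / n = s2 * (target_eta2 * (n-1) - (k-1)) / (1 - target_eta2)`.
#' At `target_eta2 = 0` the dataset is pure noise and the expected realized
#' eta-squared is the null value `(k-1)/(n-1)`.
#'
#' @param truth a `sim_truth`; a planted block must exist when
#'   `config$target_eta2 > 0`.
#' @param config a [sim_config()]; the phenotype stream is seeded with
#'   `config$seed + 1` so genotypes and phenotypes are independent.
#' @param dataset_id identifier for the resulting dataset.
#' @return A [phenotype_dataset()] with replicate-level values attached.
#' @export
simulate_phenotype <- function(truth, config, dataset_id = "simulated") {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (config$target_eta2 > 0 && is.null(truth$planted)) {
    stop("a planted block is required when target_eta2 > 0")
  }
  set.seed(config$seed + 1L)
  strains <- names(truth$group)
  n <- length(strains)
  carrier <- if (is.null(truth$planted)) rep(FALSE, n) else
    strains %in% truth$planted$carriers
  delta <- 0
  if (config$target_eta2 > 0) {
    n1 <- sum(carrier); n0 <- n - n1
    s2 <- config$strain_sd^2 +
      config$within_strain_sd^2 / config$replicates_per_strain
    a <- s2 * (config$target_eta2 * (n - 1) - 1) / (1 - config$target_eta2)
    if (a <= 0) {
      stop("target_eta2 below the null expectation (k-1)/(n-1) for this panel")
    }
    delta <- sqrt(a * n / (n1 * n0))
  }
  mu <- delta * carrier + stats::rnorm(n, 0, config$strain_sd)
  r <- config$replicates_per_strain
  reps <- lapply(seq_len(n), function(i) {
    mu[i] + stats::rnorm(r, 0, config$within_strain_sd)
  })
  names(reps) <- strains
  means <- vapply(reps, mean, numeric(1))
  sds <- if (r > 1) vapply(reps, stats::sd, numeric(1)) else rep(0, n)
  truth$group_effects <- c(carrier = delta, noncarrier = 0)
  phenotype_dataset(strains, means, sds, rep(r, n), replicates = reps,
                    dataset_id = dataset_id)
}
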