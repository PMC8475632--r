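## One-way ANOVA from a response vector and a grouping factor, computed from
## explicit sums of squares so that eta^2 = SSB/SST and the perfect-separation
## case (SSW = 0 with unequal group means) can be reported as p = 0 with an
## unbounded F, as required for exact haplotype/phenotype matches.
.oneway_ss <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  n <- length(y)
  grand <- mean(y)
  gm <- tapply(y, g, mean)
  ng <- tabulate(g)
  ssb <- sum(ng * (gm - grand)^2)
  sst <- sum((y - grand)^2)
  ssw <- sst - ssb
  list(ssb = ssb, ssw = max(ssw, 0), sst = sst, k = k, n = n)
}

#' Quality-control filter for a phenotype dataset
#'
#' A dataset is accepted for mapping when (i) every strain's summary was
#' measured in more than `min_animals` animals, (ii) a one-way ANOVA of
#' inter- versus intra-strain variation (from replicates when available,
#' otherwise reconstructed from the per-strain mean/SD/n summaries) gives
#' `p < p_cutoff`, i.e. the strain signal dominates measurement noise, and
#' (iii), when `bulk = TRUE`, the dataset is not categorical.
#'
#' @param dataset a [phenotype_dataset()].
#' @param min_animals strict lower bound on animals per strain (default 5:
#'   a strain measured in exactly 5 animals fails).
#' @param p_cutoff inter/intra-strain ANOVA p-value cutoff (default `1e-10`).
#' @param bulk logical; reject categorical datasets (default TRUE).
#' @return list with `accept` (logical), `reasons` (character codes among
#'   `"min_animals"`, `"anova_ns"`, `"categorical"`), and `p_anova`.
#' @export
qc_dataset <- function(dataset, min_animals = 5L, p_cutoff = 1e-10,
                       bulk = TRUE) {
  stopifnot(inherits(dataset, "phenotype_dataset"))
  d <- dataset$data
  if (nrow(d) < 2L) stop("ANOVA undefined for a single strain")
  reasons <- character()
  if (any(d$nindiv <= min_animals)) reasons <- c(reasons, "min_animals")
  if (bulk && dataset$categorical) reasons <- c(reasons, "categorical")
  ## strain-level ANOVA sums of squares from summaries:
  ## SSW = sum (n_i - 1) s_i^2 ; SSB = sum n_i (m_i - grand)^2
  N <- sum(d$nindiv)
  grand <- sum(d$nindiv * d$mean) / N
  ssb <- sum(d$nindiv * (d$mean - grand)^2)
  ssw <- sum((d$nindiv - 1) * d$sd^2)
  k <- nrow(d)
  df2 <- N - k
  p_anova <- if (df2 <= 0 || ssw <= 0) {
    if (ssb > 0) 0 else 1
  } else {
    f <- (ssb / (k - 1)) / (ssw / df2)
    stats::pf(f, k - 1, df2, lower.tail = FALSE)
  }
  if (!(p_anova < p_cutoff)) reasons <- c(reasons, "anova_ns")
  list(accept = length(reasons) == 0L, reasons = reasons, p_anova = p_anova)
}

#' One-way ANOVA of a phenotype across the haplotypes of a block
#'
#' Scores the association between a block's strain partition and the
#' per-strain mean values: groups are the block haplotypes (reduced to those
#' containing at least one assigned, phenotyped strain), the response is one
#' value per strain. Categorical phenotypes use the same F machinery on their
#' integer class codes. When the within-group variance is exactly zero with
#' unequal group means (the haplotype partition reproduces the phenotype
#' perfectly), the F statistic is unbounded and the p-value is exactly 0.
#'
#' @param block a `haplotype_block` (or any named per-strain label vector via
#'   `strain_groups`).
#' @param dataset a [phenotype_dataset()].
#' @return An object of class `block_association`: list with `F_statistic`,
#'   `F_unbounded` flag, `p_hbcgm`, `eta2`, `ssb`, `sst`, `k` groups used,
#'   `n` strains used, `block`.
#' @export
block_anova <- function(block, dataset) {
  groups <- if (inherits(block, "haplotype_block")) block$strain_groups
            else block
  stopifnot(!is.null(names(groups)), inherits(dataset, "phenotype_dataset"))
  y_all <- strain_means(dataset)
  common <- intersect(names(groups)[!is.na(groups)], names(y_all))
  y <- y_all[common]
  g <- groups[common]
  if (length(unique(g)) < 2L) {
    stop("degenerate grouping: fewer than 2 haplotype groups with phenotyped strains")
  }
  ss <- .oneway_ss(y, g)
  if (ss$sst == 0) {
    out <- list(F_statistic = 0, F_unbounded = FALSE, p_hbcgm = 1, eta2 = 0,
                ssb = 0, sst = 0, k = ss$k, n = ss$n)
  } else if (ss$ssw == 0) {
    ## perfect separation: unequal group means, zero within-group variance
    out <- list(F_statistic = Inf, F_unbounded = TRUE, p_hbcgm = 0,
                eta2 = 1, ssb = ss$ssb, sst = ss$sst, k = ss$k, n = ss$n)
  } else {
    f <- (ss$ssb / (ss$k - 1)) / (ss$ssw / (ss$n - ss$k))
    p <- stats::pf(f, ss$k - 1, ss$n - ss$k, lower.tail = FALSE)
    out <- list(F_statistic = f, F_unbounded = FALSE, p_hbcgm = p,
                eta2 = ss$ssb / ss$sst, ssb = ss$ssb, sst = ss$sst,
                k = ss$k, n = ss$n)
  }
  out$block <- if (inherits(block, "haplotype_block")) block else NULL
  class(out) <- "block_association"
  out
}

#' @export
print.block_association <- function(x, ...) {
  cat(sprintf("block_association: F = %s (k = %d, n = %d), p = %g, eta2 = %.3f%s\n",
              if (x$F_unbounded) "unbounded" else format(x$F_statistic, digits = 4),
              x$k, x$n, x$p_hbcgm, x$eta2,
              if (x$F_unbounded) " [perfect separation]" else ""))
  invisible(x)
}

#' Genetic effect size eta-squared
#'
#' `eta^2 = SSB / SST`, the share of the total strain-mean variance explained
#' by the haplotype grouping.
#'
#' @param result a `block_association` from [block_anova()].
#' @return eta-squared in `[0, 1]`.
#' @export
effect_size <- function(result) {
  stopifnot(inherits(result, "block_association"))
  if (result$sst == 0) stop("effect size undefined: total sum of squares is 0")
  result$ssb / result$sst
}

#' Power of the one-way ANOVA under a given effect size
#'
#' With `k` groups and total sample size `n`, the F statistic under effect
#' size eta-squared follows a noncentral `F(k-1, n-k, lambda)` with
#' noncentrality `lambda = n * eta2 / (1 - eta2)`. Power at level `alpha` is
#' the upper-tail probability of that distribution beyond the central-F
#' critical value `F_crit = qf(1 - alpha, k-1, n-k)`; at `eta2 = 0` this
#' reduces to `alpha` exactly.
#'
#' @param alpha significance level in `(0, 1)`.
#' @param eta2 effect size in `[0, 1)`.
#' @param n total sample size, `> k`.
#' @param k number of groups, `>= 2`.
#' @return power in `[0, 1]`.
#' @export
anova_power <- function(alpha, eta2, n, k) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (k < 2) stop("k must be >= 2")
  if (n <= k) stop("n must exceed k")
  if (eta2 < 0 || eta2 >= 1) stop("eta2 must lie in [0, 1)")
  lambda <- n * eta2 / (1 - eta2)
  f_crit <- stats::qf(1 - alpha, k - 1, n - k)
  stats::pf(f_crit, k - 1, n - k, ncp = lambda, lower.tail = FALSE)
}

#' Select blocks correlated with the phenotype
#'
#' Retains association results with `p_hbcgm < cutoff` (strict inequality).
#' When a `genes` labeling is supplied (one gene symbol, or `NA`, per
#' result), only the smallest-p block of each gene is kept; unlabeled blocks
#' are all retained.
#'
#' @param results list of `block_association` objects.
#' @param cutoff p-value cutoff (default 0.01).
#' @param genes optional character vector parallel to `results`.
#' @return the retained subset of `results` (ordered by increasing p).
#' @export
select_correlated <- function(results, cutoff = 0.01, genes = NULL) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  if (!length(results)) return(results)
  p <- vapply(results, function(r) r$p_hbcgm, numeric(1))
  keep <- p < cutoff
  results <- results[keep]
  p <- p[keep]
  if (!is.null(genes)) {
    genes <- genes[keep]
    drop <- rep(FALSE, length(results))
    for (gene in unique(genes[!is.na(genes)])) {
      idx <- which(!is.na(genes) & genes == gene)
      if (length(idx) > 1L) drop[idx[-which.min(p[idx])]] <- TRUE
    }
    results <- results[!drop]
    p <- p[!drop]
  }
  results[order(p)]
}
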