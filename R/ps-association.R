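## Multivariate one-factor SSCP decomposition of responses y (n x p) on a
## grouping g: total T = H + E with H the between-group and E the
## within-group sum-of-squares-and-cross-products matrices.
.manova_sscp <- function(y, g) {
  g <- factor(g)
  n <- nrow(y); p <- ncol(y); k <- nlevels(g)
  grand <- colMeans(y)
  yc <- sweep(y, 2, grand)
  tmat <- crossprod(yc)
  gm <- rowsum(y, g) / tabulate(g)
  fitted <- gm[as.integer(g), , drop = FALSE]
  resid <- y - fitted
  e <- crossprod(resid)
  h <- tmat - e
  list(h = h, e = e, t = tmat, n = n, p = p, k = k, grand = grand,
       group_means = gm, residuals = resid)
}

.pillai <- function(h, tmat) {
  sum(diag(h %*% solve(tmat)))
}

.wilks <- function(h, e) {
  det(e) / det(e + h)
}

#' Population-structure association test for a haplotype grouping
#'
#' The test inverts the usual role of population structure (PS): rather than
#' correcting a trait association for PS, it treats PS as the response. The
#' strain coordinates on the first `p` principal components of the genetic
#' relationship (or IBS) matrix form an `n x p` multivariate response `y`,
#' modelled as `y = mu + X beta + e` where `X` indicates the block's
#' haplotype group of each strain. A one-factor MANOVA then asks whether the
#' haplotype grouping explains the strains' positions in PC space; a small
#' p-value marks the grouping as mirroring population structure.
#'
#' Pillai's trace (default; most robust at small n) or Wilks' lambda is
#' converted to an approximate F. When the residual degrees of freedom
#' `n - k` fall below `p` the parametric approximation is invalid and the
#' test falls back to a permutation p-value of the statistic
#' (`n_perm` random label permutations), flagged in the result.
#'
#' @param grouping named per-strain labels (a `haplotype_block`'s
#'   `strain_groups`, or any named vector); `NA` (unassigned) strains are
#'   dropped.
#' @param coords a [pca_coordinates()].
#' @param statistic `"Pillai"` or `"Wilks"`.
#' @param n_perm permutations for the small-sample fallback (default 10000).
#' @return An object of class `manova_fit`: list with `statistic_name`,
#'   `statistic`, `approx_F`, `df1`, `df2`, `p_value`, `method`
#'   ("parametric" or "permutation"), `n`, `k`, `p`, `grand_mean`,
#'   `group_means`, `residuals`, `dropped` (unassigned strains).
#' @export
ps_manova_test <- function(grouping, coords, statistic = c("Pillai", "Wilks"),
                           n_perm = 10000L) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(coords, "pca_coordinates"))
  if (inherits(grouping, "haplotype_block")) grouping <- grouping$strain_groups
  if (is.null(names(grouping))) stop("grouping must be a named per-strain vector")
  strains <- rownames(coords$scores)
  g <- grouping[strains]
  dropped <- strains[is.na(g)]
  use <- !is.na(g)
  y <- coords$scores[use, , drop = FALSE]
  g <- factor(g[use])
  if (nlevels(g) < 2L) stop("degenerate grouping: fewer than 2 groups among scored strains")
  if (ncol(y) < 1L) stop("at least one principal component is required")
  dec <- .manova_sscp(y, g)
  n <- dec$n; p <- dec$p; k <- dec$k
  q <- k - 1; v <- n - k
  stat <- if (statistic == "Pillai") .pillai(dec$h, dec$t) else .wilks(dec$h, dec$e)
  if (v < p) {
    p_value <- .perm_pvalue(y, g, statistic, stat, n_perm)
    fit <- list(statistic_name = statistic, statistic = stat,
                approx_F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                p_value = p_value, method = "permutation")
  } else {
    if (statistic == "Pillai") {
      s <- min(p, q)
      m <- (abs(p - q) - 1) / 2
      nn <- (v - p - 1) / 2
      df1 <- s * (2 * m + s + 1)
      df2 <- s * (2 * nn + s + 1)
      fstat <- (2 * nn + s + 1) / (2 * m + s + 1) * stat / (s - stat)
    } else {
      t_exp <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
      r <- v - (p - q + 1) / 2
      u <- (p * q - 2) / 4
      df1 <- p * q
      df2 <- r * t_exp - 2 * u
      lam_t <- stat^(1 / t_exp)
      fstat <- (1 - lam_t) / lam_t * df2 / df1
    }
    p_value <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
    fit <- list(statistic_name = statistic, statistic = stat,
                approx_F = fstat, df1 = df1, df2 = df2, p_value = p_value,
                method = "parametric")
  }
  fit$n <- n; fit$k <- k; fit$p <- p
  fit$grand_mean <- dec$grand
  fit$group_means <- dec$group_means
  fit$residuals <- dec$residuals
  fit$dropped <- dropped
  class(fit) <- "manova_fit"
  fit
}

## Permutation null of the MANOVA statistic. The RNG stream is seeded
## deterministically from the instance (so repeated calls on the same data
## agree) and the caller's global RNG state is restored afterwards.
.perm_pvalue <- function(y, g, statistic, obs, n_perm) {
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(round(sum(abs(y)) * 1e6 + sum(as.integer(g))) %% 2147483647))
  extreme <- 0L
  for (b in seq_len(n_perm)) {
    gp <- sample(g)
    dp <- .manova_sscp(y, gp)
    sp <- if (statistic == "Pillai") .pillai(dp$h, dp$t) else .wilks(dp$h, dp$e)
    ## Pillai: large = structured; Wilks: small = structured
    hit <- if (statistic == "Pillai") sp >= obs - 1e-12 else sp <= obs + 1e-12
    if (hit) extreme <- extreme + 1L
  }
  (1 + extreme) / (n_perm + 1)
}

#' @export
print.manova_fit <- function(x, ...) {
  cat(sprintf("manova_fit: %s = %.4f, p = %g (%s; n = %d, k = %d, p = %d)\n",
              x$statistic_name, x$statistic, x$p_value, x$method,
              x$n, x$k, x$p))
  invisible(x)
}

#' Population-structure test for a single variant
#'
#' The haplotype-grouping term of [ps_manova_test()] is replaced by the
#' strain allele indicator of one variant: a two-level factor separating
#' carriers of the alternate allele from reference strains. Variants whose
#' minor allele is present in fewer than `min_carriers` strains are rejected
#' (rare variants cannot support a PS assessment).
#'
#' @param allele_indicator named per-strain 0/1 vector (NA = missing).
#' @param coords a [pca_coordinates()].
#' @param min_carriers strict minimum strain count for the minor allele
#'   (default 3).
#' @param ... passed to [ps_manova_test()].
#' @return A `manova_fit` (see [ps_manova_test()]).
#' @export
variant_ps_test <- function(allele_indicator, coords, min_carriers = 3L, ...) {
  if (is.null(names(allele_indicator))) {
    stop("allele_indicator must be a named per-strain vector")
  }
  x <- allele_indicator[!is.na(allele_indicator)]
  counts <- table(factor(x, levels = c(0, 1)))
  if (length(unique(x)) < 2L) stop("degenerate grouping: variant is monomorphic")
  if (min(counts) < min_carriers) {
    stop("rare variant: minor allele present in ", min(counts),
         " strains (< ", min_carriers, ")")
  }
  ps_manova_test(allele_indicator, coords, ...)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' increasingly, `p_adj(i) = min_{j >= i} min(1, p(j) * m / j)`, returned in
#' the original order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) return(p)
  if (any(is.na(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify blocks as PS+ or PS-
#'
#' A block (or variant) whose BH-adjusted PS p-value falls strictly below the
#' FDR level `q` is significantly associated with population structure
#' (`PS+`); at `p_adj >= q` the no-structure null cannot be rejected (`PS-`),
#' so the boundary value `p_adj = q` is `PS-`.
#'
#' @param p_adj numeric vector of BH-adjusted p-values.
#' @param q FDR level (default 0.05).
#' @return character vector of `"PS+"` / `"PS-"` calls.
#' @export
classify_ps <- function(p_adj, q = 0.05) {
  ifelse(p_adj < q, "PS+", "PS-")
}

#' PS-test a family of blocks with FDR control
#'
#' Runs [ps_manova_test()] on each block against the same PC coordinates,
#' adjusts the family of p-values by [bh_adjust()] (m = number of blocks
#' tested), and classifies each block at FDR level `q`.
#'
#' @param blocks list of `haplotype_block` objects (or named label vectors).
#' @param coords a [pca_coordinates()].
#' @param q FDR level (default 0.05).
#' @param ... passed to [ps_manova_test()].
#' @return data.frame with columns `ps_p`, `ps_p_adj`, `ps_class`,
#'   `ps_method`, `pc_source`, one row per block.
#' @export
ps_test_blocks <- function(blocks, coords, q = 0.05, ...) {
  if (!length(blocks)) {
    return(data.frame(ps_p = numeric(), ps_p_adj = numeric(),
                      ps_class = character(), ps_method = character(),
                      pc_source = character(), stringsAsFactors = FALSE))
  }
  fits <- lapply(blocks, ps_manova_test, coords = coords, ...)
  p <- vapply(fits, function(f) f$p_value, numeric(1))
  p_adj <- bh_adjust(p)
  data.frame(ps_p = p, ps_p_adj = p_adj,
             ps_class = classify_ps(p_adj, q),
             ps_method = vapply(fits, function(f) f$method, character(1)),
             pc_source = coords$source, stringsAsFactors = FALSE)
}
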