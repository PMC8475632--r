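#' Genetic relationship matrix (GRM)
#'
#' Variance-covariance standardized relationship matrix from per-site allele
#' calls: each site's call is standardized by its panel allele frequency,
#' `z = (x - p) / sqrt(p (1 - p))`, and the GRM entry for a strain pair is the
#' average product of their z-scores over the sites at which both are
#' observed (missing calls contribute zero; the per-pair denominator is the
#' count of co-observed sites). Monomorphic sites are skipped; no
#' minor-allele-frequency filter is applied beyond that.
#'
#' @param genotypes a [genotype_matrix()].
#' @return An object of class `relationship_matrix`: list with `kind = "GRM"`,
#'   `values` (n x n symmetric), `strains`.
#' @export
compute_grm <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  x <- genotypes$calls
  if (nrow(x) < 2L) stop("at least 2 strains are required")
  p <- colMeans(x, na.rm = TRUE)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all sites are monomorphic; GRM undefined")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(sweep(x, 2, p, "-"), 2, sqrt(p * (1 - p)), "/")
  obs <- !is.na(z)
  z[!obs] <- 0
  num <- tcrossprod(z)
  denom <- tcrossprod(obs * 1)
  if (any(denom == 0)) stop("a strain pair shares no co-observed site")
  values <- num / denom
  values <- (values + t(values)) / 2
  structure(list(kind = "GRM", values = values, strains = genotypes$strains),
            class = "relationship_matrix")
}

#' Identity-by-state (IBS) similarity matrix
#'
#' Entry (i, j) is the fraction of co-observed sites at which strains i and j
#' carry identical alleles; the diagonal is 1 and all entries lie in
#' `[0, 1]`.
#'
#' @param genotypes a [genotype_matrix()].
#' @return A `relationship_matrix` with `kind = "IBS"`.
#' @export
compute_ibs <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  x <- genotypes$calls
  if (nrow(x) < 2L) stop("at least 2 strains are required")
  obs <- !is.na(x)
  x0 <- x; x0[!obs] <- 0
  ## matches = sites where both called and equal = both 1 + both 0
  both <- tcrossprod(obs * 1)
  if (any(both == 0)) {
    bad <- which(both == 0, arr.ind = TRUE)[1, ]
    stop("strains ", genotypes$strains[bad[1]], " and ",
         genotypes$strains[bad[2]], " share no co-observed site")
  }
  ones <- tcrossprod(x0)
  zeros <- tcrossprod((1 - x0) * obs)
  values <- (ones + zeros) / both
  values <- (values + t(values)) / 2
  diag(values) <- 1
  structure(list(kind = "IBS", values = values, strains = genotypes$strains),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("relationship_matrix (%s): %d strains\n", x$kind,
              length(x$strains)))
  invisible(x)
}

#' Principal-component coordinates of a relationship matrix
#'
#' Eigendecomposition of the GRM (or IBS) matrix; the retained strain scores
#' are the leading eigenvectors, by default scaled by the square root of
#' their eigenvalues so that score geometry reproduces the matrix
#' (`scores %*% t(scores)` equals it at `p = n`) and downstream multivariate
#' tests weight components by explained variance. Column signs are fixed so
#' each component's largest-magnitude loading is positive. The fraction of
#' variance explained by a component is its eigenvalue over the trace.
#'
#' @param matrix a `relationship_matrix`.
#' @param p number of retained components (default 4).
#' @param scale `"sqrt"` (default) or `"raw"` for unscaled eigenvectors.
#' @param center logical (default TRUE): double-center the matrix before
#'   eigendecomposition, as in principal-coordinate analysis, so components
#'   describe relative strain differentiation. The GRM is already centered
#'   (its standardized site scores sum to zero across strains), so this
#'   matters only for similarity matrices such as IBS, whose leading raw
#'   eigenvector is the uninformative overall-similarity component. Set
#'   `FALSE` for a plain eigendecomposition of the matrix itself.
#' @return An object of class `pca_coordinates`: list with `scores` (n x p,
#'   strain rownames), `eigenvalues` (all n), `variance_explained` (all n),
#'   `p`, `scale`, `source` (GRM/IBS).
#' @export
pca_coordinates <- function(matrix, p = 4L, scale = c("sqrt", "raw"),
                            center = TRUE) {
  stopifnot(inherits(matrix, "relationship_matrix"))
  scale <- match.arg(scale)
  v <- matrix$values
  if (max(abs(v - t(v))) > 1e-8) stop("relationship matrix is not symmetric")
  n <- nrow(v)
  if (isTRUE(center)) {
    rm_ <- rowMeans(v)
    v <- v - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(v)
  }
  p <- as.integer(p)
  if (p < 1L || p > n) stop("p must lie in 1..n")
  eig <- eigen(v, symmetric = TRUE)
  vals <- eig$values
  vecs <- eig$vectors
  for (j in seq_len(n)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- vecs[, seq_len(p), drop = FALSE]
  if (scale == "sqrt") {
    scores <- sweep(scores, 2, sqrt(pmax(vals[seq_len(p)], 0)), "*")
  }
  rownames(scores) <- matrix$strains
  colnames(scores) <- paste0("PC", seq_len(p))
  structure(list(scores = scores, eigenvalues = vals,
                 variance_explained = vals / sum(vals), p = p, scale = scale,
                 source = matrix$kind),
            class = "pca_coordinates")
}

#' @export
print.pca_coordinates <- function(x, ...) {
  cat(sprintf("pca_coordinates: %d strains x %d PCs (%s, %s scaling); top variance fractions %s\n",
              nrow(x$scores), x$p, x$source, x$scale,
              paste(sprintf("%.1f%%", 100 * x$variance_explained[seq_len(min(4, x$p))]),
                    collapse = ", ")))
  invisible(x)
}

## Tracy-Widom (beta = 1) distribution function, Chiani (2014) shifted-gamma
## approximation: TW1 ~ Gamma(k, theta) - alpha with the constants below;
## absolute CDF error ~1e-4, far below the 0.05 decision threshold.
.ptw1 <- function(x) {
  k <- 46.44604884; theta <- 0.18605402228; alpha <- 9.84801283
  stats::pgamma(x + alpha, shape = k, scale = theta)
}

#' Tracy-Widom assessment of leading eigenvalues
#'
#' Tests whether the leading eigenvalues of a relationship matrix exceed
#' their expectation under no structure, using moment-matched normalization:
#' for the `m` eigenvalues under consideration the effective marker count is
#' estimated by matching the Marchenko-Pastur eigenvalue dispersion,
#' `n' = m S1^2 / (m S2 - S1^2)` (with `S1`, `S2` the eigenvalue sum and sum
#' of squares), the top eigenvalue is normalized to `l = m * l1 / S1` and
#' centred/scaled with the Tracy-Widom coupling constants
#' `mu = (sqrt(n'-1) + sqrt(m))^2 / n'`,
#' `sigma = ((sqrt(n'-1) + sqrt(m)) / n') (1/sqrt(n'-1) + 1/sqrt(m))^(1/3)`;
#' the statistic is referred to the Tracy-Widom (beta = 1) distribution. The
#' test is applied iteratively: after assessing the top eigenvalue it is
#' removed and the next one tested on the reduced set.
#'
#' @param eigenvalues numeric vector of eigenvalues sorted decreasingly
#'   (negative values from numerical noise are clamped to 0); typically the
#'   `n - 1` informative eigenvalues of a GRM.
#' @param n_test number of leading eigenvalues to test (default 2).
#' @return data.frame with columns `component`, `eigenvalue`, `twstat`,
#'   `p_value`.
#' @export
tw_test <- function(eigenvalues, n_test = 2L) {
  ev <- pmax(as.numeric(eigenvalues), 0)
  if (is.unsorted(rev(ev))) ev <- sort(ev, decreasing = TRUE)
  ## drop trailing (near-)zero eigenvalues: centring removes rank
  ev <- ev[ev > max(ev) * 1e-9]
  if (length(ev) < 3L) stop("at least 3 positive eigenvalues are required")
  n_test <- min(n_test, length(ev) - 2L)
  out <- data.frame(component = integer(), eigenvalue = numeric(),
                    twstat = numeric(), p_value = numeric())
  for (i in seq_len(n_test)) {
    cur <- ev[i:length(ev)]
    m <- length(cur)
    s1 <- sum(cur); s2 <- sum(cur^2)
    denom <- m * s2 - s1^2
    ## eigenvalues at (or below) the no-structure dispersion floor behave as
    ## if the marker count were unbounded: no leading-eigenvalue excess
    neff <- if (denom <= 0) 1e9 else m * s1^2 / denom
    if (!is.finite(neff) || neff <= 1) break
    l <- m * cur[1] / s1
    mu <- (sqrt(neff - 1) + sqrt(m))^2 / neff
    sigma <- (sqrt(neff - 1) + sqrt(m)) / neff *
      (1 / sqrt(neff - 1) + 1 / sqrt(m))^(1 / 3)
    x <- (l - mu) / sigma
    out <- rbind(out, data.frame(component = i, eigenvalue = ev[i],
                                 twstat = x, p_value = 1 - .ptw1(x)))
  }
  out
}

#' Sub-population assignment by hierarchical clustering of the IBS matrix
#'
#' Agglomerative clustering (average linkage by default) on the distance
#' `1 - IBS`, cut at `k` clusters. Labels are contiguous from 1 in order of
#' first appearance.
#'
#' @param matrix a `relationship_matrix` of kind IBS.
#' @param k number of sub-populations, `1 <= k <= n`.
#' @param linkage linkage passed to [stats::hclust()] (default "average").
#' @return An object of class `subpopulation_assignment`: list with `labels`
#'   (named integer vector), `k`, `linkage`, `hclust` (the tree).
#' @export
hierarchical_subpopulations <- function(matrix, k, linkage = "average") {
  stopifnot(inherits(matrix, "relationship_matrix"))
  if (matrix$kind != "IBS") stop("sub-population clustering expects an IBS matrix")
  n <- length(matrix$strains)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must lie in 1..n")
  d <- stats::as.dist(1 - matrix$values)
  hc <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(hc, k = k)
  labels <- match(raw, unique(raw))
  names(labels) <- matrix$strains
  structure(list(labels = labels, k = k, linkage = linkage, hclust = hc),
            class = "subpopulation_assignment")
}

#' @export
print.subpopulation_assignment <- function(x, ...) {
  cat(sprintf("subpopulation_assignment: %d strains in %d clusters (%s linkage); sizes %s\n",
              length(x$labels), x$k, x$linkage,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Supervised ANOVA of PC coordinates on pre-determined sub-populations
#'
#' For each retained principal component, a one-way ANOVA of the strain
#' scores across the sub-population labels quantifies how strongly that
#' component separates the pre-determined groups (p-values are conventionally
#' compared with 0.05).
#'
#' @param coords a [pca_coordinates()].
#' @param labels a `subpopulation_assignment` or named per-strain label
#'   vector covering the strains in `coords`.
#' @return data.frame with columns `component`, `F_statistic`, `p_value`.
#' @export
anova_on_pcs <- function(coords, labels) {
  stopifnot(inherits(coords, "pca_coordinates"))
  if (inherits(labels, "subpopulation_assignment")) labels <- labels$labels
  labels <- labels[rownames(coords$scores)]
  if (anyNA(labels)) stop("labels must cover every strain in the coordinates")
  if (length(unique(labels)) < 2L) stop("at least 2 sub-populations are required")
  res <- lapply(seq_len(coords$p), function(j) {
    ss <- .oneway_ss(coords$scores[, j], labels)
    if (ss$ssw <= 0 || ss$n <= ss$k) {
      f <- if (ss$ssb > 0) Inf else 0
      p <- if (ss$ssb > 0) 0 else 1
    } else if (ss$ssb == 0) {
      f <- 0; p <- 1
    } else {
      f <- (ss$ssb / (ss$k - 1)) / (ss$ssw / (ss$n - ss$k))
      p <- stats::pf(f, ss$k - 1, ss$n - ss$k, lower.tail = FALSE)
    }
    data.frame(component = j, F_statistic = f, p_value = p)
  })
  do.call(rbind, res)
}

#' Prune variants in linkage disequilibrium
#'
#' Slides windows of `window_bp` base pairs (half-window step) along each
#' chromosome; within a window, whenever a retained pair of sites has squared
#' allele-code correlation at or above `r2_threshold`, the later-positioned
#' site is removed.
#'
#' @param genotypes a [genotype_matrix()].
#' @param window_bp window size in base pairs.
#' @param r2_threshold squared-correlation threshold in `(0, 1]`.
#' @return the pruned [genotype_matrix()].
#' @seealso [ld_presets()] for the standard window/threshold combinations.
#' @export
ld_prune <- function(genotypes, window_bp = 10000L, r2_threshold = 0.5) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (window_bp <= 0) stop("window_bp must be positive")
  if (r2_threshold <= 0 || r2_threshold > 1) stop("r2_threshold must lie in (0, 1]")
  keep <- rep(TRUE, n_variants(genotypes))
  for (ch in unique(genotypes$chrom)) {
    cols <- which(genotypes$chrom == ch)
    pos <- genotypes$pos[cols]
    starts <- seq(min(pos), max(pos), by = max(1L, window_bp %/% 2L))
    for (w0 in starts) {
      in_win <- cols[pos >= w0 & pos < w0 + window_bp]
      in_win <- in_win[keep[in_win]]
      if (length(in_win) < 2L) next
      for (a in seq_len(length(in_win) - 1L)) {
        i <- in_win[a]
        if (!keep[i]) next
        for (b in (a + 1L):length(in_win)) {
          j <- in_win[b]
          if (!keep[j]) next
          r <- suppressWarnings(
            stats::cor(genotypes$calls[, i], genotypes$calls[, j],
                       use = "pairwise.complete.obs"))
          if (!is.na(r) && r^2 >= r2_threshold) keep[j] <- FALSE
        }
      }
    }
  }
  subset_variants(genotypes, keep)
}

#' Standard LD-pruning presets
#'
#' The four window/threshold combinations conventionally explored when
#' checking that sub-population structure is robust to marker thinning.
#'
#' @return named list of `list(window_bp, r2_threshold)` configurations.
#' @export
ld_presets <- function() {
  list(`10kb_r2_0.5`  = list(window_bp = 10000L, r2_threshold = 0.5),
       `10kb_r2_0.75` = list(window_bp = 10000L, r2_threshold = 0.75),
       `50kb_r2_0.5`  = list(window_bp = 50000L, r2_threshold = 0.5),
       `50kb_r2_0.75` = list(window_bp = 50000L, r2_threshold = 0.75))
}

#' Write a relationship matrix or PCA scores to TSV
#'
#' @param x a `relationship_matrix` or `pca_coordinates`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  if (inherits(x, "relationship_matrix")) {
    tab <- data.frame(strain = x$strains, x$values, check.names = FALSE)
    colnames(tab) <- c("strain", x$strains)
  } else if (inherits(x, "pca_coordinates")) {
    tab <- data.frame(strain = rownames(x$scores), x$scores, check.names = FALSE)
  } else stop("unsupported object")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
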