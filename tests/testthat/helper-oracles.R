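# Independent oracles and fixture builders used across the suite.

# Random complete-call panel on one chromosome.
random_panel <- function(n, m, seed, maf = 0.5) {
  set.seed(seed)
  calls <- matrix(stats::rbinom(n * m, 1L, maf), n, m,
                  dimnames = list(sprintf("S%02d", seq_len(n)), NULL))
  genotype_matrix(calls, chrom = rep("chr1", m), pos = seq_len(m) * 100L)
}

# Exhaustive-enumeration oracle for maximal haplotype blocks: every interval
# of >= min_snps SNPs whose distinct-string count d lies in [2, max_h] and
# whose one-column extensions (within the chromosome) exceed max(2, d)
# distinct strings; then nesting removal on (interval, partition).
brute_blocks <- function(g, min_snps = 4, max_h = 5) {
  M <- n_variants(g)
  part <- function(s, e) {
    sub <- g$calls[, s:e, drop = FALSE]
    complete <- rowSums(is.na(sub)) == 0
    lab <- rep(NA_integer_, nrow(sub))
    if (any(complete)) {
      keys <- apply(sub[complete, , drop = FALSE], 1, paste, collapse = "")
      lab[complete] <- match(keys, unique(keys))
    }
    lab
  }
  dfun <- function(s, e) {
    l <- part(s, e)
    length(unique(l[!is.na(l)]))
  }
  out <- list()
  if (M < min_snps) return(out)
  for (s in 1:(M - min_snps + 1)) {
    for (e in (s + min_snps - 1):M) {
      d <- dfun(s, e)
      if (d < 2 || d > max_h) next
      h <- max(2, d)
      dr <- if (e == M) Inf else dfun(s, e + 1)
      dl <- if (s == 1) Inf else dfun(s - 1, e)
      if (dr <= h || dl <= h) next
      out[[length(out) + 1]] <- list(s = s, e = e, lab = part(s, e))
    }
  }
  if (length(out) < 2) return(out)
  key <- sapply(out, function(b)
    paste(ifelse(is.na(b$lab), "u", b$lab), collapse = ","))
  keep <- rep(TRUE, length(out))
  for (i in seq_along(out)) {
    for (j in seq_along(out)) {
      if (i == j || key[i] != key[j]) next
      li <- out[[i]]$e - out[[i]]$s
      lj <- out[[j]]$e - out[[j]]$s
      contains <- out[[j]]$s <= out[[i]]$s && out[[j]]$e >= out[[i]]$e
      if (contains && (lj > li || (lj == li && j < i))) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out[keep]
}

block_keys <- function(blocks) {
  sapply(blocks, function(b) {
    paste(b$snp_index_range[1], b$snp_index_range[2],
          paste(ifelse(is.na(b$strain_groups), "u", b$strain_groups),
                collapse = ","), sep = "|")
  })
}

brute_keys <- function(blocks) {
  sapply(blocks, function(b) {
    paste(b$s, b$e,
          paste(ifelse(is.na(b$lab), "u", b$lab), collapse = ","), sep = "|")
  })
}

# Direct evaluation of the BH step-up formula (sorted cumulative minimum).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Wrap an arbitrary score matrix as PC coordinates for MANOVA tests.
as_coords <- function(y, source = "GRM") {
  if (is.null(rownames(y))) rownames(y) <- sprintf("S%02d", seq_len(nrow(y)))
  colnames(y) <- paste0("PC", seq_len(ncol(y)))
  structure(list(scores = y, eigenvalues = rep(1, ncol(y)),
                 variance_explained = rep(1 / ncol(y), ncol(y)),
                 p = ncol(y), scale = "raw", source = source),
            class = "pca_coordinates")
}

# Vectorized permutation null of Pillai's trace for a 2-group design, using
# the permutation invariance of the total SSCP: Pillai = tr(H T^-1) with
# H = (n1 n0 / n) d d', d the difference of group mean vectors.
perm_pillai_2group <- function(y, n1, obs, B, seed) {
  set.seed(seed)
  n <- nrow(y)
  Tm <- crossprod(sweep(y, 2, colMeans(y)))
  Ti <- solve(Tm)
  ytot <- colSums(y)
  cs <- matrix(0, ncol(y), B)
  for (b in seq_len(B)) {
    cs[, b] <- colSums(y[sample(n, n1), , drop = FALSE])
  }
  d <- cs / n1 - (ytot - cs) / (n - n1)
  pill <- (n1 * (n - n1) / n) * colSums(d * (Ti %*% d))
  (1 + sum(pill >= obs - 1e-12)) / (B + 1)
}

# Simulated panel + GRM coordinates, shared by several structure tests.
panel_coords <- function(seed, n_groups = 4, sizes = c(7, 7, 6, 5),
                         n_snps = 300, fst = 0.3, p = 4) {
  cfg <- sim_config(n_groups = n_groups, strains_per_group = sizes,
                    n_snps = n_snps, fst = fst, seed = seed)
  sim <- simulate_structured_panel(cfg)
  list(sim = sim, coords = pca_coordinates(compute_grm(sim$genotypes), p = p))
}
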