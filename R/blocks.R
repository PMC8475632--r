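#' Filter variant sites for haplotype mapping
#'
#' Restricts a genotype matrix to the strains with trait data and keeps only
#' the sites usable for block construction: sites that are polymorphic among
#' those strains and have at least `min_called` strains with unambiguous
#' (non-missing) allele calls.
#'
#' @param genotypes a [genotype_matrix()].
#' @param trait_strains character vector of strains with trait data (subset
#'   of the panel).
#' @param min_called minimum number of unambiguous calls per retained site
#'   (default 8).
#' @return The column-filtered [genotype_matrix()] restricted to
#'   `trait_strains`; possibly with zero variant columns.
#' @export
filter_variants <- function(genotypes, trait_strains, min_called = 8L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  trait_strains <- as.character(trait_strains)
  if (length(trait_strains) < 2L) stop("at least 2 trait strains are required")
  g <- subset_strains(genotypes, trait_strains)
  called <- colSums(!is.na(g$calls))
  n0 <- colSums(g$calls == 0L, na.rm = TRUE)
  n1 <- colSums(g$calls == 1L, na.rm = TRUE)
  keep <- called >= min_called & n0 > 0L & n1 > 0L
  subset_variants(g, keep)
}

## Distinct complete allele strings over columns `idx`: returns list(d = count
## of distinct strings among strains with no missing call, labels = integer
## group per strain (NA when unassigned), numbered by first occurrence).
.block_partition <- function(calls, idx) {
  sub <- calls[, idx, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  labels <- rep(NA_integer_, nrow(sub))
  if (any(complete)) {
    keys <- apply(sub[complete, , drop = FALSE], 1L, paste, collapse = "")
    labels[complete] <- match(keys, unique(keys))
  }
  list(d = length(unique(labels[!is.na(labels)])), labels = labels)
}

#' Construct maximal haplotype blocks
#'
#' Organizes consecutive SNPs into haplotype blocks: genomic intervals of at
#' least `min_snps` SNPs over which the strains (those with complete calls)
#' fall into between 2 and `max_haplotypes` distinct allele strings. Blocks
#' are *maximal*: an interval is emitted only when extending it by one SNP in
#' either direction (within its chromosome) would raise the number of
#' distinct haplotypes above the block's haplotype budget, so overlapping
#' blocks with different haplotype counts co-exist and additional SNPs enter
#' a block only when they add haplotypes. A block whose interval is nested
#' inside a larger emitted block carrying the identical strain partition is
#' removed.
#'
#' @param genotypes a filtered [genotype_matrix()] (see [filter_variants()]).
#' @param min_snps minimum SNPs per block (default 4).
#' @param max_haplotypes largest haplotype count considered (default 5).
#' @return list of `haplotype_block` objects ordered by (chrom, start,
#'   haplotype count), each with fields `chrom`, `snp_index_range` (into the
#'   input matrix), `bp_range` (1-based closed), `n_snps`, `n_haplotypes`,
#'   `strain_groups` (per-strain label, NA = unassigned), and
#'   `haplotype_strings`.
#' @export
build_blocks <- function(genotypes, min_snps = 4L, max_haplotypes = 5L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  min_snps <- as.integer(min_snps)
  M <- n_variants(genotypes)
  if (M < min_snps) return(list())
  calls <- genotypes$calls
  n <- nrow(calls)
  blocks <- list()
  for (ch in unique(genotypes$chrom)) {
    cols <- which(genotypes$chrom == ch)
    m <- length(cols)
    if (m < min_snps) next
    ## For each start s, scan e rightward refining the strain partition one
    ## column at a time (O(n) per step); the scan stops at the first column
    ## whose inclusion drives the distinct-haplotype count above
    ## max_haplotypes. d_seq[[s]] records the count at every scanned e, so the
    ## left-extension check for start s reads d_seq[[s - 1]].
    d_prev <- NULL; stop_prev <- 0L
    for (s in seq_len(m)) {
      labels <- rep(1L, n)            # partition over zero columns
      d_cur <- rep(NA_integer_, m)
      e <- s
      repeat {
        x <- calls[, cols[e]]
        labels[is.na(x)] <- NA_integer_
        assigned <- !is.na(labels)
        key <- labels[assigned] * 2L + x[assigned]
        labels[assigned] <- match(key, unique(key))
        d_cur[e] <- length(unique(labels[assigned]))
        if (d_cur[e] > max_haplotypes || e == m) break
        e <- e + 1L
      }
      e_stop <- e
      e_max <- if (d_cur[e_stop] > max_haplotypes) e_stop - 1L else e_stop
      if (e_max - s + 1L >= min_snps) {
        for (ee in (s + min_snps - 1L):e_max) {
          d <- d_cur[ee]
          if (d < 2L || d > max_haplotypes) next
          h <- max(2L, d)
          d_right <- if (ee < e_stop) d_cur[ee + 1L] else Inf
          if (d_right <= h) next                  # right extension possible
          d_left <- if (s == 1L) Inf
                    else if (ee <= stop_prev) d_prev[ee]
                    else Inf                      # previous scan exceeded before ee
          if (d_left <= h) next                   # left extension possible
          part <- .block_partition(calls, cols[s:ee])
          blocks[[length(blocks) + 1L]] <-
            .new_block(genotypes, cols[s], cols[ee], part)
        }
      }
      d_prev <- d_cur; stop_prev <- e_stop
    }
  }
  .drop_nested(blocks)
}

.new_block <- function(genotypes, c_start, c_end, part) {
  idx <- c_start:c_end
  labels <- part$labels
  names(labels) <- genotypes$strains
  strings <- character(part$d)
  for (lev in seq_len(part$d)) {
    i <- which(labels == lev)[1]
    strings[lev] <- paste(genotypes$calls[i, idx], collapse = "")
  }
  structure(list(chrom = genotypes$chrom[c_start],
                 snp_index_range = c(c_start, c_end),
                 bp_range = c(genotypes$pos[c_start], genotypes$pos[c_end]),
                 n_snps = length(idx),
                 n_haplotypes = part$d,
                 strain_groups = labels,
                 haplotype_strings = strings),
            class = "haplotype_block")
}

## Remove blocks nested inside a strictly larger block with an identical
## strain partition (same unassigned set, same grouping), and collapse exact
## duplicates. Order by (chrom, start, n_haplotypes).
.drop_nested <- function(blocks) {
  if (!length(blocks)) return(blocks)
  key <- vapply(blocks, function(b) {
    paste(b$chrom, paste(ifelse(is.na(b$strain_groups), "u", b$strain_groups),
                         collapse = ","))
  }, character(1))
  starts <- vapply(blocks, function(b) b$snp_index_range[1], numeric(1))
  ends <- vapply(blocks, function(b) b$snp_index_range[2], numeric(1))
  keep <- rep(TRUE, length(blocks))
  for (i in seq_along(blocks)) {
    same <- which(key == key[i])
    for (j in same) {
      if (j == i) next
      larger_j <- (ends[j] - starts[j]) > (ends[i] - starts[i])
      contains <- starts[j] <= starts[i] && ends[j] >= ends[i]
      dup_first <- (starts[j] == starts[i] && ends[j] == ends[i] && j < i)
      if (contains && (larger_j || dup_first)) { keep[i] <- FALSE; break }
    }
  }
  blocks <- blocks[keep]
  ord <- order(vapply(blocks, function(b) b$chrom, character(1)),
               vapply(blocks, function(b) b$snp_index_range[1], numeric(1)),
               vapply(blocks, function(b) b$n_haplotypes, numeric(1)))
  blocks[ord]
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat(sprintf("haplotype_block %s:%d-%d (%d SNPs, %d haplotypes, %d unassigned strain%s)\n",
              x$chrom, x$bp_range[1], x$bp_range[2], x$n_snps, x$n_haplotypes,
              sum(is.na(x$strain_groups)),
              if (sum(is.na(x$strain_groups)) == 1L) "" else "s"))
  invisible(x)
}

#' Assign strains to the haplotypes of a block
#'
#' Strains whose allele string over the block matches one of the block's
#' haplotype strings receive that haplotype's label (numbered by first
#' occurrence in strain order); strains with one or more missing calls inside
#' the block are unassigned (`NA`).
#'
#' @param block a `haplotype_block`.
#' @param genotypes the [genotype_matrix()] the block was built from.
#' @return named integer vector of per-strain labels (NA = unassigned).
#' @export
assign_haplotypes <- function(block, genotypes) {
  stopifnot(inherits(block, "haplotype_block"),
            inherits(genotypes, "genotype_matrix"))
  idx <- block$snp_index_range[1]:block$snp_index_range[2]
  if (max(idx) > n_variants(genotypes)) stop("block indices exceed the matrix")
  part <- .block_partition(genotypes$calls, idx)
  labels <- part$labels
  names(labels) <- genotypes$strains
  complete <- !is.na(labels)
  strings <- vapply(which(complete), function(i) {
    paste(genotypes$calls[i, idx], collapse = "")
  }, character(1))
  if (!all(strings %in% block$haplotype_strings)) {
    stop("internal consistency error: a complete allele string matches no block haplotype")
  }
  labels
}

#' Flatten haplotype blocks to a results table
#'
#' @param blocks list of `haplotype_block` objects.
#' @param strains optional character vector fixing the strain column order of
#'   the serialized per-strain labels.
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `n_haplotypes`, `strain_groups` (comma-separated labels, `.` for
#'   unassigned).
#' @export
blocks_to_table <- function(blocks, strains = NULL) {
  if (!length(blocks)) {
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      n_haplotypes = integer(), strain_groups = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(strains)) strains <- names(blocks[[1]]$strain_groups)
  data.frame(
    chrom = vapply(blocks, function(b) b$chrom, character(1)),
    start_bp = vapply(blocks, function(b) b$bp_range[1], integer(1)),
    end_bp = vapply(blocks, function(b) b$bp_range[2], integer(1)),
    n_snps = vapply(blocks, function(b) b$n_snps, integer(1)),
    n_haplotypes = vapply(blocks, function(b) b$n_haplotypes, integer(1)),
    strain_groups = vapply(blocks, function(b) {
      paste(ifelse(is.na(b$strain_groups[strains]), ".",
                   b$strain_groups[strains]), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}
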