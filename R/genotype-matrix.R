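#' Genotype matrix for a panel of inbred strains
#'
#' Container for homozygous allele calls of `n` strains at `M` variant sites.
#' Because inbred strains are fully homozygous, each strain carries a single
#' allele per site, coded `0` (reference), `1` (alternate) or `NA` (missing or
#' ambiguous). Sites are ordered by chromosome and strictly increasing 1-based
#' position within each chromosome.
#'
#' @param calls integer or numeric matrix, strains in rows, variants in
#'   columns; entries in `{0, 1, NA}`.
#' @param chrom character vector of per-variant chromosome labels.
#' @param pos integer vector of per-variant 1-based base-pair positions.
#' @param ref,alt character vectors of reference / alternate allele symbols;
#'   defaults are placeholder nucleotides.
#' @param strains character vector of unique strain names; defaults to the
#'   rownames of `calls`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls` (n x M matrix with strain rownames), `chrom`, `pos`, `ref`,
#'   `alt`, `strains`.
#' @examples
#' g <- genotype_matrix(rbind(A = c(0, 1, 1, 0), B = c(1, 0, 1, 0)),
#'                      chrom = rep("chr1", 4), pos = c(100, 200, 300, 400))
#' g
#' @export
genotype_matrix <- function(calls, chrom, pos, ref = NULL, alt = NULL,
                            strains = rownames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(strains)) stop("strain names are required (rownames or `strains`)")
  strains <- as.character(strains)
  m <- ncol(calls)
  if (nrow(calls) < 2L) stop("a genotype matrix needs at least 2 strains")
  if (anyDuplicated(strains)) {
    stop("duplicate strain names: ",
         paste(unique(strains[duplicated(strains)]), collapse = ", "))
  }
  if (length(chrom) != m || length(pos) != m) {
    stop("chrom/pos length must equal the number of variant columns")
  }
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("T", m)
  bad <- !(calls %in% c(0, 1) | is.na(calls))
  if (any(bad)) stop("calls must be 0, 1 or NA")
  storage.mode(calls) <- "integer"
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  rownames(calls) <- strains
  if (m > 0L) colnames(calls) <- paste0(chrom, ":", pos)
  structure(
    list(calls = calls, chrom = chrom, pos = pos,
         ref = as.character(ref), alt = as.character(alt), strains = strains),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nm <- sum(is.na(x$calls))
  cat(sprintf("genotype_matrix: %d strains x %d variants (%d chromosome%s, %d missing call%s)\n",
              length(x$strains), n_variants(x), length(unique(x$chrom)),
              if (length(unique(x$chrom)) == 1L) "" else "s",
              nm, if (nm == 1L) "" else "s"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of variant sites
#' @param g a [genotype_matrix()].
#' @return integer count of variant columns.
#' @export
n_variants <- function(g) length(g$pos)

#' Number of strains
#' @param g a [genotype_matrix()].
#' @return integer count of strains.
#' @export
n_strains <- function(g) length(g$strains)

## Column subset preserving metadata; keep = logical or integer index.
subset_variants <- function(g, keep) {
  genotype_matrix(g$calls[, keep, drop = FALSE],
                  chrom = g$chrom[keep], pos = g$pos[keep],
                  ref = g$ref[keep], alt = g$alt[keep], strains = g$strains)
}

## Row subset to a strain set (order preserved as given).
subset_strains <- function(g, strains) {
  miss <- setdiff(strains, g$strains)
  if (length(miss)) stop("unknown strains: ", paste(miss, collapse = ", "))
  genotype_matrix(g$calls[strains, , drop = FALSE],
                  chrom = g$chrom, pos = g$pos,
                  ref = g$ref, alt = g$alt, strains = strains)
}
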