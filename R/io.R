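#' Read strain genotypes from VCF or a strain-by-variant table
#'
#' Parses homozygous strain genotypes into a [genotype_matrix()]. VCF
#' genotypes may be haploid (`0`, `1`) or homozygous diploid (`0/0`, `1/1`,
#' phased or unphased). Heterozygous or half-missing diploid calls carry no
#' usable information for a fully inbred strain and are masked to missing;
#' calls to secondary alternate alleles of multi-allelic records are likewise
#' masked (the internal allele coding is binary per site). A warning reports
#' how many calls were masked.
#'
#' The tabular format is tab-separated with columns `chrom`, `pos`, `ref`,
#' `alt`, then one column per strain holding `0`, `1` or `NA`.
#'
#' @param path path to the input file.
#' @param format `"vcf"` or `"table"`.
#' @return A validated [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_table(path)
}

read_genotypes_vcf <- function(path) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  strains <- colnames(gt)
  if (anyDuplicated(strains)) {
    stop("duplicate strain name in VCF: ",
         paste(unique(strains[duplicated(strains)]), collapse = ", "))
  }
  ## allele-index strings per haplotype; homozygous/haploid -> 0/1 code
  code_one <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    parts <- strsplit(s, "[/|]")[[1]]
    if (any(parts == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(parts))
    if (anyNA(a)) return(NA_integer_)
    if (length(unique(a)) > 1L) return(-1L)   # heterozygous
    if (a[1] > 1L) return(-2L)                # secondary alternate
    a[1]
  }
  codes <- vapply(as.vector(gt), code_one, integer(1), USE.NAMES = FALSE)
  codes <- matrix(codes, nrow = nrow(gt), ncol = ncol(gt))
  n_het <- sum(codes == -1L, na.rm = TRUE)
  n_alt2 <- sum(codes == -2L, na.rm = TRUE)
  codes[codes < 0L] <- NA_integer_
  if (n_het > 0L) {
    warning(sprintf("%d heterozygous call%s masked to missing", n_het,
                    if (n_het == 1L) "" else "s"))
  }
  if (n_alt2 > 0L) {
    warning(sprintf("%d call%s to secondary alternate alleles masked to missing (sites kept as ref vs first alt)",
                    n_alt2, if (n_alt2 == 1L) "" else "s"))
  }
  alt <- vapply(strsplit(fix[, "ALT"], ","), `[`, character(1), 1L)
  genotype_matrix(t(codes), chrom = fix[, "CHROM"],
                  pos = as.integer(fix[, "POS"]),
                  ref = fix[, "REF"], alt = alt, strains = strains)
}

read_genotypes_table <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse genotype table '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab))) {
    stop("genotype table must have columns ", paste(need, collapse = ", "))
  }
  strains <- setdiff(names(tab), need)
  if (length(strains) < 2L) stop("genotype table needs at least 2 strain columns")
  calls <- t(as.matrix(tab[, strains, drop = FALSE]))
  genotype_matrix(calls, chrom = tab$chrom, pos = tab$pos,
                  ref = tab$ref, alt = tab$alt, strains = strains)
}

#' Write strain genotypes
#'
#' Writes a [genotype_matrix()] either as a minimal VCF 4.2 file with haploid
#' genotypes (`0`, `1`, `.`) or as the tab-separated strain-by-variant table
#' read by [read_genotypes()].
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param format `"vcf"` or `"table"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "table")) {
  format <- match.arg(format)
  if (format == "table") {
    tab <- data.frame(chrom = g$chrom, pos = g$pos, ref = g$ref, alt = g$alt,
                      t(g$calls), check.names = FALSE)
    ok <- tryCatch({
      utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("cannot write to ", path)
    return(invisible(path))
  }
  gt <- g$calls
  gt_chr <- matrix(as.character(gt), nrow = nrow(gt))
  gt_chr[is.na(gt_chr)] <- "."
  body <- paste(g$chrom, g$pos, ".", g$ref, g$alt, ".", "PASS", ".", "GT",
                apply(gt_chr, 2, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$strains), collapse = "\t")
  )
  ok <- tryCatch({ writeLines(c(header, body), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write to ", path)
  invisible(path)
}

#' Read an MPD-style phenotype table
#'
#' Expects a tab-separated file with header columns `strain`, `mean`, `sd`,
#' `nindiv`; columns named `rep1`, `rep2`, ... are attached as replicate-level
#' values (NA cells allowed for strains with fewer replicates). Metadata
#' comment lines of the form `#key=value` (keys `dataset_id`, `sex`,
#' `categorical`) are honoured when present.
#'
#' @param path path to the phenotype file.
#' @return A [phenotype_dataset()].
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list(dataset_id = "dataset", sex = "both", categorical = FALSE)
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2 && kv[1] %in% names(meta)) {
      meta[[kv[1]]] <- if (kv[1] == "categorical") as.logical(kv[2]) else kv[2]
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("phenotype file '", path, "' is empty or header-only")
  tab <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  need <- c("strain", "mean", "sd", "nindiv")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("phenotype file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(tab$mean)) stop("non-numeric mean value in phenotype file")
  rep_cols <- grep("^rep[0-9]+$", names(tab), value = TRUE)
  replicates <- NULL
  if (length(rep_cols)) {
    rep_cols <- rep_cols[order(as.integer(sub("^rep", "", rep_cols)))]
    replicates <- lapply(seq_len(nrow(tab)), function(i) {
      v <- as.numeric(unlist(tab[i, rep_cols]))
      v[!is.na(v)]
    })
    names(replicates) <- tab$strain
  }
  phenotype_dataset(tab$strain, tab$mean, tab$sd, tab$nindiv,
                    replicates = replicates, dataset_id = meta$dataset_id,
                    sex = meta$sex, categorical = isTRUE(meta$categorical))
}

#' Write an MPD-style phenotype table
#'
#' @param pheno a [phenotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  tab <- pheno$data
  if (!is.null(pheno$replicates)) {
    maxr <- max(lengths(pheno$replicates))
    reps <- t(vapply(pheno$replicates,
                     function(v) c(v, rep(NA_real_, maxr - length(v))),
                     numeric(maxr)))
    colnames(reps) <- paste0("rep", seq_len(maxr))
    tab <- cbind(tab, as.data.frame(reps, row.names = NULL))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#dataset_id=", pheno$dataset_id),
               paste0("#sex=", pheno$sex),
               paste0("#categorical=", pheno$categorical)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a block results table
#'
#' Serializes a block table (as produced by [blocks_to_table()] or
#' [run_pipeline()]) to tab-separated text with a stable column order and
#' full-precision numeric fields (15 significant digits, scientific notation
#' where needed), so that a write/read round trip preserves p-values.
#'
#' @param table data.frame of per-block rows.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  for (j in which(num)) {
    out[[j]] <- vapply(out[[j]], function(x) {
      if (is.na(x)) NA_character_ else format(x, digits = 15, scientific = NA)
    }, character(1))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write to ", path)
  invisible(path)
}

#' Read a block results table written by [write_results()]
#'
#' @param path path to the TSV file.
#' @return data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
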