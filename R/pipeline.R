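#' End-to-end run configuration
#'
#' Declares every tunable constant of the pipeline in one place: the HBCGM
#' correlation cutoff (`p_cutoff = 0.01`), the number of PCs used as the PS
#' response (`n_pcs = 4`), the FDR level for the PS classification
#' (`q = 0.05`), the dataset QC settings, and the PC source matrix.
#'
#' @param p_cutoff block-phenotype ANOVA p-value cutoff for "correlated"
#'   blocks.
#' @param n_pcs number of retained principal components.
#' @param q FDR level for PS+/PS- classification.
#' @param pc_source `"GRM"` or `"IBS"`: matrix whose eigenvectors supply the
#'   PCs.
#' @param pc_scale PC score scaling, `"sqrt"` or `"raw"`.
#' @param statistic MANOVA statistic, `"Pillai"` or `"Wilks"`.
#' @param min_animals,qc_p_cutoff dataset QC settings (see [qc_dataset()]).
#' @param min_called minimum unambiguous calls per variant site.
#' @param apply_qc logical; gate datasets through [qc_dataset()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(p_cutoff = 0.01, n_pcs = 4L, q = 0.05,
                            pc_source = c("GRM", "IBS"),
                            pc_scale = c("sqrt", "raw"),
                            statistic = c("Pillai", "Wilks"),
                            min_animals = 5L, qc_p_cutoff = 1e-10,
                            min_called = 8L, apply_qc = TRUE) {
  structure(list(p_cutoff = p_cutoff, n_pcs = as.integer(n_pcs), q = q,
                 pc_source = match.arg(pc_source),
                 pc_scale = match.arg(pc_scale),
                 statistic = match.arg(statistic),
                 min_animals = min_animals, qc_p_cutoff = qc_p_cutoff,
                 min_called = as.integer(min_called),
                 apply_qc = isTRUE(apply_qc)),
            class = "pipeline_config")
}

#' Run the full block-mapping and PS-classification pipeline
#'
#' Executes, for each phenotype dataset: dataset QC; variant filtering to
#' the dataset's strains; maximal haplotype block construction; one-way
#' ANOVA of the phenotype across each block's haplotypes; selection of
#' correlated blocks (`p < p_cutoff`); GRM (or IBS) computation and PCA on
#' the dataset's strains; the PS MANOVA test on every correlated block;
#' Benjamini-Hochberg adjustment within the dataset's block family; and
#' PS+/PS- classification at FDR level `q`. All stages are deterministic
#' given their inputs.
#'
#' @param genotypes a [genotype_matrix()] for the full panel.
#' @param datasets a [phenotype_dataset()] or list of them.
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with elements `blocks` (the block
#'   results table across datasets), `summaries` (data.frame of
#'   [dataset_summary()] rows), `log` (per-stage counts).
#' @export
run_pipeline <- function(genotypes, datasets, config = pipeline_config()) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "pipeline_config"))
  if (inherits(datasets, "phenotype_dataset")) datasets <- list(datasets)
  block_rows <- list()
  summary_rows <- list()
  log <- list()
  for (ds in datasets) {
    id <- ds$dataset_id
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("[%s] stage '%s': %s", id, name, conditionMessage(e)),
             call. = FALSE)
      })
    }
    dropped <- setdiff(ds$data$strain, genotypes$strains)
    strains <- intersect(genotypes$strains, ds$data$strain)
    if (length(dropped)) {
      message(sprintf("[%s] dropping %d strain(s) without genotypes: %s",
                      id, length(dropped), paste(dropped, collapse = ", ")))
    }
    if (config$apply_qc) {
      qc <- stage("qc", qc_dataset(ds, min_animals = config$min_animals,
                                   p_cutoff = config$qc_p_cutoff,
                                   bulk = FALSE))
      if (!qc$accept) {
        summary_rows[[id]] <- data.frame(
          dataset_id = id, n_strains = length(strains), status = "rejected",
          reasons = paste(qc$reasons, collapse = ";"), total_blocks = 0L,
          ps_minus = 0L, ps_plus = 0L, percent_ps_minus = NA_real_,
          bin = NA_character_, stringsAsFactors = FALSE)
        log[[id]] <- list(qc = qc)
        next
      }
    }
    filt <- stage("filter_variants",
                  filter_variants(genotypes, strains,
                                  min_called = config$min_called))
    blocks <- stage("build_blocks", build_blocks(filt))
    assoc <- stage("block_anova", lapply(blocks, function(b) {
      tryCatch(block_anova(b, ds), error = function(e) NULL)
    }))
    ok <- !vapply(assoc, is.null, logical(1))
    assoc <- assoc[ok]
    correlated <- stage("select_correlated",
                        select_correlated(assoc, cutoff = config$p_cutoff))
    relmat <- stage("relationship_matrix",
                    if (config$pc_source == "GRM") compute_grm(filt)
                    else compute_ibs(filt))
    coords <- stage("pca", pca_coordinates(relmat,
                                           p = min(config$n_pcs,
                                                   length(strains)),
                                           scale = config$pc_scale))
    ps <- stage("ps_test",
                ps_test_blocks(lapply(correlated, function(r) r$block),
                               coords, q = config$q,
                               statistic = config$statistic))
    tab <- blocks_to_table(lapply(correlated, function(r) r$block),
                           strains = strains)
    if (nrow(tab)) {
      tab <- cbind(dataset_id = id, tab,
                   F_statistic = vapply(correlated, function(r)
                     r$F_statistic, numeric(1)),
                   p_hbcgm = vapply(correlated, function(r)
                     r$p_hbcgm, numeric(1)),
                   eta2 = vapply(correlated, function(r) r$eta2, numeric(1)),
                   k = vapply(correlated, function(r) r$k, integer(1)),
                   n = vapply(correlated, function(r) r$n, integer(1)),
                   ps)
      block_rows[[id]] <- tab
    }
    summ <- dataset_summary(id, length(strains), ps$ps_class)
    summary_rows[[id]] <- summ
    log[[id]] <- list(n_variants_filtered = n_variants(filt),
                      n_blocks = length(blocks),
                      n_scored = length(assoc),
                      n_correlated = length(correlated))
  }
  structure(list(blocks = if (length(block_rows))
                   do.call(rbind, c(block_rows, make.row.names = FALSE))
                 else NULL,
                 summaries = do.call(rbind, c(summary_rows,
                                              make.row.names = FALSE)),
                 log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d dataset(s), %d correlated block row(s)\n",
              nrow(x$summaries), if (is.null(x$blocks)) 0L else nrow(x$blocks)))
  print(x$summaries)
  invisible(x)
}

#' Summarize the PS composition of one dataset
#'
#' Counts PS+/PS- calls among a dataset's correlated blocks and bins the
#' PS- percentage into the conventional reporting bins 0-24, 25-49, 50-74
#' and 75-100 (left-closed; a dataset with exactly 50% PS- blocks falls in
#' 50-74).
#'
#' @param dataset_id identifier.
#' @param n_strains number of strains analyzed.
#' @param ps_class character vector of `"PS+"` / `"PS-"` calls.
#' @return one-row data.frame with columns `dataset_id`, `n_strains`,
#'   `status`, `reasons`, `total_blocks`, `ps_minus`, `ps_plus`,
#'   `percent_ps_minus`, `bin`.
#' @export
dataset_summary <- function(dataset_id, n_strains, ps_class) {
  total <- length(ps_class)
  minus <- sum(ps_class == "PS-")
  plus <- total - minus
  pct <- if (total > 0) 100 * minus / total else NA_real_
  data.frame(dataset_id = dataset_id, n_strains = as.integer(n_strains),
             status = "analyzed", reasons = "",
             total_blocks = total, ps_minus = minus, ps_plus = plus,
             percent_ps_minus = pct, bin = ps_bin(pct),
             stringsAsFactors = FALSE)
}

#' Bin a PS- percentage
#'
#' @param pct percentage in `[0, 100]` (NA allowed).
#' @return bin label among `"0-24"`, `"25-49"`, `"50-74"`, `"75-100"`.
#' @export
ps_bin <- function(pct) {
  labs <- c("0-24", "25-49", "50-74", "75-100")
  out <- rep(NA_character_, length(pct))
  ok <- !is.na(pct)
  out[ok] <- labs[pmin(findInterval(pct[ok], c(0, 25, 50, 75)), 4L)]
  out
}

#' Aggregate dataset summaries by strain count
#'
#' For each distinct number of analyzed strains: the mean numbers of total,
#' PS- and PS+ correlated blocks, and quartiles/median of the PS-
#' percentage, mirroring the box-plot summaries conventionally used to show
#' how the PS burden grows with panel size.
#'
#' @param summaries data.frame of [dataset_summary()] rows (rejected
#'   datasets are ignored).
#' @return data.frame with one row per strain count.
#' @export
summarize_vs_strain_count <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  s <- summaries[summaries$status == "analyzed", , drop = FALSE]
  out <- lapply(split(s, s$n_strains), function(d) {
    qs <- stats::quantile(d$percent_ps_minus, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(n_strains = d$n_strains[1], n_datasets = nrow(d),
               mean_total_blocks = mean(d$total_blocks),
               mean_ps_minus = mean(d$ps_minus),
               mean_ps_plus = mean(d$ps_plus),
               pct_ps_minus_q25 = unname(qs[1]),
               pct_ps_minus_median = unname(qs[2]),
               pct_ps_minus_q75 = unname(qs[3]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$n_strains), , drop = FALSE]
}

#' Label blocks with genes from a BED file
#'
#' Reads gene intervals from a BED file (0-based half-open; converted to
#' 1-based closed on import) and assigns to each block the name of the first
#' overlapping gene interval, or `NA`.
#'
#' @param block_table data.frame with `chrom`, `start_bp`, `end_bp` columns
#'   (as from [blocks_to_table()]).
#' @param bed_path path to a BED file with at least 4 columns
#'   (chrom, start, end, name).
#' @return `block_table` with a `gene` column appended.
#' @export
label_blocks_with_genes <- function(block_table, bed_path) {
  stopifnot(is.data.frame(block_table))
  if (!file.exists(bed_path)) stop("file not found: ", bed_path)
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE)) {
    stop("gene labeling requires the rtracklayer and GenomicRanges packages")
  }
  genes <- rtracklayer::import(bed_path, format = "BED")
  block_table$gene <- NA_character_
  if (!nrow(block_table)) return(block_table)
  blocks_gr <- GenomicRanges::GRanges(
    block_table$chrom,
    IRanges::IRanges(block_table$start_bp, block_table$end_bp))
  hits <- GenomicRanges::findOverlaps(blocks_gr, genes, select = "first")
  has <- !is.na(hits)
  block_table$gene[has] <- as.character(genes$name[hits[has]])
  block_table
}
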