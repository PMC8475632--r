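#' Per-strain phenotype dataset
#'
#' Mirrors the record layout of Mouse Phenome Database style strain surveys:
#' one row per strain with the mean measured value, its standard deviation and
#' the number of animals measured, plus (optionally) the individual replicate
#' values each summary was computed from. Categorical phenotypes (e.g. retinal
#' degeneration present/absent) carry integer-coded class labels as values.
#'
#' @param strain character vector of unique strain names.
#' @param mean numeric per-strain mean value (or integer class code).
#' @param sd numeric per-strain standard deviation, `>= 0`.
#' @param nindiv integer number of animals per strain, `>= 1`.
#' @param replicates optional named list (one element per strain) of numeric
#'   replicate-level values.
#' @param dataset_id dataset identifier.
#' @param sex one of `"F"`, `"M"`, `"both"`.
#' @param categorical logical; `TRUE` when values are integer-coded classes.
#'
#' @return An object of class `phenotype_dataset` with elements `data`
#'   (data.frame `strain`, `mean`, `sd`, `nindiv`), `replicates`,
#'   `dataset_id`, `sex`, `categorical`.
#' @export
phenotype_dataset <- function(strain, mean, sd, nindiv, replicates = NULL,
                              dataset_id = "dataset", sex = "both",
                              categorical = FALSE) {
  strain <- as.character(strain)
  if (!length(strain)) stop("phenotype dataset is empty")
  if (anyDuplicated(strain)) {
    stop("duplicate strain names in phenotype dataset: ",
         paste(unique(strain[duplicated(strain)]), collapse = ", "))
  }
  mean <- as.numeric(mean); sd <- as.numeric(sd); nindiv <- as.integer(nindiv)
  if (length(mean) != length(strain) || length(sd) != length(strain) ||
      length(nindiv) != length(strain)) {
    stop("strain, mean, sd, nindiv must have equal length")
  }
  if (anyNA(mean)) stop("non-numeric or missing mean value")
  if (any(is.na(sd) | sd < 0)) stop("sd must be numeric and >= 0")
  if (any(is.na(nindiv) | nindiv < 1L)) stop("nindiv must be >= 1")
  sex <- match.arg(sex, c("both", "F", "M"))
  if (!is.null(replicates)) {
    if (is.null(names(replicates)) || !setequal(names(replicates), strain)) {
      stop("replicates must be a list named by strain")
    }
    replicates <- replicates[strain]
  }
  structure(
    list(data = data.frame(strain = strain, mean = mean, sd = sd,
                           nindiv = nindiv, stringsAsFactors = FALSE),
         replicates = replicates, dataset_id = as.character(dataset_id),
         sex = sex, categorical = isTRUE(categorical)),
    class = "phenotype_dataset"
  )
}

#' @export
print.phenotype_dataset <- function(x, ...) {
  cat(sprintf("phenotype_dataset '%s' (sex %s%s): %d strains%s\n",
              x$dataset_id, x$sex,
              if (x$categorical) ", categorical" else "",
              nrow(x$data),
              if (is.null(x$replicates)) "" else ", with replicates"))
  invisible(x)
}

## Named vector of strain mean values.
strain_means <- function(pheno) {
  stats::setNames(pheno$data$mean, pheno$data$strain)
}
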