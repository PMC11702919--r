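# Core data containers: expression matrices and response-profile sets.

#' Create an expression matrix with sample metadata
#'
#' Wraps a gene x sample matrix of counts (RNA-seq-like) or log-intensities
#' (microarray-like) together with a sample sheet. Gene and sample IDs must be
#' unique; counts must be non-negative integers.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs).
#' @param kind `"counts"` or `"intensity"`.
#' @param sample_sheet data.frame with one row per sample and columns
#'   `sample`, `dataset`, `condition`, `age_group`, `sex` (missing metadata
#'   columns are filled with `NA`).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, kind = c("counts", "intensity"),
                              sample_sheet = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values) || any(dim(values) == 0))
    abort_invalid("'values' must be a non-empty numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_invalid("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    abort_invalid("duplicate gene IDs")
  if (anyDuplicated(colnames(values)))
    abort_invalid("duplicate sample IDs")
  if (kind == "counts") {
    if (any(values < 0) || any(values != round(values)))
      abort_invalid("counts must be non-negative integers")
  }
  if (is.null(sample_sheet)) {
    sample_sheet <- data.frame(sample = colnames(values))
  }
  if (!"sample" %in% names(sample_sheet))
    abort_invalid("sample_sheet needs a 'sample' column")
  if (!setequal(sample_sheet$sample, colnames(values)))
    abort_invalid("sample_sheet samples do not match matrix columns")
  sample_sheet <- sample_sheet[match(colnames(values), sample_sheet$sample), ,
                               drop = FALSE]
  for (col in c("dataset", "condition", "age_group", "sex")) {
    if (!col %in% names(sample_sheet)) sample_sheet[[col]] <- NA_character_
  }
  rownames(sample_sheet) <- NULL
  structure(list(values = values, kind = kind, sample_sheet = sample_sheet),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s): %d genes x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Create a response-profile set
#'
#' The pipeline's central input: one log fold change (post vs. baseline)
#' profile per dataset, as a genes x datasets matrix, with per-dataset
#' condition metadata.
#'
#' @param logfc numeric matrix, genes in rows, datasets in columns; all values
#'   finite.
#' @param dataset_meta data.frame with columns `dataset`, `condition`
#'   (and optionally `age_group`), one row per column of `logfc`.
#' @return an object of class `response_profile_set` with fields `logfc`,
#'   `dataset_meta` and `universe` (= rownames of `logfc`).
#' @export
response_profile_set <- function(logfc, dataset_meta) {
  if (!is.matrix(logfc) || !is.numeric(logfc))
    abort_invalid("'logfc' must be a numeric matrix")
  if (any(!is.finite(logfc))) abort_invalid("logfc values must be finite")
  if (is.null(rownames(logfc)) || anyDuplicated(rownames(logfc)))
    abort_invalid("logfc needs unique gene rownames")
  if (is.null(colnames(logfc)) || anyDuplicated(colnames(logfc)))
    abort_invalid("logfc needs unique dataset colnames")
  if (!all(c("dataset", "condition") %in% names(dataset_meta)))
    abort_invalid("dataset_meta needs 'dataset' and 'condition' columns")
  if (!setequal(dataset_meta$dataset, colnames(logfc)))
    abort_invalid("dataset_meta does not match logfc columns")
  if (any(is.na(dataset_meta$condition)))
    abort_invalid("every dataset needs a condition")
  dataset_meta <- dataset_meta[match(colnames(logfc), dataset_meta$dataset), ,
                               drop = FALSE]
  rownames(dataset_meta) <- NULL
  structure(list(logfc = logfc, dataset_meta = dataset_meta,
                 universe = rownames(logfc)),
            class = "response_profile_set")
}

#' @export
print.response_profile_set <- function(x, ...) {
  cat(sprintf("response_profile_set: %d genes x %d datasets (%s)\n",
              nrow(x$logfc), ncol(x$logfc),
              paste(sprintf("%d %s", table(x$dataset_meta$condition),
                            names(table(x$dataset_meta$condition))),
                    collapse = ", ")))
  invisible(x)
}

#' Read / write tab-separated expression matrices
#'
#' Matrices are written as TSV with gene IDs in the first column (`gene_id`)
#' and a header row of sample/dataset IDs. Reading enforces unique gene IDs
#' (duplicates are a hard error).
#'
#' @param path file path.
#' @return `read_matrix_tsv`: a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("file not found: %s", path))
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) abort_invalid("matrix TSV needs an ID column plus data")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate gene ID in %s: %s", path,
                 ids[duplicated(ids)][1]))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' @param x numeric matrix with gene rownames.
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
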