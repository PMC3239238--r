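#' Read a genes-by-samples expression matrix from TSV
#'
#' The expected layout is the field's usual one: a header row of sample
#' identifiers, a first column of gene identifiers, and a numeric body of
#' log2-scale intensities.  Missing measurements are marked with
#' `missing_token` (default `"NA"`).
#'
#' @param path path to a tab-separated file.
#' @param missing_token string marking a missing value in the body.
#' @return A numeric matrix with gene ids as row names and sample ids as
#'   column names; missing entries are `NA`.
#' @export
read_expression <- function(path, missing_token = "NA") {
  if (!file.exists(path)) stop_input("expression file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, na.strings = missing_token,
                      data.table = FALSE, check.names = FALSE),
    error = function(e) stop_input("malformed expression file ", path, ": ",
                                   conditionMessage(e)))
  if (ncol(dt) < 2L) stop_input("expression file ", path,
                                " needs a gene-id column and >= 1 sample column")
  gene_ids <- as.character(dt[[1L]])
  sample_ids <- colnames(dt)[-1L]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop_input("duplicated gene id(s): ",
                              paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop_input("duplicated sample id(s): ",
                              paste(unique(dup), collapse = ", "))
  body <- dt[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) &
                     !is.na(body[[j]]))[1L]
      stop_input("non-numeric value in column '", sample_ids[j], "'",
                 if (!is.na(bad)) paste0(", row '", gene_ids[bad], "'"))
    }
  }
  x <- as.matrix(body)
  dimnames(x) <- list(gene_ids, sample_ids)
  validate_expression(x)
  x
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits so that
#' `read_expression(write_expression(x))` restores `x` exactly.
#'
#' @param x numeric matrix, genes as rows.
#' @param path output path.
#' @param missing_token string used for `NA` entries.
#' @export
write_expression <- function(x, path, missing_token = "NA") {
  validate_expression(x)
  body <- matrix(sprintf("%.17g", x), nrow(x))
  body[is.na(x)] <- missing_token
  lines <- c(paste(c("gene_id", colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Validate an expression matrix
#'
#' @param x candidate matrix.
#' @return `x`, invisibly, after checking that it is numeric, has unique
#'   non-empty row and column names, and contains no non-finite values other
#'   than `NA`.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_input("expression data must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_input("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(x))) stop_input("gene ids must be unique")
  if (anyDuplicated(colnames(x))) stop_input("sample ids must be unique")
  if (any(!is.finite(x) & !is.na(x)))
    stop_input("expression values must be finite or NA")
  invisible(x)
}

#' Read a sample annotation table
#'
#' A TSV with columns `sample_id` and `class_label`, and optionally `site`
#' (anatomical site of the metastasis, used by the "same site" accuracy
#' category).
#'
#' @param path path to a tab-separated file.
#' @return A data.frame with columns `sample_id`, `class_label` and, when
#'   present in the file, `site`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_input("annotation file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "class_label") %in% colnames(dt)))
    stop_input("annotation file needs 'sample_id' and 'class_label' columns")
  validate_annotation(dt)
  dt
}

#' Write a sample annotation table as TSV
#' @param annot data.frame as returned by [read_annotation()].
#' @param path output path.
#' @export
write_annotation <- function(annot, path) {
  validate_annotation(annot)
  data.table::fwrite(annot, path, sep = "\t")
  invisible(path)
}

validate_annotation <- function(annot, expr = NULL) {
  if (!is.data.frame(annot) ||
      !all(c("sample_id", "class_label") %in% colnames(annot)))
    stop_input("annotation must be a data.frame with sample_id and class_label")
  if (anyDuplicated(annot$sample_id))
    stop_input("annotation has duplicated sample ids")
  if (any(is.na(annot$class_label) | !nzchar(annot$class_label)))
    stop_input("class labels must be non-empty")
  if (!is.null(expr)) {
    missing <- setdiff(annot$sample_id, colnames(expr))
    if (length(missing))
      stop_input("annotated sample(s) absent from expression matrix: ",
                 paste(head(missing, 5L), collapse = ", "))
  }
  invisible(annot)
}

#' Class taxonomy for relaxed accuracy categories
#'
#' Groups reference classes into organs (for the "similar" category: a lung
#' adenocarcinoma called as lung squamous-cell carcinoma is clinically
#' actionable) and maps metastasis sites to a representative reference class
#' (for the "same site" category).
#'
#' @param organ_group named character vector, class label -> organ group.
#' @param site_class named character vector, site label -> representative
#'   reference class.
#' @return An object of class `wagep_taxonomy`.
#' @export
taxonomy <- function(organ_group = character(), site_class = character()) {
  structure(list(organ_group = organ_group, site_class = site_class),
            class = "wagep_taxonomy")
}

#' Read a taxonomy from a YAML file
#'
#' The file holds two optional maps, `organ_group` (class -> group) and
#' `site_class` (site -> representative class).
#'
#' @param path path to a YAML file.
#' @return A `wagep_taxonomy`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop_input("taxonomy file not found: ", path)
  y <- yaml::read_yaml(path)
  taxonomy(organ_group = unlist(y$organ_group %||% list()),
           site_class = unlist(y$site_class %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
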