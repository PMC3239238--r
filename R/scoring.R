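#' Tissue-match scores for one query profile
#'
#' For every gene and every reference class, the tm-score measures how well
#' the query's expression value fits that class's reference distribution:
#' the class density is evaluated at the query value (linear interpolation
#' between grid points, 0 outside the grid span) and divided by the class's
#' modal density, giving a score in `[0, 1]` that is 1 exactly at the mode.
#'
#' Entries are `NA` (masked) where the model has no density for the
#' (gene, class) pair or the query value is missing.
#'
#' @param model a `wagep_ref`.
#' @param query named numeric vector, gene id -> expression value (same scale
#'   as the reference data).
#' @return Numeric matrix, model genes x classes, values in `[0, 1]` or `NA`.
#' @export
tm_score <- function(model, query) {
  stopifnot(inherits(model, "wagep_ref"))
  if (is.null(names(query))) stop_input("query must be a named vector")
  common <- intersect(model$gene_ids, names(query))
  if (!length(common)) stop_input("no overlap between query and model genes")
  genes <- model$gene_ids
  G <- length(genes)
  x <- setNames(rep(NA_real_, G), genes)
  x[common] <- query[common]
  if (any(!is.finite(x[common]) & !is.na(x[common])))
    stop_input("query values must be finite or NA")

  from <- model$from
  dx <- (model$to - from) / (model$n_grid - 1L)
  pos <- (x - from) / dx
  i <- pmin(pmax(floor(pos), 0), model$n_grid - 2L)
  frac <- pos - i
  inside <- !is.na(x) & x >= from & x <= model$to

  tm <- matrix(NA_real_, G, length(model$class_labels),
               dimnames = list(genes, model$class_labels))
  rows <- seq_len(G)
  for (cl in model$class_labels) {
    D <- model$dens[[cl]]
    val <- D[cbind(rows, i + 1L)] * (1 - frac) + D[cbind(rows, i + 2L)] * frac
    v <- ifelse(inside, pmin(val / model$mode[, cl], 1), 0)
    v[is.na(x)] <- NA_real_
    v[!model$eligible[, cl]] <- NA_real_
    tm[, cl] <- v
  }
  tm
}

#' Tissue-specificity scores from tm-scores
#'
#' The ts-score asks not just whether a gene's value fits a class, but
#' whether it fits that class *to the exclusion of the others*:
#' `ts(g, c) = tm(g, c) - max over other classes of tm(g, c')`.  It lives in
#' `[-1, 1]`: 1 means a perfect fit to this class and no fit anywhere else,
#' -1 means the gene fits anything but this class, 0 is indeterminate.
#' Genes with fewer than two unmasked classes are fully masked.
#'
#' @param tm matrix from [tm_score()].
#' @return Numeric matrix of the same shape, values in `[-1, 1]` or `NA`.
#' @export
ts_score <- function(tm) {
  if (!is.matrix(tm)) stop_input("tm must be a matrix")
  G <- nrow(tm)
  top1 <- rep(-Inf, G)
  top2 <- rep(-Inf, G)
  for (j in seq_len(ncol(tm))) {
    v <- tm[, j]
    v[is.na(v)] <- -Inf
    was_higher <- v > top1
    top2 <- ifelse(was_higher, top1, pmax(top2, v))
    top1 <- pmax(top1, v)
  }
  usable <- rowSums(!is.na(tm)) >= 2L
  ts <- tm
  for (j in seq_len(ncol(tm))) {
    competitor <- ifelse(!is.na(tm[, j]) & tm[, j] >= top1, top2, top1)
    ts[, j] <- ifelse(usable, tm[, j] - competitor, NA_real_)
  }
  ts
}
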