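#' Build the per-gene, per-class density reference model
#'
#' For every gene, all non-missing values across the cohort define one shared
#' evaluation grid; for every class with at least `min_class_n` non-missing
#' values for that gene a Gaussian kernel density estimate is placed on that
#' grid.  Genes with fewer than two eligible classes, or with fewer than two
#' distinct pooled values, are dropped (and recorded in `model$dropped`).
#'
#' @param expr numeric matrix, genes x samples (see [read_expression()]).
#' @param annot annotation data.frame with `sample_id`, `class_label`; every
#'   sample in `expr` must be annotated.
#' @param min_class_n minimum samples per (gene, class) for a density
#'   (default 6, the smallest class size worth modeling).
#' @param n_grid grid resolution (default 512).
#' @param pad_sd grid padding in pooled standard deviations (default 3).
#' @param grids optional fixed grids: a `wagep_ref` whose grids should be
#'   reused, or a list with named numeric vectors `from` and `to`.  Used for
#'   held-out refits, where densities are rebuilt on the full-cohort grids so
#'   that curves stay pointwise comparable across folds.
#' @return An object of class `wagep_ref`.
#' @export
build_reference <- function(expr, annot, min_class_n = 6L, n_grid = 512L,
                            pad_sd = 3, grids = NULL) {
  validate_expression(expr)
  validate_annotation(annot, expr)
  unannot <- setdiff(colnames(expr), annot$sample_id)
  if (length(unannot))
    stop_input("unannotated sample(s): ", paste(head(unannot, 5L), collapse = ", "))
  class_of <- setNames(annot$class_label, annot$sample_id)[colnames(expr)]
  classes <- sort(unique(unname(class_of)))
  G <- nrow(expr)

  counts <- vapply(classes, function(cl)
    rowSums(!is.na(expr[, class_of == cl, drop = FALSE])), numeric(G))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = G,
                                             dimnames = list(rownames(expr), classes))
  storage.mode(counts) <- "integer"
  eligible <- counts >= min_class_n

  rng_lo <- suppressWarnings(apply(expr, 1L, min, na.rm = TRUE))
  rng_hi <- suppressWarnings(apply(expr, 1L, max, na.rm = TRUE))
  degenerate <- !is.finite(rng_lo) | !is.finite(rng_hi) | rng_lo == rng_hi
  keep <- rowSums(eligible) >= 2L & !degenerate

  if (!is.null(grids)) {
    if (inherits(grids, "wagep_ref")) grids <- list(from = grids$from, to = grids$to)
    keep <- keep & rownames(expr) %in% names(grids$from)
  }
  dropped <- data.frame(
    gene_id = rownames(expr)[!keep],
    reason = ifelse(degenerate[!keep], "degenerate",
                    ifelse(rowSums(eligible)[!keep] < 2L, "fewer than 2 eligible classes",
                           "no grid supplied"))
  )
  genes <- rownames(expr)[keep]
  if (length(genes) < 1L)
    stop_input("empty model: no gene has >= 2 eligible classes")

  if (is.null(grids)) {
    pooled_sd <- apply(expr[genes, , drop = FALSE], 1L, sd, na.rm = TRUE)
    pad <- pad_sd * pooled_sd
    from <- setNames(rng_lo[keep] - pad, genes)
    to <- setNames(rng_hi[keep] + pad, genes)
  } else {
    from <- grids$from[genes]
    to <- grids$to[genes]
  }
  dx <- (to - from) / (n_grid - 1L)

  dens <- list()
  for (cl in classes) {
    vals <- expr[genes, class_of == cl, drop = FALSE]
    m <- kde_class(vals, from, dx, n_grid, min_class_n)
    rownames(m) <- genes
    dens[[cl]] <- m
  }
  mode_mat <- vapply(classes, function(cl)
    suppressWarnings(apply(dens[[cl]], 1L, max)), numeric(length(genes)))
  dimnames(mode_mat) <- list(genes, classes)

  structure(list(
    gene_ids = genes, class_labels = classes,
    from = from, to = to, n_grid = as.integer(n_grid),
    dens = dens, mode = mode_mat,
    n_samples = counts[genes, , drop = FALSE],
    eligible = eligible[genes, , drop = FALSE],
    dropped = dropped,
    config = list(min_class_n = as.integer(min_class_n),
                  n_grid = as.integer(n_grid), pad_sd = pad_sd,
                  bw_rule = "silverman")
  ), class = "wagep_ref")
}

#' @export
print.wagep_ref <- function(x, ...) {
  cat(sprintf(paste0("<wagep_ref> %d genes x %d classes, grid %d points, ",
                     "min_class_n=%d (%d gene(s) dropped)\n"),
              length(x$gene_ids), length(x$class_labels), x$n_grid,
              x$config$min_class_n, nrow(x$dropped)))
  invisible(x)
}

#' Query availability of a (gene, class) density
#' @param model a `wagep_ref`.
#' @param gene gene id.
#' @param class class label.
#' @return `TRUE` if the model holds a density for the pair.
#' @export
has_density <- function(model, gene, class) {
  gene %in% model$gene_ids && class %in% model$class_labels &&
    model$eligible[gene, class]
}

#' Extract one (gene, class) density from a model
#' @inheritParams has_density
#' @return A `wagep_density`, or `NULL` when the pair is absent.
#' @export
ref_density <- function(model, gene, class) {
  if (!has_density(model, gene, class)) return(NULL)
  structure(list(
    grid = seq(model$from[gene], model$to[gene], length.out = model$n_grid),
    density = model$dens[[class]][gene, ],
    n_samples = unname(model$n_samples[gene, class]),
    bw = NA_real_), class = "wagep_density")
}

#' Serialize a reference model to disk
#'
#' Uses R's native serialization, which round-trips every grid, density
#' array, label and configuration field losslessly.
#'
#' @param model a `wagep_ref`.
#' @param path output path (conventionally `*.wagep`).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "wagep_ref"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()` returns the deserialized `wagep_ref`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_input("model file not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "wagep_ref")) stop_input("not a wagep reference model: ", path)
  model
}
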