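#' Gene-uniqueness weight for one gene and one class
#'
#' The weight is the area by which the target class's density exceeds the
#' best competing density, taken over the region where the target is strictly
#' the highest: with `f` the target density and `g` the pointwise maximum of
#' all other classes' densities, the weight is the trapezoidal integral of
#' `(f - g)` where `f > g`.  Since every density integrates to 1, the result
#' lies in `[0, 1]`: 0 for a gene whose expression is indistinguishable
#' between classes, approaching 1 when the class's expression range is
#' entirely its own.
#'
#' @param densities named list of `wagep_density` objects, one per class, all
#'   on the same grid.
#' @param target_class name of the class to weigh.
#' @return A single number in `[0, 1]`.
#' @export
gene_weight <- function(densities, target_class) {
  if (length(densities) < 2L)
    stop_input("gene weight needs >= 2 classes, got ", length(densities))
  if (!target_class %in% names(densities))
    stop_input("target class '", target_class, "' not among densities")
  grid <- densities[[1L]]$grid
  for (d in densities)
    if (!isTRUE(all.equal(d$grid, grid)))
      stop_input("densities must share one grid")
  f <- densities[[target_class]]$density
  others <- setdiff(names(densities), target_class)
  g <- Reduce(pmax, lapply(densities[others], `[[`, "density"))
  excess <- f - g
  excess[excess < 0] <- 0
  clamp_weight(trapz(grid, excess))
}

clamp_weight <- function(w) {
  if (any(w < -1e-6 | w > 1 + 1e-6, na.rm = TRUE))
    stop("internal error: weight outside [0,1] beyond numerical tolerance")
  pmin(pmax(w, 0), 1)
}

#' Gene-uniqueness weights for a whole reference model
#'
#' Applies [gene_weight()] to every available (gene, class) pair, vectorized
#' over genes.  Weights depend on the reference densities only, never on a
#' query.
#'
#' @param model a `wagep_ref`.
#' @return Numeric matrix, genes x classes, in `[0, 1]`; `NA` where the model
#'   has no density for the pair.  The model is recorded in attribute
#'   `"provenance"` as a digest of its dimensions.
#' @export
weight_matrix <- function(model) {
  stopifnot(inherits(model, "wagep_ref"))
  classes <- model$class_labels
  genes <- model$gene_ids
  dx <- (model$to - model$from) / (model$n_grid - 1L)
  W <- matrix(NA_real_, length(genes), length(classes),
              dimnames = list(genes, classes))
  K <- length(classes)
  # Densities are non-negative, so an absent (NA) competitor can be treated
  # as a zero curve: it never raises the pointwise competitor maximum, and
  # genes left without a real competitor are masked below anyway.  Prefix /
  # suffix running maxima give every class's competitor max in O(K) passes.
  zero <- function(m) { if (anyNA(m)) m[is.na(m)] <- 0; m }
  d0 <- lapply(model$dens, zero)
  prefix <- vector("list", K)
  suffix <- vector("list", K)
  acc <- NULL
  for (k in seq_len(K)) {
    prefix[k] <- list(acc)
    acc <- if (is.null(acc)) d0[[k]] else pmax(acc, d0[[k]])
  }
  acc <- NULL
  for (k in rev(seq_len(K))) {
    suffix[k] <- list(acc)
    acc <- if (is.null(acc)) d0[[k]] else pmax(acc, d0[[k]])
  }
  for (k in seq_len(K)) {
    cl <- classes[k]
    M <- if (is.null(prefix[[k]])) suffix[[k]]
         else if (is.null(suffix[[k]])) prefix[[k]]
         else pmax(prefix[[k]], suffix[[k]])
    y <- d0[[k]] - M
    y[y < 0] <- 0
    w <- dx * (rowSums(y) - 0.5 * (y[, 1L] + y[, ncol(y)]))
    w[!model$eligible[, cl]] <- NA_real_
    # genes whose only eligible class is cl have no competitor in this fold
    w[model$eligible[, cl] & rowSums(model$eligible) < 2L] <- NA_real_
    W[, cl] <- clamp_weight(w)
  }
  attr(W, "provenance") <- sprintf("wagep_ref:%dgx%dc:grid%d", length(genes),
                                   length(classes), model$n_grid)
  W
}

#' Class-specific genes by weight threshold
#'
#' @param weights matrix from [weight_matrix()].
#' @param class class label.
#' @param threshold minimum weight; genes with weight strictly above it are
#'   returned (default 0.25).
#' @return Character vector of gene ids, ordered by decreasing weight.
#' @export
specific_genes <- function(weights, class, threshold = 0.25) {
  if (!class %in% colnames(weights))
    stop_input("class '", class, "' not in weight matrix")
  w <- weights[, class]
  sel <- which(!is.na(w) & w > threshold)
  names(sort(w[sel], decreasing = TRUE))
}
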