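#' Shared evaluation grid for one gene
#'
#' All classes' densities for a gene are evaluated on one common grid so that
#' they can be compared pointwise (the uniqueness weight is an area between
#' curves).  The grid spans the pooled value range padded by `pad_sd` pooled
#' standard deviations on each side, wide enough that Gaussian-kernel tails
#' are negligible outside it.
#'
#' @param pooled_values all non-missing values of the gene across all classes.
#' @param n_grid number of grid points (default 512).
#' @param pad_sd padding on each side, in pooled standard deviations.
#' @return Strictly increasing numeric vector of length `n_grid`.
#' @export
shared_grid <- function(pooled_values, n_grid = 512L, pad_sd = 3) {
  v <- pooled_values[!is.na(pooled_values)]
  if (length(unique(v)) < 2L)
    stop_input("degenerate gene: fewer than 2 distinct pooled values")
  pad <- pad_sd * sd(v)
  seq(min(v) - pad, max(v) + pad, length.out = n_grid)
}

#' Gaussian kernel density estimate on a fixed grid
#'
#' One gene, one class.  The bandwidth defaults to Silverman's rule of thumb
#' per (gene, class), floored at one grid spacing so that tied value sets
#' still yield a proper density.  The curve is renormalized so its
#' trapezoidal integral over the grid is exactly 1.
#'
#' @param values the class's non-missing expression values for the gene.
#' @param grid evaluation grid from [shared_grid()] (uniformly spaced).
#' @param min_n minimum number of values required (default 6).
#' @param bw optional bandwidth override.
#' @return An object of class `wagep_density`: list with `grid`, `density`,
#'   `n_samples` and `bw`.
#' @export
estimate_density <- function(values, grid, min_n = 6L, bw = NULL) {
  v <- values[!is.na(values)]
  if (length(v) < min_n)
    stop_input("insufficient samples: ", length(v), " < ", min_n)
  if (any(!is.finite(v))) stop_input("values must be finite")
  dx <- (grid[length(grid)] - grid[1L]) / (length(grid) - 1L)
  if (is.null(bw)) bw <- silverman_bw(v, floor_bw = dx)
  dens <- .kde_batch_cpp(matrix(v, nrow = 1L), grid[1L], dx,
                         length(grid), bw, as.integer(min_n))[1L, ]
  structure(list(grid = grid, density = dens, n_samples = length(v), bw = bw),
            class = "wagep_density")
}

#' @export
print.wagep_density <- function(x, ...) {
  cat(sprintf("<wagep_density> n=%d, bw=%.4g, grid [%.3g, %.3g] x %d\n",
              x$n_samples, x$bw, x$grid[1L], x$grid[length(x$grid)],
              length(x$grid)))
  invisible(x)
}

# Batched KDE for all genes of one class: vals is genes x samples with NAs,
# grids given by from/dx per gene.  Bandwidths are Silverman per gene,
# floored at that gene's grid spacing.  Returns genes x n_grid, NA rows where
# fewer than min_n usable values.
kde_class <- function(vals, from, dx, n_grid, min_n) {
  bw <- vapply(seq_len(nrow(vals)), function(g) {
    v <- vals[g, ]
    v <- v[!is.na(v)]
    if (length(v) < min_n) return(NA_real_)
    silverman_bw(v, floor_bw = dx[g])
  }, numeric(1))
  .kde_batch_cpp(vals, from, dx, as.integer(n_grid), bw, as.integer(min_n))
}
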