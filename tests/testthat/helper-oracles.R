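# Independent brute-force oracles.  These deliberately avoid the package's
# computational paths (vectorized weight matrices, batched C++ KDE, index
# interpolation) and recompute everything with elementary R code.

# Fine-grid quadrature of the uniqueness weight for analytic Gaussian
# classes: integral of (f_target - max others)+ over [lo, hi].
oracle_gaussian_weight <- function(means, sds, target, lo, hi, n = 51200L) {
  x <- seq(lo, hi, length.out = n)
  f <- dnorm(x, means[target], sds[target])
  others <- setdiff(seq_along(means), target)
  g <- rep(0, n)
  for (k in others) g <- pmax(g, dnorm(x, means[k], sds[k]))
  y <- f - g
  y[y < 0] <- 0
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Sliding-window accuracy curve by explicit looping.
oracle_window_curve <- function(scores, correct, width, step) {
  lefts <- seq(min(scores), max(scores), by = step)
  out <- data.frame(window_left = lefts, n = NA_integer_, accuracy = NA_real_)
  for (i in seq_along(lefts)) {
    sel <- which(scores >= lefts[i] & scores < lefts[i] + width)
    out$n[i] <- length(sel)
    out$accuracy[i] <- if (length(sel)) mean(correct[sel]) else NA_real_
  }
  out
}

# Full re-derivation of one leave-one-out fold: KDE for every (gene, class)
# without the held-out sample, uniqueness weights by per-gene looping,
# tm via stats::approx, ts by explicit competitor scan, weighted and
# unweighted similarity, argmax with lexicographic tie-break.
oracle_fold_predict <- function(expr, class_of, held_out, from, to,
                                n_grid = 512L, min_class_n = 6L) {
  genes <- rownames(expr)
  classes <- sort(unique(unname(class_of)))
  keep <- setdiff(colnames(expr), held_out)
  silverman <- function(v, floor_bw) {
    s <- min(sd(v), diff(quantile(v, c(.25, .75), names = FALSE)) / 1.34)
    if (!is.finite(s) || s <= 0) s <- 0
    max(0.9 * s * length(v)^(-1/5), floor_bw)
  }
  best_of <- function(scores) {
    ord <- order(-scores$s, scores$cl)
    scores$cl[ord[1]]
  }
  tsw <- list()  # per class: vectors of ts and w over usable genes
  for (cl in classes) tsw[[cl]] <- list(ts = numeric(0), w = numeric(0))
  for (g in genes) {
    grid <- seq(from[g], to[g], length.out = n_grid)
    dx <- grid[2] - grid[1]
    dens <- list()
    for (cl in classes) {
      v <- expr[g, keep[class_of[keep] == cl]]
      v <- v[!is.na(v)]
      if (length(v) < min_class_n) next
      bw <- silverman(v, dx)
      d <- rowSums(dnorm(outer(grid, v, "-") / bw)) / (length(v) * bw)
      dens[[cl]] <- d / sum(diff(grid) * (d[-1] + d[-n_grid]) / 2)
    }
    if (length(dens) < 2L) next
    x <- expr[g, held_out]
    if (is.na(x)) next
    tm <- vapply(dens, function(d) {
      v <- approx(grid, d, xout = x, yleft = 0, yright = 0)$y
      min(v / max(d), 1)
    }, numeric(1))
    for (cl in names(dens)) {
      others <- setdiff(names(dens), cl)
      g_curve <- Reduce(pmax, dens[others])
      y <- dens[[cl]] - g_curve
      y[y < 0] <- 0
      w <- sum(diff(grid) * (y[-1] + y[-n_grid]) / 2)
      ts <- tm[[cl]] - max(tm[others])
      tsw[[cl]]$ts <- c(tsw[[cl]]$ts, ts)
      tsw[[cl]]$w <- c(tsw[[cl]]$w, w)
    }
  }
  sw <- data.frame(cl = names(tsw),
                   s = vapply(tsw, function(z) sum(z$ts * z$w) / sum(z$w),
                              numeric(1)))
  su <- data.frame(cl = names(tsw),
                   s = vapply(tsw, function(z) mean(z$ts), numeric(1)))
  list(best_weighted = best_of(sw), best_unweighted = best_of(su))
}
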