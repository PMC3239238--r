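#' Leave-one-out cross-validation of a labeled cohort
#'
#' Every sample is held out in turn; its class's densities (and, by default,
#' the whole weight matrix, which derives from the densities) are rebuilt
#' without it before the sample is scored and classified against all classes.
#' Evaluation grids are fixed from the full cohort so that only the held-out
#' sample's class changes between folds.  Samples whose class would fall
#' below `min_class_n` after holdout are skipped with a logged reason.
#'
#' @param expr genes x samples matrix.
#' @param annot annotation covering every sample (`sample_id`, `class_label`,
#'   optional `site`).
#' @param min_class_n,n_grid,pad_sd passed to [build_reference()].
#' @param recompute_weights rebuild the weight matrix inside every fold
#'   (default `TRUE`); `FALSE` freezes the full-cohort weights for speed.
#' @param acceptance which categories count as correct: `"exact_or_similar"`
#'   (default) or `"exact"`.
#' @param taxonomy optional [taxonomy()] for the relaxed categories.
#' @param tiers reliability thresholds, see [reliability_tier()].
#' @return A data.frame of class `wagep_cohort`, one row per scored sample,
#'   with the truth label, best/second classes and scores for the weighted
#'   and unweighted (`*_unw`) routes, accuracy categories, reliability tier,
#'   and `correct`/`correct_unw` indicators under the chosen acceptance.
#'   Attributes: `acceptance`, `skipped` (data.frame), `config`,
#'   `accuracy` and `accuracy_unweighted`.
#' @export
loocv <- function(expr, annot, min_class_n = 6L, n_grid = 512L, pad_sd = 3,
                  recompute_weights = TRUE,
                  acceptance = c("exact_or_similar", "exact"),
                  taxonomy = NULL, tiers = c(high = 0.10, medium = 0.05)) {
  acceptance <- match.arg(acceptance)
  accepted <- if (acceptance == "exact") "exact" else c("exact", "similar")
  model <- build_reference(expr, annot, min_class_n = min_class_n,
                           n_grid = n_grid, pad_sd = pad_sd)
  w_frozen <- if (!recompute_weights) weight_matrix(model) else NULL
  class_of <- setNames(annot$class_label, annot$sample_id)
  site_of <- if ("site" %in% colnames(annot))
    setNames(annot$site, annot$sample_id) else NULL
  dx <- (model$to - model$from) / (model$n_grid - 1L)

  rows <- list()
  skipped <- list()
  for (s in colnames(expr)) {
    cl <- class_of[[s]]
    members <- colnames(expr)[class_of[colnames(expr)] == cl]
    if (length(members) - 1L < min_class_n) {
      skipped[[s]] <- sprintf("class '%s' would fall below min_class_n", cl)
      next
    }
    fold <- model
    vals <- expr[model$gene_ids, setdiff(members, s), drop = FALSE]
    m <- kde_class(vals, model$from, dx, model$n_grid, min_class_n)
    rownames(m) <- model$gene_ids
    fold$dens[[cl]] <- m
    fold$n_samples[, cl] <- as.integer(rowSums(!is.na(vals)))
    fold$eligible[, cl] <- fold$n_samples[, cl] >= min_class_n
    fold$mode[, cl] <- suppressWarnings(apply(m, 1L, max))

    w <- if (recompute_weights) weight_matrix(fold) else w_frozen
    tm <- tm_score(fold, expr[model$gene_ids, s])
    ts <- ts_score(tm)
    site <- if (!is.null(site_of)) site_of[[s]] else NULL
    res_w <- classify(similarity(ts, w), truth = cl, taxonomy = taxonomy,
                      site = site, tiers = tiers)
    res_u <- classify(unweighted_similarity(ts), truth = cl,
                      taxonomy = taxonomy, site = site, tiers = tiers)
    second <- function(r) if (nrow(r$ranking) > 1L)
      c(r$ranking$class_label[2L], r$ranking$score[2L]) else c(NA, NA)
    sw <- second(res_w)
    rows[[s]] <- data.frame(
      sample_id = s, truth = cl,
      best = res_w$best_class, best_score = res_w$best_score,
      second = sw[1L], second_score = as.numeric(sw[2L]),
      category = res_w$category, tier = res_w$tier,
      n_ref = unname(fold$n_samples[1L, cl]),
      best_unw = res_u$best_class, best_score_unw = res_u$best_score,
      category_unw = res_u$category,
      correct = res_w$category %in% accepted,
      correct_unw = res_u$category %in% accepted)
  }
  if (!length(rows)) stop_input("no sample could be scored")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("wagep_cohort", "data.frame")
  attr(out, "acceptance") <- acceptance
  attr(out, "skipped") <- data.frame(
    sample_id = names(skipped),
    reason = as.character(unlist(skipped, use.names = FALSE)))
  attr(out, "config") <- list(min_class_n = min_class_n, n_grid = n_grid,
                              pad_sd = pad_sd,
                              recompute_weights = recompute_weights)
  attr(out, "accuracy") <- mean(out$correct)
  attr(out, "accuracy_unweighted") <- mean(out$correct_unw)
  out
}

#' Per-class accuracy, sensitivity and specificity
#'
#' Sensitivity of a class is the fraction of its samples classified
#' correctly (under the cohort's acceptance rule); specificity is one minus
#' the fraction of other-class samples that were predicted as this class.
#' The final row gives the totals: overall accuracy and the unweighted
#' averages of sensitivity and specificity across classes.
#'
#' @param cohort a `wagep_cohort` from [loocv()], or any data.frame with
#'   columns `truth`, `best`, `correct`.
#' @return A data.frame with columns `class_label`, `n`, `n_correct`,
#'   `percent_correct`, `sensitivity`, `specificity`.
#' @export
per_class_metrics <- function(cohort) {
  need <- c("truth", "best", "correct")
  if (!all(need %in% colnames(cohort)))
    stop_input("cohort must have columns ", paste(need, collapse = ", "))
  classes <- sort(unique(cohort$truth))
  rows <- lapply(classes, function(cl) {
    in_c <- cohort$truth == cl
    sens <- sum(cohort$correct[in_c]) / sum(in_c)
    spec <- 1 - sum(cohort$best[!in_c] == cl) / sum(!in_c)
    data.frame(class_label = cl, n = sum(in_c),
               n_correct = sum(cohort$correct[in_c]),
               percent_correct = 100 * sens,
               sensitivity = sens, specificity = spec)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(class_label = "Total/average", n = nrow(cohort),
                      n_correct = sum(cohort$correct),
                      percent_correct = 100 * mean(cohort$correct),
                      sensitivity = mean(out$sensitivity),
                      specificity = mean(out$specificity))
  rbind(out, total)
}

#' Accuracy as a function of best-hit similarity (sliding window)
#'
#' A window of width `width` (in similarity units) slides along the score
#' axis in steps of `step`, starting at the observed minimum best score;
#' within each window `[s, s + width)` the fraction of correct calls among
#' samples whose best score falls in the window is recorded.  Empty windows
#' carry count 0 and `NA` accuracy.
#'
#' @param cohort a `wagep_cohort`, or a data.frame with columns `best_score`
#'   and `correct`.
#' @param width window width in similarity units (default 0.1).
#' @param step slide step (default 0.005).
#' @return A data.frame of class `wagep_curve` with columns `window_left`,
#'   `n`, `accuracy`.
#' @export
accuracy_curve <- function(cohort, width = 0.1, step = 0.005) {
  if (!is_scalar_number(width) || width <= 0) stop_input("width must be > 0")
  if (!is_scalar_number(step) || step <= 0) stop_input("step must be > 0")
  s <- cohort$best_score
  if (!length(s)) stop_input("no samples with a best score")
  lefts <- seq(min(s), max(s), by = step)
  n <- vapply(lefts, function(l) sum(s >= l & s < l + width), integer(1))
  acc <- vapply(seq_along(lefts), function(i) {
    if (n[i] == 0L) return(NA_real_)
    in_w <- s >= lefts[i] & s < lefts[i] + width
    mean(cohort$correct[in_w])
  }, numeric(1))
  out <- data.frame(window_left = lefts, n = n, accuracy = acc)
  class(out) <- c("wagep_curve", "data.frame")
  out
}

#' Fraction of samples above a score threshold, and their accuracy
#'
#' @param cohort a `wagep_cohort`, or a data.frame with `best_score` and
#'   `correct`.
#' @param threshold best-score cutoff (inclusive).
#' @return A list with `fraction` (of samples at/above the threshold),
#'   `accuracy` among them (`NA` when none qualify), and `n`.
#' @export
threshold_accuracy <- function(cohort, threshold) {
  if (!is_scalar_number(threshold)) stop_input("threshold must be finite")
  sel <- cohort$best_score >= threshold
  list(fraction = mean(sel),
       accuracy = if (any(sel)) mean(cohort$correct[sel]) else NA_real_,
       n = sum(sel))
}

#' Specific-expression retention report for one class
#'
#' Selects the class's specific genes (uniqueness weight strictly above
#' `weight_threshold`), keeps those measured in every query, and reports the
#' unweighted ts-scores of each retained gene in each query.  Query columns
#' are ordered by decreasing weighted similarity to the class, so loss of
#' class-specific expression (e.g. metastatic dedifferentiation) shows up as
#' ts-scores dropping left to right and gene by gene.
#'
#' @param model a `wagep_ref`.
#' @param weights matrix from [weight_matrix()].
#' @param queries genes x samples matrix of query profiles.
#' @param class reference class to report on.
#' @param weight_threshold minimum gene weight (default 0.25).
#' @return Numeric matrix of ts-scores, selected genes x queries (columns
#'   ordered by similarity to `class`), with attributes `similarity` (named
#'   vector) and `class`.
#' @export
gene_retention <- function(model, weights, queries, class,
                           weight_threshold = 0.25) {
  if (!class %in% model$class_labels)
    stop_input("class '", class, "' not in model")
  sel <- specific_genes(weights, class, weight_threshold)
  if (!length(sel))
    stop_input("empty selection: no gene with weight > ", weight_threshold,
               " in class '", class, "'")
  present <- sel[sel %in% rownames(queries)]
  present <- present[rowSums(is.na(queries[present, , drop = FALSE])) == 0L]
  if (!length(present))
    stop_input("empty selection: no specific gene measured in all queries")
  scores <- matrix(NA_real_, length(present), ncol(queries),
                   dimnames = list(present, colnames(queries)))
  sims <- setNames(numeric(ncol(queries)), colnames(queries))
  for (q in colnames(queries)) {
    ts <- ts_score(tm_score(model, queries[, q]))
    scores[, q] <- ts[present, class]
    sim <- similarity(ts, weights)
    sims[q] <- sim$score[sim$class_label == class]
  }
  ord <- order(-sims)
  scores <- scores[, ord, drop = FALSE]
  attr(scores, "similarity") <- sims[ord]
  attr(scores, "class") <- class
  scores
}
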