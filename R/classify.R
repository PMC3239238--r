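#' Weighted per-class similarity scores
#'
#' The similarity between a query and a class is the weight-weighted mean of
#' the query's ts-scores for that class: each gene's ts-score is multiplied
#' by the gene's uniqueness weight for the class, and the result is
#' normalized by the mean weight of the class (which compensates for classes
#' possessing different numbers of specific genes).  Algebraically
#' `mean(ts * w) / mean(w) = sum(ts * w) / sum(w)`, the form computed here.
#' Genes masked in either input are excluded.  A class whose mean weight over
#' usable genes is below `eps` falls back to the unweighted mean of its
#' ts-scores, with `fallback = TRUE`.
#'
#' @param ts matrix from [ts_score()].
#' @param w matrix from [weight_matrix()] on the same gene/class axes, or
#'   `NULL` for unit weights.
#' @param eps minimum mean weight for the weighted formula (default 1e-6).
#' @return A data.frame of class `wagep_similarity` with columns
#'   `class_label`, `score`, `n_genes`, `fallback`, one row per class that
#'   had at least one usable gene.
#' @export
similarity <- function(ts, w = NULL, eps = 1e-6) {
  if (!is.matrix(ts)) stop_input("ts must be a matrix")
  if (is.null(w)) {
    w <- ts
    w[] <- 1
    w[is.na(ts)] <- NA_real_
  }
  if (!identical(dim(ts), dim(w)) || !identical(dimnames(ts), dimnames(w)))
    stop_input("ts and weight matrices must share gene and class axes")
  out <- data.frame(class_label = colnames(ts), score = NA_real_,
                    n_genes = 0L, fallback = FALSE)
  for (j in seq_len(ncol(ts))) {
    ok <- !is.na(ts[, j]) & !is.na(w[, j])
    n <- sum(ok)
    if (n == 0L) next
    out$n_genes[j] <- n
    sw <- sum(w[ok, j])
    if (sw / n <= eps) {
      out$score[j] <- mean(ts[ok, j])
      out$fallback[j] <- TRUE
    } else {
      out$score[j] <- sum(ts[ok, j] * w[ok, j]) / sw
    }
  }
  out <- out[out$n_genes >= 1L, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("wagep_similarity", "data.frame")
  out
}

#' Unweighted per-class similarity (plain AGEP)
#'
#' The mean of the query's ts-scores per class, i.e. [similarity()] with all
#' weights equal to 1.
#'
#' @inheritParams similarity
#' @return See [similarity()].
#' @export
unweighted_similarity <- function(ts) similarity(ts, w = NULL)

#' Rank classes and categorize a prediction
#'
#' The predicted class is the one with the highest similarity score (ties
#' broken by lexicographic class label and flagged).  When the true class is
#' supplied, the prediction is categorized as:
#' \describe{
#'   \item{exact}{the top class equals the annotation;}
#'   \item{similar}{the top class shares the annotation's organ group (e.g.
#'     one lung carcinoma subtype called as another);}
#'   \item{same_site}{the top class is the representative class of the
#'     metastasis site and the second-ranked class is exact or similar;}
#'   \item{incorrect}{none of the above.}
#' }
#'
#' @param sim a `wagep_similarity`.
#' @param truth optional true class label.
#' @param taxonomy optional [taxonomy()] providing organ groups and
#'   site-representative classes.
#' @param site optional metastasis site label of the query (needed for
#'   `same_site`).
#' @param tiers named thresholds for [reliability_tier()].
#' @return A list of class `wagep_classification`: `ranking` (data.frame),
#'   `best_class`, `best_score`, `tie`, `tier`, and `category` (NA when no
#'   truth given).
#' @export
classify <- function(sim, truth = NULL, taxonomy = NULL, site = NULL,
                     tiers = c(high = 0.10, medium = 0.05)) {
  stopifnot(inherits(sim, "wagep_similarity"), nrow(sim) >= 1L)
  ord <- order(-sim$score, sim$class_label)
  ranking <- sim[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  tie <- nrow(ranking) > 1L && ranking$score[1L] == ranking$score[2L]
  best <- ranking$class_label[1L]
  category <- NA_character_
  if (!is.null(truth)) {
    category <- categorize(best, ranking$class_label[min(2L, nrow(ranking))],
                           truth, taxonomy, site,
                           has_second = nrow(ranking) > 1L)
  }
  structure(list(ranking = ranking, best_class = best,
                 best_score = ranking$score[1L], tie = tie,
                 tier = reliability_tier(ranking$score[1L], tiers),
                 category = category),
            class = "wagep_classification")
}

categorize <- function(best, second, truth, taxonomy, site, has_second) {
  groups <- taxonomy$organ_group
  known <- unique(c(names(groups), best, second))
  if (!is.null(taxonomy) && length(groups) && !truth %in% known)
    stop_input("truth label '", truth, "' absent from taxonomy")
  same_group <- function(a, b) {
    !is.null(groups) && a %in% names(groups) && b %in% names(groups) &&
      groups[[a]] == groups[[b]]
  }
  if (best == truth) return("exact")
  if (same_group(best, truth)) return("similar")
  if (!is.null(site) && !is.null(taxonomy$site_class) &&
      site %in% names(taxonomy$site_class) &&
      best == taxonomy$site_class[[site]] && has_second &&
      (second == truth || same_group(second, truth)))
    return("same_site")
  "incorrect"
}

#' Reliability tier of a best-hit similarity score
#'
#' Confidence buckets calibrated on the observation that higher best-hit
#' similarity makes the call more likely to be correct: `high` for scores at
#' or above 0.10, `medium` for scores at or above 0.05, `low` below.
#' Both boundaries are inclusive.
#'
#' @param best_score best-hit similarity score (finite).
#' @param tiers named numeric thresholds `c(high = ..., medium = ...)`.
#' @return `"high"`, `"medium"` or `"low"`.
#' @export
reliability_tier <- function(best_score, tiers = c(high = 0.10, medium = 0.05)) {
  if (!is_scalar_number(best_score)) stop_input("best_score must be a finite number")
  if (best_score >= tiers[["high"]]) "high"
  else if (best_score >= tiers[["medium"]]) "medium"
  else "low"
}

#' @export
print.wagep_classification <- function(x, ...) {
  cat(sprintf("<wagep_classification> best: %s (score %.4f, tier %s%s)\n",
              x$best_class, x$best_score, x$tier,
              if (isTRUE(x$tie)) ", TIE" else ""))
  if (!is.na(x$category)) cat("  category:", x$category, "\n")
  print(head(x$ranking, 5L))
  invisible(x)
}
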