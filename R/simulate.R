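#' Simulation scenario for class-structured expression data
#'
#' Describes a synthetic reference cohort: `n_classes` classes of
#' `n_per_class` samples over `n_genes` genes on a log2-like scale.  Each
#' class owns a disjoint block of `n_markers` marker genes whose mean is
#' shifted by `delta` background standard deviations; all other genes are
#' pure background, shared by every class.  Queries can additionally "drift":
#' a fraction `drift` of their class's markers is redrawn from the background
#' distribution, emulating the loss of tissue-of-origin-specific expression
#' seen in metastases.
#'
#' Three named scenarios ship with the package:
#' \describe{
#'   \item{easy}{8 classes, 1000 genes, 100 markers/class, 30 samples/class,
#'     `delta = 3`: well-separated classes.}
#'   \item{noisy}{as easy, but only 25 markers/class (80% of genes are pure
#'     background) and `delta = 1.5`: weak, diluted signal where gene
#'     weighting should matter.}
#'   \item{graded}{the easy reference, with query drift drawn uniformly from
#'     `[0, 1]` so that best-hit scores span the whole reliability range.}
#' }
#'
#' @param name `"easy"`, `"noisy"` or `"graded"`; or `NULL` to build a
#'   scenario from the remaining arguments.
#' @param n_classes,n_genes,n_markers,n_per_class cohort dimensions.
#' @param delta marker shift in background-SD units.
#' @param bg_mean,bg_sd background distribution (log2-scale intensity).
#' @param drift fraction of a query's markers reverted to background, or
#'   `"uniform"` for per-query drift drawn from `[0, 1]`.
#' @param missing_rate fraction of entries set missing at random.
#' @param seed integer seed; every draw is reproducible from it.
#' @return A list of class `wagep_scenario`.
#' @export
wagep_scenario <- function(name = NULL, n_classes = 8L, n_genes = 1000L,
                           n_markers = 100L, n_per_class = 30L, delta = 3,
                           bg_mean = 8, bg_sd = 1, drift = 0,
                           missing_rate = 0, seed = 1L) {
  if (!is.null(name)) {
    base <- switch(name,
      easy = list(n_classes = 8L, n_genes = 1000L, n_markers = 100L,
                  n_per_class = 30L, delta = 3, drift = 0),
      noisy = list(n_classes = 8L, n_genes = 1000L, n_markers = 25L,
                   n_per_class = 30L, delta = 1.5, drift = 0),
      graded = list(n_classes = 8L, n_genes = 1000L, n_markers = 100L,
                    n_per_class = 30L, delta = 3, drift = "uniform"),
      stop_input("unknown scenario '", name, "'"))
    n_classes <- base$n_classes; n_genes <- base$n_genes
    n_markers <- base$n_markers; n_per_class <- base$n_per_class
    delta <- base$delta; drift <- base$drift
  }
  sc <- structure(list(
    name = name %||% "custom", n_classes = as.integer(n_classes),
    n_genes = as.integer(n_genes), n_markers = as.integer(n_markers),
    n_per_class = as.integer(n_per_class), delta = delta, bg_mean = bg_mean,
    bg_sd = bg_sd, drift = drift, missing_rate = missing_rate,
    seed = as.integer(seed)), class = "wagep_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  if (sc$n_classes * sc$n_markers > sc$n_genes)
    stop_input("n_classes * n_markers exceeds n_genes")
  if (sc$missing_rate < 0 || sc$missing_rate > 1)
    stop_input("missing_rate must be in [0, 1]")
  if (is.numeric(sc$drift) && (any(sc$drift < 0) || any(sc$drift > 1)))
    stop_input("drift must be in [0, 1]")
  invisible(sc)
}

# Marker gene assignment is deterministic in the scenario: class k owns the
# k-th block of n_markers gene ids.
scenario_markers <- function(sc) {
  genes <- sprintf("g%04d", seq_len(sc$n_genes))
  classes <- sprintf("C%02d", seq_len(sc$n_classes))
  setNames(lapply(seq_len(sc$n_classes), function(k)
    genes[((k - 1L) * sc$n_markers + 1L):(k * sc$n_markers)]), classes)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate a labeled reference cohort
#'
#' @param scenario a [wagep_scenario()].
#' @param seed optional seed override.
#' @return A list with `expr` (genes x samples matrix), `annot`
#'   (annotation data.frame) and `markers` (named list, class -> marker gene
#'   ids, the ground truth).
#' @export
simulate_reference <- function(scenario, seed = scenario$seed) {
  validate_scenario(scenario)
  sc <- scenario
  genes <- sprintf("g%04d", seq_len(sc$n_genes))
  classes <- sprintf("C%02d", seq_len(sc$n_classes))
  markers <- scenario_markers(sc)
  samples <- as.vector(vapply(classes, function(cl)
    sprintf("%s_s%02d", cl, seq_len(sc$n_per_class)),
    character(sc$n_per_class)))
  class_of <- rep(classes, each = sc$n_per_class)
  with_seed(seed, {
    x <- matrix(rnorm(sc$n_genes * length(samples), sc$bg_mean, sc$bg_sd),
                sc$n_genes, length(samples), dimnames = list(genes, samples))
    for (k in seq_along(classes))
      x[markers[[k]], class_of == classes[k]] <-
        x[markers[[k]], class_of == classes[k]] + sc$delta * sc$bg_sd
    if (sc$missing_rate > 0)
      x[runif(length(x)) < sc$missing_rate] <- NA_real_
    list(expr = x,
         annot = data.frame(sample_id = samples, class_label = class_of),
         markers = markers)
  })
}

#' Simulate metastasis-like query samples with marker drift
#'
#' Each query is drawn from its class's generative model, after which a
#' seeded fraction `drift` of the class's marker genes is redrawn from the
#' background distribution -- the synthetic analogue of a metastasis losing
#' its cancer-of-origin-specific expression.
#'
#' @param scenario a [wagep_scenario()].
#' @param class class the queries originate from.
#' @param n_queries number of query samples.
#' @param drift scalar or per-query vector in `[0, 1]`, or `"uniform"`;
#'   defaults to the scenario's drift.
#' @param seed seed (defaults to `scenario$seed + 1` so queries differ from
#'   the reference draw).
#' @return A list with `expr` (genes x queries matrix), `drift` (per-query
#'   fraction) and `drifted` (named list, query -> drifted marker gene ids).
#' @export
simulate_metastasis <- function(scenario, class, n_queries = 10L,
                                drift = scenario$drift,
                                seed = scenario$seed + 1L) {
  validate_scenario(scenario)
  sc <- scenario
  classes <- sprintf("C%02d", seq_len(sc$n_classes))
  if (!class %in% classes) stop_input("class '", class, "' not in scenario")
  markers <- scenario_markers(sc)[[class]]
  genes <- sprintf("g%04d", seq_len(sc$n_genes))
  qnames <- sprintf("%s_q%02d", class, seq_len(n_queries))
  with_seed(seed, {
    d <- if (identical(drift, "uniform")) runif(n_queries)
         else rep_len(drift, n_queries)
    x <- matrix(rnorm(sc$n_genes * n_queries, sc$bg_mean, sc$bg_sd),
                sc$n_genes, n_queries, dimnames = list(genes, qnames))
    x[markers, ] <- x[markers, ] + sc$delta * sc$bg_sd
    drifted <- setNames(vector("list", n_queries), qnames)
    for (q in seq_len(n_queries)) {
      k <- round(d[q] * length(markers))
      if (k > 0L) {
        rev_genes <- sample(markers, k)
        x[rev_genes, q] <- rnorm(k, sc$bg_mean, sc$bg_sd)
        drifted[[q]] <- sort(rev_genes)
      } else drifted[[q]] <- character(0)
    }
    if (sc$missing_rate > 0)
      x[runif(length(x)) < sc$missing_rate] <- NA_real_
    list(expr = x, drift = setNames(d, qnames), drifted = drifted)
  })
}
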