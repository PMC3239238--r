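# Small in-code fixtures shared across test files.

# Deterministic two-class expression cohort with well-separated marker genes.
tiny_cohort <- function(seed = 11, n_per_class = 8, n_genes = 12,
                        n_markers = 3, delta = 4, classes = c("kidney", "lung")) {
  sc <- wagep_scenario(n_classes = length(classes), n_genes = n_genes,
                       n_markers = n_markers, n_per_class = n_per_class,
                       delta = delta, seed = seed)
  ref <- simulate_reference(sc)
  # relabel synthetic classes with organ-like names for readability
  map <- setNames(classes, sprintf("C%02d", seq_along(classes)))
  ref$annot$class_label <- unname(map[ref$annot$class_label])
  names(ref$markers) <- unname(map[names(ref$markers)])
  ref$scenario <- sc
  ref
}

# An analytic Gaussian density placed directly on a grid (no KDE), normalized
# like the package's densities.
analytic_density <- function(grid, mean, sd = 1) {
  d <- dnorm(grid, mean, sd)
  d <- d / wagep:::trapz(grid, d)
  structure(list(grid = grid, density = d, n_samples = NA_integer_, bw = sd),
            class = "wagep_density")
}
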