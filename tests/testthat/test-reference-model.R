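test_that("expression TSV round-trips values and missing entries exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2",
               "g1\t1.5\t-2.25",
               "g2\tNA\t0.125",
               "g3\t7\t3.5"), f)
  x <- read_expression(f)
  expect_identical(dim(x), c(3L, 2L))
  expect_identical(rownames(x), c("g1", "g2", "g3"))
  expect_identical(x["g1", "s2"], -2.25)
  expect_true(is.na(x["g2", "s1"]))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, f2)
  expect_identical(read_expression(f2), x)

  # full-precision values survive a write/read cycle
  y <- matrix(c(pi, 1/3, exp(1), NA), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  f3 <- withr::local_tempfile()
  write_expression(y, f3)
  expect_identical(read_expression(f3), y)
})

test_that("malformed expression input is rejected with a named culprit", {
  f <- withr::local_tempfile()
  writeLines(c("gene_id\ts1", "gX\t1.0", "gX\t2.0"), f)
  expect_error(read_expression(f), "gX", class = "wagep_input_error")

  f2 <- withr::local_tempfile()
  writeLines(c("gene_id\ts1\ts2", "g1\t1.0\toops"), f2)
  expect_error(read_expression(f2), "s2", class = "wagep_input_error")
})

test_that("shared_grid spans the padded pooled range deterministically", {
  v <- as.numeric(0:10)
  g <- shared_grid(v)
  expect_length(g, 512L)
  expect_true(all(diff(g) > 0))
  expect_lte(g[1], 0)
  expect_gte(g[512], 10)
  expect_identical(g, shared_grid(v))
  # default padding is 3 pooled SDs on each side
  expect_equal(g[1], 0 - 3 * sd(v))
  expect_equal(g[512], 10 + 3 * sd(v))
  expect_error(shared_grid(rep(5, 10)), "degenerate",
               class = "wagep_input_error")
})

test_that("estimate_density is a normalized, deterministic Gaussian KDE", {
  set.seed(7)
  v <- rnorm(1000)
  grid <- shared_grid(v)
  d <- estimate_density(v, grid)
  expect_equal(wagep:::trapz(d$grid, d$density), 1, tolerance = 1e-3)
  expect_identical(d$n_samples, 1000L)
  # close to the analytic standard normal in sup-norm
  expect_lt(max(abs(d$density - dnorm(grid))), 0.05)
  # bitwise deterministic
  d2 <- estimate_density(v, grid)
  expect_identical(d$density, d2$density)
  expect_error(estimate_density(rnorm(3), grid), "insufficient",
               class = "wagep_input_error")
})

test_that("tied values fall back to the grid-spacing bandwidth floor", {
  grid <- seq(0, 10, length.out = 512)
  d <- estimate_density(rep(5, 10), grid)
  expect_equal(d$bw, grid[2] - grid[1])
  expect_equal(wagep:::trapz(grid, d$density), 1, tolerance = 1e-3)
  expect_true(all(d$density >= 0))
})

test_that("build_reference keeps eligible (gene, class) pairs and drops the rest", {
  set.seed(3)
  expr <- matrix(rnorm(5 * 23, 8), 5, 23,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:23)))
  annot <- data.frame(sample_id = paste0("s", 1:23),
                      class_label = rep(c("A", "B", "C"), c(10, 10, 3)))
  model <- build_reference(expr, annot)
  expect_identical(length(model$gene_ids), 5L)
  expect_identical(model$class_labels, c("A", "B", "C"))
  for (g in model$gene_ids) {
    expect_true(has_density(model, g, "A"))
    expect_true(has_density(model, g, "B"))
    # class C has 3 < 6 samples: absent, and queryably so
    expect_false(has_density(model, g, "C"))
    expect_null(ref_density(model, g, "C"))
  }
  # every stored density integrates to 1
  for (g in model$gene_ids) for (cl in c("A", "B")) {
    d <- ref_density(model, g, cl)
    expect_equal(wagep:::trapz(d$grid, d$density), 1, tolerance = 1e-3)
    expect_identical(d$n_samples, 10L)
  }
  # a single eligible class cannot make a model
  solo <- annot[annot$class_label == "C", ]
  expect_error(build_reference(expr[, solo$sample_id], solo),
               "empty model", class = "wagep_input_error")
})

test_that("build_reference is deterministic and serializes losslessly", {
  ref <- tiny_cohort()
  m1 <- build_reference(ref$expr, ref$annot)
  m2 <- build_reference(ref$expr, ref$annot)
  expect_identical(m1, m2)
  f <- withr::local_tempfile(fileext = ".wagep")
  write_model(m1, f)
  expect_identical(read_model(f), m1)
})

test_that("refitting without one sample on fixed grids changes only its class", {
  ref <- tiny_cohort(n_per_class = 10)
  full <- build_reference(ref$expr, ref$annot)
  held <- "C01_s03"  # a kidney sample; its values lie inside the pooled range
  keep <- setdiff(colnames(ref$expr), held)
  fold <- build_reference(ref$expr[, keep],
                          ref$annot[ref$annot$sample_id %in% keep, ],
                          grids = full)
  expect_identical(fold$dens[["lung"]], full$dens[["lung"]])
  expect_false(identical(fold$dens[["kidney"]], full$dens[["kidney"]]))
  expect_identical(unname(fold$n_samples[1, "kidney"]), 9L)
})
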