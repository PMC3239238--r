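test_that("LOOCV is perfect on three classes with disjoint value ranges", {
  set.seed(44)
  classes <- c("A", "B", "C")
  expr <- do.call(cbind, lapply(1:3, function(k)
    matrix(rnorm(8 * 10, 5 * k, 0.3), 8, 10)))
  dimnames(expr) <- list(paste0("g", 1:8), paste0("s", 1:30))
  annot <- data.frame(sample_id = colnames(expr),
                      class_label = rep(classes, each = 10))
  cohort <- loocv(expr, annot)
  expect_identical(nrow(cohort), 30L)
  expect_true(all(cohort$category == "exact"))
  expect_equal(attr(cohort, "accuracy"), 1)
  # the held-out sample's own class density is built from n - 1 samples
  expect_true(all(cohort$n_ref == 9))
})

test_that("samples of too-small classes are skipped with a reason", {
  set.seed(45)
  expr <- matrix(rnorm(4 * 18, 8), 4, 18,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:18)))
  expr[1, 1:12] <- expr[1, 1:12] + 5
  annot <- data.frame(sample_id = colnames(expr),
                      class_label = rep(c("A", "B"), c(12, 6)))
  cohort <- loocv(expr, annot)
  skipped <- attr(cohort, "skipped")
  expect_identical(nrow(cohort), 12L)
  expect_identical(sort(skipped$sample_id), paste0("s", 13:18))
  expect_match(skipped$reason[1], "min_class_n")
})

test_that("per-class metrics match hand-computed confusion arithmetic", {
  cohort <- data.frame(
    truth = c("A", "A", "A", "B", "B", "C", "C", "C", "C"),
    best = c("A", "A", "B", "B", "A", "C", "C", "A", "B"))
  cohort$correct <- cohort$truth == cohort$best
  m <- per_class_metrics(cohort)
  expect_equal(m$sensitivity[m$class_label == "A"], 2 / 3)
  expect_equal(m$sensitivity[m$class_label == "B"], 1 / 2)
  expect_equal(m$sensitivity[m$class_label == "C"], 2 / 4)
  # specificity: non-A samples predicted A: 2 of 6
  expect_equal(m$specificity[m$class_label == "A"], 1 - 2 / 6)
  expect_equal(m$specificity[m$class_label == "B"], 1 - 2 / 7)
  expect_equal(m$specificity[m$class_label == "C"], 1)
  total <- m[m$class_label == "Total/average", ]
  expect_equal(total$percent_correct, 100 * 5 / 9)
  expect_equal(total$sensitivity, mean(c(2 / 3, 1 / 2, 1 / 2)))

  all_right <- data.frame(truth = c("A", "B"), best = c("A", "B"),
                          correct = c(TRUE, TRUE))
  m2 <- per_class_metrics(all_right)
  expect_true(all(m2$sensitivity == 1) && all(m2$specificity == 1))
})

test_that("sliding-window accuracy matches a brute-force oracle", {
  set.seed(46)
  fixture <- data.frame(best_score = runif(20, -0.02, 0.5),
                        correct = runif(20) < 0.6)
  curve <- accuracy_curve(fixture, width = 0.1, step = 0.005)
  oracle <- oracle_window_curve(fixture$best_score, fixture$correct,
                                width = 0.1, step = 0.005)
  expect_equal(curve$window_left, oracle$window_left)
  expect_identical(curve$n, oracle$n)
  expect_equal(curve$accuracy, oracle$accuracy)

  all_ok <- data.frame(best_score = runif(10), correct = TRUE)
  expect_true(all(na.omit(accuracy_curve(all_ok)$accuracy) == 1))
  all_bad <- data.frame(best_score = runif(10), correct = FALSE)
  expect_true(all(na.omit(accuracy_curve(all_bad)$accuracy) == 0))
  expect_error(accuracy_curve(fixture, width = 0), "width",
               class = "wagep_input_error")
  expect_error(accuracy_curve(fixture, step = -1), "step",
               class = "wagep_input_error")
  # one full-range window reproduces the overall accuracy
  wide <- accuracy_curve(fixture, width = 1, step = 1)
  expect_equal(wide$accuracy[1], mean(fixture$correct))
})

test_that("threshold summaries count fractions and accuracy correctly", {
  fixture <- data.frame(best_score = seq(0.01, 0.10, by = 0.01),
                        correct = rep(c(TRUE, FALSE), 5))
  expect_equal(threshold_accuracy(fixture, 0),
               list(fraction = 1, accuracy = 0.5, n = 10L))
  above <- threshold_accuracy(fixture, 0.055)
  expect_equal(above$fraction, 0.5)
  expect_equal(above$accuracy, mean(fixture$correct[6:10]))
  top <- threshold_accuracy(fixture, 0.5)
  expect_equal(top$fraction, 0)
  expect_true(is.na(top$accuracy))
})

test_that("gene retention reports class-specific ts and drift shows up", {
  sc <- wagep_scenario(n_classes = 3, n_genes = 120, n_markers = 20,
                       n_per_class = 50, delta = 3, seed = 77)
  ref <- simulate_reference(sc)
  model <- build_reference(ref$expr, ref$annot)
  W <- weight_matrix(model)
  queries <- simulate_metastasis(sc, "C01", n_queries = 6, drift = 0.5)
  rep <- gene_retention(model, W, queries$expr, "C01")
  # every true C01 marker clears the 0.25 weight threshold and is reported
  expect_true(all(ref$markers$C01 %in% rownames(rep)))
  expect_identical(ncol(rep), 6L)
  # drifted markers score visibly lower than retained ones, per query
  markers <- intersect(rownames(rep), ref$markers$C01)
  diffs <- vapply(colnames(rep), function(q) {
    drifted <- intersect(markers, queries$drifted[[q]])
    kept <- setdiff(markers, drifted)
    mean(rep[kept, q]) - mean(rep[drifted, q])
  }, numeric(1))
  expect_gt(mean(diffs), 0)

  # a typical class member scores high across the selected genes
  member <- gene_retention(model, W, ref$expr[, 1:2, drop = FALSE], "C01")
  expect_gt(mean(member), 0.3)

  # a gene missing in one query is excluded for all queries
  q2 <- queries$expr
  q2[rownames(rep)[1], 3] <- NA
  rep2 <- gene_retention(model, W, q2, "C01")
  expect_false(rownames(rep)[1] %in% rownames(rep2))
  expect_error(gene_retention(model, W, queries$expr, "C01",
                              weight_threshold = 0.999),
               "empty selection", class = "wagep_input_error")
})
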