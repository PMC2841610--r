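test_that("balance_training keeps all positives and equalizes classes", {
  set.seed(3)
  x <- matrix(rnorm(510 * 4), 510, 4)
  y <- c(rep(TRUE, 10), rep(FALSE, 500))   # ~1:50 imbalance
  bal <- balance_training(x, y, seed = 9)
  expect_equal(sum(bal$labels), 10L)
  expect_equal(sum(!bal$labels), 10L)
  expect_equal(bal$cost_factor, 1)
  expect_true(all(which(y) %in% bal$index))

  # identity when already balanced
  bal2 <- balance_training(x[1:20, ], y[c(1:10, 501:510)], seed = 1)
  expect_equal(length(bal2$labels), 20L)
  expect_equal(bal2$cost_factor, 1)

  # determinism given seed
  bal3 <- balance_training(x, y, seed = 9)
  expect_identical(bal$index, bal3$index)
  bal4 <- balance_training(x, y, seed = 10)
  expect_false(identical(bal$index, bal4$index))

  expect_error(balance_training(x, rep(FALSE, 510)), "no positive")
})

test_that("RBF-SVM separates blobs and honours the score-sign contract", {
  set.seed(11)
  x <- rbind(matrix(rnorm(60, mean = 3), 30, 2),
             matrix(rnorm(60, mean = -3), 30, 2))
  y <- rep(c(TRUE, FALSE), each = 30)
  m <- train_svm(x, y, svm_params(gamma = 0.5, C = 1))
  s <- predict_scores(m, x)
  expect_true(all((s > 0) == y))           # training accuracy 1.0
  expect_true(all(s[1:30] > 0))

  expect_error(train_svm(x, rep(TRUE, 60)), "single-class")
  expect_error(predict_scores(m, x[, 1, drop = FALSE]), "feature width")
})

test_that("metric computations match the standard confusion-matrix definitions", {
  perfect <- compute_metrics(50, 50, 0, 0)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$accuracy, 1)

  m <- compute_metrics(30, 40, 10, 20)
  expect_equal(m$mcc, (30 * 40 - 10 * 20) / sqrt(40 * 50 * 50 * 60))
  expect_equal(round(m$mcc, 4), 0.4082)
  expect_equal(m$precision, 30 / 40)
  expect_equal(m$recall, 30 / 50)
  expect_equal(m$fpr, 10 / 50)
  expect_equal(m$fnr, 20 / 50)
  expect_equal(m$accuracy, 70 / 100)

  degen <- compute_metrics(0, 10, 0, 5)
  expect_equal(degen$precision, 0)
  expect_equal(degen$mcc, 0)
  expect_true(degen$degenerate)
  expect_error(compute_metrics(0, 0, 0, 0), "empty")
})

test_that("metrics agree with a brute-force tally over prediction lists", {
  set.seed(13)
  for (rep in 1:5) {
    pred <- runif(200) > 0.5
    truth <- runif(200) > 0.3
    m <- metrics_from_labels(pred, truth)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (k in 1:200) {
      if (pred[k] && truth[k]) tp <- tp + 1
      else if (!pred[k] && !truth[k]) tn <- tn + 1
      else if (pred[k]) fp <- fp + 1
      else fn <- fn + 1
    }
    expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(tp, tn, fp, fn))
    expect_equal(m$accuracy, (tp + tn) / 200)
  }
})

test_that("homology exclusion removes the target and its homologs from folds", {
  ids <- c("a", "b", "c", "d")
  hom <- homology_table(ids, data.frame(id1 = "a", id2 = "b", evalue = 1e-6))
  expect_setequal(fold_exclusions(hom, "a", ids), c("a", "b"))
  expect_setequal(fold_exclusions(hom, "b", ids), c("a", "b"))
  expect_setequal(fold_exclusions(hom, "c", ids), "c")
  expect_equal(fold_exclusions(NULL, "c", ids), "c")

  ds <- lipid_dataset(1:4, signal_strength = Inf)
  names(ds) <- NULL
  for (k in 1:4) ds[[k]]$id <- ids[k]
  cv <- loo_cv(ds, svm_params(gamma = 0.01, C = 1.5), homology = hom)
  expect_setequal(cv$excluded[["a"]], c("a", "b"))
  expect_setequal(cv$excluded[["c"]], "c")
})

test_that("grid search returns the MCC-maximizing point with stated ties", {
  ds <- lipid_dataset(1:4, signal_strength = 8)
  one <- grid_search_cv(ds, data.frame(gamma = 0.01, C = 1.5))
  expect_equal(one$best$gamma, 0.01)
  expect_equal(one$best$C, 1.5)
  expect_true(is.finite(one$best_mcc))

  # a grid with an absurd gamma and a sane one: the sane one must win
  grid <- expand.grid(gamma = c(0.01, 5000), C = c(1))
  gs <- grid_search_cv(ds, grid)
  expect_equal(gs$best$gamma, 0.01)
  expect_error(grid_search_cv(ds, grid[0, ]), "empty")
})
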