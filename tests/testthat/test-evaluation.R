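test_that("confusion matrix counts partition the sample", {
  cm <- confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(cm[c("tp", "fn", "tn", "fp")], list(tp = 1, fn = 1, tn = 2, fp = 0))
  perfect <- confusion_matrix(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0)
  set.seed(1)
  for (i in 1:20) {
    yt <- rbinom(17, 1, 0.4); yp <- rbinom(17, 1, 0.6)
    cm <- confusion_matrix(yt, yp)
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, 17)
  }
  expect_error(confusion_matrix(integer(0), integer(0)), "empty")
  expect_error(confusion_matrix(c(1, 2), c(0, 1)), "binary")
  expect_error(confusion_matrix(c(1, 0), c(1)), "lengths differ")
})

test_that("the published confusion matrix reproduces the reported metrics", {
  cm <- cm_from_counts(tp = 195, fp = 2, tn = 198, fn = 5)
  expect_equal(sensitivity(cm, decimals = 2), 97.50)
  expect_equal(ppv(cm, decimals = 2), 98.98)
  expect_equal(ppv(cm, decimals = 1), 99.0)
  expect_equal(accuracy(cm, decimals = 2), 98.25)
  expect_equal(accuracy(cm, decimals = 1), 98.3)
})

test_that("metric edge cases follow their formulas", {
  expect_equal(sensitivity(cm_from_counts(10, 0, 0, 0), 2), 100.00)
  expect_equal(sensitivity(cm_from_counts(0, 0, 0, 5), 2), 0.00)
  expect_equal(ppv(cm_from_counts(3, 0, 0, 0), 2), 100.00)
  expect_equal(ppv(cm_from_counts(1, 1, 0, 0), 2), 50.00)
  expect_equal(accuracy(cm_from_counts(2, 0, 3, 0), 2), 100.00)
  expect_equal(accuracy(cm_from_counts(0, 2, 0, 3), 2), 0.00)
  expect_error(sensitivity(cm_from_counts(0, 1, 1, 0)), "undefined")
  expect_error(ppv(cm_from_counts(0, 0, 1, 1)), "undefined")
})

test_that("metric algebra holds on random confusion matrices", {
  set.seed(2)
  for (i in 1:1000) {
    k <- sample(1:50, 4, replace = TRUE)
    cm <- cm_from_counts(k[1], k[2], k[3], k[4])
    acc <- accuracy(cm)
    sens <- sensitivity(cm)
    spec <- specificity(cm)
    expect_equal(acc, (sens * (cm$tp + cm$fn) + spec * (cm$tn + cm$fp)) / cm$n,
                 tolerance = 1e-10)
  }
})

test_that("swapping the positive label swaps the paired metrics", {
  set.seed(3)
  for (i in 1:50) {
    yt <- rbinom(40, 1, 0.5); yp <- rbinom(40, 1, 0.5)
    c1 <- confusion_matrix(yt, yp, positive_label = 1)
    c0 <- confusion_matrix(yt, yp, positive_label = 0)
    if (c1$tp + c1$fn > 0 && c1$tn + c1$fp > 0) {
      expect_equal(sensitivity(c1), specificity(c0), tolerance = 1e-12)
    }
    if (c1$tp + c1$fp > 0 && c1$tn + c1$fn > 0) {
      expect_equal(ppv(c1), npv(c0), tolerance = 1e-12)
    }
  }
})

test_that("evaluate() reproduces hand-computed metrics and is deterministic", {
  ds <- shared_dataset()
  model <- build_model(tiny_config(), seed = 1)
  r1 <- evaluate(model, ds$manifest, dir = ds$dir, split = NULL)
  rows <- ds$manifest
  samples <- lapply(file.path(ds$dir, rows$path), load_and_resize, size = 32)
  pred <- predict(model, samples)
  cm <- confusion_matrix(rows$label, pred)
  expect_equal(r1$accuracy, 100 * (cm$tp + cm$tn) / cm$n)
  expect_equal(r1$cm$tp, cm$tp)
  expect_equal(r1$n, nrow(rows))
  r2 <- evaluate(model, ds$manifest, dir = ds$dir, split = NULL)
  expect_identical(r1, r2)
  expect_error(evaluate(model, ds$manifest, dir = ds$dir, split = "nope"), "empty")
})

test_that("reports serialize and compare with antisymmetric margins", {
  a <- metrics_report(c(1, 1, 0, 0), c(1, 1, 0, 0), model_id = "a")
  path <- file.path(tempdir(), "report.json")
  write_report(a, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$accuracy, 100)
  expect_equal(back$model_id, "a")

  mk <- function(id, acc100) {
    structure(list(sensitivity = 90, ppv = 90, accuracy = acc100,
                   cm = cm_from_counts(1, 0, 1, 0), n = 2,
                   dataset_id = "d", model_id = id, ablation_mode = "full"),
              class = "metrics_report")
  }
  tab <- compare_models(list(mk("medusa", 98.30), mk("baseline", 90.50)))
  expect_equal(tab$accuracy_margin, c(7.80, -7.80), tolerance = 1e-12)
  one <- compare_models(list(mk("solo", 80)))
  expect_true(is.na(one$accuracy_margin))
  expect_error(compare_models(list(mk("x", 1), mk("x", 2))), "duplicate")
})
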