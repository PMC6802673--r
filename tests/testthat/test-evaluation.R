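# a tiny separable fixture: two 1-D clusters
cluster_dataset <- function(lo = seq(0, 0.4, 0.1), hi = seq(10, 10.4, 0.1),
                            extra = NULL) {
  x <- matrix(c(lo, hi, extra), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- c(rep(0L, length(lo)), rep(1L, length(hi)),
         rep(0L, length(extra)))
  structure(list(spec = list(id = "fix", output = "Fw", blocks = "Metab"),
                 x = x, y = y, columns = "f1"),
            class = "encoded_dataset")
}

test_that("the pipeline scales on training rows only and guards edge cases", {
  xtr <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), ncol = 1)
  ytr <- c(0L, 0L, 0L, 1L, 1L, 1L)
  xte <- matrix(c(0.05, 9.9), ncol = 1)
  knn <- make_classifier("KNN")
  expect_equal(fit_predict_pipeline(xtr, ytr, xte, knn), c(0L, 1L))

  # constant feature column is mapped to zeros, pipeline still runs
  xtr2 <- cbind(xtr, 5)
  xte2 <- cbind(xte, 5)
  expect_equal(fit_predict_pipeline(xtr2, ytr, xte2, knn), c(0L, 1L))

  # single-class training set -> that class, with a warning
  expect_warning(
    p <- fit_predict_pipeline(xtr, rep(1L, 6), xte, knn),
    "single-class")
  expect_equal(p, c(1L, 1L))

  # a 100x outlier makes the scaled and unscaled runs disagree: the
  # median/IQR scaling keeps the bulk of the data dominant
  svmlin <- make_classifier("SVM linear")
  xtr3 <- matrix(c(0, 0.1, 0.2, 1, 1.1, 100), ncol = 1)
  ytr3 <- c(0L, 0L, 0L, 1L, 1L, 1L)
  xte3 <- matrix(0.6, ncol = 1)
  scaled <- fit_predict_pipeline(xtr3, ytr3, xte3, svmlin)
  unscaled <- svmlin$fit_predict(xtr3, ytr3, xte3)
  expect_false(identical(scaled, unscaled))
})

test_that("LOOCV is perfect on separated clusters and matches the oracle", {
  ds <- cluster_dataset()
  expect_equal(loocv_accuracy(ds, make_classifier("KNN"))$score, 1.0)

  set.seed(31)
  x <- cbind(a = rnorm(14), b = c(rnorm(7, -1.5), rnorm(7, 1.5)))
  y <- rep(0:1, each = 7)
  ds2 <- structure(list(spec = list(id = "o", output = "Fw", blocks = "Metab"),
                        x = x, y = y, columns = colnames(x)),
                   class = "encoded_dataset")
  # independent refit-n-times oracles calling the libraries directly
  got_svm <- loocv_accuracy(ds2, make_classifier("SVM linear"))$score
  want_svm <- oracle_loocv(x, y, function(xtr, ytr, xte) {
    fit <- e1071::svm(xtr, factor(ytr, levels = 0:1), kernel = "linear",
                      cost = 1, scale = FALSE)
    as.integer(as.character(predict(fit, xte)))
  })
  expect_equal(got_svm, want_svm)

  got_knn <- loocv_accuracy(ds2, make_classifier("KNN"))$score
  want_knn <- oracle_loocv(x, y, function(xtr, ytr, xte) {
    as.integer(as.character(class::knn(xtr, xte, factor(ytr), k = 5)))
  })
  expect_equal(got_knn, want_knn)

  expect_error(loocv_accuracy(cluster_dataset(lo = 0, hi = 1),
                              make_classifier("KNN")),
               "at least 3")
})

test_that("majority voting flips under LOOCV on balanced labels", {
  # with balanced labels, the held-out record is always the training
  # minority class, so a majority-vote rule scores exactly 0
  set.seed(4)
  x <- matrix(rnorm(12), ncol = 2)
  ds <- structure(list(spec = list(id = "m", output = "Fw", blocks = "Metab"),
                       x = x, y = rep(0:1, 3), columns = c("a", "b")),
                  class = "encoded_dataset")
  expect_equal(loocv_accuracy(ds, majority_classifier())$score, 0)
})

test_that("LOOCV is invariant to record order for deterministic classifiers", {
  rec <- generate_synthetic_study(synthetic_config(n_per_cell = 3L, seed = 6))
  spec <- list(id = "Hw:MAmix", output = "Hw", blocks = "MAmix")
  ds <- assemble_dataset(rec, spec)
  perm <- sample(nrow(ds$x))
  dsp <- ds; dsp$x <- ds$x[perm, , drop = FALSE]; dsp$y <- ds$y[perm]
  for (fam in c("SVM linear", "LR")) {
    clf <- make_classifier(fam)
    expect_equal(loocv_accuracy(dsp, clf)$score, loocv_accuracy(ds, clf)$score,
                 info = fam)
  }
})

test_that("stratified k-fold balanced accuracy behaves at the extremes", {
  ds <- cluster_dataset(lo = seq(0, 0.5, 0.1), hi = seq(10, 10.5, 0.1))
  # perfectly separable -> 1.0
  expect_equal(kfold_score(ds, make_classifier("KNN"), k = 3, seed = 1)$score, 1)
  # always-predict-1 on balanced data -> sens 1, spec 0 -> 0.5
  expect_equal(kfold_score(ds, constant_classifier(1L), k = 3, seed = 1)$score,
               0.5)
  # reproducible across runs with the same seed
  rec <- generate_synthetic_study(synthetic_config(n_per_cell = 3L, seed = 8))
  ds2 <- assemble_dataset(rec, list(id = "x", output = "Hw", blocks = "MAmix"))
  a <- kfold_score(ds2, make_classifier("SVM"), k = 5, seed = 9)$score
  b <- kfold_score(ds2, make_classifier("SVM"), k = 5, seed = 9)$score
  expect_identical(a, b)
})

test_that("grid evaluation covers the cross-product and isolates failures", {
  rec <- generate_synthetic_study(synthetic_config(n_per_cell = 3L, seed = 3))
  specs <- enumerate_datasets(list(m = "MAmix"), outputs = c("Fw", "Hw"))
  clfs <- default_classifiers()[c("KNN", "SVM linear")]
  grid <- grid_evaluate(rec, specs, clfs)
  expect_equal(nrow(grid), 4)
  expect_true(all(grid$score >= 0 & grid$score <= 1))
  expect_true(all(grid$cv == "LOOCV"))

  # a failing cell is recorded, not fatal
  boom <- structure(list(family = "boom", params = list(), seed = NA,
                         fit_predict = function(...) stop("kaput")),
                    class = "fb_classifier")
  grid2 <- grid_evaluate(rec, specs[1], list(boom = boom))
  expect_equal(nrow(grid2), 1)
  expect_true(is.na(grid2$score) && grepl("kaput", grid2$error))
})

test_that("select_best ranks by score, then fewer features, then family order", {
  res <- data.frame(
    dataset_id = c("a", "b", "c"), output = "Fw",
    blocks = c("MAmix", "MAmix+Metab", "MAmix"),
    classifier = c("SVM", "SVM linear", "KNN"),
    cv = "LOOCV", score = c(0.9, 0.9, 0.8),
    n_features = c(6L, 12L, 6L), n_records = 56L,
    error = NA_character_, stringsAsFactors = FALSE)
  expect_equal(select_best(res, "Fw")$dataset_id, "a")   # fewer features
  res$n_features <- c(6L, 6L, 6L)
  res$classifier <- c("SVM", "KNN", "DT"); res$score <- c(0.9, 0.9, 0.9)
  expect_equal(select_best(res, "Fw")$classifier, "KNN") # earlier family
  expect_equal(select_best(res[1, ], "Fw")$dataset_id, "a")
  expect_error(select_best(res[0, ], "Fw"), "no results")
})

test_that("centered-feature arm beats the one-hot arm on interaction effects", {
  # labels driven purely by a within-cell (condition-interaction) signal:
  # condition indicators alone carry no class information, the centered
  # biomarker carries it all
  cfg <- synthetic_config(seed = 100)
  clf <- make_classifier("SVM linear")
  wins <- vapply(1:20, function(i) {
    rec <- generate_synthetic_study(cfg, seed = 100 + i)
    ma <- loocv_accuracy(assemble_dataset(
      rec, list(id = "a", output = "Hw", blocks = "MAmix")), clf)$score
    oh <- loocv_accuracy(assemble_dataset(
      rec, list(id = "b", output = "Hw", blocks = c("OneHot", "Metab"))),
      clf)$score
    ma > oh
  }, TRUE)
  expect_gte(mean(wins), 0.8)
})

test_that("strict LOOCV removes the held-out record from group statistics", {
  rec <- generate_synthetic_study(synthetic_config(n_per_cell = 3L, seed = 44))
  spec <- list(id = "Hw:MAmix+ProbECs", output = "Hw",
               blocks = c("MAmix", "ProbECs"))
  clf <- make_classifier("SVM linear")
  ev <- loocv_accuracy_strict(rec, spec, clf)
  expect_equal(ev$cv, "LOOCV-strict")
  expect_length(ev$predictions, 24)
  expect_true(ev$score >= 0 && ev$score <= 1)
  # deterministic
  expect_equal(loocv_accuracy_strict(rec, spec, clf)$score, ev$score)

  # when every cell's biomarkers are constant, centered features are 0
  # under both conventions, so strict and default scores coincide
  rec2 <- make_cell_table(3L)
  for (k in seq_along(fb_proteins())) {
    rec2[[fb_proteins()[k]]] <- rep(c(10, 20, 30, 40, 50, 60, 70, 80) * k,
                                    each = 3)
  }
  set.seed(45)
  rec2$Hw <- runif(24, 10, 20)
  spec2 <- list(id = "Hw:MAmix", output = "Hw", blocks = "MAmix")
  strict <- loocv_accuracy_strict(rec2, spec2, clf)$score
  dflt <- loocv_accuracy(assemble_dataset(rec2, spec2), clf)$score
  expect_equal(strict, dflt)
})
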