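test_that("robust_scale matches the interpolated-quantile definition", {
  expect_equal(robust_scale(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(robust_scale(c(7, 7, 7)), c(0, 0, 0))  # IQR-zero guard
  expect_error(robust_scale(numeric(0)), "empty")
  expect_error(robust_scale(c(1, NA)), "finite")

  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(50, sd = 10)
    expect_equal(robust_scale(x), oracle_robust_scale(x), tolerance = 1e-12)
  }
  # median maps to 0 whenever IQR > 0
  x <- rexp(31)
  expect_equal(median(robust_scale(x)), 0)
})

test_that("binarize_output thresholds at the per-animal median", {
  rec <- make_cell_table(bones = FALSE)[1:4, ]
  rec$animal <- "fetus"; rec$serum_id <- sprintf("B%02d", 1:4)
  rec$Fw <- c(1, 2, 3, 4)
  expect_equal(binarize_output(validate_study_table(rec), "Fw"),
               c(0L, 0L, 1L, 1L))

  rec3 <- rec[1:3, ]; rec3$Fw <- c(1, 2, 3)
  expect_equal(binarize_output(validate_study_table(rec3), "Fw"),
               c(0L, 0L, 1L))           # tie at the median -> class 0

  # per-animal scaling: classes must not separate by animal type
  rec4 <- make_cell_table(bones = FALSE)[1:4, ]
  rec4$animal <- c("fetus", "fetus", "mother", "mother")
  rec4$serum_id <- sprintf("C%02d", 1:4)
  rec4$Fw <- c(1, 2, 100, 200)
  expect_equal(binarize_output(validate_study_table(rec4), "Fw"),
               c(0L, 1L, 0L, 1L))

  rec5 <- rec4; rec5$Fw <- c(3, 3, 1, 2)
  expect_error(binarize_output(validate_study_table(rec5), "Fw"),
               "constant within animal type")
})

test_that("moving_average is the group mean minus the record's value", {
  rec <- make_cell_table()
  # constant protein within every group (groups of one) -> all zeros
  expect_equal(moving_average(rec, "PTH", fb_axes()), rep(0, 8))

  # one group with values {2, 4} -> {+1, -1}
  rec2 <- make_cell_table(bones = FALSE)[1:2, ]
  rec2$animal <- "fetus"; rec2$treat <- "control"; rec2$period <- "middle"
  rec2$serum_id <- c("M1", "M2"); rec2$PTH <- c(2, 4)
  expect_equal(moving_average(validate_study_table(rec2), "PTH", fb_axes()),
               c(1, -1))

  # 2x2x2 fixture vs brute-force double-loop oracle, every grouping
  set.seed(5)
  rec8 <- make_cell_table(3L)
  rec8$PTH <- runif(24, 1, 100)
  for (axes in list(fb_axes(), "animal", "treat", "period",
                    c("animal", "period"))) {
    expect_equal(moving_average(rec8, "PTH", axes),
                 oracle_moving_average(rec8, "PTH", axes))
  }
  expect_error(moving_average(rec8, "XYZ"), "should be one of")
})

test_that("feature blocks have the canonical shapes and column names", {
  rec <- make_cell_table(2L)
  b <- build_feature_blocks(rec)
  expect_equal(vapply(b, ncol, 1L),
               c(Metab = 6L, MAmix = 6L, MAi = 18L, OneHot = 6L,
                 ProbMix = 1L, ProbECs = 3L))
  expect_equal(colnames(b$MAmix),
               paste0("MA-", fb_proteins(), "-experim"))
  expect_equal(colnames(b$MAi)[c(1, 7, 13)],
               c("MA-PTH-Animal", "MA-PTH-Treat", "MA-PTH-Period"))
  expect_equal(colnames(b$OneHot),
               c("Animal_Fetus", "Animal_Mon", "Treat_Con", "Treat_Res",
                 "Period_Late", "Period_Mid"))
  expect_false(anyNA(do.call(cbind, b)))
  # each MAi column equals moving_average called directly
  expect_equal(unname(b$MAi[, "MA-BALP-Treat"]),
               moving_average(rec, "BALP", "treat"))
  # single-record input -> all centered features are 0
  one <- make_cell_table()[1, ]
  expect_true(all(build_ma_mixed(one) == 0) && all(build_ma_single(one) == 0))
})

test_that("one-hot encoding is the redundant two-columns-per-axis scheme", {
  rec <- make_cell_table()
  oh <- build_one_hot(rec)
  fcm <- oh[rec$animal == "fetus" & rec$treat == "control" &
            rec$period == "middle", ]
  expect_equal(unname(fcm), c(1, 0, 1, 0, 0, 1))
  mrl <- oh[rec$animal == "mother" & rec$treat == "restricted" &
            rec$period == "late", ]
  expect_equal(unname(mrl), c(0, 1, 0, 1, 1, 0))
  # each axis's column pair sums to 1 row-wise
  expect_true(all(oh[, 1] + oh[, 2] == 1))
  expect_true(all(oh[, 3] + oh[, 4] == 1))
  expect_true(all(oh[, 5] + oh[, 6] == 1))
})

test_that("condition probabilities are empirical cell frequencies", {
  rec <- make_cell_table()                 # 8 records, one per cell
  pr <- build_probabilities(rec)
  expect_true(all(pr$ProbECs == 0.5))      # 4/8 on each axis
  expect_true(all(pr$ProbMix == 1 / 8))
  # cell probability never exceeds any marginal axis probability
  expect_true(all(pr$ProbMix[, 1] <= pr$ProbECs))

  # unbalanced table: distinct per-axis values sum to 1 over categories
  rec2 <- make_cell_table(bones = FALSE)[1:5, ]
  rec2$animal <- c("fetus", "fetus", "fetus", "mother", "mother")
  rec2$serum_id <- sprintf("P%02d", 1:5)
  pr2 <- build_probabilities(validate_study_table(rec2))
  expect_equal(sort(unique(pr2$ProbECs[, "Prob_Animal"])), c(2 / 5, 3 / 5))
  expect_true(all(pr2$ProbMix[, 1] <= pr2$ProbECs))
})

test_that("centered features sum to zero within every group", {
  set.seed(9)
  rec <- make_cell_table(4L)
  for (p in fb_proteins()) rec[[p]] <- rlnorm(32, 2, 1)
  for (axes in list(fb_axes(), "animal", "treat", "period")) {
    g <- interaction(rec[axes], drop = TRUE)
    for (p in fb_proteins()) {
      ma <- moving_average(rec, p, axes)
      sums <- tapply(ma, g, sum)
      expect_true(all(abs(sums) < 1e-9))
    }
  }
})

test_that("engineered columns are equivariant under record shuffling", {
  set.seed(13)
  rec <- make_cell_table(3L)
  for (p in fb_proteins()) rec[[p]] <- runif(24, 1, 50)
  b <- build_feature_blocks(rec)
  perm <- sample(nrow(rec))
  bp <- build_feature_blocks(validate_study_table(rec[perm, ]))
  for (nm in names(b)) {
    expect_equal(unname(bp[[nm]]), unname(b[[nm]][perm, , drop = FALSE]),
                 info = nm)
  }
})

test_that("per animal type the binary classes are near-balanced", {
  set.seed(21)
  rec <- make_cell_table(4L)
  rec$Fw <- ifelse(rec$animal == "fetus", runif(32, 1, 20),
                   runif(32, 80, 200))
  y <- binarize_output(rec, "Fw")
  for (a in c("fetus", "mother")) {
    ya <- y[rec$animal == a]
    x <- rec$Fw[rec$animal == a]
    ties <- sum(robust_scale(x) == 0)
    expect_lte(abs(sum(ya == 1) - sum(ya == 0)), ties)
  }
})
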