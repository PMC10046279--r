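test_that("confusion counts match hand-enumerated cases", {
  truth <- c("acceptable", "acceptable", "acceptable", "unacceptable",
             "unacceptable", "uncertain", "uncertain", "uncertain",
             "uncertain")
  pred <- c("acceptable", "uncertain", "acceptable", "unacceptable",
            "acceptable", "uncertain", "uncertain", "unacceptable",
            "acceptable")
  cm <- confusion_3x3(truth, pred)
  want <- matrix(c(2L, 1L, 1L,
                   0L, 1L, 1L,
                   1L, 0L, 2L), 3, 3,
                 dimnames = dimnames(cm))
  expect_identical(cm, want)
  # perfect predictions and the empty case
  perfect <- rep(quality_classes(), each = 10)
  expect_identical(unname(diag(confusion_3x3(perfect, perfect))),
                   rep(10L, 3))
  expect_true(all(confusion_3x3(character(0), character(0)) == 0L))
})

test_that("label validation rejects mismatches and unknown classes", {
  expect_error(confusion_3x3(c("acceptable"), c("acceptable", "uncertain")),
               "equal length")
  expect_error(confusion_3x3(c("fine"), c("acceptable")), "fine")
})

test_that("the merged 2x2 matrix sums the right 3x3 blocks", {
  m <- merge_2x2(diag(c(10L, 10L, 10L)))
  expect_equal(as.numeric(m), c(20, 0, 0, 10))
  expect_identical(rownames(m), c("acceptable+uncertain", "unacceptable"))
  expect_true(all(merge_2x2(matrix(0L, 3, 3)) == 0L))
  set.seed(20)
  cm3 <- matrix(sample(0:30, 9), 3, 3)
  expect_identical(sum(merge_2x2(cm3)), sum(cm3))
})

test_that("metric formulas match hand arithmetic and flag empty denominators", {
  m <- cm_metrics(matrix(c(8, 1, 2, 9), 2, 2,
                         dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(unname(m$precision), c(8 / 9, 9 / 11))
  expect_equal(unname(m$recall), c(0.8, 0.9))
  expect_equal(m$accuracy, 0.85)
  perfect <- diag(c(5, 5, 5))
  mp <- cm_metrics(perfect)
  expect_true(all(mp$precision == 1) && all(mp$recall == 1))
  expect_equal(mp$accuracy, 1)
  # a class never predicted: precision undefined, not zero
  cm <- matrix(c(5, 3, 0, 0), 2, 2)
  expect_true(is.na(cm_metrics(cm)$precision[2]))
  expect_error(cm_metrics(matrix(0, 2, 3)), "square")
})

test_that("metrics agree with a brute-force counter on random label sequences", {
  set.seed(99)
  n <- 1000
  truth <- sample(quality_classes(), n, replace = TRUE,
                  prob = c(0.9, 0.05, 0.05))
  pred <- sample(quality_classes(), n, replace = TRUE)
  cm <- confusion_3x3(truth, pred)
  oc <- oracle_confusion(truth, pred, quality_classes())
  expect_true(all(cm == oc))
  m <- cm_metrics(cm)
  for (cl in quality_classes()) {
    expect_equal(unname(m$precision[cl]),
                 sum(truth == cl & pred == cl) / sum(pred == cl))
    expect_equal(unname(m$recall[cl]),
                 sum(truth == cl & pred == cl) / sum(truth == cl))
  }
  expect_equal(m$accuracy, mean(truth == pred))
})

test_that("merging never loses counts and helps when errors stay in-block", {
  set.seed(7)
  for (i in 1:10) {
    truth <- sample(quality_classes(), 200, replace = TRUE)
    pred <- sample(quality_classes(), 200, replace = TRUE)
    r <- evaluate_predictions(truth, pred)
    expect_identical(sum(r$cm2), sum(r$cm3))
    expect_gte(r$accuracy2, r$accuracy3)  # cross-errors here are within-block
  }
  # constructed case: acceptable <-> uncertain confusions vanish after merge
  truth <- rep(c("acceptable", "uncertain"), 50)
  pred <- rep(c("uncertain", "acceptable"), 50)
  r <- evaluate_predictions(truth, pred)
  expect_equal(r$accuracy3, 0)
  expect_equal(r$accuracy2, 1)
})
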