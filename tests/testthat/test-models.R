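# small labelled feature set with a clear class structure
toy_features <- function(n_per_class = 30, seed = 5) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * 4, 0), ncol = 4),
               matrix(rnorm(n_per_class * 4, 3), ncol = 4),
               matrix(rnorm(n_per_class * 4, -3), ncol = 4))
    colnames(X) <- paste0("f", 1:4)
    list(X = X, y = factor(rep(quality_classes(), each = n_per_class)))
  })
}

test_that("warm-start training grows the ensemble to n_repetitions x increment trees", {
  toy <- toy_features()
  m <- train_rf(toy$X, toy$y, rf_config(n_repetitions = 20L, seed = 2))
  expect_identical(m$forest$ntree, 1000L)
  expect_identical(nrow(m$history), 20L)
  m1 <- train_rf(toy$X, toy$y, rf_config(n_repetitions = 1L, seed = 2))
  expect_identical(m1$forest$ntree, 50L)
})

test_that("seeded RF training is reproducible and rejects single-class input", {
  toy <- toy_features()
  a <- train_rf(toy$X, toy$y, rf_config(n_repetitions = 3L, seed = 7))
  b <- train_rf(toy$X, toy$y, rf_config(n_repetitions = 3L, seed = 7))
  expect_identical(a$history, b$history)
  expect_identical(predict_proba(a, toy$X), predict_proba(b, toy$X))
  expect_error(train_rf(toy$X[1:30, ], rep("acceptable", 30), rf_config()),
               "2 classes")
})

test_that("probability rows are normalised and quantised by the vote count", {
  toy <- toy_features()
  m <- train_rf(toy$X, toy$y, rf_config(n_repetitions = 4L, seed = 3))
  p <- predict_proba(m, toy$X)
  expect_identical(dim(p), c(90L, 3L))
  expect_identical(colnames(p), quality_classes())
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
  # forests vote hard: probabilities are multiples of 1/ntree
  expect_true(all(abs(p * m$forest$ntree - round(p * m$forest$ntree)) < 1e-8))
  # single sample keeps matrix shape
  expect_identical(nrow(predict_proba(m, toy$X[1, , drop = FALSE])), 1L)
})

test_that("predict_proba rejects unfitted objects", {
  expect_error(predict_proba(structure(list(), class = "lm"), NULL),
               "not a fitted")
})

test_that("config validation enforces the topology constraints", {
  expect_error(cnn_config(feature_maps = c(50L, 100L, 25L)),
               "strictly decreasing")
  expect_error(cnn_config(dense_sizes = c(64L, 64L)), "strictly decreasing")
  expect_error(cnn_config(n_classes = 4L), "2 or 3")
  expect_error(rf_config(estimators_increment = 0L))
  cfg <- cnn_config()
  expect_identical(cfg$feature_maps, c(100L, 50L, 25L))
  expect_identical(cfg$pool_sizes, c(10L, 5L, 3L))
  expect_identical(cfg$dense_sizes, c(128L, 64L, 32L, 16L))
  expect_equal(cfg$activation_slope, 0.002)
  expect_equal(cfg$dropout_keep, 0.5)
  expect_equal(cfg$l2_alpha, 0.01)
  expect_equal(cfg$learning_rate, 0.001)
  expect_identical(cfg$batch_size, 50L)
})

tiny_cnn_cfg <- function(...) {
  cnn_config(feature_maps = c(4L, 2L), kernel_sizes = c(3L, 3L),
             pool_sizes = c(2L, 2L), pool_stride = 2L,
             dense_sizes = c(8L, 4L), n_classes = 2L,
             input_dim = c(12L, 14L), ...)
}

test_that("CNN analytic gradients match central finite differences", {
  cfg <- tiny_cnn_cfg(dropout_keep = 1, seed = 7)
  withr::with_seed(42, {
    net <- ecgsqc:::cnn_init(cfg)
    x <- array(rnorm(1 * 12 * 14 * 3), c(1, 12, 14, 3))
    y <- ecgsqc:::onehot(c(1L, 2L, 1L), 2L)
    fw <- ecgsqc:::cnn_forward(net, x, train = TRUE, cache = TRUE)
    gr <- ecgsqc:::cnn_grads(net, fw, y)
    lossfn <- function(n) {
      f <- ecgsqc:::cnn_forward(n, x)
      ecgsqc:::cnn_loss(n, f$probs, y)
    }
    eps <- 1e-5
    for (nm in names(net$params)) {
      p <- net$params[[nm]]
      ii <- sample(length(p), min(4, length(p)))
      num <- vapply(ii, function(i) {
        n1 <- net; n1$params[[nm]][i] <- p[i] + eps
        n2 <- net; n2$params[[nm]][i] <- p[i] - eps
        (lossfn(n1) - lossfn(n2)) / (2 * eps)
      }, numeric(1))
      expect_equal(num, as.numeric(gr[[nm]])[ii], tolerance = 1e-6,
                   label = nm)
    }
  })
})

test_that("a tiny CNN separates a linearly separable image set", {
  withr::with_seed(33, {
    n <- 40
    mu <- matrix(0, 12, 14); mu[4:8, 5:9] <- 1
    X <- array(rnorm(12 * 14 * 2 * n, 0, 0.2), c(12, 14, 2 * n))
    for (i in seq_len(n)) X[, , i] <- X[, , i] + mu
  })
  y <- factor(rep(c("good", "bad"), each = n))
  cfg <- tiny_cnn_cfg(n_steps = 4L, epochs_per_step = 25L, patience = 4L,
                      batch_size = 16L, seed = 5)
  m <- train_cnn(X, y, cfg)
  p <- predict_proba(m, X)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  acc <- mean(colnames(p)[max.col(p)] == as.character(y))
  expect_gte(acc, 0.95)
})

test_that("CNN training validates shapes and class structure", {
  X <- array(rnorm(12 * 14 * 4), c(12, 14, 4))
  expect_error(train_cnn(X, factor(rep("a", 4)), tiny_cnn_cfg()),
               "2 classes")
  expect_error(train_cnn(X, factor(c("a", "a", "b", "b")),
                         cnn_config(n_classes = 2L)),
               "does not match")
  m <- NULL
  expect_error(predict_proba(structure(list(cfg = tiny_cnn_cfg(),
                                            classes = c("a", "b")),
                                       class = "ecgsqc_cnn"),
                             array(0, c(9, 9, 1))),
               "does not match")
})

test_that("seeded CNN training is exactly reproducible", {
  withr::with_seed(21, {
    X <- array(rnorm(12 * 14 * 20), c(12, 14, 20))
  })
  y <- factor(rep(c("a", "b"), 10))
  cfg <- tiny_cnn_cfg(n_steps = 2L, epochs_per_step = 2L, batch_size = 8L,
                      seed = 9)
  m1 <- train_cnn(X, y, cfg)
  m2 <- train_cnn(X, y, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$net$params, m2$net$params)
})
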