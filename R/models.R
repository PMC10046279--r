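#' Configuration of the warm-start random forest
#'
#' The forest is grown incrementally: each of `n_repetitions` training steps
#' draws a fresh balanced sample (new draws from the abundant acceptable
#' class), fits `estimators_increment` new trees with bootstrap and
#' out-of-bag scoring, and appends them to the ensemble (warm start). The
#' final ensemble therefore holds `n_repetitions * estimators_increment`
#' trees (1000 by default). Tree hyper-parameters beyond those listed stay at
#' the randomForest defaults.
#'
#' @param estimators_increment Trees added per step (default 50).
#' @param bootstrap Sample with replacement when fitting each tree.
#' @param use_oob Keep out-of-bag error estimates.
#' @param warm_start Grow the ensemble across steps (the scheme above);
#'   setting FALSE refits from scratch each step and returns the last fit.
#' @param n_repetitions Number of balanced-resampling training steps.
#' @param val_fraction Fraction of each step's sample held out for
#'   validation (default 0.2).
#' @param seed Integer seed for sampling and tree growing.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(estimators_increment = 50L, bootstrap = TRUE,
                      use_oob = TRUE, warm_start = TRUE,
                      n_repetitions = 20L, val_fraction = 0.2, seed = 1L) {
  stopifnot(estimators_increment > 0, n_repetitions >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(estimators_increment = as.integer(estimators_increment),
                 bootstrap = bootstrap, use_oob = use_oob,
                 warm_start = warm_start,
                 n_repetitions = as.integer(n_repetitions),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "rf_config")
}

#' Configuration of the small 2D CNN
#'
#' Fixes the network topology and training scheme: three conv blocks with
#' geometrically decreasing feature maps (100, 50, 25) and correspondingly
#' decreasing kernels (7, 5, 3), average pooling with pool sizes (10, 5, 3)
#' at stride 3, leaky rectification with negative-side slope 0.002, dense
#' layers (128, 64, 32, 16) with dropout keep probability 0.5, a softmax
#' head, L2 penalty 0.01 on all weights, and Adam at learning rate 0.001
#' with batch size 50. Training runs up to `n_steps` balanced-resampling
#' steps of `epochs_per_step` epochs each (at most `max_epochs` epochs in
#' total), with early stopping on the held-out validation loss and
#' restoration of the checkpoint with the best validation precision+recall.
#'
#' @param feature_maps Strictly decreasing feature-map counts per conv block.
#' @param kernel_sizes Kernel edge per block (square kernels).
#' @param pool_sizes Average-pool window per block, non-increasing.
#' @param pool_stride Pooling stride.
#' @param activation_slope Negative-side slope of the leaky rectifier.
#' @param dropout_keep Keep probability of the dense-layer dropout.
#' @param dense_sizes Strictly decreasing hidden dense widths.
#' @param l2_alpha L2 penalty weight.
#' @param learning_rate,batch_size,max_epochs Adam optimiser settings.
#' @param n_classes 2 or 3 output classes.
#' @param n_steps Balanced-resampling training steps (default 20).
#' @param epochs_per_step Optimiser epochs per step; defaults to
#'   `max(1, max_epochs %/% n_steps)`.
#' @param patience Steps without validation-loss improvement before
#'   stopping; the default 1 stops at the first non-improving step, the
#'   usual early-stopping convention.
#' @param val_fraction Held-out fraction per step (default 0.2).
#' @param input_dim Image dimensions (rows, cols), default c(80, 100).
#' @param seed Integer seed.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(feature_maps = c(100L, 50L, 25L),
                       kernel_sizes = c(7L, 5L, 3L),
                       pool_sizes = c(10L, 5L, 3L), pool_stride = 3L,
                       activation_slope = 0.002, dropout_keep = 0.5,
                       dense_sizes = c(128L, 64L, 32L, 16L),
                       l2_alpha = 0.01, learning_rate = 0.001,
                       batch_size = 50L, max_epochs = 100L, n_classes = 3L,
                       n_steps = 20L, epochs_per_step = NULL, patience = 1L,
                       val_fraction = 0.2, input_dim = c(80L, 100L),
                       seed = 1L) {
  stopifnot(length(feature_maps) == length(kernel_sizes),
            length(feature_maps) == length(pool_sizes))
  if (any(diff(feature_maps) >= 0))
    stop("feature_maps must be strictly decreasing", call. = FALSE)
  if (any(diff(dense_sizes) >= 0))
    stop("dense_sizes must be strictly decreasing", call. = FALSE)
  if (any(diff(pool_sizes) > 0))
    stop("pool_sizes must be non-increasing", call. = FALSE)
  if (!n_classes %in% c(2L, 3L))
    stop("n_classes must be 2 or 3", call. = FALSE)
  if (is.null(epochs_per_step))
    epochs_per_step <- max(1L, as.integer(max_epochs) %/% as.integer(n_steps))
  structure(list(feature_maps = as.integer(feature_maps),
                 kernel_sizes = as.integer(kernel_sizes),
                 pool_sizes = as.integer(pool_sizes),
                 pool_stride = as.integer(pool_stride),
                 activation_slope = activation_slope,
                 dropout_keep = dropout_keep,
                 dense_sizes = as.integer(dense_sizes),
                 l2_alpha = l2_alpha, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 n_classes = as.integer(n_classes),
                 n_steps = as.integer(n_steps),
                 epochs_per_step = as.integer(epochs_per_step),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 input_dim = as.integer(input_dim),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

# Fresh balanced draw: n per class (defaults to the minority count),
# sampled without replacement inside the caller's RNG stream.
draw_balanced <- function(labels, n_per_class = NULL) {
  labels <- droplevels(factor(labels))
  counts <- table(labels)
  if (is.null(n_per_class)) n_per_class <- min(counts)
  if (n_per_class < 1) stop("a required class is empty", call. = FALSE)
  idx <- unlist(lapply(levels(labels), function(lv) {
    pool <- which(labels == lv)
    pool[sample.int(length(pool), n_per_class)]
  }), use.names = FALSE)
  idx[sample.int(length(idx))]
}

# Macro per-class precision/recall of predictions vs truth (both factors on
# the same levels); undefined per-class values are dropped from the macro
# average.
macro_pr <- function(truth, pred) {
  cm <- table(truth, pred)
  prec <- diag(cm) / colSums(cm)
  rec <- diag(cm) / rowSums(cm)
  c(precision = mean(prec, na.rm = TRUE), recall = mean(rec, na.rm = TRUE))
}

#' Train the warm-start random forest
#'
#' Runs `cfg$n_repetitions` balanced-resampling steps. Each step draws a
#' fresh equal-sized sample from every class (re-drawing from the abundant
#' acceptable class), holds out `cfg$val_fraction` of it for validation,
#' fits `cfg$estimators_increment` new trees and appends them to the
#' ensemble. Per-step validation precision/recall of the growing ensemble is
#' recorded; the returned model is the full ensemble of
#' `n_repetitions * estimators_increment` trees with the best-scoring step
#' noted in `best_step`.
#'
#' @param features Numeric matrix or data.frame of feature columns.
#' @param labels Class labels (>= 2 classes present).
#' @param cfg An [rf_config()].
#' @param sampler Optional function(step, labels) returning the row indices
#'   of that step's balanced sample; defaults to fresh minority-balanced
#'   draws.
#' @return An object of class `ecgsqc_rf` with elements `forest`, `classes`,
#'   `feature_names`, `history` (per-step validation metrics), `best_step`
#'   and `cfg`.
#' @export
train_rf <- function(features, labels, cfg = rf_config(), sampler = NULL) {
  X <- as.matrix(features)
  if ("segment_id" %in% colnames(X))
    stop("drop the segment_id column before training", call. = FALSE)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 classes", call. = FALSE)
  stopifnot(nrow(X) == length(labels))
  withr::with_seed(cfg$seed, {
    ensemble <- NULL
    hist <- vector("list", cfg$n_repetitions)
    for (step in seq_len(cfg$n_repetitions)) {
      idx <- if (is.null(sampler)) draw_balanced(labels) else
        sampler(step, labels)
      n_val <- max(1L, floor(cfg$val_fraction * length(idx)))
      val_idx <- idx[seq_len(n_val)]
      tr_idx <- idx[-seq_len(n_val)]
      fit <- randomForest::randomForest(
        x = X[tr_idx, , drop = FALSE], y = labels[tr_idx],
        ntree = cfg$estimators_increment, replace = cfg$bootstrap,
        keep.forest = TRUE)
      ensemble <- if (is.null(ensemble) || !cfg$warm_start) fit else
        randomForest::combine(ensemble, fit)
      pv <- predict(ensemble, X[val_idx, , drop = FALSE], type = "response")
      pr <- macro_pr(labels[val_idx], factor(pv, levels = levels(labels)))
      hist[[step]] <- data.frame(step = step, n_trees = ensemble$ntree,
                                 val_precision = pr["precision"],
                                 val_recall = pr["recall"],
                                 score = pr["precision"] + pr["recall"])
    }
    history <- do.call(rbind, hist)
    rownames(history) <- NULL
    structure(list(forest = ensemble, classes = levels(labels),
                   feature_names = colnames(X), history = history,
                   best_step = which.max(history$score), cfg = cfg),
              class = "ecgsqc_rf")
  })
}

# Normalise image input (list of matrices / 3-d array) to (H, W, 1, N).
as_image_array <- function(images, input_dim) {
  if (is.list(images)) {
    arr <- vapply(images, function(m) {
      m <- unclass(m)
      stopifnot(is.matrix(m))
      m
    }, matrix(0, input_dim[1], input_dim[2]))
    arr <- array(arr, c(input_dim, length(images)))
  } else if (is.array(images) && length(dim(images)) == 3) {
    arr <- images
  } else if (is.matrix(images)) {
    arr <- array(images, c(dim(images), 1L))
  } else {
    stop("images must be a list of matrices or a (rows, cols, n) array",
         call. = FALSE)
  }
  if (!all(dim(arr)[1:2] == input_dim))
    stop(sprintf("image shape (%d, %d) does not match expected (%d, %d)",
                 dim(arr)[1], dim(arr)[2], input_dim[1], input_dim[2]),
         call. = FALSE)
  # channel-first singleton axis; linear layout is unchanged
  array(arr, c(1L, input_dim[1], input_dim[2], dim(arr)[3]))
}

#' Train the small 2D CNN
#'
#' Balanced-resampling training of the convolutional classifier: each step
#' draws a fresh equal-sized sample per class, holds out `cfg$val_fraction`
#' for validation, and runs `cfg$epochs_per_step` epochs of minibatch Adam.
#' Validation loss, accuracy and macro precision/recall are recorded per
#' step; training stops early once the validation loss has not improved for
#' `cfg$patience` steps, and the weights of the step with the highest
#' validation precision+recall are restored.
#'
#' @param images List of (80 x 100) input matrices or a (80, 100, n) array
#'   (see [transform_batch()]).
#' @param labels Class labels; the number of classes must equal
#'   `cfg$n_classes`.
#' @param cfg A [cnn_config()].
#' @return An object of class `ecgsqc_cnn` with elements `net`, `classes`,
#'   `history`, `best_step`, `n_steps_run` and `cfg`.
#' @export
train_cnn <- function(images, labels, cfg = cnn_config()) {
  X <- as_image_array(images, cfg$input_dim)
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 classes", call. = FALSE)
  if (nlevels(labels) != cfg$n_classes)
    stop(sprintf("labels have %d classes but cfg$n_classes is %d",
                 nlevels(labels), cfg$n_classes), call. = FALSE)
  stopifnot(dim(X)[4] == length(labels))
  K <- cfg$n_classes
  withr::with_seed(cfg$seed, {
    net <- cnn_init(cfg)
    state <- adam_init(net$params)
    best_loss <- Inf; wait <- 0L
    best_score <- -Inf; best_params <- net$params; best_step <- 0L
    hist <- list()
    epochs_total <- 0L
    for (step in seq_len(cfg$n_steps)) {
      idx <- draw_balanced(labels)
      n_val <- max(1L, floor(cfg$val_fraction * length(idx)))
      val_idx <- idx[seq_len(n_val)]
      tr_idx <- idx[-seq_len(n_val)]
      for (ep in seq_len(cfg$epochs_per_step)) {
        if (epochs_total >= cfg$max_epochs) break
        upd <- cnn_train_epoch(net, state, X, as.integer(labels), K,
                               tr_idx[sample.int(length(tr_idx))])
        net <- upd$net; state <- upd$state
        epochs_total <- epochs_total + 1L
      }
      fw <- cnn_forward(net, X[, , , val_idx, drop = FALSE], train = FALSE)
      val_y <- labels[val_idx]
      # early stopping monitors the data term of the validation loss; the
      # L2 penalty shrinks monotonically and would mask convergence
      val_loss <- -mean(rowSums(onehot(as.integer(val_y), K) *
                                  log(pmax(fw$probs, 1e-12))))
      pred <- factor(levels(labels)[max.col(fw$probs, ties.method = "first")],
                     levels = levels(labels))
      pr <- macro_pr(val_y, pred)
      acc <- mean(pred == val_y)
      hist[[step]] <- data.frame(step = step, val_loss = val_loss,
                                 val_accuracy = acc,
                                 val_precision = pr["precision"],
                                 val_recall = pr["recall"],
                                 score = pr["precision"] + pr["recall"])
      score <- pr["precision"] + pr["recall"]
      if (is.finite(score) && score > best_score) {
        best_score <- score; best_params <- net$params; best_step <- step
      }
      if (val_loss < best_loss - 1e-8) {
        best_loss <- val_loss; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
      if (epochs_total >= cfg$max_epochs) break
    }
    net$params <- best_params  # restore best checkpoint
    history <- do.call(rbind, hist)
    rownames(history) <- NULL
    structure(list(net = net, classes = levels(labels), history = history,
                   best_step = best_step, n_steps_run = nrow(history),
                   cfg = cfg),
              class = "ecgsqc_cnn")
  })
}

#' Class-probability predictions
#'
#' @param object A fitted model (`ecgsqc_rf`, `ecgsqc_cnn`, or a cascade
#'   step).
#' @param newdata Features (matrix/data.frame) or images matching training.
#' @param ... Unused.
#' @return Numeric matrix, one row per observation, one named column per
#'   class; rows are nonnegative and sum to 1.
#' @export
predict_proba <- function(object, newdata, ...) UseMethod("predict_proba")

#' @export
predict_proba.ecgsqc_rf <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    if (is.null(colnames(X)) && ncol(X) == length(object$feature_names))
      colnames(X) <- object$feature_names
    X <- X[, object$feature_names, drop = FALSE]
  }
  p <- predict(object$forest, X, type = "prob")
  p[, object$classes, drop = FALSE]
}

#' @export
predict_proba.ecgsqc_cnn <- function(object, newdata, ...) {
  X <- as_image_array(newdata, object$cfg$input_dim)
  n <- dim(X)[4]
  bs <- object$cfg$batch_size
  out <- matrix(NA_real_, n, length(object$classes),
                dimnames = list(NULL, object$classes))
  for (b0 in seq(1, n, by = bs)) {
    take <- b0:min(n, b0 + bs - 1)
    fw <- cnn_forward(object$net, X[, , , take, drop = FALSE], train = FALSE)
    out[take, ] <- fw$probs
  }
  out
}

#' @export
predict_proba.default <- function(object, newdata, ...) {
  stop("predict_proba: not a fitted ecgsqc model", call. = FALSE)
}

# Stub model whose class-1 probability is read straight from a column of
# newdata; used for exhaustive decision-logic checks.
passthru_model <- function(classes, column) {
  structure(list(classes = classes, column = column),
            class = "ecgsqc_passthru")
}

#' @export
predict_proba.ecgsqc_passthru <- function(object, newdata, ...) {
  p <- as.matrix(newdata)[, object$column]
  out <- cbind(p, 1 - p)
  colnames(out) <- object$classes
  out
}

# Fixed-probability stub model used for decision-logic testing.
constant_model <- function(probs, classes) {
  probs <- matrix(probs, ncol = length(classes))
  colnames(probs) <- classes
  structure(list(probs = probs, classes = classes), class = "ecgsqc_fixed")
}

#' @export
predict_proba.ecgsqc_fixed <- function(object, newdata, ...) {
  n <- if (is.matrix(newdata) || is.data.frame(newdata)) nrow(newdata)
       else length(newdata)
  object$probs[rep(seq_len(nrow(object$probs)), length.out = n), ,
               drop = FALSE]
}
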