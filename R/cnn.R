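# A small 2D convolutional network implemented with explicit matrix algebra
# (im2col convolutions, average pooling, leaky rectification, dropout, dense
# stack, softmax head) and an Adam optimiser. The topology is fixed by
# cnn_config(): stacked conv blocks with geometrically decreasing feature
# maps and kernels, average pooling with decreasing pool sizes at stride 3,
# then dense layers 128-64-32-16 and a softmax output.
#
# Activations are held channel-first, (C, H, W, B), so that a convolution
# computed as crossprod(W, im2col_cf(x)) reshapes to the next layer's array
# by setting dim only -- no permutation copies anywhere in the hot path.

leaky <- function(z, slope) z * (1 + (slope - 1) * (z < 0))
leaky_grad <- function(a, slope) 1 + (slope - 1) * (a < 0)

# Layer geometry for a given input size; errors if the stack does not fit.
cnn_dims <- function(cfg) {
  H <- cfg$input_dim[1]; W <- cfg$input_dim[2]; C <- 1L
  blocks <- list()
  for (i in seq_along(cfg$feature_maps)) {
    k <- cfg$kernel_sizes[i]
    Hc <- H - k + 1L; Wc <- W - k + 1L
    if (Hc < 1 || Wc < 1) stop("conv kernel larger than input", call. = FALSE)
    p <- cfg$pool_sizes[i]; s <- cfg$pool_stride
    Hp <- (Hc - p) %/% s + 1L; Wp <- (Wc - p) %/% s + 1L
    if (Hp < 1 || Wp < 1) stop("pool window larger than input", call. = FALSE)
    blocks[[i]] <- list(in_dim = c(C, H, W), k = k,
                        conv_dim = c(cfg$feature_maps[i], Hc, Wc),
                        p = p, s = s,
                        out_dim = c(cfg$feature_maps[i], Hp, Wp))
    H <- Hp; W <- Wp; C <- cfg$feature_maps[i]
  }
  list(blocks = blocks, flat = H * W * C)
}

# He-style initialisation of all weights inside the caller's RNG stream.
# Conv weights are (k*k*C_in x M); dense weights (in x out).
cnn_init <- function(cfg) {
  dims <- cnn_dims(cfg)
  params <- list()
  for (i in seq_along(dims$blocks)) {
    bl <- dims$blocks[[i]]
    fan_in <- bl$k^2 * bl$in_dim[1]
    params[[paste0("convW", i)]] <-
      matrix(rnorm(fan_in * bl$conv_dim[1], 0, sqrt(2 / fan_in)),
             fan_in, bl$conv_dim[1])
    params[[paste0("convb", i)]] <- numeric(bl$conv_dim[1])
  }
  sizes <- c(dims$flat, cfg$dense_sizes, cfg$n_classes)
  for (j in seq_len(length(sizes) - 1)) {
    params[[paste0("denseW", j)]] <-
      matrix(rnorm(sizes[j] * sizes[j + 1], 0, sqrt(2 / sizes[j])),
             sizes[j], sizes[j + 1])
    params[[paste0("denseb", j)]] <- numeric(sizes[j + 1])
  }
  list(cfg = cfg, dims = dims, params = params,
       n_dense = length(sizes) - 1)
}

# Conv backward from the cached im2col expansion of the layer input. The
# gradient w.r.t. the input is only materialised when a previous layer
# needs it.
conv_backward_cf <- function(cols, dZm, W, k, in_dim, B, need_dx = TRUE) {
  dW <- tcrossprod(cols, dZm)
  db <- rowSums(dZm)
  dx <- NULL
  if (need_dx) {
    dcols <- W %*% dZm
    dx <- col2im_cf(dcols, in_dim[1], in_dim[2], in_dim[3], B, k, 1L)
    dim(dx) <- c(in_dim, B)
  }
  list(dW = dW, db = db, dx = dx)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass; with cache = TRUE keeps every layer input for the backward
# pass. Dropout (inverted, keep probability cfg$dropout_keep) is applied to
# the hidden dense activations only when train = TRUE, drawing masks from
# the caller's RNG stream.
cnn_forward <- function(net, x, train = FALSE, cache = FALSE) {
  cfg <- net$cfg; dims <- net$dims
  B <- dim(x)[4]
  cc <- list(cols = list(), pool_in = list(),
             dense_in = list(), drop_mask = list())
  a <- x
  for (i in seq_along(dims$blocks)) {
    bl <- dims$blocks[[i]]
    cols <- im2col_cf(a, bl$in_dim[1], bl$in_dim[2], bl$in_dim[3], B,
                      bl$k, 1L)
    if (cache) cc$cols[[i]] <- cols
    a <- bias_leaky_inplace(crossprod(net$params[[paste0("convW", i)]], cols),
                            net$params[[paste0("convb", i)]],
                            cfg$activation_slope)
    if (cache) cc$pool_in[[i]] <- a
    dim(a) <- c(bl$conv_dim, B)
    a <- avgpool_cf_fwd(a, bl$conv_dim[1], bl$conv_dim[2], bl$conv_dim[3],
                        B, bl$p, bl$s)
    dim(a) <- c(bl$out_dim, B)
  }
  h <- t(matrix(a, dims$flat, B))
  for (j in seq_len(net$n_dense)) {
    if (cache) cc$dense_in[[j]] <- h
    z <- sweep(h %*% net$params[[paste0("denseW", j)]], 2,
               net$params[[paste0("denseb", j)]], "+")
    if (j < net$n_dense) {
      h <- leaky(z, cfg$activation_slope)
      if (train) {
        mask <- matrix((runif(length(h)) < cfg$dropout_keep) /
                         cfg$dropout_keep, nrow(h), ncol(h))
        h <- h * mask
        if (cache) cc$drop_mask[[j]] <- mask
      } else if (cache) cc$drop_mask[j] <- list(NULL)
    } else {
      h <- z
    }
  }
  probs <- softmax_rows(h)
  list(probs = probs, cache = if (cache) cc else NULL)
}

# Cross-entropy loss with L2 penalty alpha * sum(w^2) over every weight
# matrix (biases unpenalised).
cnn_loss <- function(net, probs, y_onehot) {
  ce <- -mean(rowSums(y_onehot * log(pmax(probs, 1e-12))))
  l2 <- sum(vapply(grep("W", names(net$params), value = TRUE),
                   function(nm) sum(net$params[[nm]]^2), numeric(1)))
  ce + net$cfg$l2_alpha * l2
}

cnn_grads <- function(net, fw, y_onehot) {
  cfg <- net$cfg; dims <- net$dims
  B <- nrow(fw$probs)
  grads <- list()
  dh <- (fw$probs - y_onehot) / B
  for (j in rev(seq_len(net$n_dense))) {
    hin <- fw$cache$dense_in[[j]]
    Wj <- net$params[[paste0("denseW", j)]]
    grads[[paste0("denseW", j)]] <- crossprod(hin, dh) + 2 * cfg$l2_alpha * Wj
    grads[[paste0("denseb", j)]] <- colSums(dh)
    dh <- tcrossprod(dh, Wj)
    if (j > 1) {
      mask <- fw$cache$drop_mask[[j - 1]]
      if (!is.null(mask)) dh <- dh * mask
      # sign of the (post-dropout) activation equals the pre-activation sign
      dh <- dh * leaky_grad(fw$cache$dense_in[[j]], cfg$activation_slope)
    }
  }
  nb <- length(dims$blocks)
  da <- matrix(t(dh), dims$flat, B)
  dim(da) <- c(dims$blocks[[nb]]$out_dim, B)
  for (i in rev(seq_along(dims$blocks))) {
    bl <- dims$blocks[[i]]
    da <- avgpool_cf_bwd(da, bl$conv_dim[1], bl$conv_dim[2], bl$conv_dim[3],
                         B, bl$p, bl$s)
    apre <- fw$cache$pool_in[[i]]  # (M x P*B) activation matrix
    dz <- leaky_grad_mul_inplace(da, apre, cfg$activation_slope)
    dim(dz) <- dim(apre)
    bw <- conv_backward_cf(fw$cache$cols[[i]], dz,
                           net$params[[paste0("convW", i)]],
                           bl$k, bl$in_dim, B, need_dx = i > 1)
    grads[[paste0("convW", i)]] <- bw$dW +
      2 * cfg$l2_alpha * net$params[[paste0("convW", i)]]
    grads[[paste0("convb", i)]] <- bw$db
    da <- bw$dx
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

onehot <- function(y, K) {
  m <- matrix(0, length(y), K)
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

# One epoch of minibatch Adam over the given index order.
cnn_train_epoch <- function(net, state, X, y_int, K, idx) {
  cfg <- net$cfg
  bs <- cfg$batch_size
  for (b0 in seq(1, length(idx), by = bs)) {
    take <- idx[b0:min(length(idx), b0 + bs - 1)]
    xb <- X[, , , take, drop = FALSE]
    yb <- onehot(y_int[take], K)
    fw <- cnn_forward(net, xb, train = TRUE, cache = TRUE)
    grads <- cnn_grads(net, fw, yb)
    upd <- adam_step(net$params, grads, state, cfg$learning_rate)
    net$params <- upd$params
    state <- upd$state
  }
  list(net = net, state = state)
}
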