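# Convolutional regression network mapping a zero-padded 6-channel stride
# window to stride length. The stack is conv(valid, ReLU) -> maxpool(2) ->
# conv(valid, ReLU) -> maxpool(2) -> flatten -> dense(ReLU) -> dropout ->
# dense(1, linear), trained with mean-squared error and Adam. Implemented
# directly on arrays (im2col convolutions with BLAS matrix products); the
# network is small enough that no framework is needed.

#' Network architecture specification
#'
#' Defaults give the reference architecture: 32 kernels of length 30, 16
#' kernels of length 15, pooling by 2 after each convolution (floor on odd
#' lengths), a 128-unit hidden dense layer with 30% dropout after its
#' activation, and one linear output. Feature-map lengths for a 200-sample
#' input are 171 -> 85 -> 71 -> 35, so the flattened feature vector has
#' 35 * 16 = 560 entries and the default network has exactly 85,425 trainable
#' parameters; the wider (n2 = 64, m1 = 1024) variant has 2,332,385.
#'
#' @param input_len Input length in samples. Default 200.
#' @param channels Input channels. Default 6.
#' @param n1,k1 Filters and kernel length of the first convolution (32, 30).
#' @param n2,k2 Filters and kernel length of the second convolution (16, 15).
#' @param pool Pooling factor (non-overlapping maxima). Default 2.
#' @param m1 Hidden dense units. Default 128.
#' @param dropout_rate Dropout fraction between the dense layers. Default 0.30.
#' @return List of class `network_spec`.
#' @export
network_spec <- function(input_len = 200L, channels = 6L,
                         n1 = 32L, k1 = 30L, n2 = 16L, k2 = 15L,
                         pool = 2L, m1 = 128L, dropout_rate = 0.30) {
  l1 <- input_len - k1 + 1L
  p1 <- l1 %/% pool
  l2 <- p1 - k2 + 1L
  p2 <- l2 %/% pool
  if (l1 < 1L || l2 < 1L || p2 < 1L)
    stop("spec error: input too short for two valid convolutions with pooling")
  structure(list(input_len = as.integer(input_len), channels = as.integer(channels),
                 n1 = as.integer(n1), k1 = as.integer(k1),
                 n2 = as.integer(n2), k2 = as.integer(k2),
                 pool = as.integer(pool), m1 = as.integer(m1),
                 dropout_rate = dropout_rate,
                 l1 = l1, p1 = p1, l2 = l2, p2 = p2,
                 flat = p2 * as.integer(n2)),
            class = "network_spec")
}

#' Zero-pad a stride window to the network input length
#'
#' Trailing zeros are appended per channel; the original samples are
#' unchanged. Strides longer than `target_len` are an error (the stride is
#' too slow for the architecture).
#'
#' @param stride n x C numeric matrix (one stride, channels in columns).
#' @param target_len Target length in samples. Default 200.
#' @return `target_len` x C matrix.
#' @export
pad_stride_to_fixed_length <- function(stride, target_len = 200L) {
  stride <- as.matrix(stride)
  n <- nrow(stride)
  if (n > target_len)
    stop(sprintf("input error: stride of %d samples exceeds the %d-sample network input",
                 n, target_len))
  if (n == target_len) return(stride)
  rbind(stride, matrix(0, target_len - n, ncol(stride)))
}

#' Build an (untrained) network
#'
#' Allocates the weight store for a [network_spec()]. Convolutions use one
#' bias per filter and dense layers one bias per output unit. With
#' `init = "he"`, weights are drawn from scaled normal distributions suited
#' to ReLU stacks; `init = "zero"` gives an all-zero network (useful as a
#' fixed point: zero input then maps to output 0).
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the weight draw.
#' @param init `"he"` or `"zero"`.
#' @return List of class `cnn_model` with elements `spec`, `params`,
#'   `trained`, `epochs`, `batch_size` and `loss_history`.
#' @export
build_network <- function(spec = network_spec(), seed = 1L,
                          init = c("he", "zero")) {
  init <- match.arg(init)
  stopifnot(inherits(spec, "network_spec"))
  dims <- list(W1 = c(spec$k1 * spec$channels, spec$n1), b1 = spec$n1,
               W2 = c(spec$k2 * spec$n1, spec$n2),       b2 = spec$n2,
               W3 = c(spec$flat, spec$m1),               b3 = spec$m1,
               W4 = c(spec$m1, 1L),                      b4 = 1L)
  params <- if (init == "zero") {
    lapply(dims, function(d) if (length(d) == 2L) matrix(0, d[1], d[2]) else numeric(d))
  } else {
    set.seed(seed)
    out <- list()
    for (nm in names(dims)) {
      d <- dims[[nm]]
      out[[nm]] <- if (length(d) == 2L) {
        matrix(rnorm(prod(d), sd = sqrt(2 / d[1])), d[1], d[2])
      } else numeric(d)
    }
    out
  }
  structure(list(spec = spec, params = params, trained = FALSE,
                 epochs = 5L, batch_size = 16L, loss_history = numeric(0)),
            class = "cnn_model")
}

#' Count trainable parameters
#'
#' @param model A `cnn_model`.
#' @return Integer total of all weight and bias entries.
#' @examples
#' count_parameters(build_network(network_spec()))                  # 85425
#' count_parameters(build_network(network_spec(n2 = 64, m1 = 1024))) # 2332385
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  sum(vapply(model$params, length, integer(1)))
}

# ---- array plumbing ---------------------------------------------------------

# xarr: (len, C, B). Returns (L_out * B) x (K * C) matrix, rows ordered with
# position fastest, then batch; columns in channel-major blocks of K.
im2col <- function(xarr, K) {
  len <- dim(xarr)[1]; C <- dim(xarr)[2]; B <- dim(xarr)[3]
  L_out <- len - K + 1L
  idx <- as.vector(outer(seq_len(L_out), 0:(K - 1L), "+"))
  out <- matrix(0, L_out * B, K * C)
  for (c in seq_len(C)) {
    slab <- matrix(xarr[, c, ], len, B)          # len x B
    g <- array(slab[idx, ], c(L_out, K, B))      # gather
    out[, ((c - 1L) * K + 1L):(c * K)] <- matrix(aperm(g, c(1, 3, 2)), L_out * B, K)
  }
  out
}

# inverse scatter-add of im2col for gradients: dX ((L_out*B) x (K*C)) ->
# (len, C, B)
col2im_add <- function(dX, len, C, B, K) {
  L_out <- len - K + 1L
  acc <- array(0, c(len, C, B))
  for (k in seq_len(K)) {
    cols <- (seq_len(C) - 1L) * K + k
    g <- array(dX[, cols], c(L_out, B, C))       # (L_out, B, C)
    acc[k:(k + L_out - 1L), , ] <- acc[k:(k + L_out - 1L), , , drop = FALSE] +
      aperm(g, c(1, 3, 2))
  }
  acc
}

# (L_out*B) x N matrix (position fastest) -> (L_out, N, B)
to_feature_array <- function(m, L_out, B) {
  aperm(array(m, c(L_out, B, ncol(m))), c(1, 3, 2))
}

# (L, N, B) -> matrix ((L*B) x N), position fastest
to_feature_matrix <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(1, 3, 2)), d[1] * d[3], d[2])
}

# non-overlapping max pooling over the first dimension (factor 2, floor);
# returns pooled array and the winner mask for backprop
maxpool2 <- function(arr) {
  L <- dim(arr)[1]
  Lp <- L %/% 2L
  i1 <- arr[seq(1L, 2L * Lp, 2L), , , drop = FALSE]
  i2 <- arr[seq(2L, 2L * Lp, 2L), , , drop = FALSE]
  list(out = pmax(i1, i2), first_wins = i1 >= i2, L_in = L)
}

maxpool2_backward <- function(dpool, pool) {
  d <- dim(dpool)
  dA <- array(0, c(pool$L_in, d[2], d[3]))
  dA[seq(1L, 2L * d[1], 2L), , ] <- dpool * pool$first_wins
  dA[seq(2L, 2L * d[1], 2L), , ] <- dpool * !pool$first_wins
  dA
}

# Forward pass. xarr (len, C, B); returns prediction vector and, if
# keep_cache, everything backprop needs. dropout_mask NULL => inference.
cnn_forward <- function(model, xarr, dropout_mask = NULL, keep_cache = FALSE) {
  sp <- model$spec; pr <- model$params
  B <- dim(xarr)[3]
  X1 <- im2col(xarr, sp$k1)
  Z1 <- sweep(X1 %*% pr$W1, 2L, pr$b1, "+")
  A1 <- to_feature_array(pmax(Z1, 0), sp$l1, B)
  P1 <- maxpool2(A1)
  X2 <- im2col(P1$out, sp$k2)
  Z2 <- sweep(X2 %*% pr$W2, 2L, pr$b2, "+")
  A2 <- to_feature_array(pmax(Z2, 0), sp$l2, B)
  P2 <- maxpool2(A2)
  Fm <- t(matrix(P2$out, sp$flat, B))            # B x flat
  Z3 <- sweep(Fm %*% pr$W3, 2L, pr$b3, "+")
  H <- pmax(Z3, 0)
  Hd <- if (is.null(dropout_mask)) H else H * dropout_mask
  out <- drop(Hd %*% pr$W4) + pr$b4
  if (!keep_cache) return(list(pred = out))
  list(pred = out, X1 = X1, Z1 = Z1, P1 = P1, X2 = X2, Z2 = Z2, P2 = P2,
       Fm = Fm, Z3 = Z3, Hd = Hd, B = B)
}

# Backward pass for the MSE loss; returns gradients named like params.
cnn_backward <- function(model, cache, dout, dropout_mask) {
  sp <- model$spec; pr <- model$params
  B <- cache$B
  dout <- matrix(dout, B, 1L)
  gW4 <- t(cache$Hd) %*% dout
  gb4 <- sum(dout)
  dHd <- dout %*% t(pr$W4)
  if (!is.null(dropout_mask)) dHd <- dHd * dropout_mask
  dZ3 <- dHd * (cache$Z3 > 0)
  gW3 <- t(cache$Fm) %*% dZ3
  gb3 <- colSums(dZ3)
  dFm <- dZ3 %*% t(pr$W3)                        # B x flat
  dP2 <- array(t(dFm), c(sp$p2, sp$n2, B))
  dA2 <- maxpool2_backward(dP2, cache$P2)
  dZ2 <- to_feature_matrix(dA2) * (cache$Z2 > 0)
  gW2 <- t(cache$X2) %*% dZ2
  gb2 <- colSums(dZ2)
  dX2 <- dZ2 %*% t(pr$W2)
  dP1 <- col2im_add(dX2, sp$p1, sp$n1, B, sp$k2)
  dA1 <- maxpool2_backward(dP1, cache$P1)
  dZ1 <- to_feature_matrix(dA1) * (cache$Z1 > 0)
  gW1 <- t(cache$X1) %*% dZ1
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

#' Train the network with mean-squared error and Adam
#'
#' Runs `epochs` passes over the data in shuffled mini-batches, applying
#' inverted dropout between the dense layers during training only. All
#' randomness (shuffling, dropout) flows from `seed`, so two runs with the
#' same seed give identical loss histories.
#'
#' @param model A `cnn_model` from [build_network()].
#' @param x Array of padded strides, `(input_len, channels, n)` — see
#'   [pad_stride_to_fixed_length()].
#' @param y Numeric vector of target stride lengths (m), length `n`.
#' @param epochs,batch_size Training recipe; defaults 5 and 16.
#' @param lr Adam step size. Default 1e-3.
#' @param seed Integer seed.
#' @return The trained `cnn_model`, with `loss_history` (mean training MSE
#'   per epoch) and `initial_mse` (MSE of the untrained model on `x`).
#' @export
train_model <- function(model, x, y, epochs = 5L, batch_size = 16L,
                        lr = 1e-3, seed = 1L) {
  stopifnot(inherits(model, "cnn_model"))
  if (length(dim(x)) != 3L || dim(x)[3] != length(y))
    stop("'x' must be (input_len, channels, n) with one target per stride")
  if (anyNA(x) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("data error: non-finite training inputs or targets")
  n <- length(y)
  if (n < batch_size) stop("need at least one full batch of training strides")
  set.seed(seed)
  p <- model$spec$dropout_rate
  adam_m <- lapply(model$params, function(w) w * 0)
  adam_v <- lapply(model$params, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
  model$initial_mse <- mean((cnn_forward(model, x)$pred - y)^2)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (b0 in seq(1L, n - batch_size + 1L, by = batch_size)) {
      take <- ord[b0:(b0 + batch_size - 1L)]
      xb <- x[, , take, drop = FALSE]
      yb <- y[take]
      mask <- if (p > 0) {
        matrix(stats::rbinom(batch_size * model$spec$m1, 1L, 1 - p),
               batch_size, model$spec$m1) / (1 - p)
      } else NULL
      cache <- cnn_forward(model, xb, dropout_mask = mask, keep_cache = TRUE)
      err <- cache$pred - yb
      losses <- c(losses, mean(err^2))
      grads <- cnn_backward(model, cache, 2 * err / batch_size, mask)
      step <- step + 1L
      for (nm in names(model$params)) {
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grads[[nm]]
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - beta1^step)
        vhat <- adam_v[[nm]] / (1 - beta2^step)
        model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    history[ep] <- mean(losses)
  }
  model$trained <- TRUE
  model$epochs <- as.integer(epochs)
  model$batch_size <- as.integer(batch_size)
  model$loss_history <- history
  model
}

#' Predict stride length for padded stride windows
#'
#' Inference pass (dropout inactive, so repeated calls are bit-identical).
#'
#' @param model A `cnn_model`.
#' @param x `(input_len, channels, n)` array, or a single
#'   `input_len x channels` matrix.
#' @return Numeric vector of predicted stride lengths (m), unclamped.
#' @export
predict_stride_length <- function(model, x) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  cnn_forward(model, x)$pred
}

#' Deep-learning stride estimates
#'
#' For each initial-contact window: slice the 6 channels, zero-pad to the
#' network input length, regress stride length (clamped at 0 with a warning
#' when negative), and divide by the window's stride time for velocity.
#'
#' @param rec An [imu_recording()].
#' @param windows A [stride_windows()] data frame (initial-contact anchored).
#' @param model A trained `cnn_model`.
#' @return A [stride_estimates()] data frame (algorithm `"deep_learning"`).
#' @export
estimate_strides_deep_learning <- function(rec, windows, model) {
  if (!inherits(model, "cnn_model") || !isTRUE(model$trained))
    stop("state error: 'model' must be a trained cnn_model")
  sp <- model$spec
  n_w <- nrow(windows)
  if (n_w == 0L)
    return(stride_estimates(numeric(0), numeric(0), algorithm = "deep_learning"))
  x <- array(0, c(sp$input_len, sp$channels, n_w))
  for (i in seq_len(n_w)) {
    seg <- cbind(rec$a, rec$g)[windows$start[i]:(windows$end[i] - 1L), , drop = FALSE]
    x[, , i] <- pad_stride_to_fixed_length(seg, sp$input_len)
  }
  d <- predict_stride_length(model, x)
  if (any(d < 0)) {
    warning(sprintf("%d negative stride-length prediction(s) clamped to 0",
                    sum(d < 0)))
    d <- pmax(d, 0)
  }
  stride_estimates(d, stride_time_from_window(windows, rec$fs),
                   algorithm = "deep_learning")
}
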