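# A small convolutional classifier in vectorized base R.
#
# Architecture: `depth` blocks of [3x3 same-padding convolution -> ReLU ->
# 2x2 max pool], a global average pool, and a dense softmax head. This is
# the desk-scale stand-in for a large compound-scaled network family: the
# same width/depth/resolution scaling applies, only the base is small
# enough to train on a CPU in minutes.
#
# Convolutions are computed as matrix products over im2col-gathered window
# matrices; the full backward pass (including the gradient with respect to
# the input image, needed for saliency maps) is implemented the same way.
# Tensors are H x W x C x B arrays (rows = y), values in [0, 1].

# im2col linear-index template for one sample: P x K matrix of indices into
# a zero-padded (H+2) x (W+2) x C array; P = H*W output positions
# (column-major: y fastest), K = 9*C window elements.
im2col_template <- function(H, W, C) {
  i <- rep(seq_len(H), times = W)       # output row (y)
  j <- rep(seq_len(W), each = H)        # output col (x)
  K <- 9L * C
  M0 <- matrix(0L, H * W, K)
  k <- 0L
  for (ch in seq_len(C)) {
    for (dj in 0:2) {
      for (di in 0:2) {
        k <- k + 1L
        M0[, k] <- (i + di) + (H + 2L) * ((j + dj - 1L) + (W + 2L) * (ch - 1L))
      }
    }
  }
  M0
}

# batched im2col: returns (B*P) x K matrix, rows ordered sample-major
im2col <- function(x, M0) {
  d <- dim(x)  # H W C B
  H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  xp <- array(0, c(H + 2L, W + 2L, C, B))
  xp[2:(H + 1L), 2:(W + 1L), , ] <- x
  P <- H * W
  per <- (H + 2L) * (W + 2L) * C
  IDX <- M0[rep(seq_len(P), times = B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * per, each = P)
  cols <- xp[IDX]
  dim(cols) <- dim(IDX)
  list(cols = cols, IDX = IDX, pad_dim = c(H + 2L, W + 2L, C, B))
}

# scatter-add of window gradients back to the (unpadded) input
col2im <- function(dcols, IDX, pad_dim) {
  dpad <- numeric(prod(pad_dim))
  for (k in seq_len(ncol(dcols))) {
    idx <- IDX[, k]
    dpad[idx] <- dpad[idx] + dcols[, k]
  }
  dim(dpad) <- pad_dim
  H <- pad_dim[1] - 2L; W <- pad_dim[2] - 2L
  dpad[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
}

# (B*P) x Cout matrix (sample-major rows) -> H x W x Cout x B array
rows_to_array <- function(m, H, W, B) {
  Cout <- ncol(m)
  aperm(array(m, c(H, W, B, Cout)), c(1, 2, 4, 3))
}

# inverse of rows_to_array
array_to_rows <- function(a) {
  d <- dim(a)  # H W C B
  m <- aperm(a, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

# 2x2 max pool with argmax bookkeeping; odd trailing rows/cols are dropped
maxpool_forward <- function(a) {
  d <- dim(a)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  ro <- seq_len(2L * H2); co <- seq_len(2L * W2)
  q <- list(
    a[ro[c(TRUE, FALSE)], co[c(TRUE, FALSE)], , , drop = FALSE],
    a[ro[c(FALSE, TRUE)], co[c(TRUE, FALSE)], , , drop = FALSE],
    a[ro[c(TRUE, FALSE)], co[c(FALSE, TRUE)], , , drop = FALSE],
    a[ro[c(FALSE, TRUE)], co[c(FALSE, TRUE)], , , drop = FALSE]
  )
  m <- pmax(q[[1]], q[[2]], q[[3]], q[[4]])
  # first matching quadrant wins on ties (deterministic)
  wq <- array(1L, dim(m))
  wq[q[[1]] != m & q[[2]] == m] <- 2L
  wq[q[[1]] != m & q[[2]] != m & q[[3]] == m] <- 3L
  wq[q[[1]] != m & q[[2]] != m & q[[3]] != m] <- 4L
  list(out = m, wq = wq, in_dim = d)
}

maxpool_backward <- function(dm, pool) {
  d <- pool$in_dim
  dx <- array(0, d)
  H2 <- dim(dm)[1]; W2 <- dim(dm)[2]
  slices <- list(
    list(seq(1L, 2L * H2, 2L), seq(1L, 2L * W2, 2L)),
    list(seq(2L, 2L * H2, 2L), seq(1L, 2L * W2, 2L)),
    list(seq(1L, 2L * H2, 2L), seq(2L, 2L * W2, 2L)),
    list(seq(2L, 2L * H2, 2L), seq(2L, 2L * W2, 2L))
  )
  for (qi in 1:4) {
    g <- dm
    g[pool$wq != qi] <- 0
    dx[slices[[qi]][[1]], slices[[qi]][[2]], , ] <- g
  }
  dx
}

#' Initialize a small convolutional classifier
#'
#' He-normal initialization under the given seed. See [build_model()] for
#' the scaled-family entry point.
#'
#' @param depth number of conv blocks.
#' @param width channels per block.
#' @param resolution input side (px).
#' @param n_classes output classes.
#' @param seed integer seed.
#' @return object of class `cnn_classifier`.
#' @export
cnn_init <- function(depth, width, resolution, n_classes, seed = 1L) {
  stopifnot(depth >= 1, width >= 1, n_classes >= 2)
  if (resolution < 32) stop("model resolution must be at least 32 px")
  withr::with_seed(as.integer(seed), {
    conv_W <- list(); conv_b <- list()
    cin <- 3L
    for (l in seq_len(depth)) {
      K <- 9L * cin
      conv_W[[l]] <- matrix(stats::rnorm(K * width, 0, sqrt(2 / K)), K, width)
      conv_b[[l]] <- numeric(width)
      cin <- width
    }
    dense_W <- matrix(stats::rnorm(width * n_classes, 0, sqrt(2 / width)),
                      width, n_classes)
    dense_b <- numeric(n_classes)
  })
  templates <- list()
  h <- as.integer(resolution); cin <- 3L
  for (l in seq_len(depth)) {
    templates[[l]] <- im2col_template(h, h, cin)
    h <- h %/% 2L
    cin <- as.integer(width)
  }
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 resolution = as.integer(resolution),
                 n_classes = as.integer(n_classes),
                 conv_W = conv_W, conv_b = conv_b,
                 dense_W = dense_W, dense_b = dense_b,
                 templates = templates),
            class = "cnn_classifier")
}

#' Number of trainable parameters of a classifier
#' @param model a `cnn_classifier`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$conv_W, length, 0)) + sum(vapply(model$conv_b, length, 0)) +
    length(model$dense_W) + length(model$dense_b)
}

# forward pass; keep_cache=TRUE retains everything backward needs
cnn_forward <- function(model, x, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] != 3L) stop("input must have 3 channels")
  if (dim(x)[1] != model$resolution || dim(x)[2] != model$resolution) {
    stop("input must be ", model$resolution, " x ", model$resolution, " px")
  }
  B <- dim(x)[4]
  cache <- list(x = x, layers = vector("list", model$depth))
  a <- x - 0.5  # inputs arrive in [0, 1]; the net sees them centered
  for (l in seq_len(model$depth)) {
    ic <- im2col(a, model$templates[[l]])
    z <- ic$cols %*% model$conv_W[[l]]
    z <- z + rep(model$conv_b[[l]], each = nrow(z))
    relu_mask <- z > 0
    zr <- z * relu_mask
    arr <- rows_to_array(zr, dim(a)[1], dim(a)[2], B)
    pool <- maxpool_forward(arr)
    if (keep_cache) {
      cache$layers[[l]] <- list(cols = ic$cols, IDX = ic$IDX,
                                pad_dim = ic$pad_dim, relu_mask = relu_mask,
                                pool = pool, in_hw = dim(a)[1:2])
    }
    a <- pool$out
  }
  hw <- prod(dim(a)[1:2])
  fmat <- t(matrix(a, hw, model$width * B) |> colMeans() |>
              matrix(model$width, B))  # B x width
  logits <- fmat %*% model$dense_W
  logits <- logits + rep(model$dense_b, each = B)
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, logits = logits, fmat = fmat,
       feat_hw = dim(a)[1:2], cache = if (keep_cache) cache)
}

# backward pass from dlogits; returns parameter grads and optionally dinput
cnn_backward <- function(model, fwd, dlogits, want_input_grad = FALSE) {
  B <- nrow(dlogits)
  g <- list(conv_W = vector("list", model$depth),
            conv_b = vector("list", model$depth))
  g$dense_W <- crossprod(fwd$fmat, dlogits)
  g$dense_b <- colSums(dlogits)
  dfmat <- dlogits %*% t(model$dense_W)  # B x width
  hw <- prod(fwd$feat_hw)
  # GAP backward: each spatial position gets grad / (H*W)
  da <- array(rep(t(dfmat) / hw, each = hw),
              c(fwd$feat_hw[1], fwd$feat_hw[2], model$width, B))
  for (l in rev(seq_len(model$depth))) {
    ly <- fwd$cache$layers[[l]]
    darr <- maxpool_backward(da, ly$pool)
    dz <- array_to_rows(darr)
    dz <- dz * ly$relu_mask
    g$conv_W[[l]] <- crossprod(ly$cols, dz)
    g$conv_b[[l]] <- colSums(dz)
    if (l > 1L || want_input_grad) {
      dcols <- dz %*% t(model$conv_W[[l]])
      da <- col2im(dcols, ly$IDX, ly$pad_dim)
    }
  }
  if (want_input_grad) g$input <- da
  g
}

#' Class probabilities for a batch of images
#'
#' @param model a `cnn_classifier`.
#' @param x H x W x 3 x B array (or a single H x W x 3 image) in `[0, 1]`.
#' @param batch_size forward batch size; outputs are batching-invariant.
#' @return B x n_classes probability matrix (rows sum to 1).
#' @export
cnn_probs <- function(model, x, batch_size = 64L) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  B <- dim(x)[4]
  out <- matrix(NA_real_, B, model$n_classes)
  for (s in seq(1L, B, by = batch_size)) {
    e <- min(B, s + batch_size - 1L)
    out[s:e, ] <- cnn_forward(model, x[, , , s:e, drop = FALSE])$probs
  }
  out
}

# flatten/unflatten parameters for the optimizer
param_list <- function(model) {
  c(model$conv_W, model$conv_b, list(model$dense_W, model$dense_b))
}

set_params <- function(model, plist) {
  d <- model$depth
  model$conv_W <- plist[seq_len(d)]
  model$conv_b <- plist[d + seq_len(d)]
  model$dense_W <- plist[[2L * d + 1L]]
  model$dense_b <- plist[[2L * d + 2L]]
  model
}

grad_list <- function(model, g) {
  c(g$conv_W, g$conv_b, list(g$dense_W, g$dense_b))
}

#' One Adam update over a parameter list
#' @keywords internal
adam_step <- function(plist, glist, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) {
    state <- list(t = 0L,
                  m = lapply(plist, function(p) p * 0),
                  v = lapply(plist, function(p) p * 0))
  }
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (i in seq_along(plist)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * glist[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * glist[[i]]^2
    plist[[i]] <- plist[[i]] -
      lr * (state$m[[i]] / c1) / (sqrt(state$v[[i]] / c2) + eps)
  }
  list(params = plist, state = state)
}

#' Gradient of a class score with respect to the input image
#'
#' Generic used by the saliency module. For the CNN the score is the
#' pre-softmax logit of the target class.
#'
#' @param model a differentiable classifier.
#' @param x input image H x W x 3 (values in `[0, 1]`).
#' @param class_index integer target class.
#' @return gradient array with the shape of `x`.
#' @export
input_gradient <- function(model, x, class_index) {
  UseMethod("input_gradient")
}

#' @export
input_gradient.cnn_classifier <- function(model, x, class_index) {
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(dim(x), 1L)
  fwd <- cnn_forward(model, x, keep_cache = TRUE)
  dlogits <- matrix(0, dim(x)[4], model$n_classes)
  dlogits[, class_index] <- 1
  g <- cnn_backward(model, fwd, dlogits, want_input_grad = TRUE)
  out <- g$input
  if (single) out <- array(out, dim(x)[1:3])
  out
}

#' @export
input_gradient.default <- function(model, x, class_index) {
  stop("input_gradient is not implemented for models of class ",
       paste(class(model), collapse = "/"))
}

#' A linear per-class score model (analytic reference)
#'
#' Score of class k is `sum(w[[k]] * x)`. Its input gradient is the
#' constant array `w[[k]]`, which gives a closed form against which
#' gradient-based saliency can be checked.
#'
#' @param w list of weight arrays, one per class, each the input shape.
#' @return object of class `linear_score_model`.
#' @export
linear_score_model <- function(w) {
  structure(list(w = w), class = "linear_score_model")
}

#' @export
input_gradient.linear_score_model <- function(model, x, class_index) {
  g <- model$w[[class_index]]
  stopifnot(all(dim(g) == dim(x)))
  g + 0 * x
}
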