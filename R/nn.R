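# R-side glue for the tiny CNN backbone. The compute kernels (im2col +
# BLAS gemm convolutions, batch norm, pooling, and the fused
# forward/backward pass of one mini-batch) live in src/conv.cpp; R holds
# the parameters, the SGD state and the training loop.
#
# A batch of B images of size H x W x C is a (B*H*W) x C matrix, each
# image flattened column-major (row p = y + (x-1)*H, image blocks
# stacked). Convolution weights are (9*Cin) x Cout matrices whose rows
# are grouped per input channel, the nine kernel offsets fastest.
# Architecture: four 3x3 same-padded conv layers (channels 3-8-16-32-32),
# each followed by batch normalization and ReLU, 2x2 max pooling after
# the first three, global average pooling, linear head. Batch norm uses
# batch statistics during training and exponentially averaged running
# statistics (momentum 0.1) at inference.

tiny_channels <- c(3L, 8L, 16L, 32L, 32L)   # conv1..conv4 in/out chain
bn_momentum <- 0.1

init_tiny_params <- function(num_classes, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  conv <- vector("list", 4L)
  for (l in 1:4) {
    cin <- tiny_channels[l]; cout <- tiny_channels[l + 1L]
    sd <- sqrt(2 / (9 * cin))               # He initialization
    conv[[l]] <- list(
      W = matrix(stats::rnorm(9L * cin * cout, 0, sd), 9L * cin, cout),
      gamma = rep(1, cout), beta = rep(0, cout),
      rmean = rep(0, cout), rvar = rep(1, cout))
  }
  fc <- list(W = matrix(stats::rnorm(tiny_channels[5] * num_classes, 0,
                                     sqrt(1 / tiny_channels[5])),
                        tiny_channels[5], num_classes),
             b = rep(0, num_classes))
  list(conv = conv, fc = fc)
}

pl <- function(params, field) lapply(params$conv, `[[`, field)

# Forward pass to logits (inference mode). X: (B*H*W) x 3 in [0,1].
tiny_forward <- function(params, X, H, W, B) {
  .tiny_logits(pl(params, "W"), pl(params, "gamma"), pl(params, "beta"),
               pl(params, "rmean"), pl(params, "rvar"),
               params$fc$W, params$fc$b, X, H, W, B)
}

# Fused forward + loss-gradient + backward pass for one mini-batch.
# y: 1-based labels; alpha: weight of the misclassified-sample loss term
# (0 = plain cross-entropy). Returns logits, parameter gradients and the
# batch-norm batch statistics.
tiny_step <- function(params, X, H, W, B, y, alpha) {
  .tiny_step(pl(params, "W"), pl(params, "gamma"), pl(params, "beta"),
             pl(params, "rmean"), pl(params, "rvar"),
             params$fc$W, params$fc$b, X, H, W, B, as.integer(y), alpha)
}

# Post-ReLU activations of conv layer `layer` and the gradient of the
# class-v logit with respect to them (Grad-CAM inputs; inference mode).
tiny_actgrad <- function(params, X, H, W, B, v, layer) {
  .tiny_actgrad(pl(params, "W"), pl(params, "gamma"), pl(params, "beta"),
                pl(params, "rmean"), pl(params, "rvar"),
                params$fc$W, params$fc$b, X, H, W, B,
                as.integer(v), as.integer(layer))
}

sgd_step <- function(params, step, state, lr, momentum) {
  if (is.null(state)) {
    state <- list(conv = lapply(params$conv, function(cl)
      list(W = cl$W * 0, gamma = cl$gamma * 0, beta = cl$beta * 0)),
      fc = list(W = params$fc$W * 0, b = params$fc$b * 0))
  }
  for (l in 1:4) {
    state$conv[[l]]$W <- momentum * state$conv[[l]]$W + step$gW[[l]]
    params$conv[[l]]$W <- params$conv[[l]]$W - lr * state$conv[[l]]$W
    state$conv[[l]]$gamma <- momentum * state$conv[[l]]$gamma +
      as.numeric(step$ggamma[[l]])
    params$conv[[l]]$gamma <- params$conv[[l]]$gamma -
      lr * state$conv[[l]]$gamma
    state$conv[[l]]$beta <- momentum * state$conv[[l]]$beta +
      as.numeric(step$gbeta[[l]])
    params$conv[[l]]$beta <- params$conv[[l]]$beta -
      lr * state$conv[[l]]$beta
    # running statistics (not gradient-trained)
    params$conv[[l]]$rmean <- (1 - bn_momentum) * params$conv[[l]]$rmean +
      bn_momentum * as.numeric(step$bmean[[l]])
    params$conv[[l]]$rvar <- (1 - bn_momentum) * params$conv[[l]]$rvar +
      bn_momentum * as.numeric(step$bvar[[l]])
  }
  state$fc$W <- momentum * state$fc$W + step$gfcW
  params$fc$W <- params$fc$W - lr * state$fc$W
  state$fc$b <- momentum * state$fc$b + as.numeric(step$gfcb)
  params$fc$b <- params$fc$b - lr * state$fc$b
  list(params = params, state = state)
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

# Load an image file as a (H*W) x 3 matrix in [0,1], resizing on demand.
load_image_matrix <- function(path, input_size) {
  img <- read_image(path)
  if (nrow(img) != input_size[2] || ncol(img) != input_size[1])
    img <- resize_image(img, input_size)
  matrix(img, ncol = 3L) / 255
}

# Column-major index permutation realizing a horizontal flip of an
# H x W image flattened as p = y + (x-1)*H.
hflip_index <- function(H, W) {
  as.vector(outer(seq_len(H), (W:1 - 1L) * H, "+"))
}
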