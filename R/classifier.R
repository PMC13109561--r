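backbone_registry <- c("vgg19", "resnet18", "mobilenetv2", "inceptionv3",
                       "efficientnet", "densenet121", "tiny")

#' Build a classification backbone
#'
#' Constructs a model whose output dimension equals `num_classes`. The
#' `tiny` backbone is a small from-scratch convolutional network (four 3x3
#' convolution blocks with max pooling, global average pooling, and a
#' linear head) designed to train offline on CPU; it requires input sizes
#' divisible by 8. The remaining registry names identify large ImageNet
#' architectures whose weights and runtime are not bundled with this
#' package: requesting them raises an informative error advising `tiny` or
#' `pretrained = FALSE` as appropriate.
#'
#' @param backbone One of `"vgg19"`, `"resnet18"`, `"mobilenetv2"`,
#'   `"inceptionv3"`, `"efficientnet"`, `"densenet121"`, `"tiny"`.
#' @param num_classes Number of output classes (>= 2).
#' @param pretrained Initialize from published source-task weights.
#' @param input_size `c(width, height)` of the images the model consumes.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `variety_cnn_model`.
#' @export
build_model <- function(backbone = "tiny", num_classes, pretrained = FALSE,
                        input_size = c(96L, 128L), seed = 1L) {
  if (!backbone %in% backbone_registry)
    stop("unknown backbone '", backbone, "'; registry: ",
         paste(backbone_registry, collapse = ", "))
  stopifnot(num_classes >= 2L)
  if (backbone != "tiny") {
    if (pretrained)
      stop("pretrained weights for '", backbone, "' are not available in ",
           "this installation; use backbone = 'tiny' or pretrained = FALSE")
    stop("backbone '", backbone, "' requires an external deep-learning ",
         "runtime and weight bundle not shipped with this package; ",
         "use backbone = 'tiny'")
  }
  if (pretrained)
    stop("'tiny' is a from-scratch backbone with no published source-task ",
         "weights; use pretrained = FALSE")
  if (any(input_size %% 8L != 0L) || any(input_size < 32L))
    stop("input_size must be >= 32 and divisible by 8 in both dimensions")
  structure(list(
    backbone = backbone,
    num_classes = as.integer(num_classes),
    input_size = as.integer(input_size),
    pretrained = FALSE,
    params = init_tiny_params(num_classes, seed),
    label_levels = NULL), class = "variety_cnn_model")
}

check_probs <- function(probs, labels) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1L)
  if (is.factor(labels)) labels <- as.integer(labels)
  if (length(labels) != nrow(probs))
    stop("length of labels (", length(labels), ") does not match rows of ",
         "probs (", nrow(probs), ")")
  if (any(labels < 1L) || any(labels > ncol(probs)))
    stop("labels must be integers in 1..ncol(probs)")
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probs rows must be non-negative and sum to 1")
  list(probs = probs, labels = labels)
}

#' Cross-entropy loss
#'
#' Mean negative log-probability of the true classes,
#' `-(1/N) sum_i log p_i[y_i]`. Probabilities are floored at `eps` before
#' taking logarithms.
#'
#' @param probs N x C matrix of class probabilities (rows sum to 1).
#' @param labels True classes: integers in 1..C or a factor of length N.
#' @param eps Floor applied to probabilities before `log`.
#' @return Non-negative scalar.
#' @export
cross_entropy_loss <- function(probs, labels, eps = 1e-12) {
  b <- check_probs(probs, labels)
  p_true <- b$probs[cbind(seq_len(nrow(b$probs)), b$labels)]
  -mean(log(pmax(p_true, eps)))
}

#' Adaptive (hard-example weighted) cross-entropy loss
#'
#' Standard cross-entropy plus an `alpha`-weighted second cross-entropy
#' term contributed only by currently misclassified samples:
#' `L = (1/N) sum_i ce_i + (alpha/N) sum_i wrong_i * ce_i`, where `wrong_i`
#' indicates `argmax(probs_i) != labels_i` (argmax ties resolved to the
#' lowest class index). The indicator is a constant of the current
#' predictions: no gradient flows through it. With `alpha = 0` the value
#' equals [cross_entropy_loss()] exactly; on an all-correct batch it equals
#' cross-entropy for every `alpha`; on an all-wrong batch it equals
#' `(1 + alpha)` times cross-entropy.
#'
#' @inheritParams cross_entropy_loss
#' @param alpha Non-negative weight on the misclassified-sample term.
#' @return Scalar `>= cross_entropy_loss(probs, labels)`.
#' @export
ace_loss <- function(probs, labels, alpha = 1, eps = 1e-12) {
  if (alpha < 0) stop("alpha must be non-negative")
  b <- check_probs(probs, labels)
  n <- nrow(b$probs)
  ce_i <- -log(pmax(b$probs[cbind(seq_len(n), b$labels)], eps))
  wrong <- max.col(b$probs, ties.method = "first") != b$labels
  mean(ce_i) + alpha * mean(ce_i * wrong)
}

#' Training configuration
#'
#' Bundles the optimizer schedule, augmentation switches and loss choice
#' for a training run. Defaults follow the reference protocol: SGD with
#' learning rate 0.01 and momentum 0.9, batch size 64, random horizontal
#' flip with probability 0.5.
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param loss `"ce"` or `"ace"`.
#' @param alpha Misclassification weight of the adaptive loss.
#' @param learning_rate,momentum SGD hyperparameters.
#' @param batch_size Mini-batch size.
#' @param hflip_prob Per-image horizontal-flip probability in [0, 1].
#' @param seed Integer seed controlling shuffling, flips and (through
#'   [build_model()]) initialization.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 20L, loss = c("ce", "ace"), alpha = 1,
                         learning_rate = 0.01, momentum = 0.9,
                         batch_size = 64L, hflip_prob = 0.5, seed = 42L) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1L, alpha >= 0, hflip_prob >= 0, hflip_prob <= 1,
            batch_size >= 1L, learning_rate >= 0, momentum >= 0)
  structure(list(epochs = as.integer(epochs), loss = loss, alpha = alpha,
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 hflip_prob = hflip_prob, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a model on the manifest's training split
#'
#' Runs mini-batch SGD with momentum over the `split == "train"` records
#' (rows without a split assignment are treated as training). Each image
#' is flipped horizontally with probability `hflip_prob` independently at
#' every epoch. The loss is cross-entropy or its adaptive variant; for the
#' adaptive loss the per-sample gradient is scaled by
#' `1 + alpha * wrong_i`, the misclassification indicator being a constant
#' of the current forward pass. With a fixed seed the loss history is
#' reproducible on one device.
#'
#' @param model A `variety_cnn_model` from [build_model()].
#' @param manifest Manifest data.frame; images must share the model's
#'   input size (they are resized on load otherwise).
#' @param config A [train_config()].
#' @return A list with the trained `model` (its `label_levels` filled) and
#'   `history`, a data.frame of per-epoch train loss and accuracy.
#' @export
train_model <- function(model, manifest, config = train_config()) {
  stopifnot(inherits(model, "variety_cnn_model"))
  train <- manifest[is.na(manifest$split) | manifest$split != "test", ,
                    drop = FALSE]
  if (nrow(train) == 0L) stop("no training records in manifest")
  levels <- sort(unique(train$accession))
  if (length(levels) != model$num_classes)
    stop("manifest has ", length(levels), " accession classes but the ",
         "model head outputs ", model$num_classes,
         "; rebuild the model with the matching num_classes")
  model$label_levels <- levels
  y <- match(train$accession, levels)
  w <- model$input_size[1]; h <- model$input_size[2]
  HW <- h * w
  imgs <- lapply(train$path, load_image_matrix, input_size = model$input_size)
  flip_idx <- hflip_index(h, w)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- model$params
  state <- NULL
  alpha_eff <- if (config$loss == "ace") config$alpha else 0
  n <- length(imgs)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    flips <- stats::runif(n) < config$hflip_prob
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1L, n)]
      B <- length(take)
      X <- matrix(0, B * HW, 3L)
      for (bi in seq_len(B)) {
        m <- imgs[[take[bi]]]
        if (flips[take[bi]]) m <- m[flip_idx, , drop = FALSE]
        X[((bi - 1L) * HW + 1L):(bi * HW), ] <- m
      }
      yb <- y[take]
      st <- tiny_step(params, X, h, w, B, yb, alpha_eff)
      probs <- softmax_rows(st$logits)
      wrong <- max.col(probs, ties.method = "first") != yb
      ce_i <- -log(pmax(probs[cbind(seq_len(B), yb)], 1e-12))
      ep_loss <- ep_loss + sum(ce_i * (1 + alpha_eff * wrong))
      ep_correct <- ep_correct + sum(!wrong)
      upd <- sgd_step(params, st, state, config$learning_rate,
                      config$momentum)
      params <- upd$params; state <- upd$state
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n))
  }
  model$params <- params
  list(model = model, history = history)
}

#' Fit an image-based variety classifier
#'
#' The package's central fitting function: builds a backbone with a
#' classification head sized to the manifest's accession classes and
#' trains it on the manifest's training split. Returns a classed object
#' with `print`, `summary`, `coef`, `predict` and `plot` methods.
#'
#' @param manifest Manifest data.frame (see [build_manifest()],
#'   [split_dataset()]); records with `split == "test"` are held out.
#' @param backbone Backbone name (see [build_model()]).
#' @param input_size `c(width, height)` the images are fed at.
#' @param pretrained Passed to [build_model()].
#' @param ... Passed to [train_config()] (epochs, loss, alpha,
#'   learning_rate, momentum, batch_size, hflip_prob, seed).
#' @return An object of class `variety_cnn`.
#' @export
#' @examples
#' \donttest{
#' dir <- tempfile(); man <- generate_synthetic_dataset(dir, 3, 3,
#'   image_size = c(48, 64), seed = 1)
#' man <- split_dataset(man, 0.2, seed = 1)
#' fit <- variety_cnn(man, input_size = c(48, 64), epochs = 3)
#' print(fit)
#' }
variety_cnn <- function(manifest, backbone = "tiny",
                        input_size = c(96L, 128L), pretrained = FALSE, ...) {
  config <- train_config(...)
  train <- manifest[is.na(manifest$split) | manifest$split != "test", ,
                    drop = FALSE]
  levels <- sort(unique(train$accession))
  if (length(levels) < 2L)
    stop("training split must contain at least two accession classes")
  model <- build_model(backbone, num_classes = length(levels),
                       pretrained = pretrained, input_size = input_size,
                       seed = config$seed)
  tr <- train_model(model, manifest, config)
  structure(list(model = tr$model, history = tr$history, config = config,
                 levels = levels, n_train = nrow(train),
                 call = match.call()), class = "variety_cnn")
}

#' Predict from a fitted variety classifier
#'
#' @param object A `variety_cnn` fit.
#' @param newdata A manifest data.frame, a character vector of image
#'   paths, a single `[H, W, 3]` array (0..255), or a list of such arrays.
#' @param type `"class"` (factor), `"prob"` (N x C matrix) or `"logit"`.
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return Predictions in the requested form.
#' @export
predict.variety_cnn <- function(object, newdata,
                                type = c("class", "prob", "logit"),
                                batch_size = 64L, ...) {
  type <- match.arg(type)
  model <- object$model
  paths <- NULL
  if (is.data.frame(newdata)) paths <- newdata$path
  else if (is.character(newdata)) paths <- newdata
  mats <- if (!is.null(paths)) {
    lapply(paths, load_image_matrix, input_size = model$input_size)
  } else {
    arrs <- if (is.list(newdata)) newdata else list(newdata)
    lapply(arrs, function(a) {
      if (nrow(a) != model$input_size[2] || ncol(a) != model$input_size[1])
        a <- resize_image(a, model$input_size)
      matrix(a, ncol = 3L) / 255
    })
  }
  w <- model$input_size[1]; h <- model$input_size[2]; HW <- h * w
  n <- length(mats)
  out <- matrix(0, n, model$num_classes)
  for (start in seq(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    B <- length(take)
    X <- do.call(rbind, mats[take])
    out[take, ] <- tiny_forward(model$params, X, h, w, B)
  }
  colnames(out) <- model$label_levels
  switch(type,
    logit = out,
    prob = softmax_rows(out),
    class = factor(model$label_levels[max.col(out, ties.method = "first")],
                   levels = model$label_levels))
}

#' @export
print.variety_cnn <- function(x, ...) {
  cat("Image-based variety classifier (backbone:", x$model$backbone, ")\n")
  cat(sprintf("  classes: %d, training images: %d, input %dx%d\n",
              length(x$levels), x$n_train,
              x$model$input_size[1], x$model$input_size[2]))
  cat(sprintf("  loss: %s%s, lr %g, momentum %g, batch %d, epochs %d\n",
              x$config$loss,
              if (x$config$loss == "ace") sprintf(" (alpha=%g)", x$config$alpha) else "",
              x$config$learning_rate, x$config$momentum,
              x$config$batch_size, x$config$epochs))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss %.4f, train accuracy %.3f\n",
              last$loss, last$accuracy))
  invisible(x)
}

#' @export
summary.variety_cnn <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5L), row.names = FALSE)
  npar <- sum(vapply(object$model$params$conv, function(cl)
    sum(vapply(cl$W, length, 1L)) + length(cl$b), 1)) +
    length(object$model$params$fc$W) + length(object$model$params$fc$b)
  cat(sprintf("\nParameters: %d\n", npar))
  invisible(object)
}

#' @export
coef.variety_cnn <- function(object, ...) object$model$params

#' @export
plot.variety_cnn <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$history$epoch, x$history$loss, type = "l", xlab = "epoch",
       ylab = "train loss", main = "Loss", ...)
  plot(x$history$epoch, x$history$accuracy, type = "l", xlab = "epoch",
       ylab = "train accuracy", ylim = c(0, 1), main = "Accuracy", ...)
  invisible(x)
}
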