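#' Gradient-weighted class activation map
#'
#' Computes a spatial relevance heatmap for one class: the gradient of the
#' pre-softmax logit of the target class is taken with respect to the
#' chosen convolutional layer's (post-ReLU) feature maps, spatially
#' averaged into one weight per channel, and the weighted channel sum is
#' rectified (`ReLU`) into a non-negative map at the layer's resolution,
#' then upsampled bilinearly to the input size.
#'
#' @param object A fitted `variety_cnn` (or a `variety_cnn_model`).
#' @param image An `[H, W, 3]` array (0..255) or an image path.
#' @param target_class Class index (1..C) or level name; defaults to the
#'   model's argmax prediction for the image.
#' @param layer Convolutional layer name, `"conv1"`..`"conv4"`; defaults
#'   to the last convolutional layer (`"conv4"`).
#' @return An object of class `gradcam_map` with fields `heatmap`
#'   (layer-resolution matrix, all entries >= 0), `preact` (the map before
#'   rectification), `upsampled` (input-resolution matrix), `target_class`,
#'   and `layer_name`.
#' @export
gradcam <- function(object, image, target_class = NULL, layer = NULL) {
  model <- if (inherits(object, "variety_cnn")) object$model else object
  stopifnot(inherits(model, "variety_cnn_model"))
  layers <- paste0("conv", 1:4)
  if (is.null(layer)) layer <- "conv4"
  if (!layer %in% layers)
    stop("unknown layer '", layer, "'; candidate layers with spatial ",
         "extent: ", paste(layers, collapse = ", "))
  l <- match(layer, layers)
  if (is.character(image) && length(image) == 1L) image <- read_image(image)
  if (nrow(image) != model$input_size[2] || ncol(image) != model$input_size[1])
    image <- resize_image(image, model$input_size)
  w <- model$input_size[1]; h <- model$input_size[2]
  X <- matrix(image, ncol = 3L) / 255
  if (is.null(target_class)) {
    logits <- tiny_forward(model$params, X, h, w, 1L)
    v <- max.col(logits, ties.method = "first")[1]
  } else if (is.character(target_class)) {
    v <- match(target_class, model$label_levels)
    if (is.na(v)) stop("unknown class '", target_class, "'")
  } else v <- as.integer(target_class)
  stopifnot(v >= 1L, v <= model$num_classes)
  ag <- tiny_actgrad(model$params, X, h, w, 1L, v, l)
  hw <- c(h, w) %/% c(1L, 2L, 4L, 8L)[l]
  A <- ag$A                                  # (Hl*Wl) x K post-ReLU maps
  alpha <- colMeans(ag$dA)                   # spatial mean of the gradients
  pre <- matrix(as.vector(A %*% alpha), hw[1], hw[2])
  heat <- pmax(pre, 0)
  up <- upsample_bilinear(heat, w, h)
  structure(list(heatmap = heat, preact = pre, upsampled = up,
                 target_class = v, layer_name = layer),
            class = "gradcam_map")
}

upsample_bilinear <- function(m, w, h) {
  e <- EBImage::resize(EBImage::Image(t(m)), w = w, h = h,
                       filter = "bilinear", antialias = FALSE)
  t(EBImage::imageData(e))
}

#' @export
print.gradcam_map <- function(x, ...) {
  cat(sprintf("Grad-CAM map: layer %s, class %d, %dx%d (upsampled %dx%d)\n",
              x$layer_name, x$target_class, nrow(x$heatmap), ncol(x$heatmap),
              nrow(x$upsampled), ncol(x$upsampled)))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$heatmap), max(x$heatmap)))
  invisible(x)
}

#' Overlay a class activation map on the source image
#'
#' Min-max normalizes the upsampled heatmap to [0, 1] per image, maps it
#' through a blue (low) to red (high) colormap, and alpha-blends it over
#' the image. A constant heatmap maps to the low end of the ramp.
#'
#' @param image `[H, W, 3]` array, 0..255, same size as the map's
#'   `upsampled` field.
#' @param map A `gradcam_map`.
#' @param opacity Blend weight of the heatmap in [0, 1]; 0 returns the
#'   original image.
#' @return `[H, W, 3]` array, 0..255.
#' @export
overlay_heatmap <- function(image, map, opacity = 0.5) {
  stopifnot(inherits(map, "gradcam_map"), opacity >= 0, opacity <= 1)
  up <- map$upsampled
  if (!identical(dim(image)[1:2], dim(up)))
    stop("image size ", paste(dim(image)[1:2], collapse = "x"),
         " does not match heatmap size ", paste(dim(up), collapse = "x"))
  rng <- range(up)
  norm <- if (diff(rng) > 0) (up - rng[1]) / diff(rng) else up * 0
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(norm))
  out <- image
  for (ch in 1:3)
    out[, , ch] <- (1 - opacity) * image[, , ch] +
      opacity * matrix(cols[, ch], nrow(up), ncol(up))
  pmin(pmax(round(out), 0), 255)
}
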