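#' Crop to the plant and resize to a standard frame
#'
#' Standardizes a raw whole-plant photograph for training. With
#' `crop = TRUE` the plant is localized by Otsu-thresholding the HSV
#' saturation channel, keeping the largest connected foreground component,
#' and cropping to its bounding box expanded by `margin` (a fraction of the
#' box size) on every side; the crop is then resized. With `crop = FALSE`
#' the full frame is resized directly. Resizing is bilinear with
#' antialiasing; an image already at `size` with `crop = FALSE` is returned
#' unchanged.
#'
#' If thresholding finds no foreground (uniform frame), the crop step is
#' skipped with a warning and the full frame is used.
#'
#' @param img Numeric array `[H, W, 3]`, values 0..255.
#' @param size Target size `c(width, height)`.
#' @param crop Localize the plant before resizing (default `FALSE`).
#' @param margin Fractional padding around the foreground bounding box.
#' @return Numeric array `[height, width, 3]`, 0..255.
#' @export
preprocess_image <- function(img, size = c(360L, 480L), crop = FALSE,
                             margin = 0.05) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L, all(size > 0))
  if (crop) {
    box <- foreground_bbox(img, margin = margin)
    if (is.null(box)) {
      warning("no foreground found; skipping crop", call. = FALSE)
    } else {
      img <- img[box[1]:box[2], box[3]:box[4], , drop = FALSE]
    }
  }
  resize_image(img, size)
}

# Bounding box (rmin, rmax, cmin, cmax) of the largest connected component
# of the Otsu-thresholded saturation channel, padded by `margin`; NULL when
# nothing exceeds the threshold.
foreground_bbox <- function(img, margin = 0.05) {
  hsv <- rgb_to_hsv_array(img)
  sat <- hsv[, , 2]
  thr <- tryCatch(EBImage::otsu(EBImage::Image(t(sat)), range = c(0, 1)),
                  error = function(e) NA_real_)
  if (is.na(thr)) return(NULL)
  mask <- sat > thr
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  lab <- t(EBImage::imageData(lab))
  tab <- tabulate(lab[lab > 0])
  biggest <- which.max(tab)
  keep <- lab == biggest
  rows <- which(rowSums(keep) > 0)
  cols <- which(colSums(keep) > 0)
  rmin <- min(rows); rmax <- max(rows); cmin <- min(cols); cmax <- max(cols)
  pr <- ceiling(margin * (rmax - rmin + 1L))
  pc <- ceiling(margin * (cmax - cmin + 1L))
  c(max(1L, rmin - pr), min(nrow(img), rmax + pr),
    max(1L, cmin - pc), min(ncol(img), cmax + pc))
}

# HSV array [H, W, 3] with H in [0,1), S and V in [0,1]
rgb_to_hsv_array <- function(img) {
  m <- grDevices::rgb2hsv(r = as.vector(img[, , 1]), g = as.vector(img[, , 2]),
                          b = as.vector(img[, , 3]), maxColorValue = 255)
  array(c(m[1, ], m[2, ], m[3, ]), dim = dim(img))
}

#' Preprocess every image in a manifest
#'
#' Applies [preprocess_image()] to each record and writes the results under
#' `out_dir`, preserving the encoded filenames so the output folder parses
#' back into an equivalent manifest.
#'
#' @inheritParams preprocess_image
#' @param manifest Manifest data.frame.
#' @param out_dir Output directory (created if missing).
#' @return The manifest with `path` pointing at the processed copies.
#' @export
preprocess_manifest <- function(manifest, out_dir, size = c(360L, 480L),
                                crop = FALSE, margin = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(manifest))) {
    img <- read_image(manifest$path[i])
    out <- preprocess_image(img, size = size, crop = crop, margin = margin)
    dest <- file.path(out_dir, paste0(
      tools::file_path_sans_ext(basename(manifest$path[i])), ".png"))
    write_image(out, dest)
    manifest$path[i] <- dest
  }
  manifest
}
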