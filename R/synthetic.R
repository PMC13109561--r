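#' Generate a deterministic synthetic plant-image dataset
#'
#' Writes a grid of accessions x sampling dates x viewpoints as PNG files
#' named by the `accession_tag_date_viewpoint` grammar, so the folder feeds
#' directly into [build_manifest()], the mixed-augmentation stage and the
#' trainer. Each accession carries a reproducible visual signature (a base
#' hue plus a stripe frequency keyed to the accession index); the plant
#' "blob" area grows monotonically with the date index, emulating growth;
#' the side view evaluates the front-view pattern under a fixed affine
#' coordinate transform. All randomness (pixel noise) flows from one seeded
#' generator, so identical seeds give byte-identical files.
#'
#' `class_signal` interpolates between a shared appearance (0: all
#' accessions look alike, classifiers should be at chance) and fully
#' distinct signatures (1: trivially separable by color).
#'
#' @param out_dir Output directory (created if missing).
#' @param n_accessions Number of accessions (>= 2).
#' @param n_dates Number of sampling dates (>= 1); date tokens are
#'   days-after-sowing starting at 42 in steps of 7.
#' @param viewpoints Subset of `c("front", "side")`.
#' @param image_size `c(width, height)` in pixels (>= 32 each).
#' @param seed Integer RNG seed.
#' @param class_signal Accession-signature strength in [0, 1].
#' @param noise_sd Gaussian pixel noise, on the 0..1 intensity scale.
#' @return A manifest data.frame; `stage` holds the date token and
#'   `subspecies` splits the accessions into two halves ("grpA"/"grpB").
#' @export
generate_synthetic_dataset <- function(out_dir, n_accessions = 10L,
                                       n_dates = 5L,
                                       viewpoints = c("front", "side"),
                                       image_size = c(96L, 128L),
                                       seed = 42L, class_signal = 1,
                                       noise_sd = 0.02) {
  stopifnot(n_accessions >= 2L, n_dates >= 1L,
            all(viewpoints %in% c("front", "side")), length(viewpoints) >= 1L,
            all(image_size >= 32L), class_signal >= 0, class_signal <= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  recs <- list()
  for (a in seq_len(n_accessions)) {
    acc <- sprintf("A%03d", a)
    for (d in seq_len(n_dates)) {
      date <- sprintf("%03d", 42L + 7L * (d - 1L))
      for (vp in viewpoints) {
        img <- synth_pattern(a, n_accessions, d, n_dates, vp,
                             image_size[1], image_size[2], class_signal)
        if (noise_sd > 0)
          img <- img + stats::rnorm(length(img), 0, noise_sd * 255)
        path <- file.path(out_dir, sprintf("%s_p1_%s_%s.png", acc, date, vp))
        write_image(img, path)
        recs[[length(recs) + 1L]] <- data.frame(
          path = path, accession = acc, tag = "p1", date = date,
          viewpoint = vp, stage = date,
          subspecies = if (a <= ceiling(n_accessions / 2)) "grpA" else "grpB",
          stringsAsFactors = FALSE)
      }
    }
  }
  order_manifest(new_manifest(do.call(rbind, recs)))
}

#' Background color of the synthetic generator
#'
#' @return RGB triple on the 0..255 scale.
#' @export
synth_background <- function() c(46, 46, 51)

# Noise-free synthetic plant pattern, [H, W, 3] in 0..255.
synth_pattern <- function(a, n_acc, d, n_dates, viewpoint, W, H, class_signal) {
  xn <- matrix(rep((seq_len(W) - (W + 1) / 2) / (W / 2), each = H), H, W)
  yn <- matrix(rep((seq_len(H) - (H + 1) / 2) / (H / 2), times = W), H, W)
  if (viewpoint == "side") {          # fixed affine remap of the generator frame
    x2 <- 0.80 * xn + 0.30 * yn
    yn <- 0.95 * yn
    xn <- x2
  }
  g <- if (n_dates > 1) 0.65 + 0.35 * d / n_dates else 1
  inside <- (xn / (0.55 * g))^2 + (yn / (0.80 * g))^2 <= 1
  s <- class_signal
  # hue band starts away from the background hue (~0.64) so whole-image
  # color statistics separate even the smallest plants
  hue <- (s * (0.72 + 0.92 * (a - 1) / n_acc) + (1 - s) * 0.33) %% 1
  freq <- 3 + ((a - 1) %% 4)
  phase <- 2 * pi * (a - 1) / n_acc
  stripe <- s * sin(2 * pi * freq * yn + phase) + (1 - s) * sin(2 * pi * 4 * yn)
  vbase <- 0.55 + s * 0.25 * ((a - 1) / max(1, n_acc - 1) - 0.5)
  val <- vbase + 0.22 * stripe
  bg <- synth_background()
  img <- array(0, dim = c(H, W, 3))
  img[, , 1] <- bg[1]; img[, , 2] <- bg[2]; img[, , 3] <- bg[3]
  if (any(inside)) {
    rgb <- grDevices::col2rgb(grDevices::hsv(hue, 0.8, pmin(pmax(val[inside], 0), 1)))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- rgb[ch, ]
      img[, , ch] <- plane
    }
  }
  img
}

#' Foreground proportion of a synthetic image
#'
#' Fraction of pixels whose Euclidean RGB distance from the (known,
#' uniform) background color exceeds `threshold` (on the 0..1 scale). Used
#' to verify growth monotonicity and crop behavior on generated fixtures.
#'
#' @param img Numeric array `[H, W, 3]`, 0..255.
#' @param background RGB triple, 0..255 (default [synth_background()]).
#' @param threshold Distance threshold on the 0..1 scale.
#' @return Proportion in [0, 1].
#' @export
foreground_mass <- function(img, background = synth_background(),
                            threshold = 0.08) {
  d2 <- (img[, , 1] - background[1])^2 + (img[, , 2] - background[2])^2 +
    (img[, , 3] - background[3])^2
  mean(sqrt(d2) / 255 > threshold)
}
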