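rgb_to_gray <- function(img) {
  0.2125 * img[, , 1] + 0.7154 * img[, , 2] + 0.0721 * img[, , 3]
}

hu_moments <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  y <- matrix(rep(seq_len(H) - 1, W), H, W)       # row coordinate
  x <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  m00 <- sum(gray)
  if (m00 == 0) return(rep(0, 7))
  cx <- sum(x * gray) / m00
  cy <- sum(y * gray) / m00
  mu <- function(p, q) sum((x - cx)^p * (y - cy)^q * gray)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2))
}

signed_log10 <- function(x, eps = 1e-30) sign(x) * log10(abs(x) + eps)

# Symmetric, normalized gray-level co-occurrence matrix contrast at one
# (distance, angle) offset. Angles follow the usual convention:
# 0 -> (0, d), 45 -> (-d, d), 90 -> (-d, 0), 135 -> (-d, -d).
glcm_contrast <- function(q, levels, distance, angle) {
  off <- switch(as.character(angle),
    "0" = c(0L, distance), "45" = c(-distance, distance),
    "90" = c(-distance, 0L), "135" = c(-distance, -distance),
    stop("unsupported GLCM angle: ", angle, " (use 0, 45, 90, 135)"))
  H <- nrow(q); W <- ncol(q)
  r1 <- max(1L, 1L - off[1]):min(H, H - off[1])
  c1 <- max(1L, 1L - off[2]):min(W, W - off[2])
  if (length(r1) < 1L || length(c1) < 1L) return(0)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- tabulate(a * levels + b + 1L, nbins = levels^2)
  counts <- matrix(counts, levels, levels, byrow = TRUE)
  counts <- counts + t(counts)                  # symmetric
  P <- counts / sum(counts)
  ij <- outer(seq_len(levels) - 1L, seq_len(levels) - 1L, "-")
  sum(P * ij^2)
}

# Uniform LBP histogram, radius R / P sampling points, over pixels at
# least R away from the border; P + 2 bins, normalized.
lbp_uniform_hist <- function(gray, R = 3L, P = 24L) {
  H <- nrow(gray); W <- ncol(gray)
  if (H < 2L * R + 1L || W < 2L * R + 1L)
    stop("image too small for LBP with radius ", R)
  rows <- (R + 1L):(H - R); cols <- (R + 1L):(W - R)
  center <- gray[rows, cols, drop = FALSE]
  theta <- 2 * pi * (seq_len(P) - 1L) / P
  dr <- -R * sin(theta)
  dc <- R * cos(theta)
  bits <- array(0L, dim = c(length(rows), length(cols), P))
  for (k in seq_len(P)) {
    r0 <- floor(dr[k]); c0 <- floor(dc[k])
    fr <- dr[k] - r0; fc <- dc[k] - c0
    r1 <- if (fr > 0) r0 + 1L else r0        # zero-weight neighbors stay
    c1 <- if (fc > 0) c0 + 1L else c0        # in bounds at integer offsets
    g <- function(ro, co) gray[rows + ro, cols + co, drop = FALSE]
    val <- (1 - fr) * (1 - fc) * g(r0, c0) +
           (1 - fr) * fc       * g(r0, c1) +
           fr       * (1 - fc) * g(r1, c0) +
           fr       * fc       * g(r1, c1)
    bits[, , k] <- (val >= center) * 1L
  }
  ones <- apply(bits, c(1, 2), sum)
  trans <- array(0L, dim = dim(ones))
  for (k in seq_len(P))
    trans <- trans + abs(bits[, , k] - bits[, , if (k == P) 1L else k + 1L])
  code <- ifelse(trans <= 2L, ones, P + 1L)
  h <- tabulate(code + 1L, nbins = P + 2L)
  h / sum(h)
}

#' Extract handcrafted image descriptors
#'
#' Computes the classical feature vector used by the baseline classifiers:
#' seven Hu invariant moments of the grayscale image (signed-log10
#' transformed), gray-level co-occurrence contrast at every
#' (distance, orientation) pair (32 gray levels, symmetric normalized
#' matrices), a 26-bin normalized uniform local-binary-pattern histogram
#' (radius 3, 24 sampling points), and the mean H, S, V channels (H in
#' [0,1), S and V in [0,1]). With the default grid the vector has length
#' 7 + 12 + 26 + 3 = 48.
#'
#' @param img `[H, W, 3]` array, 0..255.
#' @param glcm_distances Integer pixel distances (default `1:3`).
#' @param glcm_orientations Angles in degrees from `c(0, 45, 90, 135)`.
#' @param glcm_levels Gray quantization levels for the co-occurrence
#'   matrix (default 32).
#' @return Named numeric vector.
#' @export
extract_features <- function(img, glcm_distances = 1:3,
                             glcm_orientations = c(0, 45, 90, 135),
                             glcm_levels = 32L) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L,
            length(glcm_distances) >= 1L, length(glcm_orientations) >= 1L)
  if (nrow(img) < 2L || ncol(img) < 2L)
    stop("image too small for co-occurrence features (need >= 2x2)")
  gray <- rgb_to_gray(img)
  hu <- signed_log10(hu_moments(gray))
  names(hu) <- paste0("hu", 1:7)
  q <- pmin(floor(gray / 256 * glcm_levels), glcm_levels - 1L)
  grid <- expand.grid(angle = glcm_orientations, distance = glcm_distances)
  contrast <- mapply(function(d, a) glcm_contrast(q, glcm_levels, d, a),
                     grid$distance, grid$angle)
  names(contrast) <- sprintf("glcm_d%d_a%d", grid$distance, grid$angle)
  lbp <- lbp_uniform_hist(gray)
  names(lbp) <- sprintf("lbp%02d", 0:25)
  hsv <- rgb_to_hsv_array(img)
  hsvm <- c(h_mean = mean(hsv[, , 1]), s_mean = mean(hsv[, , 2]),
            v_mean = mean(hsv[, , 3]))
  c(hu, contrast, lbp, hsvm)
}

#' Feature matrix for a whole manifest
#'
#' @inheritParams extract_features
#' @param manifest Manifest data.frame with readable `path`s.
#' @return Numeric matrix, one row per record, with feature names as
#'   column names and the manifest accessions as `rownames`-free
#'   attribute `labels`.
#' @export
extract_features_manifest <- function(manifest, glcm_distances = 1:3,
                                      glcm_orientations = c(0, 45, 90, 135)) {
  rows <- lapply(manifest$path, function(p)
    extract_features(read_image(p), glcm_distances, glcm_orientations))
  m <- do.call(rbind, rows)
  attr(m, "labels") <- manifest$accession
  m
}

#' Z-score normalization with train-only statistics
#'
#' Standardizes each feature to zero mean and unit standard deviation
#' (sample sd, n - 1 denominator) using statistics computed on the
#' training matrix only, then applies the same transform to `apply_matrix`.
#' Constant columns map to 0.
#'
#' @param train_matrix Numeric matrix (>= 2 rows) of training features.
#' @param apply_matrix Optional matrix transformed with the train stats.
#' @return List with `train`, `apply` (or `NULL`), `means`, `sds`.
#' @export
zscore_normalize <- function(train_matrix, apply_matrix = NULL) {
  stopifnot(nrow(train_matrix) >= 2L)
  means <- colMeans(train_matrix)
  sds <- apply(train_matrix, 2L, stats::sd)
  scale1 <- function(m) {
    z <- sweep(m, 2L, means)
    z <- sweep(z, 2L, ifelse(sds > 0, sds, 1), "/")
    z[, sds == 0] <- 0
    z
  }
  list(train = scale1(train_matrix),
       apply = if (!is.null(apply_matrix)) scale1(apply_matrix),
       means = means, sds = sds)
}

#' @rdname zscore_normalize
#' @param normalized A matrix produced by `zscore_normalize`.
#' @param stats The list returned by `zscore_normalize` (for `means`/`sds`).
#' @export
zscore_denormalize <- function(normalized, stats) {
  z <- sweep(normalized, 2L, ifelse(stats$sds > 0, stats$sds, 1), "*")
  z <- sweep(z, 2L, stats$means, "+")
  z[, stats$sds == 0] <- matrix(stats$means[stats$sds == 0],
                                nrow(z), sum(stats$sds == 0), byrow = TRUE)
  z
}

#' Fit the four classical baseline classifiers
#'
#' Trains Naive Bayes, a decision tree, an SVM (radial kernel, library
#' defaults) and k-nearest neighbours (k = 5) on z-score-normalized
#' features, using the same train/test partition as the CNN run, and
#' scores each with [compute_metrics()]. Zero-variance training features
#' are dropped before fitting. Classifier internals are the standard
#' library implementations (e1071, rpart, class).
#'
#' @param features Numeric feature matrix, one row per image.
#' @param labels Class label per row (character or factor).
#' @param split `"train"`/`"test"` assignment per row.
#' @param classifiers Subset of `c("nb", "dt", "svm", "knn")`.
#' @param knn_k Neighbours for KNN.
#' @param seed Integer seed (tie-breaking in KNN).
#' @return Named list of `eval_report`s, one per classifier.
#' @export
fit_baselines <- function(features, labels, split,
                          classifiers = c("nb", "dt", "svm", "knn"),
                          knn_k = 5L, seed = 1L) {
  stopifnot(nrow(features) == length(labels), length(split) == length(labels),
            all(classifiers %in% c("nb", "dt", "svm", "knn")))
  labels <- factor(labels)
  tr <- split == "train"; te <- split == "test"
  if (!any(tr) || !any(te)) stop("need both train and test rows")
  unseen <- setdiff(unique(labels[te]), unique(labels[tr]))
  if (length(unseen))
    warning("test classes unseen in training: ",
            paste(unseen, collapse = ", "), call. = FALSE)
  z <- zscore_normalize(features[tr, , drop = FALSE],
                        features[te, , drop = FALSE])
  keep <- z$sds > 0
  xtr <- z$train[, keep, drop = FALSE]
  xte <- z$apply[, keep, drop = FALSE]
  ytr <- droplevels(labels[tr])
  yte <- labels[te]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  out <- list()
  for (clf in classifiers) {
    set.seed(as.integer(seed))
    pred <- switch(clf,
      nb = {
        fit <- e1071::naiveBayes(xtr, ytr)
        stats::predict(fit, xte)
      },
      dt = {
        d <- data.frame(xtr); d$.y <- ytr
        # accession datasets have few images per class; allow small splits
        fit <- rpart::rpart(.y ~ ., data = d, method = "class",
                            control = rpart::rpart.control(
                              minsplit = 2L, cp = 0.01, xval = 0L))
        stats::predict(fit, data.frame(xte), type = "class")
      },
      svm = {
        fit <- e1071::svm(xtr, ytr)
        stats::predict(fit, xte)
      },
      knn = class::knn(xtr, xte, cl = ytr, k = knn_k))
    pred <- factor(as.character(pred), levels = levels(labels))
    out[[clf]] <- compute_metrics(pred, yte, n_classes = nlevels(labels))
  }
  out
}
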