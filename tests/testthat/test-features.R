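# A deterministic reference image whose descriptor values were frozen
# from an independent scikit-image computation (graycomatrix/graycoprops
# with matching offsets, local_binary_pattern method "uniform", and
# moments_hu on the same luminance-weighted grayscale).
oracle_image <- function() {
  H <- 40L; W <- 30L
  yy <- matrix(rep(1:H, W), H, W)
  xx <- matrix(rep(1:W, each = H), H, W)
  img <- array(0, c(H, W, 3))
  for (c in 1:3) img[, , c] <- (37 * yy + 17 * xx + 11 * c +
                                  (yy * xx) %% 23) %% 256
  img
}

test_that("the feature vector has the configured layout", {
  f <- extract_features(oracle_image())
  expect_length(f, 48L)   # 7 Hu + 3x4 contrasts + 26 LBP bins + 3 HSV
  expect_equal(sum(startsWith(names(f), "lbp")), 26L)
  f2 <- extract_features(oracle_image(), glcm_distances = c(1, 5),
                         glcm_orientations = c(0, 90))
  expect_length(f2, 7L + 4L + 26L + 3L)
  # LBP histogram is a probability vector
  expect_equal(sum(f[grep("^lbp", names(f))]), 1, tolerance = 1e-9)
  expect_true(all(f[grep("^lbp", names(f))] >= 0))
  # deterministic
  expect_identical(f, extract_features(oracle_image()))
  expect_error(extract_features(array(1, c(1, 1, 3))), "too small")
})

test_that("co-occurrence contrast matches the frozen independent values", {
  f <- extract_features(oracle_image())
  frozen <- c(
    glcm_d1_a0 = 46.6293103448, glcm_d1_a45 = 56.0132625995,
    glcm_d1_a90 = 107.9487179487, glcm_d1_a135 = 151.7824933687,
    glcm_d2_a0 = 98.8160714286, glcm_d2_a45 = 116.2650375940,
    glcm_d2_a90 = 190.5535087719, glcm_d2_a135 = 229.8176691729,
    glcm_d3_a0 = 143.8018518519, glcm_d3_a45 = 164.0530530531,
    glcm_d3_a90 = 230.5972972973, glcm_d3_a135 = 215.6776776777)
  expect_equal(f[names(frozen)], frozen, tolerance = 1e-9)
  # a constant image has no intensity transitions at any offset
  flat <- array(123, c(20, 20, 3))
  expect_true(all(extract_features(flat)[grep("^glcm",
    names(f))] == 0))
})

test_that("uniform LBP matches the frozen histogram and is shift-invariant", {
  f <- extract_features(oracle_image())
  frozen <- c(0.1507352941, 0.0208333333, 0.0330882353, 0, 0, 0, 0, 0, 0,
              0, 0, 0, 0.0085784314, 0.0012254902, 0, 0, 0, 0, 0, 0, 0, 0,
              0.0122549020, 0.0220588235, 0.1348039216, 0.6164215686)
  expect_equal(unname(f[grep("^lbp", names(f))]), frozen, tolerance = 1e-9)
  # invariant to an order-preserving global gray shift
  img <- oracle_image()
  dim3 <- dim(img)
  shifted <- pmin(img * 0.5 + 40, 255)   # affine, order-preserving
  h1 <- varietyid:::lbp_uniform_hist(varietyid:::rgb_to_gray(img))
  h2 <- varietyid:::lbp_uniform_hist(varietyid:::rgb_to_gray(img) * 0.5 + 40)
  expect_equal(h1, h2)
})

test_that("Hu moments match the frozen values and are translation invariant", {
  f <- extract_features(oracle_image())
  # signed-log10 of the frozen raw invariants
  raw <- c(1.367211685441e-03, 1.417695494324e-07, 1.478101192501e-13,
           4.328956630224e-14, -4.524276152048e-28, -4.608397651339e-18,
           3.433113307133e-27)
  expect_equal(unname(f[1:6]), (sign(raw) * log10(abs(raw) + 1e-30))[1:6],
               tolerance = 1e-6)
  # the seventh invariant flips sign under axis reflection; its magnitude
  # is convention-independent
  expect_equal(abs(unname(f[7])), abs(sign(raw[7]) *
    log10(abs(raw[7]) + 1e-30)), tolerance = 1e-6)

  # translation on a larger black canvas leaves the moments unchanged
  blob <- array(0, c(60, 60, 3))
  blob[10:25, 8:20, ] <- oracle_image()[1:16, 1:13, ]
  moved <- array(0, c(60, 60, 3))
  moved[30:45, 38:50, ] <- oracle_image()[1:16, 1:13, ]
  hu1 <- varietyid:::hu_moments(varietyid:::rgb_to_gray(blob))
  hu2 <- varietyid:::hu_moments(varietyid:::rgb_to_gray(moved))
  expect_equal(hu1, hu2, tolerance = 1e-6)
})

test_that("z-score normalization uses train statistics with sample sd", {
  z <- zscore_normalize(matrix(c(1, 3, 5, 5), 2))
  expect_equal(z$train[, 1], c(-1, 1) / sqrt(2))   # sd = sqrt(2), n-1
  expect_equal(z$train[, 2], c(0, 0))              # constant column
  m <- matrix(rnorm(30), 10)
  z2 <- zscore_normalize(m, m)
  expect_equal(colMeans(z2$apply), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z2$apply, 2, sd), rep(1, 3), tolerance = 1e-12)
  # round trip within 1e-9
  expect_equal(zscore_denormalize(z2$train, z2), m, tolerance = 1e-9)
  zc <- zscore_normalize(matrix(c(1, 3, 7, 7), 2))
  expect_equal(zscore_denormalize(zc$train, zc), matrix(c(1, 3, 7, 7), 2))
})

test_that("the four classical baselines separate the synthetic classes", {
  man <- small_fixture(3, 4, image_size = c(48, 64))
  man <- split_dataset(man, 0.25, seed = 9)
  feats <- extract_features_manifest(man)
  reps <- fit_baselines(feats, man$accession, man$split, seed = 1)
  expect_named(reps, c("nb", "dt", "svm", "knn"))
  for (r in reps) expect_gte(r$accuracy, 0.95)

  # shuffled labels: near chance level
  set.seed(5)
  shuffled <- sample(man$accession)
  reps0 <- fit_baselines(feats, shuffled, man$split,
                         classifiers = "knn", seed = 1)
  expect_lt(reps0$knn$accuracy, 1 / 3 + 0.45)
})

test_that("tied identical features resolve by neighbour majority", {
  # Feature rows carry no label information: each test point ties with a
  # set of training rows whose majority label is always A, so k = 1 with
  # tie inclusion answers A everywhere and accuracy equals the
  # label-majority rate of the test set (the brute-force tally).
  feats <- matrix(1, 15, 3)
  feats[, 1] <- c(0, 1, 0, 1, 0, 1,  0, 1, 0, 1,  0, 1, 0, 1, 0)
  labels <- c(rep("A", 6), rep("B", 4), "A", "A", "A", "B", "B")
  split <- c(rep("train", 10), rep("test", 5))
  rep <- fit_baselines(feats, labels, split, classifiers = "knn",
                       knn_k = 1, seed = 2)
  majority_rate <- mean(labels[11:15] == "A")
  expect_equal(rep$knn$accuracy, majority_rate)
})
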