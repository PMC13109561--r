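test_that("mixgen computes the rounded, clipped convex combination", {
  a <- array(100, c(4, 4, 3)); b <- array(200, c(4, 4, 3))
  expect_true(all(mixgen(a, b, 0.5) == 150))
  x <- random_rgb(8, 8, seed = 1); y <- random_rgb(8, 8, seed = 2)
  expect_identical(mixgen(x, y, 1), x)       # lambda = 1 copies image_i
  expect_identical(mixgen(x, y, 0), y)
  expect_identical(mixgen(x, x, 0.5), x)     # fixed point
  # per-pixel bounds and lambda = 0.5 symmetry within rounding
  for (lam in c(0.3, 0.5, 0.8)) {
    m <- mixgen(x, y, lam)
    expect_true(all(m >= pmin(x, y) & m <= pmax(x, y)))
  }
  expect_true(all(abs(mixgen(x, y, 0.5) - mixgen(y, x, 0.5)) <= 1))
  expect_error(mixgen(x, random_rgb(4, 4), 0.5), "preprocess")
})

test_that("enumerate_mix_jobs emits exactly the three pair constructions", {
  # two dates x both views: 2 viewpoint + 2 temporal + 1 view_stage
  g <- fake_manifest("A", c("d1", "d2"), c("front", "side"))
  jobs <- enumerate_mix_jobs(g)
  expect_equal(nrow(jobs), 5L)
  expect_equal(as.vector(table(jobs$mix_type)[c("temporal", "viewpoint",
                                                "view_stage")]),
               c(2L, 2L, 1L))
  bf <- brute_force_mix_jobs(g)
  expect_equal(job_key(g, jobs), sort(paste(bf$left, bf$right, bf$mix_type)))

  # a group of one image yields nothing
  expect_equal(nrow(enumerate_mix_jobs(fake_manifest("A", "d1", "front"))),
               0L)

  # full grids: D viewpoint + 2(D-1) temporal + (D-1) view_stage = 4D-3
  for (D in 1:6) {
    g <- fake_manifest("A", sprintf("%02d", seq_len(D)), c("front", "side"))
    jobs <- enumerate_mix_jobs(g)
    expect_equal(nrow(jobs), 4L * D - 3L)
    expect_equal(sum(jobs$mix_type == "viewpoint"), D)
    expect_equal(sum(jobs$mix_type == "temporal"), 2L * (D - 1L))
    expect_equal(sum(jobs$mix_type == "view_stage"), D - 1L)
  }

  # the mirrored view-stage variant adds side(t) x front(t+1)
  g <- fake_manifest("A", c("d1", "d2", "d3"), c("front", "side"))
  expect_equal(sum(enumerate_mix_jobs(g,
    view_stage_symmetric = TRUE)$mix_type == "view_stage"), 4L)

  expect_error(enumerate_mix_jobs(fake_manifest(c("A", "B"), "d1", "front")),
               "single accession")
})

test_that("enumeration adjacency follows dates actually present", {
  # missing middle date: successor is the next date present
  g <- fake_manifest("A", c("01", "03", "07"), "front")
  jobs <- enumerate_mix_jobs(g)
  expect_equal(nrow(jobs), 2L)
  expect_true(all(jobs$mix_type == "temporal"))
  expect_equal(job_key(g, jobs),
               with(brute_force_mix_jobs(g),
                    sort(paste(left, right, mix_type))))
  # numeric date ordering (2 < 10 despite lexicographic order)
  g2 <- fake_manifest("A", c("2", "10"), "front")
  j2 <- enumerate_mix_jobs(g2)
  expect_equal(nrow(j2), 1L)
  g2s <- varietyid:::order_manifest(g2)
  expect_equal(g2s$date[j2$left], "2")
  expect_equal(g2s$date[j2$right], "10")
})

test_that("run_gmma writes mixed images and a consistent report", {
  man <- small_fixture(3, 3)
  man$split <- "train"
  out <- withr::local_tempdir()
  res <- run_gmma(man, out)
  rep <- res$report
  # per accession 4D-3 = 9 jobs
  expect_equal(rep$n_original, 18L)
  expect_equal(rep$n_viewpoint, 9L)
  expect_equal(rep$n_temporal, 12L)
  expect_equal(rep$n_view_stage, 6L)
  expect_equal(rep$n_total,
               rep$n_original + rep$n_viewpoint + rep$n_temporal +
                 rep$n_view_stage)
  written <- list.files(out, pattern = "\\.png$")
  added <- res$manifest[res$manifest$is_mixed, ]
  expect_equal(length(written), rep$n_total - rep$n_original)
  expect_equal(nrow(added), length(written))
  expect_true(all(added$split == "train"))
  # label consistency: mixed filenames start with their accession
  expect_true(all(startsWith(basename(added$path), added$accession)))
  # mixed pixels lie within the parent envelope at lambda = 0.5
  one <- added[added$path == file.path(out,
    "A001_mix-viewpoint_042-042_frontside.png"), ]
  m <- read_image(one$path)
  pa <- read_image(man$path[man$accession == "A001" & man$date == "042" &
                              man$viewpoint == "front"])
  pb <- read_image(man$path[man$accession == "A001" & man$date == "042" &
                              man$viewpoint == "side"])
  expect_true(all(m >= pmin(pa, pb) & m <= pmax(pa, pb)))

  # determinism: a second run writes byte-identical images
  out2 <- withr::local_tempdir()
  res2 <- run_gmma(man, out2)
  expect_identical(unname(tools::md5sum(sort(file.path(out, written)))),
                   unname(tools::md5sum(sort(res2$manifest$path[
                     res2$manifest$is_mixed]))))
})

test_that("run_gmma respects splits and degenerate manifests", {
  man <- small_fixture(3, 3)
  man <- split_dataset(man, 0.3, seed = 5)
  res <- run_gmma(man, withr::local_tempdir())
  expect_true(all(res$manifest$split[res$manifest$is_mixed] == "train"))
  expect_equal(res$report$n_original, sum(man$split == "train"))
  # test rows are never parents: every mixed image's accession group in
  # the train split must be able to produce it
  expect_equal(nrow(res$manifest), nrow(man) + res$report$n_total -
                 res$report$n_original)

  # front-only manifest: no viewpoint or view-stage mixes
  fr <- man[man$viewpoint == "front", ]
  fr$split <- "train"
  res_f <- run_gmma(fr, withr::local_tempdir())
  expect_equal(res_f$report$n_viewpoint, 0L)
  expect_equal(res_f$report$n_view_stage, 0L)
  expect_gt(res_f$report$n_temporal, 0L)

  # empty train split: all-zero report, nothing written
  te <- man; te$split <- "test"
  out <- withr::local_tempdir()
  res_e <- run_gmma(te, out)
  expect_equal(res_e$report$n_total, 0L)
  expect_equal(length(list.files(out)), 0L)
})
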