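test_that("metrics match hand-computed confusion arithmetic", {
  r <- compute_metrics(1:4, 1:4, 4)
  expect_equal(r$accuracy, 1)
  expect_equal(r$macro_precision, 1)
  expect_equal(r$macro_recall, 1)
  expect_equal(r$macro_f1, 1)

  # labels (0,0,1,1,2,2), preds (0,1,1,1,2,0) in 1-based form
  labels <- c(1, 1, 2, 2, 3, 3)
  preds <- c(1, 2, 2, 2, 3, 1)
  r <- compute_metrics(preds, labels, 3)
  expect_equal(r$accuracy, 4 / 6)
  expect_equal(r$per_class$precision, c(1 / 2, 2 / 3, 1))
  expect_equal(r$per_class$recall, c(1 / 2, 1, 1 / 2))
  expect_equal(r$macro_precision, 13 / 18)
  # accuracy equals micro precision equals micro recall
  with(r$per_class, {
    expect_equal(sum(tp) / (sum(tp) + sum(fp)), r$accuracy)
    expect_equal(sum(tp) / (sum(tp) + sum(fn)), r$accuracy)
  })

  # an empty class contributes P = R = F1 = 0 to the macro means
  r0 <- compute_metrics(c(1, 1), c(1, 1), 3)
  expect_equal(r0$per_class$f1, c(1, 0, 0))
  expect_equal(r0$macro_f1, 1 / 3)

  expect_error(compute_metrics(1:3, 1:4), "lengths")
})

test_that("metrics agree with an independent confusion-matrix oracle", {
  set.seed(100)
  for (i in 1:100) {
    C <- sample(2:10, 1)
    n <- sample(5:50, 1)
    labels <- sample.int(C, n, replace = TRUE)
    preds <- sample.int(C, n, replace = TRUE)
    r <- compute_metrics(preds, labels, C)
    o <- oracle_metrics(preds, labels, C)
    expect_equal(r$accuracy, o$accuracy)
    expect_equal(r$macro_precision, o$macro_precision)
    expect_equal(r$macro_recall, o$macro_recall)
    expect_equal(r$macro_f1, o$macro_f1)
    # integer identity: sum TP = number of correct predictions
    expect_equal(sum(r$per_class$tp), sum(preds == labels))
  }
})

test_that("per-stage accuracies aggregate back to the overall accuracy", {
  set.seed(3)
  preds <- sample.int(4, 60, replace = TRUE)
  labels <- sample.int(4, 60, replace = TRUE)
  stages <- sample(c("042", "049", "056"), 60, replace = TRUE)
  tab <- stage_accuracy(preds, labels, stages)
  expect_equal(tab$stage, c("042", "049", "056"))
  expect_equal(sum(tab$accuracy * tab$n_images) / 60, mean(preds == labels))

  one <- stage_accuracy(preds, labels, rep("s1", 60))
  expect_equal(one$accuracy, mean(preds == labels))
  expect_equal(one$n_images, 60L)

  two <- stage_accuracy(c(1, 1, 2, 2), c(1, 1, 1, 1),
                        c("a", "a", "b", "b"))
  expect_equal(two$accuracy, c(1, 0))

  # missing stage labels are collected under "unstaged", reported last
  tab2 <- stage_accuracy(c(1, 1), c(1, 1), c("042", NA))
  expect_equal(tab2$stage, c("042", "unstaged"))
  expect_equal(tab2$n_images, c(1L, 1L))
})

test_that("confusion partition splits errors by class group", {
  expect_equal(confusion_partition(1:4, 1:4, rep("g", 4)),
               c(within = 0L, across = 0L))
  # all classes in one group: across is structurally zero
  set.seed(8)
  preds <- sample.int(4, 30, replace = TRUE)
  labels <- sample.int(4, 30, replace = TRUE)
  one <- confusion_partition(preds, labels, rep("g", 4))
  expect_equal(one[["across"]], 0L)
  expect_equal(sum(one), sum(preds != labels))

  # random predictions vs a brute-force per-sample tally
  groups <- c("ind", "ind", "jap", "jap")
  cp <- confusion_partition(preds, labels, groups)
  tally <- c(within = 0L, across = 0L)
  for (i in seq_along(preds)) {
    if (preds[i] == labels[i]) next
    k <- if (groups[preds[i]] == groups[labels[i]]) "within" else "across"
    tally[k] <- tally[k] + 1L
  }
  expect_equal(cp, tally)
  # counts sum to N - sum TP
  r <- compute_metrics(preds, labels, 4)
  expect_equal(sum(cp), length(preds) - sum(r$per_class$tp))

  expect_error(confusion_partition(preds, labels, c("a", "b")), "every class")
})

test_that("relative improvement reproduces reported comparisons", {
  expect_equal(relative_improvement(59.43, 77.85), 30.99)
  expect_equal(relative_improvement(42.88, 79.95), 86.45)
  expect_equal(relative_improvement(50, 50), 0)
  expect_error(relative_improvement(0, 10), "positive")
})

test_that("phenological binning follows per-accession milestones", {
  miles <- data.frame(accession = c("A", "B"),
                      heading_date = c("070", "080"),
                      mpa_date = c("100", "110"),
                      harvest_date = c("150", "160"))
  out <- bin_phenological_stage(
    accessions = c("A", "A", "A", "A", "B", "C"),
    dates = c("042", "070", "120", "150", "085", "042"),
    milestones = miles)
  expect_equal(out, c("pre_heading", "heading_to_mpa", "mpa_to_preharvest",
                      "harvest", "heading_to_mpa", NA))
})

test_that("evaluate_model assembles the full report on a fitted model", {
  man <- small_fixture(3, 3, image_size = c(40, 40))
  man <- split_dataset(man, 0.3, seed = 2)
  fit <- variety_cnn(man, input_size = c(40, 40), epochs = 6,
                     batch_size = 8, seed = 1)
  rep <- evaluate_model(fit, man)
  expect_s3_class(rep, "eval_report")
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  expect_equal(sum(rep$per_stage$n_images), sum(man$split == "test"))
  expect_equal(sum(rep$per_stage$accuracy * rep$per_stage$n_images) /
                 sum(rep$per_stage$n_images), rep$accuracy)
  expect_named(rep$confusion_partition, c("within", "across"))
})
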