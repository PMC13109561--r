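# Shared fixture builders and independent oracles.

# Manifest data.frame without backing image files (for enumeration and
# splitting logic; run_gmma and training need real files).
fake_manifest <- function(accessions, dates, viewpoints,
                          drop = character()) {
  grid <- expand.grid(accession = accessions, date = dates,
                      viewpoint = viewpoints, stringsAsFactors = FALSE)
  key <- paste(grid$accession, grid$date, grid$viewpoint)
  grid <- grid[!key %in% drop, , drop = FALSE]
  data.frame(path = sprintf("%s_p1_%s_%s.png", grid$accession, grid$date,
                            grid$viewpoint),
             accession = grid$accession, tag = "p1", date = grid$date,
             viewpoint = grid$viewpoint, stage = grid$date,
             subspecies = NA_character_, split = NA_character_,
             is_mixed = FALSE, stringsAsFactors = FALSE)
}

# Independent brute-force enumeration oracle: tests every ordered image
# pair of one accession against the three eligibility predicates.
brute_force_mix_jobs <- function(group) {
  sort_tokens <- function(d) {
    u <- unique(d)
    num <- suppressWarnings(as.numeric(u))
    if (!anyNA(num)) u[order(num)] else sort(u)
  }
  dates_all <- sort_tokens(group$date)
  succ_all <- function(d) {
    k <- match(d, dates_all)
    if (k < length(dates_all)) dates_all[k + 1L] else NA_character_
  }
  out <- data.frame(left = character(), right = character(),
                    mix_type = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(group))) for (j in seq_len(nrow(group))) {
    if (i == j) next
    a <- group[i, ]; b <- group[j, ]
    if (a$viewpoint == b$viewpoint) {
      dv <- sort_tokens(group$date[group$viewpoint == a$viewpoint])
      k <- match(a$date, dv)
      if (k < length(dv) && identical(b$date, dv[k + 1L]))
        out <- rbind(out, data.frame(left = a$path, right = b$path,
                                     mix_type = "temporal"))
    }
    if (identical(a$date, b$date) && a$viewpoint == "front" &&
        b$viewpoint == "side")
      out <- rbind(out, data.frame(left = a$path, right = b$path,
                                   mix_type = "viewpoint"))
    if (a$viewpoint == "front" && b$viewpoint == "side" &&
        identical(b$date, succ_all(a$date)))
      out <- rbind(out, data.frame(left = a$path, right = b$path,
                                   mix_type = "view_stage"))
  }
  out
}

# enumerate_mix_jobs indexes into the group after its internal sort; use
# the same ordering to translate indices back to paths
job_key <- function(group, jobs) {
  if (nrow(jobs) == 0L) return(character())
  g <- varietyid:::order_manifest(group)
  sort(paste(g$path[jobs$left], g$path[jobs$right], jobs$mix_type))
}

# Independent metrics oracle built on base::table.
oracle_metrics <- function(preds, labels, C) {
  cm <- table(factor(labels, levels = seq_len(C)),
              factor(preds, levels = seq_len(C)))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  div0 <- function(a, b) ifelse(b == 0, 0, a / b)
  p <- div0(tp, tp + fp); r <- div0(tp, tp + fn)
  list(accuracy = sum(tp) / length(labels),
       macro_precision = mean(p), macro_recall = mean(r),
       macro_f1 = mean(div0(2 * p * r, p + r)))
}

# A small synthetic image dataset on disk, built once per test run.
.fix_cache <- new.env(parent = emptyenv())
small_fixture <- function(n_accessions = 3L, n_dates = 3L,
                          image_size = c(48L, 64L), seed = 7L,
                          viewpoints = c("front", "side"),
                          class_signal = 1, noise_sd = 0.02) {
  key <- paste(n_accessions, n_dates, paste(image_size, collapse = "x"),
               seed, paste(viewpoints, collapse = ","), class_signal,
               noise_sd)
  if (is.null(.fix_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("fix_", abs(sum(utf8ToInt(key)))))
    .fix_cache[[key]] <- generate_synthetic_dataset(
      dir, n_accessions = n_accessions, n_dates = n_dates,
      viewpoints = viewpoints, image_size = image_size, seed = seed,
      class_signal = class_signal, noise_sd = noise_sd)
  }
  .fix_cache[[key]]
}

random_rgb <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(as.numeric(sample(0:255, h * w * 3, replace = TRUE)),
        dim = c(h, w, 3))
}
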