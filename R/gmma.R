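#' Convex mix of two images
#'
#' Pixelwise convex combination `lambda * image_i + (1 - lambda) * image_j`
#' computed in floating point, rounded to the nearest integer and clipped
#' to [0, 255]. This is the primitive behind all three mixed-augmentation
#' pair types.
#'
#' @param image_i,image_j Numeric arrays of identical dimensions, 0..255.
#'   `image_i` contributes weight `lambda`.
#' @param lambda Mixing coefficient in [0, 1].
#' @return Array of the input dimensions, integer-valued in 0..255.
#' @export
mixgen <- function(image_i, image_j, lambda = 0.5) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (!identical(dim(image_i), dim(image_j)))
    stop("image dimensions differ (",
         paste(dim(image_i), collapse = "x"), " vs ",
         paste(dim(image_j), collapse = "x"),
         "); preprocess both images to a common size first")
  pmin(pmax(round(lambda * image_i + (1 - lambda) * image_j), 0), 255)
}

mix_types <- c("temporal", "viewpoint", "view_stage")

#' Enumerate eligible mixing jobs for one accession
#'
#' Given all images of a single accession, lists every image pair eligible
#' for one of the three mixing constructions:
#' \describe{
#'   \item{temporal}{same viewpoint, dates immediately consecutive in the
#'     sorted list of dates present for that viewpoint; the earlier image
#'     takes weight `lambda`.}
#'   \item{viewpoint}{same date, front (weight `lambda`) with side.}
#'   \item{view_stage}{front at date t with side at the immediately
#'     following date t+1 (consecutive in the accession's pooled date
#'     list).}
#' }
#' Only pairs satisfying one of the three constructions are mixed; when a
#' (date, viewpoint) slot holds several images the Cartesian product of
#' candidates is enumerated. Groups of one image yield no jobs. Job order
#' is deterministic: by mix type (temporal, viewpoint, view_stage), then by
#' the left record's (date, viewpoint, tag) sort key.
#'
#' @param group Manifest rows of one accession (raw images only).
#' @param lambda Mixing coefficient in (0, 1), recorded per job.
#' @param view_stage_symmetric Also emit the mirrored side(t) x front(t+1)
#'   view-stage pairs (default `FALSE`).
#' @return A data.frame with columns `left`, `right` (row indices into the
#'   sorted `group`), `mix_type`, `lambda`, plus the left/right date and
#'   viewpoint tokens; zero rows when no pair is eligible.
#' @export
enumerate_mix_jobs <- function(group, lambda = 0.5,
                               view_stage_symmetric = FALSE) {
  if (length(unique(group$accession)) > 1L)
    stop("enumerate_mix_jobs expects records of a single accession")
  group <- order_manifest(group)
  n <- nrow(group)
  empty <- data.frame(left = integer(), right = integer(),
                      mix_type = character(), lambda = numeric(),
                      left_date = character(), right_date = character(),
                      left_view = character(), right_view = character(),
                      stringsAsFactors = FALSE)
  if (n <= 1L) return(empty)
  jobs <- list()
  add <- function(l, r, type) {
    for (li in l) for (ri in r)
      jobs[[length(jobs) + 1L]] <<- data.frame(
        left = li, right = ri, mix_type = type, lambda = lambda,
        left_date = group$date[li], right_date = group$date[ri],
        left_view = group$viewpoint[li], right_view = group$viewpoint[ri],
        stringsAsFactors = FALSE)
  }
  dates_all <- unique(group$date)
  dates_all <- dates_all[order(date_rank(dates_all))]
  # temporal: consecutive dates within each viewpoint
  for (vp in c("front", "side")) {
    dv <- dates_all[dates_all %in% group$date[group$viewpoint == vp]]
    if (length(dv) >= 2L)
      for (k in seq_len(length(dv) - 1L))
        add(which(group$date == dv[k] & group$viewpoint == vp),
            which(group$date == dv[k + 1L] & group$viewpoint == vp),
            "temporal")
  }
  # viewpoint: front x side at one date
  for (d in dates_all)
    add(which(group$date == d & group$viewpoint == "front"),
        which(group$date == d & group$viewpoint == "side"),
        "viewpoint")
  # view_stage: front at t x side at t+1 (pooled date list)
  if (length(dates_all) >= 2L)
    for (k in seq_len(length(dates_all) - 1L)) {
      add(which(group$date == dates_all[k] & group$viewpoint == "front"),
          which(group$date == dates_all[k + 1L] & group$viewpoint == "side"),
          "view_stage")
      if (view_stage_symmetric)
        add(which(group$date == dates_all[k] & group$viewpoint == "side"),
            which(group$date == dates_all[k + 1L] & group$viewpoint == "front"),
            "view_stage")
    }
  if (length(jobs) == 0L) return(empty)
  out <- do.call(rbind, jobs)
  out <- out[order(match(out$mix_type, mix_types), out$left, out$right), ]
  rownames(out) <- NULL
  out
}

#' Run mixed augmentation over a training manifest
#'
#' Enumerates mixing jobs per accession over the training records
#' (`split == "test"` rows are excluded and never augmented; rows with no
#' split assignment count as training), executes each job with [mixgen()],
#' writes the mixed images as PNG under `out_dir` using the naming scheme
#' `<accession>_mix-<type>_<dateL>-<dateR>_<viewL><viewR>.png` (numeric
#' suffix on collision), and appends the corresponding records with
#' `is_mixed = TRUE` and `split = "train"`. Mixing never crosses
#' accessions; already-mixed records are not re-mixed.
#'
#' @inheritParams enumerate_mix_jobs
#' @param manifest Manifest data.frame with readable `path`s.
#' @param out_dir Directory for the mixed images (created if missing).
#' @return A list with `manifest` (augmented) and `report`, a `mix_report`
#'   with fields `n_original`, `n_temporal`, `n_viewpoint`, `n_view_stage`,
#'   `n_total` satisfying `n_total = n_original + sum(per-type counts)`.
#' @export
run_gmma <- function(manifest, out_dir, lambda = 0.5,
                     view_stage_symmetric = FALSE) {
  stopifnot(lambda > 0, lambda < 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  train <- manifest[(is.na(manifest$split) | manifest$split != "test") &
                      !manifest$is_mixed, , drop = FALSE]
  counts <- c(temporal = 0L, viewpoint = 0L, view_stage = 0L)
  new_recs <- list()
  for (acc in sort(unique(train$accession))) {
    group <- order_manifest(train[train$accession == acc, , drop = FALSE])
    jobs <- enumerate_mix_jobs(group, lambda = lambda,
                               view_stage_symmetric = view_stage_symmetric)
    for (k in seq_len(nrow(jobs))) {
      job <- jobs[k, ]
      imgs <- tryCatch(
        list(read_image(group$path[job$left]), read_image(group$path[job$right])),
        error = function(e) {
          warning("skipping mix job for '", acc, "': ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
      if (is.null(imgs)) next
      mixed <- mixgen(imgs[[1]], imgs[[2]], lambda)
      base <- sprintf("%s_mix-%s_%s-%s_%s%s", acc, job$mix_type,
                      job$left_date, job$right_date,
                      job$left_view, job$right_view)
      dest <- file.path(out_dir, paste0(base, ".png"))
      suffix <- 1L
      while (file.exists(dest)) {
        suffix <- suffix + 1L
        dest <- file.path(out_dir, paste0(base, "-", suffix, ".png"))
      }
      write_image(mixed, dest)
      counts[job$mix_type] <- counts[job$mix_type] + 1L
      left <- group[job$left, ]
      new_recs[[length(new_recs) + 1L]] <- data.frame(
        path = dest, accession = acc, tag = "mix", date = left$date,
        viewpoint = left$viewpoint, stage = left$stage,
        subspecies = left$subspecies, split = "train", is_mixed = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  augmented <- if (length(new_recs))
    rbind(new_manifest(manifest), new_manifest(do.call(rbind, new_recs)))
  else new_manifest(manifest)
  rownames(augmented) <- NULL
  report <- structure(list(
    n_original = nrow(train),
    n_temporal = unname(counts["temporal"]),
    n_viewpoint = unname(counts["viewpoint"]),
    n_view_stage = unname(counts["view_stage"]),
    n_total = nrow(train) + sum(counts)), class = "mix_report")
  list(manifest = augmented, report = report)
}

#' @export
print.mix_report <- function(x, ...) {
  cat("Mixed-augmentation report\n")
  cat(sprintf("  original images : %d\n", x$n_original))
  cat(sprintf("  temporal mixes  : %d\n", x$n_temporal))
  cat(sprintf("  viewpoint mixes : %d\n", x$n_viewpoint))
  cat(sprintf("  view-stage mixes: %d\n", x$n_view_stage))
  cat(sprintf("  total after augmentation: %d\n", x$n_total))
  invisible(x)
}
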