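#' Parse a filename following the accession_tag_date_viewpoint grammar
#'
#' Dataset filenames encode metadata as `accession_tag_date_viewpoint.<ext>`,
#' e.g. `"R0001_p1_20210601_front.png"`. The stem is split on underscores:
#' the first field is the accession, the last the viewpoint, the
#' second-to-last the sampling date, and everything in between is absorbed
#' into the free-form tag (so tags may themselves contain underscores).
#'
#' @param name A filename (with or without directory components).
#' @return A list with elements `accession`, `tag`, `date`, `viewpoint`
#'   (normalized to `"front"`/`"side"`).
#' @export
#' @examples
#' parse_image_filename("R0001_p1_20210601_front.png")
parse_image_filename <- function(name) {
  stem <- tools::file_path_sans_ext(basename(name))
  ext <- tolower(tools::file_ext(name))
  if (!ext %in% c("png", "jpg", "jpeg", "tif", "tiff"))
    stop("unsupported image extension in '", name, "'")
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (length(parts) < 4L)
    stop("cannot parse '", name, "': stem has ", length(parts),
         " underscore-separated fields, need at least 4 ",
         "(accession_tag_date_viewpoint)")
  vp <- tolower(parts[length(parts)])
  vp <- switch(vp, f = "front", s = "side", vp)
  if (!vp %in% c("front", "side"))
    stop("unknown viewpoint token '", parts[length(parts)], "' in '", name,
         "'; accepted tokens: front, side, f, s")
  acc <- parts[1]
  if (!nzchar(acc)) stop("empty accession field in '", name, "'")
  list(
    accession = acc,
    tag = paste(parts[2:(length(parts) - 2L)], collapse = "_"),
    date = parts[length(parts) - 1L],
    viewpoint = vp
  )
}

manifest_columns <- c("path", "accession", "tag", "date", "viewpoint",
                      "stage", "subspecies", "split", "is_mixed")

new_manifest <- function(df) {
  for (col in manifest_columns)
    if (is.null(df[[col]])) df[[col]] <- if (col == "is_mixed") FALSE else NA_character_
  df <- df[, manifest_columns]
  df$is_mixed <- as.logical(df$is_mixed)
  rownames(df) <- NULL
  df
}

# order key used everywhere records are sorted: accession, date, viewpoint
order_manifest <- function(df) {
  df[order(df$accession, date_rank(df$date), df$viewpoint, df$tag), , drop = FALSE]
}

# Rank date tokens: numeric when all tokens parse as integers, otherwise
# lexicographic (ISO dates sort correctly either way).
date_rank <- function(dates) {
  num <- suppressWarnings(as.numeric(dates))
  if (!anyNA(num[!is.na(dates)])) num else xtfrm(dates)
}

#' Build a dataset manifest from a folder of encoded filenames
#'
#' Scans `folder` for raster files named by the
#' `accession_tag_date_viewpoint` grammar and assembles one record per
#' parseable file. Files that fail to parse are skipped with a warning;
#' duplicate (accession, date, viewpoint) triples are kept but flagged in a
#' warning. Records are sorted by (accession, date, viewpoint) so repeated
#' builds are deterministic.
#'
#' @param folder Directory containing the images.
#' @return A data.frame with columns `path, accession, tag, date,
#'   viewpoint, stage, subspecies, split, is_mixed`.
#' @export
build_manifest <- function(folder) {
  if (!dir.exists(folder)) stop("folder does not exist: ", folder)
  files <- list.files(folder, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in folder: ", folder)
  recs <- list()
  for (f in files) {
    p <- tryCatch(parse_image_filename(f), error = function(e) {
      warning("skipping '", basename(f), "': ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(p))
      recs[[length(recs) + 1L]] <- data.frame(
        path = f, accession = p$accession, tag = p$tag, date = p$date,
        viewpoint = p$viewpoint, stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L)
    stop("no parseable image files in folder: ", folder)
  df <- new_manifest(do.call(rbind, recs))
  df <- order_manifest(df)
  key <- paste(df$accession, df$date, df$viewpoint, sep = "\r")
  if (anyDuplicated(key))
    warning("duplicate (accession, date, viewpoint) triples retained: ",
            paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  df
}

#' Stratified train/test split of a manifest
#'
#' Assigns each record to the train or test split. By default the split is
#' stratified per accession: within each accession, `round(test_fraction *
#' n)` images (floored at 0, capped at n - 1 so every accession keeps at
#' least one training image) are drawn at random into the test set. With
#' `stratify = FALSE` a single global draw of `round(test_fraction * N)`
#' records is used instead. The same seed always reproduces the same split.
#'
#' @param manifest Manifest data.frame (see [build_manifest()]).
#' @param test_fraction Proportion of images held out, in (0, 1).
#' @param seed Integer RNG seed.
#' @param stratify Stratify per accession (default `TRUE`).
#' @return The manifest with its `split` column filled with
#'   `"train"`/`"test"`.
#' @export
split_dataset <- function(manifest, test_fraction = 0.2, seed = 42L,
                          stratify = TRUE) {
  stopifnot(nrow(manifest) > 0L, test_fraction > 0, test_fraction < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  manifest$split <- "train"
  if (stratify) {
    for (acc in sort(unique(manifest$accession))) {
      idx <- which(manifest$accession == acc)
      n <- length(idx)
      k <- min(max(round(test_fraction * n), 0L), n - 1L)
      if (n == 1L)
        warning("accession '", acc, "' has a single image; kept in train",
                call. = FALSE)
      if (k > 0L)
        manifest$split[sample(idx, k)] <- "test"
    }
  } else {
    n <- nrow(manifest)
    k <- min(max(round(test_fraction * n), 0L), n - 1L)
    if (k > 0L) manifest$split[sample.int(n, k)] <- "test"
  }
  manifest
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read a manifest CSV
#'
#' The on-disk format is a plain CSV with header
#' `path,accession,tag,date,viewpoint,stage,subspecies,split,is_mixed`.
#'
#' @param manifest Manifest data.frame.
#' @param path CSV file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(new_manifest(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    path = "character", accession = "character", tag = "character",
    date = "character", viewpoint = "character", stage = "character",
    subspecies = "character", split = "character", is_mixed = "logical"))
  new_manifest(df)
}
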