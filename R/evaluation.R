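coerce_classes <- function(preds, labels, n_classes = NULL) {
  if (is.factor(preds) || is.factor(labels)) {
    lev <- union(levels(as.factor(labels)), levels(as.factor(preds)))
    preds <- match(as.character(preds), lev)
    labels <- match(as.character(labels), lev)
    if (is.null(n_classes)) n_classes <- length(lev)
  }
  if (length(preds) != length(labels))
    stop("preds and labels have different lengths (", length(preds),
         " vs ", length(labels), ")")
  if (is.null(n_classes)) n_classes <- max(preds, labels)
  stopifnot(all(preds >= 1L), all(preds <= n_classes),
            all(labels >= 1L), all(labels <= n_classes))
  list(preds = as.integer(preds), labels = as.integer(labels),
       C = as.integer(n_classes))
}

#' Accuracy and macro-averaged classification metrics
#'
#' Computes overall accuracy (`sum TP_i / N`) and per-class precision,
#' recall and F1, macro-averaged with equal class weight. A class with no
#' predicted and no true positives contributes P = R = F1 = 0 to the macro
#' means (0/0 is defined as 0), so empty classes deflate rather than
#' inflate the macro scores.
#'
#' @param preds,labels Predicted and true classes: integers in 1..C or
#'   factors over the same levels.
#' @param n_classes Number of classes C (inferred when omitted).
#' @return An object of class `eval_report`: list with `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `n`, and `per_class`,
#'   a data.frame of TP/FP/FN and P/R/F1 per class.
#' @export
compute_metrics <- function(preds, labels, n_classes = NULL) {
  z <- coerce_classes(preds, labels, n_classes)
  C <- z$C; n <- length(z$preds)
  tp <- fp <- fn <- integer(C)
  correct <- z$preds == z$labels
  for (c in seq_len(C)) {
    tp[c] <- sum(correct & z$labels == c)
    fp[c] <- sum(!correct & z$preds == c)
    fn[c] <- sum(!correct & z$labels == c)
  }
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  structure(list(
    accuracy = sum(tp) / n,
    macro_precision = mean(prec),
    macro_recall = mean(rec),
    macro_f1 = mean(f1),
    n = n,
    per_class = data.frame(class = seq_len(C), tp = tp, fp = fp, fn = fn,
                           precision = prec, recall = rec, f1 = f1)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d images, %d classes\n", x$n,
              nrow(x$per_class)))
  cat(sprintf("  accuracy        %.4f\n", x$accuracy))
  cat(sprintf("  macro precision %.4f\n", x$macro_precision))
  cat(sprintf("  macro recall    %.4f\n", x$macro_recall))
  cat(sprintf("  macro F1        %.4f\n", x$macro_f1))
  invisible(x)
}

#' Per-growth-stage accuracy breakdown
#'
#' Slices the test predictions by growth-stage label (sampling dates,
#' phenological bins, or S1..S9 tokens) and reports accuracy and image
#' count per stage, ordered by the stages' natural order (numeric when
#' all tokens parse as numbers, lexicographic otherwise). Missing stage
#' labels are collected under `"unstaged"`. The image-count-weighted mean
#' of the per-stage accuracies equals the overall accuracy whenever the
#' stages partition the evaluated set.
#'
#' @inheritParams compute_metrics
#' @param stages Stage label per evaluated image.
#' @return data.frame with columns `stage`, `accuracy`, `n_images`.
#' @export
stage_accuracy <- function(preds, labels, stages) {
  z <- coerce_classes(preds, labels)
  stages <- as.character(stages)
  if (length(stages) != length(z$preds))
    stop("stages must have one label per evaluated image")
  stages[is.na(stages) | !nzchar(stages)] <- "unstaged"
  u <- unique(stages)
  known <- u[u != "unstaged"]
  u <- c(known[order(date_rank(known))], if ("unstaged" %in% u) "unstaged")
  out <- data.frame(stage = u, accuracy = NA_real_, n_images = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(u)) {
    sel <- stages == u[i]
    out$accuracy[i] <- mean(z$preds[sel] == z$labels[sel])
    out$n_images[i] <- sum(sel)
  }
  out
}

#' Within- vs across-group error partition
#'
#' Splits the misclassified samples by whether the predicted and true
#' classes belong to the same group (e.g. rice subspecies). The two counts
#' always sum to the total number of errors.
#'
#' @inheritParams compute_metrics
#' @param group_of Named vector or factor mapping each class (by level
#'   name for factors, by 1..C index otherwise) to a group label.
#' @return Named integer vector `c(within = ..., across = ...)`.
#' @export
confusion_partition <- function(preds, labels, group_of) {
  if (is.factor(preds) || is.factor(labels)) {
    lev <- union(levels(as.factor(labels)), levels(as.factor(preds)))
    if (is.null(names(group_of)))
      stop("group_of must be named by class level when preds are factors")
    if (!all(lev %in% names(group_of)))
      stop("classes without a group: ",
           paste(setdiff(lev, names(group_of)), collapse = ", "))
    group_of <- group_of[lev]
  }
  z <- coerce_classes(preds, labels)
  if (length(group_of) < max(z$preds, z$labels))
    stop("group_of must map every class to a group")
  if (anyNA(group_of)) stop("every class needs a non-missing group")
  err <- z$preds != z$labels
  within <- sum(err & group_of[z$preds] == group_of[z$labels])
  c(within = within, across = sum(err) - within)
}

#' Relative accuracy improvement
#'
#' Percentage change of an accuracy (or any positive percentage) over a
#' baseline: `100 * (new - baseline) / baseline`, rounded to two decimals
#' for reporting.
#'
#' @param baseline_pct Baseline value (> 0), on the percent scale.
#' @param new_pct New value, on the percent scale.
#' @return Relative change in percent, rounded to 2 decimals.
#' @export
#' @examples
#' relative_improvement(59.43, 77.85)  # 30.99
relative_improvement <- function(baseline_pct, new_pct) {
  if (any(baseline_pct <= 0)) stop("baseline must be positive")
  round(100 * (new_pct - baseline_pct) / baseline_pct, 2L)
}

#' Bin sampling dates into phenological stages
#'
#' Maps per-image sampling dates to the four rice phenological bins given
#' per-accession milestone dates: `pre_heading` (date < heading),
#' `heading_to_mpa`, `mpa_to_preharvest`, and `harvest` (date >= harvest).
#' Date tokens must be orderable the same way the manifest orders them.
#'
#' @param accessions Accession label per image.
#' @param dates Sampling-date token per image.
#' @param milestones data.frame with columns
#'   `accession, heading_date, mpa_date, harvest_date`.
#' @return Character vector of stage bins (NA when an accession has no
#'   milestone row).
#' @export
bin_phenological_stage <- function(accessions, dates, milestones) {
  need <- c("accession", "heading_date", "mpa_date", "harvest_date")
  if (!all(need %in% names(milestones)))
    stop("milestones must have columns: ", paste(need, collapse = ", "))
  i <- match(accessions, milestones$accession)
  d <- date_rank(c(dates, milestones$heading_date, milestones$mpa_date,
                   milestones$harvest_date))
  n <- length(dates)
  dd <- d[seq_len(n)]
  hd <- d[n + i]
  md <- d[n + nrow(milestones) + i]
  vd <- d[n + 2L * nrow(milestones) + i]
  out <- rep(NA_character_, n)
  out[!is.na(i) & dd < hd] <- "pre_heading"
  out[!is.na(i) & dd >= hd & dd < md] <- "heading_to_mpa"
  out[!is.na(i) & dd >= md & dd < vd] <- "mpa_to_preharvest"
  out[!is.na(i) & dd >= vd] <- "harvest"
  out
}

#' Evaluate a fitted classifier on a manifest split
#'
#' Predicts the requested split and assembles the full evaluation report:
#' overall and macro metrics, per-stage accuracy (from the manifest's
#' `stage` column when present), and the within/across-group confusion
#' partition (from the `subspecies` column or an explicit `groups`
#' mapping).
#'
#' @param object A fitted `variety_cnn`.
#' @param manifest Manifest data.frame.
#' @param split Which split to evaluate (default `"test"`).
#' @param groups Optional named vector mapping accession -> group;
#'   defaults to the manifest's `subspecies` column when filled.
#' @return An `eval_report` with additional `per_stage` and
#'   `confusion_partition` components.
#' @export
evaluate_model <- function(object, manifest, split = "test", groups = NULL) {
  rows <- manifest[!is.na(manifest$split) & manifest$split == split, ,
                   drop = FALSE]
  if (nrow(rows) == 0L) stop("no records with split == '", split, "'")
  preds <- predict(object, rows, type = "class")
  labels <- factor(rows$accession, levels = object$levels)
  if (anyNA(labels))
    warning("test classes unseen in training: ",
            paste(setdiff(unique(rows$accession), object$levels),
                  collapse = ", "), call. = FALSE)
  keep <- !is.na(labels)
  rep <- compute_metrics(preds[keep], labels[keep],
                         n_classes = length(object$levels))
  rep$per_class$class <- object$levels
  if (any(!is.na(rows$stage[keep])))
    rep$per_stage <- stage_accuracy(preds[keep], labels[keep],
                                    rows$stage[keep])
  if (is.null(groups) && any(!is.na(rows$subspecies))) {
    m <- rows[keep, ]
    groups <- stats::setNames(m$subspecies[!duplicated(m$accession)],
                              m$accession[!duplicated(m$accession)])
  }
  if (!is.null(groups) && all(object$levels %in% names(groups)))
    rep$confusion_partition <- confusion_partition(preds[keep], labels[keep],
                                                   groups)
  rep
}
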