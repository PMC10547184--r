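# Pixel-level and object-level evaluation: accuracy, recall, precision,
# Dice, F1, TPRp, FPRp, and object metrics built on one-to-one instance
# matching at a DSC threshold (0.7). Undefined ratios (empty denominators)
# are reported as NA, never silently as 0.

#' Threshold a probability map
#' @param prob_map numeric array in `[0,1]`
#' @param threshold scalar cut
#' @return logical mask, `prob_map > threshold`
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  prob_map > threshold
}

#' Pixel confusion counts
#' @param pred,gt logical masks of equal shape
#' @return list(TP, TN, FP, FN)
#' @export
pixel_confusion <- function(pred, gt) {
  check_same_shape(pred, gt)
  p <- pred > 0; g <- gt > 0
  list(TP = sum(p & g), TN = sum(!p & !g),
       FP = sum(p & !g), FN = sum(!p & g))
}

#' @rdname pixel_metrics
#' @export
pixel_accuracy <- function(c) {
  tot <- c$TP + c$TN + c$FP + c$FN
  if (tot == 0) return(NA_real_)
  (c$TP + c$TN) / tot
}

#' Pixel-level ratios from a confusion list
#'
#' `pixel_accuracy = (TP+TN)/total`, `pixel_recall = tpr_p = TP/(TP+FN)`,
#' `pixel_precision = TP/(TP+FP)`, `fpr_p = FP/(FP+TN)`. A ratio whose
#' denominator is empty is NA.
#'
#' @param c list with TP, TN, FP, FN as from [pixel_confusion()]
#' @return scalar in `[0,1]` or NA when undefined
#' @name pixel_metrics
#' @export
pixel_recall <- function(c) {
  if (c$TP + c$FN == 0) return(NA_real_)
  c$TP / (c$TP + c$FN)
}

#' @rdname pixel_metrics
#' @export
pixel_precision <- function(c) {
  if (c$TP + c$FP == 0) return(NA_real_)
  c$TP / (c$TP + c$FP)
}

#' @rdname pixel_metrics
#' @export
tpr_p <- function(c) pixel_recall(c)

#' @rdname pixel_metrics
#' @export
fpr_p <- function(c) {
  if (c$FP + c$TN == 0) return(NA_real_)
  c$FP / (c$FP + c$TN)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |pred & gt| / (|pred| + |gt|)`; two empty masks count as perfect
#' agreement (1), with a message.
#'
#' @param pred,gt logical masks of equal shape
#' @return scalar in `[0,1]`
#' @export
dice_coefficient <- function(pred, gt) {
  check_same_shape(pred, gt)
  p <- pred > 0; g <- gt > 0
  denom <- sum(p) + sum(g)
  if (denom == 0) {
    message("dice_coefficient: both masks empty; returning 1 by convention")
    return(1)
  }
  2 * sum(p & g) / denom
}

#' F1 score from precision and recall
#'
#' `2 P R / (P + R)`; defined as 0 (with a message) when both are zero.
#' For binary masks F1 of the pixel confusion equals the Dice coefficient.
#'
#' @param precision,recall scalars in `[0,1]`
#' @return scalar in `[0,1]`
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) {
    message("f1_score: precision and recall both zero; returning 0")
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' One-to-one instance matching by Dice coefficient
#'
#' Computes pairwise DSC between all overlapping (gt, pred) instance pairs
#' and greedily matches in order of descending DSC among pairs exceeding
#' the threshold; ties break on ascending (gt id, pred id) so the matching
#' is deterministic.
#'
#' @param pred_instances,gt_instances integer label maps of equal shape
#' @param dsc_threshold minimum DSC for a valid match (strict >)
#' @return an `object_matching` list: `pairs` (data.frame gt, pred, dsc),
#'   `unmatched_gt`, `unmatched_pred`, `dsc_threshold`
#' @export
match_objects <- function(pred_instances, gt_instances, dsc_threshold = 0.7) {
  check_same_shape(pred_instances, gt_instances)
  gt_ids <- setdiff(sort(unique(as.vector(gt_instances))), 0L)
  pred_ids <- setdiff(sort(unique(as.vector(pred_instances))), 0L)
  gt_sizes <- tabulate(gt_instances[gt_instances > 0L], nbins = max(gt_instances, 1L))
  pred_sizes <- tabulate(pred_instances[pred_instances > 0L], nbins = max(pred_instances, 1L))
  both <- gt_instances > 0L & pred_instances > 0L
  cand <- data.frame(gt = integer(), pred = integer(), dsc = numeric())
  if (any(both)) {
    key <- paste(gt_instances[both], pred_instances[both])
    ov <- table(key)
    parts <- strsplit(names(ov), " ", fixed = TRUE)
    g <- as.integer(vapply(parts, `[`, "", 1))
    p <- as.integer(vapply(parts, `[`, "", 2))
    dsc <- 2 * as.numeric(ov) / (gt_sizes[g] + pred_sizes[p])
    cand <- data.frame(gt = g, pred = p, dsc = dsc)
    cand <- cand[cand$dsc > dsc_threshold, , drop = FALSE]
    cand <- cand[order(-cand$dsc, cand$gt, cand$pred), , drop = FALSE]
  }
  used_gt <- integer(); used_pred <- integer()
  pairs <- list()
  for (i in seq_len(nrow(cand))) {
    if (cand$gt[i] %in% used_gt || cand$pred[i] %in% used_pred) next
    used_gt <- c(used_gt, cand$gt[i])
    used_pred <- c(used_pred, cand$pred[i])
    pairs[[length(pairs) + 1L]] <- cand[i, ]
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gt = integer(), pred = integer(), dsc = numeric())
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_gt = setdiff(gt_ids, pairs$gt),
                 unmatched_pred = setdiff(pred_ids, pairs$pred),
                 dsc_threshold = dsc_threshold),
            class = "object_matching")
}

#' Object-level accuracy, recall and false-negative rate
#'
#' `recall_o = matched / n_gt`, `fnr_o = 1 - recall_o`, and
#' `acc_o = matched / (n_gt + n_pred - matched)` (Jaccard-style
#' union-normalized object accuracy).
#'
#' @param m an `object_matching` from [match_objects()]
#' @param n_gt,n_pred instance counts in ground truth and prediction
#' @return list(acc_o, recall_o, fnr_o); NA when `n_gt` is 0
#' @export
object_metrics <- function(m, n_gt, n_pred) {
  matched <- nrow(m$pairs)
  stopifnot(n_gt >= matched, n_pred >= matched)
  if (n_gt == 0) {
    return(list(acc_o = NA_real_, recall_o = NA_real_, fnr_o = NA_real_))
  }
  recall_o <- matched / n_gt
  denom <- n_gt + n_pred - matched
  list(acc_o = if (denom > 0) matched / denom else NA_real_,
       recall_o = recall_o,
       fnr_o = 1 - recall_o)
}

metric_names <- c("acc_o", "recall_o", "acc_p", "recall_p", "dice",
                  "f1", "tpr_p", "fpr_p", "fnr_o")

#' All nine report metrics for one image
#'
#' @param pred logical mask or integer instance map of the prediction
#' @param gt logical mask or integer instance map of the ground truth
#' @param dsc_threshold object-matching DSC threshold
#' @return named list of the nine metrics
#' @export
evaluate_pair <- function(pred, gt, dsc_threshold = 0.7) {
  pred_inst <- if (is.logical(pred)) label_components(pred) else pred
  gt_inst <- if (is.logical(gt)) label_components(gt) else gt
  pred_bin <- pred_inst > 0L
  gt_bin <- gt_inst > 0L
  conf <- pixel_confusion(pred_bin, gt_bin)
  prec <- pixel_precision(conf)
  rec <- pixel_recall(conf)
  m <- match_objects(pred_inst, gt_inst, dsc_threshold)
  om <- object_metrics(m, n_gt = length(setdiff(unique(as.vector(gt_inst)), 0L)),
                       n_pred = length(setdiff(unique(as.vector(pred_inst)), 0L)))
  list(acc_o = om$acc_o, recall_o = om$recall_o,
       acc_p = pixel_accuracy(conf), recall_p = rec,
       dice = dice_coefficient(pred_bin, gt_bin),
       f1 = f1_score(prec, rec),
       tpr_p = tpr_p(conf), fpr_p = fpr_p(conf),
       fnr_o = om$fnr_o)
}

#' Evaluate a directory of predictions against ground truth
#'
#' Pairs files by shared name stem (`mask_k.png` predictions against
#' `instance_k.tiff` ground truth when present, else `mask_k.png`), writes
#' a per-image CSV and returns mean and sd of each metric.
#'
#' @param pred_dir directory of predicted binary masks (PNG)
#' @param gt_dir dataset directory with a manifest (see
#'   [generate_dataset()]) or matching mask files
#' @param dsc_threshold object-matching DSC threshold
#' @param csv_path optional output path for the per-image table
#' @return list(per_image data.frame, mean named vector, sd named vector)
#' @export
evaluate_dataset <- function(pred_dir, gt_dir, dsc_threshold = 0.7,
                             csv_path = NULL) {
  manifest_path <- file.path(gt_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    man <- read_manifest(gt_dir)
    gt_files <- file.path(gt_dir, man$instance)
    pred_files <- file.path(pred_dir, man$mask)
    names_out <- man$mask
  } else {
    names_out <- sort(list.files(gt_dir, pattern = "\\.png$"))
    gt_files <- file.path(gt_dir, names_out)
    pred_files <- file.path(pred_dir, names_out)
  }
  if (length(gt_files) == 0) stop("no ground-truth files under ", gt_dir)
  rows <- vector("list", length(gt_files))
  for (i in seq_along(gt_files)) {
    if (!file.exists(pred_files[i])) {
      stop("missing prediction for ", names_out[i], ": ", pred_files[i])
    }
    gt <- if (grepl("\\.tiff?$", gt_files[i])) {
      read_instance_tiff(gt_files[i])
    } else {
      read_mask_png(gt_files[i])
    }
    pred <- read_mask_png(pred_files[i])
    met <- evaluate_pair(pred, gt, dsc_threshold)
    rows[[i]] <- cbind(data.frame(file = names_out[i]), as.data.frame(met))
  }
  per_image <- do.call(rbind, rows)
  mu <- vapply(metric_names, function(k) mean(per_image[[k]], na.rm = TRUE),
               numeric(1))
  sdv <- vapply(metric_names, function(k) stats::sd(per_image[[k]], na.rm = TRUE),
                numeric(1))
  if (!is.null(csv_path)) utils::write.csv(per_image, csv_path, row.names = FALSE)
  list(per_image = per_image, mean = mu, sd = sdv)
}
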