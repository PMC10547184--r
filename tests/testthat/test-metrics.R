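# Pixel and object metrics against loop oracles, identities, and an
# exhaustive assignment oracle for instance matching.

oracle_confusion <- function(pred, gt) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] && gt[i]) tp <- tp + 1
    else if (pred[i] && !gt[i]) fp <- fp + 1
    else if (!pred[i] && gt[i]) fn <- fn + 1
    else tn <- tn + 1
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# best one-to-one assignment over all injections (small instance counts)
oracle_best_matching <- function(pred_inst, gt_inst, thr) {
  gt_ids <- setdiff(sort(unique(as.vector(gt_inst))), 0)
  pred_ids <- setdiff(sort(unique(as.vector(pred_inst))), 0)
  dsc <- function(g, p) {
    a <- gt_inst == g; b <- pred_inst == p
    2 * sum(a & b) / (sum(a) + sum(b))
  }
  best <- 0L
  if (length(gt_ids) == 0 || length(pred_ids) == 0) return(0L)
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(r) c(v[i], r))))
  k <- min(length(gt_ids), length(pred_ids))
  gsub <- utils::combn(gt_ids, k, simplify = FALSE)
  for (gs in gsub) {
    for (ps in perms(pred_ids)) {
      cnt <- sum(vapply(seq_len(k), function(i) dsc(gs[i], ps[i]) > thr,
                        logical(1)))
      best <- max(best, cnt)
    }
  }
  best
}

test_that("binarize thresholds correctly and is idempotent on binary maps", {
  expect_false(any(binarize(matrix(0.4, 3, 3), 0.5)))
  m <- matrix(c(0, 0.2, 0, 0.7), 2, 2)
  expect_identical(binarize(m, 0), m > 0)
  b <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  expect_identical(binarize(b * 1, 0.5), b)
})

test_that("pixel confusion and ratio formulas match loop oracles", {
  set.seed(21)
  for (rep in 1:25) {
    p <- random_binary_map(4, 4) > 0
    g <- random_binary_map(4, 4) > 0
    c1 <- pixel_confusion(p, g)
    c2 <- oracle_confusion(p, g)
    expect_equal(c1, c2)
    tot <- 16
    expect_equal(c1$TP + c1$TN + c1$FP + c1$FN, tot)
    expect_equal(pixel_accuracy(c1), (c2$TP + c2$TN) / tot)
    if (c2$TP + c2$FN > 0) {
      expect_equal(pixel_recall(c1), c2$TP / (c2$TP + c2$FN))
      expect_equal(tpr_p(c1), pixel_recall(c1))
    }
    if (c2$FP + c2$TN > 0) {
      expect_equal(fpr_p(c1), c2$FP / (c2$FP + c2$TN))
    }
  }
  # fixed arithmetic case
  cf <- list(TP = 3, TN = 2, FP = 1, FN = 2)
  expect_equal(pixel_accuracy(cf), 5 / 8)
  expect_equal(pixel_recall(cf), 3 / 5)
  # degenerate confusions give NA, never a silent zero
  expect_true(is.na(pixel_recall(list(TP = 0, TN = 4, FP = 0, FN = 0))))
  expect_true(is.na(fpr_p(list(TP = 4, TN = 0, FP = 0, FN = 0))))
})

test_that("dice coefficient arithmetic and conventions", {
  p <- matrix(FALSE, 3, 3); p[1:2, 1:2] <- TRUE      # |pred| = 4
  g <- matrix(FALSE, 3, 3); g[1:2, 1:3] <- TRUE      # |gt| = 6
  # overlap 4 -> 8/10; shrink gt to get the 3-overlap case
  g2 <- matrix(FALSE, 3, 3); g2[1, 1:2] <- TRUE; g2[2, 1] <- TRUE
  g2[3, 3] <- TRUE; g2[2, 3] <- TRUE                  # |gt| = 5, overlap 3
  expect_equal(dice_coefficient(p, g2), 2 * 3 / (4 + 5))
  expect_equal(dice_coefficient(g, g), 1)
  expect_message(d0 <- dice_coefficient(matrix(FALSE, 2, 2),
                                        matrix(FALSE, 2, 2)), "empty")
  expect_equal(d0, 1)
})

test_that("F1 identities: harmonic fixed point and F1 == Dice on masks", {
  expect_equal(f1_score(0.7, 0.7), 0.7)
  expect_equal(f1_score(1, 0.5), 2 / 3)
  expect_message(expect_equal(f1_score(0, 0), 0), "zero")
  set.seed(22)
  for (rep in 1:20) {
    p <- random_binary_map(8, 8) > 0
    g <- random_binary_map(8, 8) > 0
    cf <- pixel_confusion(p, g)
    pr <- pixel_precision(cf); rc <- pixel_recall(cf)
    if (!is.na(pr) && !is.na(rc) && (pr + rc) > 0 && (sum(p) + sum(g)) > 0) {
      expect_equal(f1_score(pr, rc), dice_coefficient(p, g),
                   tolerance = 1e-12)
    }
  }
})

test_that("object matching: identity, disjoint, and assignment oracle", {
  inst <- matrix(0L, 6, 6)
  inst[1:2, 1:2] <- 1L; inst[4:6, 4:6] <- 2L
  m <- match_objects(inst, inst)
  expect_equal(nrow(m$pairs), 2)
  expect_true(all(m$pairs$dsc == 1))
  expect_length(m$unmatched_gt, 0)

  other <- matrix(0L, 6, 6); other[1:2, 4:6] <- 1L
  m2 <- match_objects(other, inst)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched_gt, 1:2)
  expect_equal(m2$unmatched_pred, 1L)

  set.seed(23)
  for (rep in 1:15) {
    gt <- matrix(sample(0:3, 16, replace = TRUE), 4, 4)
    pr <- matrix(sample(0:3, 16, replace = TRUE), 4, 4)
    # at the working threshold 0.7, DSC > 0.7 implies IoU > 0.5, so every
    # instance has at most one admissible partner: greedy is exactly optimal
    mm7 <- match_objects(pr, gt, dsc_threshold = 0.7)
    expect_equal(nrow(mm7$pairs), oracle_best_matching(pr, gt, 0.7))
    # at permissive thresholds greedy is a maximal matching: within one of
    # optimal on <= 3x3 toys, never above it (disagreement cases possible)
    mm <- match_objects(pr, gt, dsc_threshold = 0.3)
    opt <- oracle_best_matching(pr, gt, 0.3)
    expect_lte(nrow(mm$pairs), opt)
    expect_gte(nrow(mm$pairs), opt - 1L)
    # matched count is symmetric in the roles of pred and gt
    ms <- match_objects(gt, pr, dsc_threshold = 0.3)
    expect_equal(nrow(mm$pairs), nrow(ms$pairs))
    expect_true(all(mm$pairs$dsc > 0.3))
    expect_false(any(duplicated(mm$pairs$gt)))
    expect_false(any(duplicated(mm$pairs$pred)))
  }
})

test_that("object metrics arithmetic and the recall/fnr identity", {
  inst <- matrix(0L, 4, 4); inst[1:2, 1:2] <- 1L
  m <- match_objects(inst, inst)
  om <- object_metrics(m, n_gt = 1, n_pred = 1)
  expect_equal(om$acc_o, 1); expect_equal(om$recall_o, 1)
  expect_equal(om$fnr_o, 0)
  # synthetic matching record: 8 gt, 10 pred, 6 matched
  fake <- structure(list(pairs = data.frame(gt = 1:6, pred = 1:6,
                                            dsc = rep(0.9, 6)),
                         unmatched_gt = 7:8, unmatched_pred = 7:10,
                         dsc_threshold = 0.7), class = "object_matching")
  om2 <- object_metrics(fake, n_gt = 8, n_pred = 10)
  expect_equal(om2$recall_o, 0.75)
  expect_equal(om2$acc_o, 6 / 12)
  expect_equal(om2$recall_o + om2$fnr_o, 1)
  empty <- match_objects(matrix(0L, 2, 2), matrix(0L, 2, 2))
  expect_true(is.na(object_metrics(empty, 0, 0)$recall_o))
})

test_that("evaluate_pair is perfect on identical maps and bounded on random", {
  inst <- matrix(0L, 8, 8); inst[2:4, 2:4] <- 1L; inst[6:8, 6:8] <- 2L
  r <- evaluate_pair(inst, inst)
  for (k in c("acc_o", "recall_o", "acc_p", "recall_p", "dice", "f1", "tpr_p")) {
    expect_equal(r[[k]], 1)
  }
  expect_equal(r$fpr_p, 0); expect_equal(r$fnr_o, 0)
  set.seed(24)
  for (rep in 1:10) {
    a <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
    b <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
    r <- suppressMessages(evaluate_pair(a, b))
    for (k in names(r)) {
      if (!is.na(r[[k]])) {
        expect_gte(r[[k]], 0); expect_lte(r[[k]], 1)
      }
    }
  }
})

test_that("evaluate_dataset aggregates per-image metrics and errors clearly", {
  gt_dir <- withr::local_tempdir()
  pred_dir <- withr::local_tempdir()
  man <- generate_dataset(2, tiny_scene_params(seed = 31), gt_dir)
  for (f in man$mask) file.copy(file.path(gt_dir, f), file.path(pred_dir, f))
  rep <- evaluate_dataset(pred_dir, gt_dir,
                          csv_path = file.path(pred_dir, "metrics.csv"))
  expect_equal(nrow(rep$per_image), 2)
  expect_equal(unname(rep$mean["dice"]),
               mean(rep$per_image$dice))
  expect_equal(unname(rep$mean["dice"]), 1)
  expect_true(file.exists(file.path(pred_dir, "metrics.csv")))
  file.remove(file.path(pred_dir, man$mask[2]))
  expect_error(evaluate_dataset(pred_dir, gt_dir), "missing prediction")
})
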