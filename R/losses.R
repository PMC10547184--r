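# Composite training objective: Dice, BCE, focal Tversky and combo losses,
# and the two decoder-head combinations (focal Tversky + w_seg*(Dice+BCE) for
# segmentation, focal Tversky + w_bou*combo for boundaries).
#
# Every loss is written once as a differentiable graph over autodiff nodes;
# the exported numeric functions evaluate that same graph on constant nodes,
# so the training loop and the public API cannot drift apart. Within an image
# sums run over pixels; across a batch losses are averaged, which keeps the
# composite weights comparable across crop sizes.

BCE_EPS <- 1e-7

to4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("prediction/target must be a matrix or array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d[1], d[2], 1L, d[3])
  else if (length(d) != 4L) stop("expected 2-, 3- or 4-d input")
  x
}

check_same_shape <- function(pred, target) {
  if (!identical(dim2(pred), dim2(target))) {
    stop("prediction shape (", paste(dim2(pred), collapse = "x"),
         ") does not match target shape (",
         paste(dim2(target), collapse = "x"), ")")
  }
}

# --- per-image (vector over batch) graph builders ---------------------------

dice_vec_graph <- function(p, t, E, tape) {
  num <- ag_add(ag_mul(ag_sum_spatial(ag_mul(p, t, tape), tape), 2, tape),
                E, tape)
  den <- ag_add(ag_add(ag_sum_spatial(p, tape), ag_sum_spatial(t, tape), tape),
                E, tape)
  ag_sub(1, ag_div(num, den, tape), tape)
}

bce_vec_graph <- function(p, t, tape) {
  pc <- ag_clamp(p, BCE_EPS, 1 - BCE_EPS, tape)
  ll <- ag_add(ag_mul(t, ag_log(pc, tape), tape),
               ag_mul(ag_sub(1, t, tape),
                      ag_log(ag_sub(1, pc, tape), tape), tape), tape)
  npix <- prod(dim(ag_value(p))[1:3])
  ag_mul(ag_sum_spatial(ll, tape), -1 / npix, tape)
}

ft_vec_graph <- function(p, t, alpha, beta, gamma, E, tape) {
  tp <- ag_sum_spatial(ag_mul(p, t, tape), tape)
  fp <- ag_sum_spatial(ag_mul(p, ag_sub(1, t, tape), tape), tape)
  fn <- ag_sum_spatial(ag_mul(t, ag_sub(1, p, tape), tape), tape)
  ti <- ag_div(ag_add(tp, E, tape),
               ag_add(ag_add(tp, ag_mul(fp, alpha, tape), tape),
                      ag_add(ag_mul(fn, beta, tape), E, tape), tape), tape)
  # floor keeps the focal exponent's gradient finite as TI -> 1
  ag_pow(ag_clamp(ag_sub(1, ti, tape), 1e-12, 1, tape), 1 / gamma, tape)
}

combo_vec_graph <- function(p, t, alpha, beta, E, tape) {
  pc <- ag_clamp(p, BCE_EPS, 1 - BCE_EPS, tape)
  wll <- ag_add(ag_mul(ag_mul(t, ag_log(pc, tape), tape), beta, tape),
                ag_mul(ag_mul(ag_sub(1, t, tape),
                              ag_log(ag_sub(1, pc, tape), tape), tape),
                       1 - beta, tape), tape)
  npix <- prod(dim(ag_value(p))[1:3])
  cew <- ag_mul(ag_sum_spatial(wll, tape), -1 / npix, tape)
  dsc <- ag_sub(1, dice_vec_graph(p, t, E, tape), tape)
  ag_sub(ag_mul(cew, alpha, tape), ag_mul(dsc, 1 - alpha, tape), tape)
}

seg_head_vec_graph <- function(p, t, cfg, tape) {
  ft <- ft_vec_graph(p, t, cfg$alpha_ft, cfg$beta_ft, cfg$gamma_ft, cfg$E, tape)
  dc <- dice_vec_graph(p, t, cfg$E, tape)
  bc <- bce_vec_graph(p, t, tape)
  ag_add(ft, ag_mul(ag_add(dc, bc, tape), cfg$w_seg, tape), tape)
}

bou_head_vec_graph <- function(p, t, cfg, tape) {
  ft <- ft_vec_graph(p, t, cfg$alpha_ft, cfg$beta_ft, cfg$gamma_ft, cfg$E, tape)
  cb <- combo_vec_graph(p, t, cfg$alpha_combo, cfg$beta_combo, cfg$E, tape)
  ag_add(ft, ag_mul(cb, cfg$w_bou, tape), tape)
}

eval_loss_graph <- function(pred, target, builder) {
  check_same_shape(pred, target)
  p <- ag_const(to4d(pred))
  t <- ag_const(to4d(target))
  v <- builder(p, t)
  mean(ag_value(v))
}

# --- exported numeric losses ------------------------------------------------

#' Dice loss
#'
#' `1 - (2 * sum(p*t) + E) / (sum(p) + sum(t) + E)`; batched inputs are
#' reduced per image then averaged.
#'
#' @param pred probability map in `[0,1]` (matrix, or array with batch as the
#'   last dimension)
#' @param target binary map of the same shape
#' @param E smoothness constant
#' @return scalar loss in `[0, 1]` (up to E-slack)
#' @export
dice_loss <- function(pred, target, E = 1e-3) {
  eval_loss_graph(pred, target,
                  function(p, t) dice_vec_graph(p, t, E, NULL))
}

#' Binary cross-entropy loss
#'
#' `-(1/P) * sum(t*log(p) + (1-t)*log(1-p))` with predictions clipped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @inheritParams dice_loss
#' @return scalar loss, >= 0
#' @export
bce_loss <- function(pred, target) {
  eval_loss_graph(pred, target, function(p, t) bce_vec_graph(p, t, NULL))
}

#' Focal Tversky loss
#'
#' Tversky index `TI = (TP + E) / (TP + alpha*FP + beta*FN + E)` raised to a
#' focal exponent: `loss = (1 - TI)^(1/gamma_ft)`. `alpha_ft` weights false
#' positives, `beta_ft` false negatives; with `alpha = beta = 0.5` and
#' `gamma = 1` the loss reduces exactly to the Dice loss.
#'
#' @inheritParams dice_loss
#' @param alpha_ft false-positive weight
#' @param beta_ft false-negative weight
#' @param gamma_ft focal exponent
#' @return scalar loss in `[0, 1]`
#' @export
focal_tversky_loss <- function(pred, target, alpha_ft = 0.3, beta_ft = 0.7,
                               gamma_ft = 4 / 3, E = 1e-3) {
  eval_loss_graph(pred, target, function(p, t)
    ft_vec_graph(p, t, alpha_ft, beta_ft, gamma_ft, E, NULL))
}

#' Combo loss
#'
#' `alpha_combo * CE_w - (1 - alpha_combo) * DSC` where `CE_w` is the
#' class-weighted cross-entropy (`beta_combo` on the foreground term) and
#' DSC the smoothed Dice score. Bounded below by `-(1 - alpha_combo)`.
#'
#' @inheritParams dice_loss
#' @param alpha_combo weight between the CE and Dice terms
#' @param beta_combo foreground class weight inside the CE term
#' @return scalar loss, >= `-(1 - alpha_combo)`
#' @export
combo_loss <- function(pred, target, alpha_combo = 0.5, beta_combo = 0.5,
                       E = 1e-3) {
  eval_loss_graph(pred, target, function(p, t)
    combo_vec_graph(p, t, alpha_combo, beta_combo, E, NULL))
}

#' Segmentation-head loss
#'
#' `focal_tversky + w_seg * (dice_loss + bce_loss)`, the best-performing
#' composite of the loss ablation with `w_seg = 0.4`.
#'
#' @inheritParams dice_loss
#' @param cfg a [loss_config()]
#' @return scalar loss
#' @export
seg_head_loss <- function(pred, target, cfg = loss_config()) {
  eval_loss_graph(pred, target,
                  function(p, t) seg_head_vec_graph(p, t, cfg, NULL))
}

#' Boundary-head loss
#'
#' `focal_tversky + w_bou * combo_loss` with `w_bou = 0.4` by default.
#'
#' @inheritParams seg_head_loss
#' @return scalar loss
#' @export
boundary_head_loss <- function(pred, target, cfg = loss_config()) {
  eval_loss_graph(pred, target,
                  function(p, t) bou_head_vec_graph(p, t, cfg, NULL))
}

#' Total dual-head loss with component breakdown
#'
#' `seg_head_loss + head_balance * boundary_head_loss`. The returned
#' breakdown carries each component averaged over the batch, and satisfies
#' `total == seg + head_balance * boundary` to numerical precision.
#'
#' @param outputs list with `seg_prob` and `boundary_prob` maps
#' @param targets list with `mask` and `boundary` binary maps of matching shape
#' @param cfg a [loss_config()]
#' @return list with `total` and `components` (named scalars)
#' @export
total_loss <- function(outputs, targets, cfg = loss_config()) {
  seg <- seg_head_loss(outputs$seg_prob, targets$mask, cfg)
  bou <- boundary_head_loss(outputs$boundary_prob, targets$boundary, cfg)
  list(total = seg + cfg$head_balance * bou,
       components = list(
         seg_head = seg,
         boundary_head = bou,
         seg_focal_tversky = focal_tversky_loss(
           outputs$seg_prob, targets$mask,
           cfg$alpha_ft, cfg$beta_ft, cfg$gamma_ft, cfg$E),
         seg_dice = dice_loss(outputs$seg_prob, targets$mask, cfg$E),
         seg_bce = bce_loss(outputs$seg_prob, targets$mask),
         bou_focal_tversky = focal_tversky_loss(
           outputs$boundary_prob, targets$boundary,
           cfg$alpha_ft, cfg$beta_ft, cfg$gamma_ft, cfg$E),
         bou_combo = combo_loss(outputs$boundary_prob, targets$boundary,
                                cfg$alpha_combo, cfg$beta_combo, cfg$E)))
}

# training-time loss over ag nodes: returns scalar node
total_loss_graph <- function(seg_node, bou_node, mask, boundary, cfg, tape) {
  seg <- ag_mean_vec(seg_head_vec_graph(seg_node, ag_const(to4d(mask)),
                                        cfg, tape), tape)
  bou <- ag_mean_vec(bou_head_vec_graph(bou_node, ag_const(to4d(boundary)),
                                        cfg, tape), tape)
  ag_add(seg, ag_mul(bou, cfg$head_balance, tape), tape)
}
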