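# H&E sparse stain separation and structure-preserving normalization.
#
# An RGB image is mapped to optical density OD = -log((I255 + 1) / 255)
# (Beer-Lambert), background pixels (OD norm below a floor) are excluded,
# and the stained pixels are factorized OD ~ C %*% B with C >= 0 the
# per-pixel stain densities (n x 2) and B >= 0 the 2 x 3 stain color basis
# with unit rows.
#
# The fit is a debiased sparse separation. Hematoxylin and eosin OD vectors
# are strongly collinear (~37 degrees apart), and an L1 penalty coupled into
# the basis alternation collapses mixed (nucleus) pixels onto single-stain
# supports, rotating the recovered hematoxylin vector by ~10 degrees toward
# the nucleus mixture color regardless of the penalty magnitude. The basis
# is therefore estimated by the unpenalized alternation (closed-form
# two-stain NNLS coding + multiplicative basis update with per-iteration row
# normalization), while the L1 penalty applies where sparsity belongs: to
# the density-map coding that feeds the robust density maxima.

rgb_to_od <- function(image) {
  i255 <- pmin(pmax(image, 0), 1) * 255
  od <- -log((i255 + 1) / 255)
  dim(od) <- c(prod(dim(image)[1:2]), 3L)
  od
}

od_to_rgb <- function(od, h, w) {
  i01 <- exp(-od) - 1 / 255
  array(pmin(pmax(i01, 0), 1), c(h, w, 3L))
}

# hematoxylin transmits blue (absorbs red), so its OD vector has the larger
# red-minus-blue component; order rows hematoxylin first
order_hematoxylin_first <- function(basis) {
  score <- basis[, 1] - basis[, 3]
  basis[order(score, decreasing = TRUE), , drop = FALSE]
}

# closed-form two-stain non-negative lasso coding of OD rows against basis B:
# per pixel, argmin 0.5 ||od - c B||^2 + lambda ||c||_1 subject to c >= 0
nnls2_code <- function(V, B, lambda = 0) {
  g11 <- sum(B[1, ]^2); g22 <- sum(B[2, ]^2); g12 <- sum(B[1, ] * B[2, ])
  b1 <- V %*% B[1, ] - lambda
  b2 <- V %*% B[2, ] - lambda
  det <- g11 * g22 - g12^2
  c1 <- (g22 * b1 - g12 * b2) / det
  c2 <- (g11 * b2 - g12 * b1) / det
  neg1 <- c1 < 0; neg2 <- c2 < 0
  c1[neg1] <- 0
  c2[neg1] <- pmax(b2[neg1] / g22, 0)
  c2[neg2 & !neg1] <- 0
  c1[neg2 & !neg1] <- pmax(b1[neg2 & !neg1] / g11, 0)
  cbind(c1, c2)
}

#' Fit a two-stain separation model
#'
#' Estimates the hematoxylin/eosin optical-density color basis of an image
#' by alternating non-negative factorization of its OD matrix (closed-form
#' NNLS coding, multiplicative basis updates, unit-row normalization each
#' iteration), initialized from the published H&E reference basis.
#' The L1 `sparsity` weight is applied to the density-map coding from which
#' the robust per-stain maxima (99th percentile) are taken; see the module
#' notes for why it is kept out of the basis alternation. The procedure
#' draws no random numbers, so repeated fits are identical.
#'
#' @param image RGB array H x W x 3 in `[0,1]`
#' @param sparsity L1 penalty weight on the density maps
#' @param od_floor optical-density norm below which a pixel counts as
#'   unstained background and is excluded from fitting
#' @param max_iter alternating-update iterations
#' @param max_pixels stained-pixel budget; larger images are subsampled on a
#'   deterministic stride
#' @return a `stain_model` with `basis` (2 x 3, unit rows, hematoxylin
#'   first), `max_densities` (length 2) and the `sparsity` used
#' @export
fit_stain_model <- function(image, sparsity = 0.1, od_floor = 0.15,
                            max_iter = 200L, max_pixels = 20000L) {
  od <- rgb_to_od(image)
  norms <- sqrt(rowSums(od^2))
  fg <- norms > od_floor
  if (mean(fg) < 0.01) {
    stop("no stained tissue: fewer than 1% of pixels exceed the OD floor")
  }
  V <- od[fg, , drop = FALSE]
  if (nrow(V) > max_pixels) {
    stride <- ceiling(nrow(V) / max_pixels)
    V <- V[seq(1, nrow(V), by = stride), , drop = FALSE]
  }
  B <- he_reference_basis()
  eps <- 1e-10
  for (it in seq_len(max_iter)) {
    C <- pmax(nnls2_code(V, B), eps)
    B <- B * (t(C) %*% V) / ((t(C) %*% C) %*% B + eps)
    B <- pmax(B, eps)
    B <- B / sqrt(rowSums(B^2))
  }
  B <- order_hematoxylin_first(B)
  dimnames(B) <- NULL
  # robust density maxima from the sparse codes of all stained pixels
  Csp <- nnls2_code(od[fg, , drop = FALSE], B, lambda = sparsity)
  md <- pmax(apply(Csp, 2, stats::quantile, probs = 0.99, names = FALSE),
             1e-6)
  structure(list(basis = B, max_densities = md, sparsity = sparsity),
            class = "stain_model")
}

#' Per-pixel stain densities under a fixed basis
#'
#' Closed-form two-variable non-negative least squares projection of each
#' pixel's OD vector onto the basis rows, optionally soft-thresholded by an
#' L1 penalty (`sparsity > 0`).
#'
#' @param image RGB array H x W x 3
#' @param model a `stain_model` (only `basis` is used)
#' @param sparsity L1 penalty on the codes; 0 gives the exact projection
#'   used for reconstruction and normalization
#' @return array H x W x 2 of hematoxylin/eosin densities
#' @export
stain_densities <- function(image, model, sparsity = 0) {
  d <- dim(image)
  C <- nnls2_code(rgb_to_od(image), model$basis, lambda = sparsity)
  array(C, c(d[1], d[2], 2L))
}

#' Reconstruct an RGB image from stain densities
#'
#' @param densities H x W x 2 array as from [stain_densities()]
#' @param model a `stain_model`
#' @return RGB array H x W x 3 in `[0,1]`
#' @export
stain_reconstruct <- function(densities, model) {
  d <- dim(densities)
  C <- matrix(densities, ncol = 2)
  od_to_rgb(C %*% model$basis, d[1], d[2])
}

#' Structure-preserving stain normalization
#'
#' Separates the source image into densities under its own model, rescales
#' each stain by the ratio of target to source robust maxima, and recombines
#' with the target basis. Only color changes; unstained (white) pixels have
#' near-zero densities and stay white.
#'
#' @param source RGB array H x W x 3
#' @param source_model `stain_model` fitted to the source (fitted on the fly
#'   when NULL)
#' @param target_model `stain_model` of the color reference
#' @return recolored RGB array in `[0,1]`
#' @export
normalize_stains <- function(source, source_model, target_model) {
  if (is.null(source_model)) source_model <- fit_stain_model(source)
  stopifnot(inherits(source_model, "stain_model"),
            inherits(target_model, "stain_model"))
  dens <- stain_densities(source, source_model)
  for (s in 1:2) {
    dens[, , s] <- dens[, , s] *
      (target_model$max_densities[s] / source_model$max_densities[s])
  }
  stain_reconstruct(dens, target_model)
}

# angle in degrees between two stain vectors
stain_angle <- function(u, v) {
  acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) * 180 / pi
}
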