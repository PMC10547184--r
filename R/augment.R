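# Data augmentation: geometric transforms applied identically to the image
# and both supervision targets (nearest-neighbor for masks, bilinear for the
# image), photometric transforms applied to the image only. Every transform
# draws from a seeded RNG, so augmentation is a pure function of
# (inputs, policy, seed).

#' Augmentation policy
#'
#' Each entry is a list with a probability `p` and transform-specific
#' magnitude ranges. Geometric transforms move the image and the masks
#' together; photometric transforms leave the masks untouched.
#'
#' @param geometric named list over `horizontal_flip`, `vertical_flip`,
#'   `resize_rescale`, `translation`, `elastic_deformation`
#' @param photometric named list over `gaussian_blur`, `gaussian_noise`,
#'   `additive_gaussian_noise`, `hue_shift`, `saturation_shift`,
#'   `contrast_shift`
#' @param seed integer RNG seed
#' @return an `augmentation_policy` list
#' @export
augmentation_policy <- function(
    geometric = list(
      horizontal_flip = list(p = 0.5),
      vertical_flip = list(p = 0.5),
      resize_rescale = list(p = 0.25, scale_range = c(0.85, 1.18)),
      translation = list(p = 0.25, max_shift = c(20L, 20L)),
      elastic_deformation = list(p = 0.2, alpha = 12, sigma = 8)),
    photometric = list(
      gaussian_blur = list(p = 0.25, sigma_range = c(0.5, 1.5)),
      gaussian_noise = list(p = 0.2, sigma_range = c(0.005, 0.02)),
      additive_gaussian_noise = list(p = 0.2, sigma_range = c(0.005, 0.02)),
      hue_shift = list(p = 0.2, max_shift = 0.05),
      saturation_shift = list(p = 0.2, factor_range = c(0.8, 1.2)),
      contrast_shift = list(p = 0.2, factor_range = c(0.8, 1.2))),
    seed = 1L) {
  for (g in c(geometric, photometric)) {
    if (!is.null(g$p) && (g$p < 0 || g$p > 1)) {
      stop("transform probabilities must lie in [0, 1]")
    }
  }
  structure(list(geometric = geometric, photometric = photometric,
                 seed = as.integer(seed)),
            class = "augmentation_policy")
}

resize_nn_mask <- function(mask, oh, ow) {
  H <- nrow(mask); W <- ncol(mask)
  # pixel k covers (k-1, k]: the source pixel containing sample point p is
  # ceiling(p), not round(p) (centers sit at half-integers)
  ri <- pmin(pmax(ceiling((seq_len(oh) - 0.5) * H / oh), 1L), H)
  ci <- pmin(pmax(ceiling((seq_len(ow) - 0.5) * W / ow), 1L), W)
  mask[ri, ci, drop = FALSE]
}

resize_bilinear_rgb <- function(img, oh, ow) {
  x <- img
  dim(x) <- c(dim(img)[1:2], dim(img)[3], 1L)
  y <- .cpp_resize_bilinear_forward(x, as.integer(oh), as.integer(ow))
  dim(y) <- c(oh, ow, dim(img)[3])
  y
}

shift_matrix <- function(m, dy, dx, fill) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  sr <- max(1, 1 - dy):min(H, H - dy)
  sc <- max(1, 1 - dx):min(W, W - dx)
  if (length(sr) > 0 && length(sc) > 0) out[sr + dy, sc + dx] <- m[sr, sc]
  out
}

crop_or_pad <- function(m, H, W, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, H, W)
  r0 <- max(0L, (h - H) %/% 2L); c0 <- max(0L, (w - W) %/% 2L)
  ro <- max(0L, (H - h) %/% 2L); co <- max(0L, (W - w) %/% 2L)
  nh <- min(h, H); nw <- min(w, W)
  out[ro + seq_len(nh), co + seq_len(nw)] <- m[r0 + seq_len(nh), c0 + seq_len(nw)]
  out
}

# bilinear sample of a matrix at fractional coordinates (vectors sy, sx)
bilinear_sample <- function(m, sy, sx) {
  H <- nrow(m); W <- ncol(m)
  sy <- pmin(pmax(sy, 1), H); sx <- pmin(pmax(sx, 1), W)
  y0 <- floor(sy); x0 <- floor(sx)
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  ty <- sy - y0; tx <- sx - x0
  m[cbind(y0, x0)] * (1 - ty) * (1 - tx) + m[cbind(y1, x0)] * ty * (1 - tx) +
    m[cbind(y0, x1)] * (1 - ty) * tx + m[cbind(y1, x1)] * ty * tx
}

hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

apply_hsv <- function(img, hue_delta = 0, sat_factor = 1) {
  d <- dim(img)
  m <- matrix(img, ncol = 3)
  hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 1)
  h <- (hsv[1, ] + hue_delta) %% 1
  s <- pmin(pmax(hsv[2, ] * sat_factor, 0), 1)
  out <- hsv_to_rgb(h, s, hsv[3, ])
  array(out, d)
}

#' Augment an image together with its segmentation/boundary targets
#'
#' Geometric transforms (flips, resize-rescale, translation, elastic
#' deformation) are applied identically to the image and both targets with
#' nearest-neighbor mask interpolation; photometric transforms (blur, two
#' noise models, hue/saturation/contrast) touch the image only. An elastic
#' field strong enough to fold the sampling grid is rescaled, with a
#' warning.
#'
#' @param image RGB array H x W x 3
#' @param targets list with `mask` and `boundary` logical matrices
#' @param policy an [augmentation_policy()]
#' @return list(image, targets) of the same shapes
#' @export
augment_pair <- function(image, targets, policy) {
  stopifnot(inherits(policy, "augmentation_policy"))
  d <- dim(image)
  if (!identical(dim(targets$mask), d[1:2]) ||
      !identical(dim(targets$boundary), d[1:2])) {
    stop("image and targets must share height and width")
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(policy$seed)
  H <- d[1]; W <- d[2]
  img <- image
  mk <- targets$mask > 0
  bd <- targets$boundary > 0
  geo <- policy$geometric
  on_masks <- function(f) { mk <<- f(mk); bd <<- f(bd) }

  if (!is.null(geo$horizontal_flip) &&
      stats::runif(1) < geo$horizontal_flip$p) {
    img <- img[, W:1, , drop = FALSE]
    on_masks(function(m) m[, W:1, drop = FALSE])
  }
  if (!is.null(geo$vertical_flip) && stats::runif(1) < geo$vertical_flip$p) {
    img <- img[H:1, , , drop = FALSE]
    on_masks(function(m) m[H:1, , drop = FALSE])
  }
  if (!is.null(geo$resize_rescale) &&
      stats::runif(1) < geo$resize_rescale$p) {
    s <- stats::runif(1, geo$resize_rescale$scale_range[1],
                      geo$resize_rescale$scale_range[2])
    oh <- max(8L, round(H * s)); ow <- max(8L, round(W * s))
    img <- resize_bilinear_rgb(img, oh, ow)
    img <- array(vapply(1:3, function(ch)
      crop_or_pad(img[, , ch], H, W, fill = 1), matrix(0, H, W)), c(H, W, 3))
    on_masks(function(m) crop_or_pad(resize_nn_mask(m, oh, ow), H, W, FALSE))
  }
  if (!is.null(geo$translation) && stats::runif(1) < geo$translation$p) {
    ms <- geo$translation$max_shift
    dy <- sample(-ms[1]:ms[1], 1); dx <- sample(-ms[2]:ms[2], 1)
    img <- array(vapply(1:3, function(ch)
      shift_matrix(img[, , ch], dy, dx, fill = 1), matrix(0, H, W)),
      c(H, W, 3))
    on_masks(function(m) shift_matrix(m, dy, dx, FALSE))
  }
  if (!is.null(geo$elastic_deformation) &&
      stats::runif(1) < geo$elastic_deformation$p) {
    el <- geo$elastic_deformation
    dyf <- EBImage::gblur(matrix(stats::rnorm(H * W), H, W), el$sigma)
    dxf <- EBImage::gblur(matrix(stats::rnorm(H * W), H, W), el$sigma)
    dyf <- dyf / max(abs(dyf)) * el$alpha
    dxf <- dxf / max(abs(dxf)) * el$alpha
    # forbid grid folding: the displacement gradient must stay below 1
    gmax <- max(abs(diff(dyf)), abs(t(diff(t(dxf)))))
    if (gmax >= 0.9) {
      warning("elastic deformation magnitude clipped to avoid grid folding")
      dyf <- dyf * (0.9 / gmax); dxf <- dxf * (0.9 / gmax)
    }
    yy <- matrix(seq_len(H), H, W) + dyf
    xx <- matrix(seq_len(W), H, W, byrow = TRUE) + dxf
    img <- array(vapply(1:3, function(ch)
      matrix(bilinear_sample(img[, , ch], as.vector(yy), as.vector(xx)), H, W),
      matrix(0, H, W)), c(H, W, 3))
    ri <- pmin(pmax(round(yy), 1), H); ci <- pmin(pmax(round(xx), 1), W)
    on_masks(function(m) matrix(m[cbind(as.vector(ri), as.vector(ci))], H, W))
  }

  ph <- policy$photometric
  if (!is.null(ph$gaussian_blur) && stats::runif(1) < ph$gaussian_blur$p) {
    s <- stats::runif(1, ph$gaussian_blur$sigma_range[1],
                      ph$gaussian_blur$sigma_range[2])
    for (ch in 1:3) img[, , ch] <- EBImage::gblur(img[, , ch], s)
  }
  if (!is.null(ph$gaussian_noise) && stats::runif(1) < ph$gaussian_noise$p) {
    s <- stats::runif(1, ph$gaussian_noise$sigma_range[1],
                      ph$gaussian_noise$sigma_range[2])
    nz <- matrix(stats::rnorm(H * W, sd = s), H, W)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + nz
  }
  if (!is.null(ph$additive_gaussian_noise) &&
      stats::runif(1) < ph$additive_gaussian_noise$p) {
    s <- stats::runif(1, ph$additive_gaussian_noise$sigma_range[1],
                      ph$additive_gaussian_noise$sigma_range[2])
    img <- img + array(stats::rnorm(length(img), sd = s), dim(img))
  }
  if (!is.null(ph$hue_shift) && stats::runif(1) < ph$hue_shift$p) {
    delta <- stats::runif(1, -ph$hue_shift$max_shift, ph$hue_shift$max_shift)
    img <- apply_hsv(pmin(pmax(img, 0), 1), hue_delta = delta)
  }
  if (!is.null(ph$saturation_shift) &&
      stats::runif(1) < ph$saturation_shift$p) {
    f <- stats::runif(1, ph$saturation_shift$factor_range[1],
                      ph$saturation_shift$factor_range[2])
    img <- apply_hsv(pmin(pmax(img, 0), 1), sat_factor = f)
  }
  if (!is.null(ph$contrast_shift) && stats::runif(1) < ph$contrast_shift$p) {
    f <- stats::runif(1, ph$contrast_shift$factor_range[1],
                      ph$contrast_shift$factor_range[2])
    img <- (img - 0.5) * f + 0.5
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, targets = list(mask = mk, boundary = bd))
}
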