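# Synthetic cytology scenes: elliptical, partially overlapping,
# hematoxylin-dark nuclei inside eosin-tinted cytoplasm halos on a white
# slide background, with blur, additive noise, impurity blobs and
# border-truncated nuclei — plus exact instance-level ground truth, so the
# whole segmentation pipeline is testable without any real dataset.

#' Reference H&E optical-density stain basis
#'
#' Rows are the hematoxylin and eosin optical-density color vectors
#' (unit-normalized); the standard published H&E reference.
#' @return 2 x 3 matrix, rows hematoxylin then eosin
#' @export
he_reference_basis <- function() {
  b <- rbind(h = c(0.65, 0.70, 0.29),
             e = c(0.07, 0.99, 0.11))
  b / sqrt(rowSums(b^2))
}

#' Parameters of a synthetic cytology scene
#'
#' Defaults emulate a 1024 x 768 liquid-based-cytology field at roughly
#' 0.32 um/pixel: 5-60 nuclei with semi-axes 10-26 px, moderate
#' eccentricity, a small fraction of overlapping pairs, occasional nuclei
#' truncated by the image border, impurity blobs that are rendered but not
#' annotated, mild defocus blur and sensor noise.
#'
#' @param image_height,image_width scene size in pixels (>= 64)
#' @param n_nuclei_range integer interval for the nucleus count
#' @param nucleus_radius_range interval for the major semi-axis in pixels
#' @param eccentricity_range interval in `[0, 1)`
#' @param overlap_fraction target fraction of nuclei allowed to intersect
#'   another nucleus
#' @param border_truncation_prob probability that a nucleus is placed so the
#'   border clips it
#' @param impurity_count_range integer interval for unannotated debris blobs
#' @param blur_sigma_range Gaussian blur sigma interval (pixels)
#' @param noise_sigma_range additive Gaussian noise sd interval (intensity)
#' @param stain_basis 2 x 3 optical-density basis (hematoxylin, eosin rows)
#' @param seed integer seed; scenes are pure functions of (params, seed)
#' @return a `scene_params` list
#' @export
scene_params <- function(image_height = 768L, image_width = 1024L,
                         n_nuclei_range = c(5L, 60L),
                         nucleus_radius_range = c(10, 26),
                         eccentricity_range = c(0, 0.7),
                         overlap_fraction = 0.15,
                         border_truncation_prob = 0.1,
                         impurity_count_range = c(0L, 10L),
                         blur_sigma_range = c(0.5, 1.5),
                         noise_sigma_range = c(0.005, 0.02),
                         stain_basis = he_reference_basis(),
                         seed = 1L) {
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  stopifnot(rng_ok(n_nuclei_range), rng_ok(nucleus_radius_range),
            rng_ok(eccentricity_range), rng_ok(impurity_count_range),
            rng_ok(blur_sigma_range), rng_ok(noise_sigma_range),
            nucleus_radius_range[1] >= 1,
            eccentricity_range[1] >= 0, eccentricity_range[2] < 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            border_truncation_prob >= 0, border_truncation_prob <= 1,
            is.matrix(stain_basis), all(dim(stain_basis) == c(2, 3)))
  if (image_height < 64 || image_width < 64) {
    stop("image dimensions must be at least 64 pixels, got ",
         image_height, " x ", image_width)
  }
  if (nucleus_radius_range[2] > min(image_height, image_width) / 2) {
    stop("nucleus_radius_range upper bound ", nucleus_radius_range[2],
         " exceeds min(H, W)/2 = ", min(image_height, image_width) / 2)
  }
  if (any(sqrt(rowSums(stain_basis^2)) <= 0)) {
    stop("stain_basis rows must have strictly positive norm")
  }
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_nuclei_range = as.integer(n_nuclei_range),
                 nucleus_radius_range = nucleus_radius_range,
                 eccentricity_range = eccentricity_range,
                 overlap_fraction = overlap_fraction,
                 border_truncation_prob = border_truncation_prob,
                 impurity_count_range = as.integer(impurity_count_range),
                 blur_sigma_range = blur_sigma_range,
                 noise_sigma_range = noise_sigma_range,
                 stain_basis = stain_basis,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# TRUE/FALSE mask of a rotated ellipse, restricted to its bounding box;
# returns list(rows, cols, inside-matrix) or NULL if fully outside.
ellipse_patch <- function(H, W, cy, cx, a, b, theta) {
  r <- max(a, b)
  r0 <- max(1L, floor(cy - r)); r1 <- min(H, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(W, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(NULL)
  ys <- r0:r1; xs <- c0:c1
  dy <- matrix(ys - cy, length(ys), length(xs))
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(NULL)
  list(rows = ys, cols = xs, inside = inside)
}

#' Generate one labeled synthetic cytology scene
#'
#' Places rotated ellipses with controlled pairwise overlap and optional
#' border truncation, renders hematoxylin/eosin density fields, converts
#' them to RGB by Beer-Lambert attenuation through the stain basis, then
#' applies Gaussian blur, additive noise and unannotated impurity blobs.
#' Overlapping nuclei keep distinct instance labels with later-placed
#' nuclei on top; the semantic mask is their union.
#'
#' @param params a [scene_params()] object
#' @return a `labeled_scene` list with `image` (H x W x 3 in `[0,1]`),
#'   `instance_map` (integer, 0 = background), `semantic_mask` and
#'   `boundary_map` (logical matrices), and `params`
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(params$seed)

  H <- params$image_height; W <- params$image_width
  n <- if (params$n_nuclei_range[1] == params$n_nuclei_range[2]) {
    params$n_nuclei_range[1]
  } else {
    sample(params$n_nuclei_range[1]:params$n_nuclei_range[2], 1)
  }

  nuclei <- list()
  overlap_budget <- round(params$overlap_fraction * n)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in 1:50) {
      a <- stats::runif(1, params$nucleus_radius_range[1],
                        params$nucleus_radius_range[2])
      ecc <- stats::runif(1, params$eccentricity_range[1],
                          params$eccentricity_range[2])
      b <- a * sqrt(1 - ecc^2)
      theta <- stats::runif(1, 0, pi)
      r <- max(a, b)
      if (stats::runif(1) < params$border_truncation_prob) {
        side <- sample(4, 1)
        cy <- switch(side, stats::runif(1, -r / 2, r / 2),
                     stats::runif(1, H - r / 2, H + r / 2),
                     stats::runif(1, r + 1, H - r),
                     stats::runif(1, r + 1, H - r))
        cx <- switch(side, stats::runif(1, r + 1, W - r),
                     stats::runif(1, r + 1, W - r),
                     stats::runif(1, -r / 2, r / 2),
                     stats::runif(1, W - r / 2, W + r / 2))
      } else {
        cy <- stats::runif(1, r + 1, H - r)
        cx <- stats::runif(1, r + 1, W - r)
      }
      hits <- 0L
      for (q in nuclei) {
        if ((cy - q$cy)^2 + (cx - q$cx)^2 < (r + q$r)^2) hits <- hits + 1L
      }
      if (hits == 0L || hits <= overlap_budget || try == 50L) {
        if (hits > 0L) overlap_budget <- overlap_budget - hits
        nuclei[[k]] <- list(cy = cy, cx = cx, a = a, b = b,
                            theta = theta, r = r,
                            h_density = stats::runif(1, 0.7, 1.1),
                            e_density = stats::runif(1, 0.25, 0.45))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("internal: nucleus placement failed")
  }

  instance <- matrix(0L, H, W)
  h_map <- matrix(0, H, W)
  e_map <- matrix(0, H, W)
  halo_scale <- 2.2
  for (k in seq_along(nuclei)) {
    q <- nuclei[[k]]
    halo <- ellipse_patch(H, W, q$cy, q$cx, q$a * halo_scale,
                          q$b * halo_scale, q$theta)
    if (!is.null(halo)) {
      e_sub <- e_map[halo$rows, halo$cols]
      e_map[halo$rows, halo$cols] <- pmax(e_sub, q$e_density * halo$inside)
    }
  }
  for (k in seq_along(nuclei)) {
    q <- nuclei[[k]]
    p <- ellipse_patch(H, W, q$cy, q$cx, q$a, q$b, q$theta)
    if (is.null(p)) next
    sub <- instance[p$rows, p$cols]
    sub[p$inside] <- k   # later-placed on top
    instance[p$rows, p$cols] <- sub
    h_sub <- h_map[p$rows, p$cols]
    h_map[p$rows, p$cols] <- pmax(h_sub, q$h_density * p$inside)
  }
  # drop instances fully covered by later nuclei, keep labels compact
  present <- sort(unique(instance[instance > 0L]))
  if (length(present) && !identical(present, seq_along(present))) {
    relabel <- integer(max(present))
    relabel[present] <- seq_along(present)
    pos <- instance > 0L
    instance[pos] <- relabel[instance[pos]]
  }

  n_imp <- if (params$impurity_count_range[1] == params$impurity_count_range[2]) {
    params$impurity_count_range[1]
  } else {
    sample(params$impurity_count_range[1]:params$impurity_count_range[2], 1)
  }
  for (k in seq_len(n_imp)) {
    a <- stats::runif(1, 2, 8); b <- a * stats::runif(1, 0.5, 1)
    p <- ellipse_patch(H, W, stats::runif(1, 1, H), stats::runif(1, 1, W),
                       a, b, stats::runif(1, 0, pi))
    if (is.null(p)) next
    hd <- stats::runif(1, 0.15, 0.4); ed <- stats::runif(1, 0.1, 0.3)
    h_map[p$rows, p$cols] <- pmax(h_map[p$rows, p$cols], hd * p$inside)
    e_map[p$rows, p$cols] <- pmax(e_map[p$rows, p$cols], ed * p$inside)
  }

  basis <- params$stain_basis
  image <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    image[, , ch] <- exp(-(h_map * basis[1, ch] + e_map * basis[2, ch]))
  }

  blur_sigma <- stats::runif(1, params$blur_sigma_range[1],
                             params$blur_sigma_range[2])
  if (blur_sigma > 0) {
    for (ch in 1:3) image[, , ch] <- EBImage::gblur(image[, , ch], blur_sigma)
  }
  noise_sigma <- stats::runif(1, params$noise_sigma_range[1],
                              params$noise_sigma_range[2])
  if (noise_sigma > 0) {
    image <- image + array(stats::rnorm(length(image), sd = noise_sigma),
                           dim(image))
  }
  image <- pmin(pmax(image, 0), 1)

  structure(list(image = image,
                 instance_map = instance,
                 semantic_mask = instance > 0L,
                 boundary_map = make_boundary_map(instance, thickness = 2L),
                 params = params),
            class = "labeled_scene")
}

#' Write a dataset of synthetic scenes to disk
#'
#' Scene k uses seed `params$seed + k - 1`. For each scene writes
#' `image_k.png`, `instance_k.tiff` (16-bit labels), `mask_k.png` and
#' `boundary_k.png`, plus a `manifest.json` listing the files and seeds.
#'
#' @param n_scenes number of scenes (0 gives an empty manifest, no files)
#' @param params a [scene_params()] template
#' @param out_dir output directory (created if needed)
#' @return manifest as a data.frame (invisibly written to manifest.json)
#' @export
generate_dataset <- function(n_scenes, params, out_dir) {
  stopifnot(n_scenes >= 0, inherits(params, "scene_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n_scenes)
  for (k in seq_len(n_scenes)) {
    pk <- params
    pk$seed <- params$seed + k - 1L
    sc <- generate_scene(pk)
    files <- c(image = sprintf("image_%d.png", k),
               instance = sprintf("instance_%d.tiff", k),
               mask = sprintf("mask_%d.png", k),
               boundary = sprintf("boundary_%d.png", k))
    ok <- try({
      write_image_rgb(sc$image, file.path(out_dir, files["image"]))
      write_instance_tiff(sc$instance_map, file.path(out_dir, files["instance"]))
      write_mask_png(sc$semantic_mask, file.path(out_dir, files["mask"]))
      write_mask_png(sc$boundary_map, file.path(out_dir, files["boundary"]))
    }, silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop("failed writing scene ", k, " under ", out_dir, ": ",
           attr(ok, "condition")$message)
    }
    rows[[k]] <- data.frame(scene = k, seed = pk$seed,
                            image = files[["image"]],
                            instance = files[["instance"]],
                            mask = files[["mask"]],
                            boundary = files[["boundary"]],
                            stringsAsFactors = FALSE)
  }
  manifest <- if (n_scenes > 0) do.call(rbind, rows) else
    data.frame(scene = integer(), seed = integer(), image = character(),
               instance = character(), mask = character(),
               boundary = character(), stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = FALSE)
  attr(manifest, "dir") <- out_dir
  manifest
}

#' Read a dataset manifest written by [generate_dataset()]
#' @param dir dataset directory containing `manifest.json`
#' @return manifest data.frame with a `dir` attribute
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json under ", dir)
  m <- jsonlite::fromJSON(path)
  if (length(m) == 0) {
    m <- data.frame(scene = integer(), seed = integer(), image = character(),
                    instance = character(), mask = character(),
                    boundary = character(), stringsAsFactors = FALSE)
  }
  attr(m, "dir") <- dir
  m
}
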