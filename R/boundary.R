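# Boundary ground truth: closing nucleus contours truncated at image edges
# (so augmentation never sees open curves) and generating the boundary-map
# supervision target for the boundary decoder.

disc_brush <- function(r) EBImage::makeBrush(2L * r + 1L, shape = "disc")

#' Boundary supervision map from an instance label map
#'
#' Morphological gradient (dilation minus erosion with a disc of radius
#' `ceiling(thickness/2)`) of every instance, unioned. Because each
#' instance is processed separately, pixels between two touching instances
#' are always boundary.
#'
#' @param instance_map integer matrix, 0 = background, k = nucleus k
#' @param thickness nominal boundary thickness in pixels (>= 1)
#' @return logical H x W boundary map
#' @export
make_boundary_map <- function(instance_map, thickness = 2L) {
  stopifnot(thickness >= 1)
  r <- as.integer(ceiling(thickness / 2))
  H <- nrow(instance_map); W <- ncol(instance_map)
  out <- matrix(FALSE, H, W)
  labs <- sort(unique(instance_map[instance_map > 0L]))
  if (length(labs) == 0L) return(out)
  brush <- disc_brush(r)
  for (lab in labs) {
    idx <- which(instance_map == lab, arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1]) - r); r1 <- min(H, max(idx[, 1]) + r)
    c0 <- max(1L, min(idx[, 2]) - r); c1 <- min(W, max(idx[, 2]) + r)
    sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- 1
    dil <- EBImage::dilate(sub, brush) > 0.5
    ero <- EBImage::erode(sub, brush) > 0.5
    grad <- dil & !ero
    out[r0:r1, c0:c1] <- out[r0:r1, c0:c1] | grad
  }
  out
}

#' 8-connectivity connected components
#'
#' Deterministic labeling (column-major scan order) used to turn binary
#' predictions into instances before object matching.
#'
#' @param mask logical matrix
#' @return integer matrix of component labels, 0 = background
#' @export
label_components <- function(mask) {
  .cpp_label8(as.matrix(mask) > 0)
}

# perimeter pixel cycle of an H x W frame, clockwise from (1,1):
# returns matrix (row, col) of length 2(H+W) - 4
perimeter_cycle <- function(H, W) {
  rbind(cbind(1L, seq_len(W)),
        if (H > 1L) cbind(2:H, W),
        if (W > 1L) cbind(H, (W - 1L):1L),
        if (H > 2L) cbind((H - 1L):2L, 1L))
}

#' Close contours of foreground components truncated by the image border
#'
#' For every foreground component that touches the border, its border
#' contacts are connected along the shortest border arcs and any region so
#' enclosed is filled, so that extracting contours from the result yields
#' only closed curves. Components not touching the border are returned
#' unchanged; the operation is idempotent.
#'
#' @param mask logical (or 0/1) matrix
#' @return logical matrix with border-truncated components enclosed
#' @export
enclose_boundaries <- function(mask) {
  mask <- as.matrix(mask) > 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- label_components(mask)
  per <- perimeter_cycle(H, W)
  npos <- nrow(per)
  pos_of <- matrix(0L, H, W)
  pos_of[per] <- seq_len(npos)
  out <- mask
  border_labs <- setdiff(unique(lab[per]), 0L)
  for (lb in border_labs) {
    contacts <- sort(pos_of[per][lab[per] == lb])
    if (length(contacts) <= 1L) next
    # cyclic clusters of contiguous contact positions
    brk <- which(diff(contacts) > 1L)
    if (length(brk) == 0L) next  # single contiguous run: already closed
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(contacts))
    k <- length(starts)
    # cyclic gaps between cluster i end and cluster i+1 start
    gap_from <- contacts[ends]
    gap_to <- contacts[starts][c(2:k, 1L)]
    gap_len <- (gap_to - gap_from - 1L) %% npos
    keep_open <- which.max(gap_len)   # leave the largest arc open
    add <- logical(npos)
    for (i in seq_len(k)) {
      if (i == keep_open || gap_len[i] == 0L) next
      span <- (seq.int(gap_from[i], gap_from[i] + gap_len[i] + 1L) - 1L) %% npos + 1L
      add[span] <- TRUE
    }
    if (!any(add)) next
    comp <- lab == lb
    comp[per[add, , drop = FALSE]] <- TRUE
    filled <- EBImage::fillHull(comp * 1) > 0.5
    out <- out | filled
  }
  out
}

#' Contour pixels of a binary mask
#'
#' A foreground pixel is a contour pixel when one of its 4-neighbors is
#' background or lies outside the image (the image border counts as
#' background), so border-truncated regions expose their border run as
#' contour.
#'
#' @param mask logical matrix
#' @return logical matrix of contour pixels
#' @export
mask_contours <- function(mask) {
  mask <- as.matrix(mask) > 0
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  interior <- pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)] &
    pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)]
  mask & !interior
}
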