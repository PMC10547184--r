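# Image I/O helpers: 8-bit PNG for RGB images and binary masks, 16-bit TIFF
# for instance label maps, JSON manifests.

read_image_rgb <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  img
}

write_image_rgb <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
}

read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
}

read_instance_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

write_instance_tiff <- function(instance_map, path) {
  if (max(instance_map) > 65535) stop("more than 65535 instances")
  tiff::writeTIFF(instance_map / 65535, path,
                  bits.per.sample = 16L, compression = "none")
}
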