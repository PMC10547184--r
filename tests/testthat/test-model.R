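# Network components: encoder shapes, gating, weighted fusion, CSFI,
# WCU separability, dual decoder coupling, full-forward contracts.

test_that("encoder pyramid halves spatial sides and caps channels", {
  m <- reduced_model()
  x <- array(stats::runif(128 * 128 * 3), c(128, 128, 3))
  pyr <- cunet_encode(m, x)
  sides <- vapply(pyr, function(p) dim(p)[1], numeric(1))
  expect_equal(sides, 128 / 2^(0:6))
  chans <- vapply(pyr, function(p) dim(p)[3], numeric(1))
  expect_equal(chans, pmin(8 * 2^(0:6), 64))
  expect_error(cunet_encode(m, array(0.5, c(100, 100, 3))), "divisible")
})

test_that("gate with zeroed conv weights halves the feature magnitude", {
  m <- reduced_model()
  lv <- 3L
  m$params[["gate.p3.w"]][] <- 0
  # eval-mode BN at initialization is the identity on a zero input
  x <- array(stats::runif(16 * 16 * 16 * 1), c(16, 16, 16, 1))
  g <- cunet_gate(m, x, level = lv)
  expect_equal(g, 0.5 * x, tolerance = 1e-6)
  # generic gate never amplifies (sigmoid <= 1, dropout off in eval)
  m2 <- reduced_model(seed = 5)
  g2 <- cunet_gate(m2, x, level = lv)
  expect_true(all(abs(g2) <= abs(x) + 1e-12))
  expect_identical(dim(g2), dim(x))
})

test_that("fuse_weighted matches brute force, limits, and scale equivariance", {
  set.seed(61)
  e <- 1e-4
  a <- array(stats::rnorm(60), c(5, 4, 3, 1))
  b <- array(stats::rnorm(60), c(5, 4, 3, 1))
  cc <- array(stats::rnorm(60), c(5, 4, 3, 1))
  expect_equal(fuse_weighted(list(a, b), c(1, 1)), (a + b) / (2 + e),
               tolerance = 1e-12)
  expect_equal(fuse_weighted(list(a, b), c(0, 5)), 5 * b / (5 + e),
               tolerance = 1e-12)
  # per-element scalar brute force on a random 3-input node
  v <- c(0.3, 2, 0.7)
  f <- fuse_weighted(list(a, b, cc), v)
  r <- pmax(v, 0); S <- sum(r) + e
  for (i in sample(60, 10)) {
    expect_equal(f[i], (r[1] * a[i] + r[2] * b[i] + r[3] * cc[i]) / S,
                 tolerance = 1e-12)
  }
  # negative weights are rectified away; normalized weights sum below 1
  f2 <- fuse_weighted(list(a, b), c(-3, 1))
  expect_equal(f2, b / (1 + e), tolerance = 1e-12)
  w <- pmax(c(0.3, 2, 0.7), 0) / S
  expect_true(all(w >= 0) && sum(w) < 1)
  # scale equivariance
  expect_equal(fuse_weighted(lapply(list(a, b, cc), function(x) 3 * x), v),
               3 * f, tolerance = 1e-12)
  expect_error(fuse_weighted(list(a, b[, 1:2, , , drop = FALSE]), c(1, 1)),
               "input 2")
  expect_error(fuse_weighted(list(a, b), c(1, 1, 1)), "length 3")
})

test_that("csfi output is constant for constant inputs and correct width", {
  m <- reduced_model(n_layers = 3L)
  x <- array(0.5, c(128, 128, 3))
  pyr <- cunet_encode(m, x)
  out <- csfi_forward(m, pyr)
  expect_equal(length(out), 5)
  for (lv in 3:7) {
    o <- out[[as.character(lv)]]
    expect_equal(dim(o)[3], 16)
    expect_equal(dim(o)[1], 128 / 2^(lv - 1))
  }
  expect_error(csfi_forward(m, pyr[1:4]), "levels")

  # exact spatial constancy under a constant field needs every contributing
  # level to keep a padding-free interior: a 4-level pyramid at 256 px
  # qualifies (the deepest map is 32 px against a ~10 px rim)
  mc <- cunet_model(encoder_config(levels = 4, base_channels = 8,
                                   channel_cap = 32, dropout_rate = 0),
                    csfi_config(n_layers = 1, fpn_channels = 8,
                                levels_used = 2:4),
                    wcu_config(3), seed = 95)
  pyrc <- cunet_encode(mc, array(0.5, c(256, 256, 3)))
  outc <- csfi_forward(mc, pyrc)
  for (lv in 2:4) {
    o <- outc[[as.character(lv)]]
    side <- dim(o)[1]
    core <- o[(side / 2 - side / 8):(side / 2 + side / 8),
              (side / 2 - side / 8):(side / 2 + side / 8), 1, 1]
    expect_lt(max(abs(core - core[1, 1])), 1e-10)
  }
})

test_that("single-layer CSFI on a toy pyramid matches a hand-unrolled graph", {
  m <- cunet_model(encoder_config(levels = 5, base_channels = 8,
                                  channel_cap = 32, dropout_rate = 0),
                   csfi_config(n_layers = 1, fpn_channels = 8,
                               levels_used = 3:5),
                   wcu_config(3), seed = 71)
  x <- array(stats::runif(48 * 48 * 3), c(48, 48, 3))
  pyr <- cunet_encode(m, x)
  got <- csfi_forward(m, pyr)

  # hand-unrolled composition using only fuse_weighted, bilinear resize and
  # the conv/BN/ReLU primitive applied step by step
  P <- m$params
  resize <- function(a, h, w) {
    y <- cunet:::.cpp_resize_bilinear_forward(a, as.integer(h), as.integer(w))
    y
  }
  conv_bn_relu <- function(a, nm) {
    y <- cunet:::.cpp_conv2d_forward(a, P[[paste0(nm, ".w")]],
                                     numeric(dim(P[[paste0(nm, ".w")]])[4]))
    st <- m$bn[[paste0(nm, ".bn")]]
    C <- dim(y)[3]
    ym <- matrix(aperm(y, c(1, 2, 4, 3)), ncol = C)
    xh <- sweep(sweep(ym, 2, st$running_mean, "-"), 2,
                1 / sqrt(st$running_var + 1e-5), "*")
    ym <- sweep(sweep(xh, 2, P[[paste0(nm, ".bn.gamma")]], "*"), 2,
                P[[paste0(nm, ".bn.beta")]], "+")
    y <- aperm(array(ym, dim(y)[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
    pmax(y, 0)
  }
  lat <- list()
  for (lv in 3:5) {
    l0 <- cunet:::.cpp_conv2d_forward(pyr[[lv]],
                                      P[[sprintf("lat.p%d.w", lv)]],
                                      P[[sprintf("lat.p%d.b", lv)]])
    lat[[as.character(lv)]] <- cunet_gate(m, l0, level = lv)
  }
  po5 <- lat[["5"]]
  d4 <- dim(lat[["4"]])
  po4 <- conv_bn_relu(fuse_weighted(list(lat[["4"]],
                                         resize(po5, d4[1], d4[2])),
                                    P[["csfi1.td.p4.v"]]), "csfi1.td.p4")
  d3 <- dim(lat[["3"]])
  po3 <- conv_bn_relu(fuse_weighted(list(lat[["3"]],
                                         resize(po4, d3[1], d3[2])),
                                    P[["csfi1.td.p3.v"]]), "csfi1.td.p3")
  out3 <- conv_bn_relu(fuse_weighted(list(lat[["3"]], po3),
                                     P[["csfi1.bu.p3.v"]]), "csfi1.bu.p3")
  out4 <- conv_bn_relu(fuse_weighted(list(lat[["4"]], po4,
                                          resize(out3, d4[1], d4[2])),
                                     P[["csfi1.bu.p4.v"]]), "csfi1.bu.p4")
  d5 <- dim(lat[["5"]])
  out5 <- conv_bn_relu(fuse_weighted(list(lat[["5"]],
                                          resize(out4, d5[1], d5[2])),
                                     P[["csfi1.bu.p5.v"]]), "csfi1.bu.p5")
  expect_equal(got[["3"]], out3, tolerance = 1e-10)
  expect_equal(got[["4"]], out4, tolerance = 1e-10)
  expect_equal(got[["5"]], out5, tolerance = 1e-10)
})

test_that("WCU: impulse kernels double the input; separable oracle matches", {
  N <- 5; C <- 2
  mk <- function(kh, kw) {
    w <- array(0, c(kh, kw, C, C))
    for (c in 1:C) w[(kh + 1) %/% 2, (kw + 1) %/% 2, c, c] <- 1
    w
  }
  weights <- list(a1 = list(w = mk(N, 1), b = numeric(C)),
                  a2 = list(w = mk(1, N), b = numeric(C)),
                  b1 = list(w = mk(1, N), b = numeric(C)),
                  b2 = list(w = mk(N, 1), b = numeric(C)))
  x <- array(stats::runif(7 * 7 * C), c(7, 7, C, 1))
  expect_equal(wcu_forward(x, weights), 2 * x, tolerance = 1e-12)

  # random single-channel kernels vs a dense 2-D convolution oracle from the
  # outer composition of the 1-D kernels
  set.seed(81)
  k_n1_a <- stats::rnorm(N); k_1n_a <- stats::rnorm(N)
  k_1n_b <- stats::rnorm(N); k_n1_b <- stats::rnorm(N)
  as_w <- function(v, kh, kw) array(v, c(kh, kw, 1, 1))
  weights2 <- list(a1 = list(w = as_w(k_n1_a, N, 1), b = 0),
                   a2 = list(w = as_w(k_1n_a, 1, N), b = 0),
                   b1 = list(w = as_w(k_1n_b, 1, N), b = 0),
                   b2 = list(w = as_w(k_n1_b, N, 1), b = 0))
  x2 <- array(stats::rnorm(5 * 5), c(5, 5, 1, 1))
  got <- wcu_forward(x2, weights2)
  dense <- function(img, K) {
    H <- nrow(img); W <- ncol(img)
    kh <- nrow(K); kw <- ncol(K)
    ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
    out <- matrix(0, H, W)
    for (y in 1:H) for (x0 in 1:W) {
      s <- 0
      for (i in 1:kh) for (j in 1:kw) {
        yy <- y + i - 1 - ph; xx <- x0 + j - 1 - pw
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= W) {
          s <- s + img[yy, xx] * K[i, j]
        }
      }
      out[y, x0] <- s
    }
    out
  }
  # composing Nx1 then 1xN with zero padding equals the dense outer-product
  # kernel only away from the padding rim; compare the interior
  K_a <- outer(k_n1_a, k_1n_a)
  K_b <- outer(k_n1_b, k_1n_b)
  oracle <- dense(x2[, , 1, 1], K_a) + dense(x2[, , 1, 1], K_b)
  core <- 3:3  # with N = 5 on a 5x5 input only the center is rim-free
  expect_equal(got[core, core, 1, 1], oracle[core, core], tolerance = 1e-5)
  expect_error(wcu_forward(x2, list(
    a1 = list(w = array(0, c(4, 1, 1, 1)), b = 0),
    a2 = weights2$a2, b1 = weights2$b1, b2 = weights2$b2)), "odd")
})

test_that("dual decoder: bounds, seg->boundary one-way coupling", {
  m <- reduced_model(seed = 91)
  x <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  out <- cunet_forward(m, x)
  expect_identical(dim(out$seg_prob), c(64L, 64L, 1L))
  expect_identical(dim(out$boundary_prob), c(64L, 64L, 1L))
  expect_true(all(out$seg_prob >= 0 & out$seg_prob <= 1))
  expect_true(all(out$boundary_prob >= 0 & out$boundary_prob <= 1))
  # zeroing every boundary-branch parameter must not change seg output
  m2 <- m
  for (nm in grep("^(dec\\.bou|head\\.bou)", names(m2$params), value = TRUE)) {
    m2$params[[nm]][] <- 0
  }
  out2 <- cunet_forward(m2, x)
  expect_identical(out2$seg_prob, out$seg_prob)
  expect_false(identical(out2$boundary_prob, out$boundary_prob))
})

test_that("constant input yields spatially constant seg output centrally", {
  # configuration chosen so no contributing feature map is all padding rim
  m <- cunet_model(encoder_config(levels = 4, base_channels = 8,
                                  channel_cap = 32, dropout_rate = 0),
                   csfi_config(n_layers = 1, fpn_channels = 8,
                               levels_used = 2:4),
                   wcu_config(3), seed = 95)
  x <- array(0.4, c(256, 256, 3))
  out <- cunet_forward(m, x)
  core <- out$seg_prob[112:144, 112:144, 1]
  expect_lt(max(abs(core - core[1, 1])), 1e-10)
  core_b <- out$boundary_prob[112:144, 112:144, 1]
  expect_lt(max(abs(core_b - core_b[1, 1])), 1e-10)
})

test_that("full forward: 512 contract, batch determinism, gradient coverage", {
  m <- reduced_model(seed = 97)
  x512 <- array(stats::runif(512 * 512 * 3), c(512, 512, 3))
  out <- cunet_forward(m, x512)
  expect_identical(dim(out$seg_prob), c(512L, 512L, 1L))
  expect_true(all(out$seg_prob >= 0 & out$seg_prob <= 1))

  xb <- array(stats::runif(64 * 64 * 3), c(64, 64, 3, 1))
  x2 <- array(c(xb, xb), c(64, 64, 3, 2))
  o2 <- cunet_forward(m, x2)
  expect_identical(o2$seg_prob[, , 1], o2$seg_prob[, , 2])
  # eval-mode forward is bit-deterministic across calls
  expect_identical(cunet_forward(m, x2), cunet_forward(m, x2))

  set.seed(99)
  xg <- array(stats::runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  mask <- array(stats::rbinom(64 * 64 * 2, 1, 0.5), c(64, 64, 1, 2))
  bnd <- array(stats::rbinom(64 * 64 * 2, 1, 0.5), c(64, 64, 1, 2))
  tape <- cunet:::ag_tape()
  P <- cunet:::wrap_params(m, tape)
  og <- cunet:::cunet_graph(P, cunet:::ag_const(xg), m, TRUE, tape)
  ln <- cunet:::total_loss_graph(og$seg_prob, og$boundary_prob, mask, bnd,
                                 loss_config(), tape)
  cunet:::ag_backward(tape, ln)
  no_grad <- names(P)[vapply(P, function(p)
    is.null(p$grad) || all(p$grad == 0), logical(1))]
  expect_identical(no_grad, character(0))
})
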