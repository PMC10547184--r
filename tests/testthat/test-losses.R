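# Loss functions against pure scalar-loop oracles and closed forms.

# scalar loop oracles, written independently of the package implementation
oracle_dice <- function(p, t, E) {
  num <- 0; sp <- 0; st <- 0
  for (i in seq_along(p)) {
    num <- num + p[i] * t[i]; sp <- sp + p[i]; st <- st + t[i]
  }
  1 - (2 * num + E) / (sp + st + E)
}

oracle_bce <- function(p, t, eps = 1e-7) {
  s <- 0
  for (i in seq_along(p)) {
    pc <- min(max(p[i], eps), 1 - eps)
    s <- s + t[i] * log(pc) + (1 - t[i]) * log(1 - pc)
  }
  -s / length(p)
}

oracle_ft <- function(p, t, a, b, g, E) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(p)) {
    tp <- tp + p[i] * t[i]
    fp <- fp + (1 - t[i]) * p[i]
    fn <- fn + t[i] * (1 - p[i])
  }
  ti <- (tp + E) / (tp + a * fp + b * fn + E)
  max(1 - ti, 1e-12)^(1 / g)
}

oracle_combo <- function(p, t, a, b, E, eps = 1e-7) {
  s <- 0
  for (i in seq_along(p)) {
    pc <- min(max(p[i], eps), 1 - eps)
    s <- s + b * t[i] * log(pc) + (1 - b) * (1 - t[i]) * log(1 - pc)
  }
  cew <- -s / length(p)
  dsc <- 1 - oracle_dice(p, t, E)
  a * cew - (1 - a) * dsc
}

test_that("closed-form loss values match the stated identities", {
  ones <- matrix(1, 2, 2)
  zeros <- matrix(0, 2, 2)
  E <- 1e-3
  expect_equal(dice_loss(ones, ones, E), 0)
  expect_equal(dice_loss(zeros, ones, E), 1 - E / (4 + E))
  expect_equal(bce_loss(ones, ones), -log(1 - 1e-7), tolerance = 1e-10)
  expect_equal(bce_loss(matrix(0.5, 3, 3), matrix(1, 3, 3)), log(2))
  expect_equal(focal_tversky_loss(ones, ones), 0, tolerance = 1e-8)
})

test_that("all losses match scalar-loop oracles on random 5x5 maps", {
  set.seed(42)
  cfg <- loss_config()
  for (rep in 1:100) {
    p <- random_prob_map(5, 5)
    t <- random_binary_map(5, 5)
    expect_equal(dice_loss(p, t, cfg$E), oracle_dice(p, t, cfg$E),
                 tolerance = 1e-6)
    expect_equal(bce_loss(p, t), oracle_bce(p, t), tolerance = 1e-6)
    expect_equal(
      focal_tversky_loss(p, t, cfg$alpha_ft, cfg$beta_ft, cfg$gamma_ft, cfg$E),
      oracle_ft(p, t, cfg$alpha_ft, cfg$beta_ft, cfg$gamma_ft, cfg$E),
      tolerance = 1e-6)
    expect_equal(
      combo_loss(p, t, cfg$alpha_combo, cfg$beta_combo, cfg$E),
      oracle_combo(p, t, cfg$alpha_combo, cfg$beta_combo, cfg$E),
      tolerance = 1e-6)
    expect_equal(
      seg_head_loss(p, t, cfg),
      oracle_ft(p, t, cfg$alpha_ft, cfg$beta_ft, cfg$gamma_ft, cfg$E) +
        cfg$w_seg * (oracle_dice(p, t, cfg$E) + oracle_bce(p, t)),
      tolerance = 1e-6)
    expect_equal(
      boundary_head_loss(p, t, cfg),
      oracle_ft(p, t, cfg$alpha_ft, cfg$beta_ft, cfg$gamma_ft, cfg$E) +
        cfg$w_bou * oracle_combo(p, t, cfg$alpha_combo, cfg$beta_combo, cfg$E),
      tolerance = 1e-6)
  }
})

test_that("Tversky with alpha = beta = 0.5, gamma = 1 reduces to Dice", {
  set.seed(7)
  # with alpha = beta = 0.5 the Tversky denominator is half the Dice
  # denominator, so the smoothness constant must scale by 1/2 for the
  # identity to be exact at finite E (it is exact in the E -> 0 limit)
  for (rep in 1:20) {
    p <- random_prob_map(6, 6)
    t <- random_binary_map(6, 6)
    expect_equal(focal_tversky_loss(p, t, 0.5, 0.5, 1, 5e-4),
                 dice_loss(p, t, 1e-3), tolerance = 1e-9)
    expect_equal(focal_tversky_loss(p, t, 0.5, 0.5, 1, 1e-3),
                 dice_loss(p, t, 1e-3), tolerance = 1e-4)
  }
})

test_that("parameter limits reduce composite losses to their components", {
  set.seed(8)
  p <- random_prob_map(5, 5)
  t <- random_binary_map(5, 5)
  cfg0 <- loss_config(w_seg = 0, w_bou = 0)
  expect_equal(seg_head_loss(p, t, cfg0),
               focal_tversky_loss(p, t, cfg0$alpha_ft, cfg0$beta_ft,
                                  cfg0$gamma_ft, cfg0$E),
               tolerance = 1e-12)
  expect_equal(boundary_head_loss(p, t, cfg0),
               focal_tversky_loss(p, t, cfg0$alpha_ft, cfg0$beta_ft,
                                  cfg0$gamma_ft, cfg0$E),
               tolerance = 1e-12)
  # combo at alpha 0 is the negative Dice score alone
  expect_equal(combo_loss(p, t, alpha_combo = 0),
               -(1 - dice_loss(p, t, 1e-3)), tolerance = 1e-12)
  # combo at alpha 1, beta 0.5 is half the BCE
  expect_equal(combo_loss(p, t, alpha_combo = 1, beta_combo = 0.5),
               0.5 * bce_loss(p, t), tolerance = 1e-12)
})

test_that("total loss bookkeeping: breakdown sums to total, head_balance 0", {
  set.seed(9)
  out <- list(seg_prob = random_prob_map(8, 8),
              boundary_prob = random_prob_map(8, 8))
  tg <- list(mask = random_binary_map(8, 8),
             boundary = random_binary_map(8, 8))
  cfg <- loss_config()
  tl <- total_loss(out, tg, cfg)
  expect_equal(tl$total,
               tl$components$seg_head +
                 cfg$head_balance * tl$components$boundary_head,
               tolerance = 1e-9)
  expect_equal(tl$components$seg_head,
               tl$components$seg_focal_tversky +
                 cfg$w_seg * (tl$components$seg_dice + tl$components$seg_bce),
               tolerance = 1e-9)
  cfg0 <- loss_config(head_balance = 0)
  tl0 <- total_loss(out, tg, cfg0)
  expect_equal(tl0$total, seg_head_loss(out$seg_prob, tg$mask, cfg0),
               tolerance = 1e-12)
})

test_that("loss bounds and finiteness at prediction extremes", {
  t <- random_binary_map(4, 4)
  for (v in c(1e-7, 1 - 1e-7)) {
    p <- matrix(v, 4, 4)
    expect_true(is.finite(boundary_head_loss(p, t)))
    expect_true(is.finite(seg_head_loss(p, t)))
  }
  set.seed(10)
  for (rep in 1:20) {
    p <- random_prob_map(4, 4); t <- random_binary_map(4, 4)
    expect_gte(dice_loss(p, t), 0)
    expect_lte(dice_loss(p, t), 1)
    expect_gte(focal_tversky_loss(p, t), 0)
    expect_lte(focal_tversky_loss(p, t), 1)
    a <- 0.3
    expect_gte(combo_loss(p, t, alpha_combo = a), -(1 - a))
  }
})

test_that("moving predictions toward the target never increases Dice or FT", {
  set.seed(11)
  for (rep in 1:10) {
    t <- random_binary_map(5, 5)
    p <- random_prob_map(5, 5)
    # step every pixel a random fraction toward its target value
    p2 <- p + (t - p) * matrix(stats::runif(25, 0, 1), 5, 5)
    expect_lte(dice_loss(p2, t), dice_loss(p, t) + 1e-12)
    expect_lte(focal_tversky_loss(p2, t), focal_tversky_loss(p, t) + 1e-12)
  }
})

test_that("losses reject mismatched shapes", {
  expect_error(dice_loss(matrix(0.5, 3, 3), matrix(1, 4, 4)), "shape")
  expect_error(bce_loss(matrix(0.5, 2, 3), matrix(1, 3, 2)), "shape")
})
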