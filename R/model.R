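# C-UNet: 7-level UNet encoder, gated laterals, stacked bidirectional
# weighted-fusion pyramid (CSFI), wide context unit, and interconnected
# segmentation/boundary decoders.

enc_channels <- function(cfg) {
  pmin(cfg$base_channels * 2L^(seq_len(cfg$levels) - 1L), cfg$channel_cap)
}

he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

new_bn_state <- function(C) {
  s <- new.env(parent = emptyenv())
  s$running_mean <- numeric(C)
  s$running_var <- rep(1, C)
  s
}

#' Build a C-UNet model
#'
#' Allocates and initializes every learnable parameter (He-normal conv
#' weights, zero biases, unit batch-norm gains, fusion weights at 1) and the
#' batch-norm running statistics. The returned object is self-describing: it
#' carries its three configuration blocks and the seed used for
#' initialization.
#'
#' @param encoder_cfg see [encoder_config()]
#' @param csfi_cfg see [csfi_config()]
#' @param wcu_cfg see [wcu_config()]
#' @param seed integer seed for parameter initialization
#' @return an object of class `cunet_model`
#' @export
cunet_model <- function(encoder_cfg = encoder_config(),
                        csfi_cfg = csfi_config(),
                        wcu_cfg = wcu_config(),
                        seed = 1L) {
  stopifnot(inherits(encoder_cfg, "encoder_config"),
            inherits(csfi_cfg, "csfi_config"),
            inherits(wcu_cfg, "wcu_config"))
  if (max(csfi_cfg$levels_used) > encoder_cfg$levels) {
    stop("levels_used reaches level ", max(csfi_cfg$levels_used),
         " but the encoder has only ", encoder_cfg$levels)
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  P <- list()
  bn <- list()
  ch <- enc_channels(encoder_cfg)
  fpn <- csfi_cfg$fpn_channels
  lvs <- csfi_cfg$levels_used
  top <- max(lvs); bot <- min(lvs)

  add_conv <- function(name, kh, kw, cin, cout, bias = TRUE) {
    P[[paste0(name, ".w")]] <<- he_init(kh, kw, cin, cout)
    # convs feeding a BN layer are bias-free: BN's mean subtraction makes a
    # preceding bias a dead parameter
    if (bias) P[[paste0(name, ".b")]] <<- numeric(cout)
  }
  add_bn <- function(name, C) {
    P[[paste0(name, ".gamma")]] <<- rep(1, C)
    P[[paste0(name, ".beta")]] <<- numeric(C)
    bn[[name]] <<- new_bn_state(C)
  }

  cin <- 3L
  for (l in seq_len(encoder_cfg$levels)) {
    add_conv(sprintf("enc.l%d.c1", l), 3, 3, cin, ch[l])
    add_conv(sprintf("enc.l%d.c2", l), 3, 3, ch[l], ch[l])
    cin <- ch[l]
  }

  for (lv in lvs) {
    add_conv(sprintf("lat.p%d", lv), 1, 1, ch[lv], fpn)
    add_conv(sprintf("gate.p%d", lv), 1, 1, fpn, fpn, bias = FALSE)
    add_bn(sprintf("gate.p%d.bn", lv), fpn)
  }

  for (i in seq_len(csfi_cfg$n_layers)) {
    for (lv in setdiff(lvs, top)) {
      nm <- sprintf("csfi%d.td.p%d", i, lv)
      add_conv(nm, 3, 3, fpn, fpn, bias = FALSE); add_bn(paste0(nm, ".bn"), fpn)
      P[[paste0(nm, ".v")]] <- rep(1, 2)
    }
    for (lv in lvs) {
      nm <- sprintf("csfi%d.bu.p%d", i, lv)
      add_conv(nm, 3, 3, fpn, fpn, bias = FALSE); add_bn(paste0(nm, ".bn"), fpn)
      P[[paste0(nm, ".v")]] <- rep(1, if (lv %in% c(bot, top)) 2 else 3)
    }
  }

  N <- wcu_cfg$kernel_extent
  add_conv("wcu.a1", N, 1, fpn, fpn); add_conv("wcu.a2", 1, N, fpn, fpn)
  add_conv("wcu.b1", 1, N, fpn, fpn); add_conv("wcu.b2", N, 1, fpn, fpn)

  for (head in c("seg", "bou")) {
    nm <- sprintf("dec.%s.p%d", head, top)
    add_conv(nm, 3, 3, fpn, fpn, bias = FALSE); add_bn(paste0(nm, ".bn"), fpn)
    P[[paste0(nm, ".v")]] <- rep(1, 2)
    for (lv in rev(setdiff(lvs, top))) {
      nm <- sprintf("dec.%s.p%d", head, lv)
      add_conv(nm, 3, 3, fpn, fpn, bias = FALSE); add_bn(paste0(nm, ".bn"), fpn)
      P[[paste0(nm, ".v")]] <- rep(1, 3)
    }
    nm <- sprintf("head.%s.refine3", head)
    add_conv(nm, 3, 3, fpn, fpn, bias = FALSE); add_bn(paste0(nm, ".bn"), fpn)
    nm <- sprintf("head.%s.refine1", head)
    add_conv(nm, 1, 1, fpn, fpn, bias = FALSE); add_bn(paste0(nm, ".bn"), fpn)
    add_conv(sprintf("head.%s.out", head), 1, 1, fpn, 1)
  }

  structure(list(params = P, bn = bn,
                 encoder_cfg = encoder_cfg, csfi_cfg = csfi_cfg,
                 wcu_cfg = wcu_cfg, seed = as.integer(seed)),
            class = "cunet_model")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# wrap parameters as tape variables (training) or constants (inference)
wrap_params <- function(model, tape = NULL) {
  if (is.null(tape)) lapply(model$params, ag_const)
  else lapply(model$params, ag_var, tape = tape)
}

as_image_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L || dim(x)[3] != 3L) {
    stop("expected an H x W x 3 image or H x W x 3 x N batch")
  }
  x
}

check_divisible <- function(h, w, levels) {
  d <- 2L^(levels - 1L)
  if (h %% d != 0L || w %% d != 0L) {
    stop("input side ", h, "x", w, " must be divisible by 2^(levels-1) = ",
         d, " for a ", levels, "-level encoder")
  }
}

# conv -> BN -> ReLU block used throughout CSFI and the decoders
conv_block <- function(x, name, P, model, training, tape) {
  y <- ag_conv2d(x, P[[paste0(name, ".w")]], P[[paste0(name, ".b")]], tape)
  y <- ag_batchnorm(y, P[[paste0(name, ".bn.gamma")]],
                    P[[paste0(name, ".bn.beta")]],
                    model$bn[[paste0(name, ".bn")]], training, tape,
                    momentum = model$bn_momentum %||% 0.99)
  ag_relu(y, tape)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- graph builders (operate on ag nodes) -----------------------------------

encode_graph <- function(P, x, model, training, tape) {
  cfg <- model$encoder_cfg
  pyr <- vector("list", cfg$levels)
  cur <- x
  for (l in seq_len(cfg$levels)) {
    cur <- ag_relu(ag_conv2d(cur, P[[sprintf("enc.l%d.c1.w", l)]],
                             P[[sprintf("enc.l%d.c1.b", l)]], tape), tape)
    cur <- ag_relu(ag_conv2d(cur, P[[sprintf("enc.l%d.c2.w", l)]],
                             P[[sprintf("enc.l%d.c2.b", l)]], tape), tape)
    if (l == cfg$levels) {
      cur <- ag_dropout(cur, cfg$dropout_rate, training, tape)
    }
    pyr[[l]] <- cur
    if (l < cfg$levels) cur <- ag_maxpool2(cur, tape)
  }
  pyr
}

gate_graph <- function(x, name, P, model, training, tape) {
  g <- ag_conv2d(x, P[[paste0(name, ".w")]], P[[paste0(name, ".b")]], tape)
  g <- ag_batchnorm(g, P[[paste0(name, ".bn.gamma")]],
                    P[[paste0(name, ".bn.beta")]],
                    model$bn[[paste0(name, ".bn")]], training, tape,
                    momentum = model$bn_momentum %||% 0.99)
  g <- ag_sigmoid(g, tape)
  g <- ag_dropout(g, model$encoder_cfg$dropout_rate, training, tape)
  ag_mul(x, g, tape)
}

# lateral 1x1 projection + gating of the used encoder levels
lateral_graph <- function(P, pyr, model, training, tape) {
  lvs <- model$csfi_cfg$levels_used
  out <- list()
  for (lv in lvs) {
    lat <- ag_conv2d(pyr[[lv]], P[[sprintf("lat.p%d.w", lv)]],
                     P[[sprintf("lat.p%d.b", lv)]], tape)
    out[[as.character(lv)]] <-
      gate_graph(lat, sprintf("gate.p%d", lv), P, model, training, tape)
  }
  out
}

resize_to <- function(x, ref, tape) {
  d <- dim(ref$value)
  ag_resize_bilinear(x, d[1], d[2], tape)
}

csfi_graph <- function(P, lat, model, training, tape) {
  lvs <- model$csfi_cfg$levels_used
  top <- max(lvs); bot <- min(lvs)
  pin <- lat
  for (i in seq_len(model$csfi_cfg$n_layers)) {
    po <- list()
    po[[as.character(top)]] <- pin[[as.character(top)]]
    for (lv in rev(setdiff(lvs, top))) {
      nm <- sprintf("csfi%d.td.p%d", i, lv)
      f <- ag_fuse(list(pin[[as.character(lv)]],
                        resize_to(po[[as.character(lv + 1)]],
                                  pin[[as.character(lv)]], tape)),
                   P[[paste0(nm, ".v")]], tape = tape)
      po[[as.character(lv)]] <- conv_block(f, nm, P, model, training, tape)
    }
    pout <- list()
    for (lv in lvs) {
      nm <- sprintf("csfi%d.bu.p%d", i, lv)
      ins <- if (lv == bot) {
        list(pin[[as.character(lv)]], po[[as.character(lv)]])
      } else if (lv == top) {
        list(pin[[as.character(lv)]],
             resize_to(pout[[as.character(lv - 1)]],
                       pin[[as.character(lv)]], tape))
      } else {
        list(pin[[as.character(lv)]], po[[as.character(lv)]],
             resize_to(pout[[as.character(lv - 1)]],
                       pin[[as.character(lv)]], tape))
      }
      f <- ag_fuse(ins, P[[paste0(nm, ".v")]], tape = tape)
      pout[[as.character(lv)]] <- conv_block(f, nm, P, model, training, tape)
    }
    pin <- pout
  }
  pin
}

wcu_graph <- function(P, x, tape) {
  b1 <- ag_conv2d(ag_conv2d(x, P[["wcu.a1.w"]], P[["wcu.a1.b"]], tape),
                  P[["wcu.a2.w"]], P[["wcu.a2.b"]], tape)
  b2 <- ag_conv2d(ag_conv2d(x, P[["wcu.b1.w"]], P[["wcu.b1.b"]], tape),
                  P[["wcu.b2.w"]], P[["wcu.b2.b"]], tape)
  ag_add(b1, b2, tape)
}

head_graph <- function(P, x, head, out_h, out_w, model, training, tape) {
  y <- conv_block(x, sprintf("head.%s.refine3", head), P, model, training, tape)
  y <- conv_block(y, sprintf("head.%s.refine1", head), P, model, training, tape)
  y <- ag_resize_bilinear(y, out_h, out_w, tape)
  y <- ag_conv2d(y, P[[sprintf("head.%s.out.w", head)]],
                 P[[sprintf("head.%s.out.b", head)]], tape)
  ag_sigmoid(y, tape)
}

decode_graph <- function(P, pyr, wcu, out_h, out_w, model, training, tape) {
  lvs <- model$csfi_cfg$levels_used
  top <- max(lvs); bot <- min(lvs)
  seg <- list(); bou <- list()
  nm <- sprintf("dec.seg.p%d", top)
  f <- ag_fuse(list(pyr[[as.character(top)]],
                    resize_to(wcu, pyr[[as.character(top)]], tape)),
               P[[paste0(nm, ".v")]], tape = tape)
  seg[[as.character(top)]] <- conv_block(f, nm, P, model, training, tape)
  for (lv in rev(setdiff(lvs, top))) {
    nm <- sprintf("dec.seg.p%d", lv)
    f <- ag_fuse(list(pyr[[as.character(lv)]],
                      resize_to(seg[[as.character(lv + 1)]],
                                pyr[[as.character(lv)]], tape),
                      resize_to(pyr[[as.character(lv + 1)]],
                                pyr[[as.character(lv)]], tape)),
                 P[[paste0(nm, ".v")]], tape = tape)
    seg[[as.character(lv)]] <- conv_block(f, nm, P, model, training, tape)
  }
  nm <- sprintf("dec.bou.p%d", top)
  f <- ag_fuse(list(seg[[as.character(top)]],
                    resize_to(wcu, seg[[as.character(top)]], tape)),
               P[[paste0(nm, ".v")]], tape = tape)
  bou[[as.character(top)]] <- conv_block(f, nm, P, model, training, tape)
  for (lv in rev(setdiff(lvs, top))) {
    nm <- sprintf("dec.bou.p%d", lv)
    f <- ag_fuse(list(seg[[as.character(lv)]],
                      resize_to(bou[[as.character(lv + 1)]],
                                seg[[as.character(lv)]], tape),
                      resize_to(pyr[[as.character(lv + 1)]],
                                seg[[as.character(lv)]], tape)),
                 P[[paste0(nm, ".v")]], tape = tape)
    bou[[as.character(lv)]] <- conv_block(f, nm, P, model, training, tape)
  }
  list(
    seg_prob = head_graph(P, seg[[as.character(bot)]], "seg",
                          out_h, out_w, model, training, tape),
    boundary_prob = head_graph(P, bou[[as.character(bot)]], "bou",
                               out_h, out_w, model, training, tape)
  )
}

# full forward over ag nodes; returns list(seg_prob, boundary_prob) nodes
cunet_graph <- function(P, x, model, training, tape) {
  d <- dim(x$value)
  pyr <- encode_graph(P, x, model, training, tape)
  lat <- lateral_graph(P, pyr, model, training, tape)
  csfi <- csfi_graph(P, lat, model, training, tape)
  wcu_lv <- as.character(min(max(model$csfi_cfg$levels_used), 6L))
  wcu <- wcu_graph(P, csfi[[wcu_lv]], tape)
  decode_graph(P, csfi, wcu, d[1], d[2], model, training, tape)
}

# --- public array-level wrappers --------------------------------------------

#' Forward pass of the full network
#'
#' @param model a `cunet_model`
#' @param images an H x W x 3 image or H x W x 3 x N batch, values in `[0,1]`
#' @param training logical; enables dropout and batch-statistics BN
#' @return list with `seg_prob` and `boundary_prob`, each H x W x N in `[0,1]`
#' @export
cunet_forward <- function(model, images, training = FALSE) {
  x <- as_image_batch(images)
  d <- dim(x)
  check_divisible(d[1], d[2], model$encoder_cfg$levels)
  P <- wrap_params(model)
  out <- cunet_graph(P, ag_const(x), model, training, tape = NULL)
  seg <- out$seg_prob$value; dim(seg) <- c(d[1], d[2], d[4])
  bou <- out$boundary_prob$value; dim(bou) <- c(d[1], d[2], d[4])
  list(seg_prob = seg, boundary_prob = bou)
}

#' Encoder feature pyramid
#'
#' @inheritParams cunet_forward
#' @return list of feature arrays, level l having spatial side input/2^(l-1)
#' @export
cunet_encode <- function(model, images, training = FALSE) {
  x <- as_image_batch(images)
  d <- dim(x)
  check_divisible(d[1], d[2], model$encoder_cfg$levels)
  P <- wrap_params(model)
  pyr <- encode_graph(P, ag_const(x), model, training, tape = NULL)
  lapply(pyr, ag_value)
}

#' Fast normalized weighted fusion
#'
#' Combines equal-shape feature maps as
#' `sum_i ReLU(v_i) x_i / (sum_j ReLU(v_j) + e)`; the ReLU keeps every
#' effective weight non-negative and `e` stabilizes the normalization.
#'
#' @param inputs list of equal-shape numeric arrays
#' @param v numeric vector of learnable scalars, one per input
#' @param e stabilizer constant
#' @return fused array of the common input shape
#' @export
fuse_weighted <- function(inputs, v, e = 1e-4) {
  stopifnot(is.list(inputs), length(inputs) >= 1)
  ag_value(ag_fuse(lapply(inputs, ag_const), ag_const(v), e = e))
}

#' Gating unit
#'
#' Multiplies a feature map by a learned gate
#' `g = dropout(sigmoid(BN(conv_1x1(x))))`, suppressing the response of
#' insignificant regions.
#'
#' @param model a `cunet_model`
#' @param feature array (H, W, fpn_channels, N) at one of the gated levels
#' @param level which pyramid level's gate parameters to use
#' @param training logical
#' @return gated array, same shape as `feature`
#' @export
cunet_gate <- function(model, feature, level = min(model$csfi_cfg$levels_used),
                       training = FALSE) {
  P <- wrap_params(model)
  ag_value(gate_graph(ag_const(feature), sprintf("gate.p%d", level),
                      P, model, training, tape = NULL))
}

#' CSFI: stacked bidirectional weighted-fusion pyramid
#'
#' Projects the used encoder levels to the working width, gates them, and
#' runs `n_layers` top-down + bottom-up weighted fusion passes.
#'
#' @param model a `cunet_model`
#' @param pyramid encoder pyramid as returned by [cunet_encode()]
#' @param training logical
#' @return named list (by level) of fused arrays at `fpn_channels` width
#' @export
csfi_forward <- function(model, pyramid, training = FALSE) {
  lvs <- model$csfi_cfg$levels_used
  if (length(pyramid) < max(lvs)) {
    stop("pyramid has ", length(pyramid), " levels but levels_used needs ",
         max(lvs))
  }
  P <- wrap_params(model)
  nodes <- lapply(pyramid, ag_const)
  lat <- lateral_graph(P, nodes, model, training, tape = NULL)
  lapply(csfi_graph(P, lat, model, training, tape = NULL), ag_value)
}

#' Wide context unit forward pass
#'
#' `branch1 = conv_1xN(conv_Nx1(x))`, `branch2 = conv_Nx1(conv_1xN(x))`,
#' output = branch1 + branch2, spatial shape preserved by same-padding.
#'
#' @param feature array (H, W, C, N)
#' @param weights named list with elements `a1`, `a2`, `b1`, `b2`, each a
#'   list(w, b); defaults to the model's own WCU parameters when a
#'   `cunet_model` is given
#' @return array of the same spatial shape
#' @export
wcu_forward <- function(feature, weights) {
  if (inherits(weights, "cunet_model")) {
    m <- weights
    weights <- list(
      a1 = list(w = m$params[["wcu.a1.w"]], b = m$params[["wcu.a1.b"]]),
      a2 = list(w = m$params[["wcu.a2.w"]], b = m$params[["wcu.a2.b"]]),
      b1 = list(w = m$params[["wcu.b1.w"]], b = m$params[["wcu.b1.b"]]),
      b2 = list(w = m$params[["wcu.b2.w"]], b = m$params[["wcu.b2.b"]]))
  }
  for (nm in c("a1", "a2", "b1", "b2")) {
    kd <- dim(weights[[nm]]$w)
    if (max(kd[1:2]) %% 2L == 0L) {
      stop("WCU kernel extent must be odd, got ", max(kd[1:2]))
    }
  }
  x <- ag_const(feature)
  P <- list(
    "wcu.a1.w" = weights$a1$w, "wcu.a1.b" = weights$a1$b,
    "wcu.a2.w" = weights$a2$w, "wcu.a2.b" = weights$a2$b,
    "wcu.b1.w" = weights$b1$w, "wcu.b1.b" = weights$b1$b,
    "wcu.b2.w" = weights$b2$w, "wcu.b2.b" = weights$b2$b)
  P <- lapply(P, ag_const)
  ag_value(wcu_graph(P, x, tape = NULL))
}

#' Interconnected dual decoder
#'
#' Two coupled top-down decoders: the segmentation path fuses CSFI features
#' with its own upsampled state; the boundary path consumes the segmentation
#' features (one-way coupling). Both heads end in a 3x3 + 1x1 refinement
#' unit, bilinear upsampling to the output size, a 1x1 conv and a sigmoid.
#'
#' @param model a `cunet_model`
#' @param csfi_pyramid named list from [csfi_forward()]
#' @param wcu_feature array from [wcu_forward()]
#' @param out_size integer c(H, W) of the network input
#' @param training logical
#' @return list with `seg_prob` and `boundary_prob`, each H x W x N
#' @export
decode_dual <- function(model, csfi_pyramid, wcu_feature, out_size,
                        training = FALSE) {
  P <- wrap_params(model)
  nodes <- lapply(csfi_pyramid, ag_const)
  out <- decode_graph(P, nodes, ag_const(wcu_feature),
                      out_size[1], out_size[2], model, training, tape = NULL)
  n <- dim(out$seg_prob$value)[4]
  seg <- out$seg_prob$value; dim(seg) <- c(out_size[1], out_size[2], n)
  bou <- out$boundary_prob$value; dim(bou) <- c(out_size[1], out_size[2], n)
  list(seg_prob = seg, boundary_prob = bou)
}
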