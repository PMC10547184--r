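#' @useDynLib cunet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Reverse-mode autodiff on a dynamic tape.
#
# Values are plain R arrays with layout (H, W, C, N) for feature maps; scalars
# and vectors are allowed wherever elementwise semantics make sense. A node is
# an environment holding the value, its parents and a backward closure that
# maps the incoming gradient to per-parent gradients. Nodes are recorded on a
# tape in creation order; `ag_backward()` walks the tape in reverse. When no
# tape is supplied (inference) the parent links are dropped so intermediates
# can be garbage-collected.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ag_node <- function(value, parents = list(), backward = NULL, tape = NULL,
                    requires = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  if (is.null(requires)) {
    requires <- any(vapply(parents, function(p) isTRUE(p$requires), logical(1)))
  }
  n$requires <- requires
  n$grad <- NULL
  if (!is.null(tape) && requires) {
    n$parents <- parents
    n$backward <- backward
    if (tape$n == length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- n
  } else {
    n$parents <- list()
    n$backward <- NULL
  }
  class(n) <- "ag_node"
  n
}

ag_var <- function(value, tape) {
  ag_node(value, tape = tape, requires = TRUE)
}

ag_const <- function(value) {
  ag_node(value, requires = FALSE)
}

as_node <- function(x) {
  if (inherits(x, "ag_node")) x else ag_const(x)
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

# Accumulate `g` into node's grad slot, collapsing to scalar if needed.
ag_accum <- function(node, g) {
  if (length(node$value) == 1L && length(g) > 1L) g <- sum(g)
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Run reverse-mode differentiation from a scalar root node
#'
#' Seeds the root gradient with 1 and walks the tape in reverse creation
#' order, accumulating gradients into every recorded node.
#' @param tape tape created with the internal tape constructor
#' @param root scalar output node
#' @keywords internal
ag_backward <- function(tape, root) {
  stopifnot(length(root$value) == 1L)
  root$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    n <- tape$nodes[[i]]
    if (is.null(n$grad) || is.null(n$backward)) next
    gs <- n$backward(n$grad)
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      if (isTRUE(p$requires) && !is.null(gs[[k]])) ag_accum(p, gs[[k]])
    }
  }
  invisible(NULL)
}

# --- elementwise / scalar ops -----------------------------------------------

# broadcast check: identical dims, or one side scalar
check_ew <- function(a, b) {
  if (length(a$value) == 1L || length(b$value) == 1L) return(invisible(NULL))
  if (!identical(dim2(a$value), dim2(b$value))) {
    stop("elementwise op on mismatched shapes: (",
         paste(dim2(a$value), collapse = "x"), ") vs (",
         paste(dim2(b$value), collapse = "x"), ")")
  }
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

ag_add <- function(a, b, tape = NULL) {
  a <- as_node(a); b <- as_node(b); check_ew(a, b)
  ag_node(a$value + b$value, list(a, b),
          function(g) list(g, g), tape)
}

ag_sub <- function(a, b, tape = NULL) {
  a <- as_node(a); b <- as_node(b); check_ew(a, b)
  ag_node(a$value - b$value, list(a, b),
          function(g) list(g, -g), tape)
}

ag_mul <- function(a, b, tape = NULL) {
  a <- as_node(a); b <- as_node(b); check_ew(a, b)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b),
          function(g) list(g * bv, g * av), tape)
}

ag_div <- function(a, b, tape = NULL) {
  a <- as_node(a); b <- as_node(b); check_ew(a, b)
  av <- a$value; bv <- b$value
  ag_node(av / bv, list(a, b),
          function(g) list(g / bv, -g * av / bv^2), tape)
}

ag_pow <- function(a, p, tape = NULL) {
  a <- as_node(a)
  av <- a$value
  ag_node(av^p, list(a),
          function(g) list(g * p * av^(p - 1)), tape)
}

ag_log <- function(a, tape = NULL) {
  a <- as_node(a)
  av <- a$value
  ag_node(log(av), list(a), function(g) list(g / av), tape)
}

ag_clamp <- function(a, lo, hi, tape = NULL) {
  a <- as_node(a)
  av <- a$value
  inside <- (av >= lo) & (av <= hi)
  y <- pmin(pmax(av, lo), hi)
  if (!is.null(dim(av))) dim(y) <- dim(av)
  ag_node(y, list(a), function(g) list(g * inside), tape)
}

ag_relu <- function(a, tape = NULL) {
  a <- as_node(a)
  av <- a$value
  pos <- av > 0
  y <- av * pos
  ag_node(y, list(a), function(g) list(g * pos), tape)
}

ag_sigmoid <- function(a, tape = NULL) {
  a <- as_node(a)
  s <- 1 / (1 + exp(-a$value))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)), tape)
}

ag_sum <- function(a, tape = NULL) {
  a <- as_node(a)
  d <- dim2(a$value)
  ag_node(sum(a$value), list(a),
          function(g) list(array(g, d)), tape)
}

# Sum over all but the batch (last) dimension of a 4-d tensor -> length-N vector.
ag_sum_spatial <- function(a, tape = NULL) {
  a <- as_node(a)
  d <- dim(a$value)
  stopifnot(length(d) == 4L)
  m <- matrix(a$value, ncol = d[4])
  ag_node(colSums(m), list(a),
          function(g) list(array(rep(g, each = prod(d[1:3])), d)), tape)
}

ag_mean_vec <- function(a, tape = NULL) {
  a <- as_node(a)
  k <- length(a$value)
  ag_node(mean(a$value), list(a), function(g) list(rep(g / k, k)), tape)
}

# --- network ops ------------------------------------------------------------

ag_conv2d <- function(x, w, b = NULL, tape = NULL) {
  x <- as_node(x); w <- as_node(w)
  if (is.null(b)) b <- numeric(dim(w$value)[4])  # bias-free conv (pre-BN)
  b <- as_node(b)
  y <- .cpp_conv2d_forward(x$value, w$value, b$value)
  xv <- x$value; wv <- w$value
  need_gx <- isTRUE(x$requires)
  ag_node(y, list(x, w, b), function(g) {
    dim(g) <- dim(y)
    bk <- .cpp_conv2d_backward(xv, wv, g, need_gx)
    list(if (need_gx) bk$gx else NULL, bk$gw, bk$gb)
  }, tape)
}

ag_maxpool2 <- function(x, tape = NULL) {
  x <- as_node(x)
  fw <- .cpp_maxpool2_forward(x$value)
  ind <- dim(x$value)
  ag_node(fw$y, list(x), function(g) {
    list(.cpp_maxpool2_backward(as.numeric(g), fw$argmax, ind))
  }, tape)
}

ag_resize_bilinear <- function(x, oh, ow, tape = NULL) {
  x <- as_node(x)
  d <- dim(x$value)
  if (d[1] == oh && d[2] == ow) return(x)
  y <- .cpp_resize_bilinear_forward(x$value, as.integer(oh), as.integer(ow))
  ag_node(y, list(x), function(g) {
    dim(g) <- dim(y)
    list(.cpp_resize_bilinear_backward(g, d[1], d[2]))
  }, tape)
}

# Batch normalization over (H, W, N) per channel. `state` is an environment
# holding running_mean / running_var, updated as a side effect in training
# mode with momentum `momentum` (running <- momentum * running + (1-m) * batch).
ag_batchnorm <- function(x, gamma, beta, state, training, tape = NULL,
                         momentum = 0.99, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  d <- dim(x$value)
  C <- d[3]
  m <- prod(d) / C
  # channel-major matrix view: rows = H*W*N samples, cols = C
  xm <- matrix(aperm(x$value, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    state$running_mean <- momentum * state$running_mean + (1 - momentum) * mu
    state$running_var <- momentum * state$running_var + (1 - momentum) * va
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, istd, "*")
  ym <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  y <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  ag_node(y, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(array(g, d), c(1, 2, 4, 3)), ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- sweep(gm, 2, gamma$value, "*")
    if (training) {
      dxm <- sweep(
        dxhat -
          matrix(rep(colMeans(dxhat), each = nrow(gm)), ncol = C) -
          xhat * matrix(rep(colMeans(dxhat * xhat), each = nrow(gm)), ncol = C),
        2, istd, "*")
    } else {
      dxm <- sweep(dxhat, 2, istd, "*")
    }
    gx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
    list(gx, dgamma, dbeta)
  }, tape)
}

ag_dropout <- function(x, rate, training, tape = NULL) {
  x <- as_node(x)
  if (!training || rate <= 0) return(x)
  keep <- (stats::runif(length(x$value)) >= rate) / (1 - rate)
  dim(keep) <- dim(x$value)
  ag_node(x$value * keep, list(x), function(g) list(g * keep), tape)
}

# Fast normalized fusion: sum_i ReLU(v_i) x_i / (sum_j ReLU(v_j) + e).
# `xs` is a list of equal-shape nodes, `v` a vector node of the same length.
ag_fuse <- function(xs, v, e = 1e-4, tape = NULL) {
  xs <- lapply(xs, as_node)
  v <- as_node(v)
  k <- length(xs)
  if (length(v$value) != k) {
    stop("fusion weight vector has length ", length(v$value),
         " but ", k, " inputs were given")
  }
  d0 <- dim2(xs[[1]]$value)
  for (i in seq_along(xs)) {
    if (!identical(dim2(xs[[i]]$value), d0)) {
      stop("fusion input ", i, " has shape (",
           paste(dim2(xs[[i]]$value), collapse = "x"),
           "), expected (", paste(d0, collapse = "x"), ")")
    }
  }
  r <- pmax(v$value, 0)
  S <- sum(r) + e
  out <- xs[[1]]$value * (r[1] / S)
  if (k > 1) for (i in 2:k) out <- out + xs[[i]]$value * (r[i] / S)
  vals <- lapply(xs, function(x) x$value)
  ag_node(out, c(xs, list(v)), function(g) {
    gx <- lapply(seq_len(k), function(i) g * (r[i] / S))
    gv <- vapply(seq_len(k), function(i) {
      if (v$value[i] > 0) sum(g * (vals[[i]] - out)) / S else 0
    }, numeric(1))
    c(gx, list(gv))
  }, tape)
}
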