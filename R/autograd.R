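#' @useDynLib medusa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ------------------------------------------------------------------------
# Reverse-mode autodiff tape.
#
# A tape records nodes in creation (topological) order. Each node is an
# environment holding the forward value, the accumulated gradient, its
# parent nodes, and a backward closure mapping the node's output gradient
# to a list of parent gradients. ag_backward() walks the tape in reverse.
#
# Tensors are plain R arrays, dim (H, W, C); vectors are plain numerics.
# ------------------------------------------------------------------------

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ag_node <- function(tape, value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- node
  node
}

# Leaf node (input or parameter); gradients accumulate into $grad.
ag_leaf <- function(tape, value) ag_node(tape, value)

ag_backward <- function(tape, root) {
  root$grad <- if (length(root$value) == 1L) 1 else array(1, dim = dim(root$value))
  for (i in seq.int(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    pg <- node$backward(node$grad)
    for (k in seq_along(node$parents)) {
      if (is.null(pg[[k]])) next
      p <- node$parents[[k]]
      p$grad <- if (is.null(p$grad)) pg[[k]] else p$grad + pg[[k]]
    }
  }
  invisible(NULL)
}

# --- primitive ops -------------------------------------------------------

op_conv2d <- function(tape, x, w, b, stride = 1L) {
  out <- .conv2d_fwd(x$value, w$value, b$value, as.integer(stride))
  ag_node(tape, out, list(x, w, b), function(g) {
    gr <- .conv2d_bwd(x$value, w$value, g, as.integer(stride))
    list(gr$dx, gr$dw, gr$db)
  })
}

op_relu <- function(tape, x) {
  mask <- x$value > 0
  ag_node(tape, x$value * mask, list(x), function(g) list(g * mask))
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  ag_node(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

op_maxpool2 <- function(tape, x) {
  f <- .maxpool2_fwd(x$value)
  xd <- dim(x$value)
  ag_node(tape, f$out, list(x), function(g) list(.maxpool2_bwd(g, f$idx, xd)))
}

op_upnearest2 <- function(tape, x) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = 2L)
  rj <- rep(seq_len(d[2]), each = 2L)
  out <- x$value[ri, rj, , drop = FALSE]
  ag_node(tape, out, list(x), function(g) {
    # sum each 2x2 block back onto the source pixel
    g1 <- g[seq(1L, 2L * d[1], 2L), , , drop = FALSE] +
      g[seq(2L, 2L * d[1], 2L), , , drop = FALSE]
    dx <- g1[, seq(1L, 2L * d[2], 2L), , drop = FALSE] +
      g1[, seq(2L, 2L * d[2], 2L), , drop = FALSE]
    list(dx)
  })
}

op_bilinear <- function(tape, x, th, tw) {
  xd <- dim(x$value)
  out <- .bilinear_fwd(x$value, as.integer(th), as.integer(tw))
  ag_node(tape, out, list(x), function(g) list(.bilinear_bwd(g, xd)))
}

op_concat_c <- function(tape, a, b) {
  da <- dim(a$value); db <- dim(b$value)
  out <- array(c(a$value, b$value), dim = c(da[1], da[2], da[3] + db[3]))
  ag_node(tape, out, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), drop = FALSE],
         g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

op_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

# Residual attention gating: out = a * f + f  (a: attention map, f: features)
op_gate <- function(tape, a, f) {
  ag_node(tape, a$value * f$value + f$value, list(a, f), function(g) {
    list(g * f$value, g * (a$value + 1))
  })
}

op_gap <- function(tape, x) {
  d <- dim(x$value)
  out <- apply(x$value, 3L, mean)
  ag_node(tape, out, list(x), function(g) {
    list(array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), dim = d))
  })
}

op_dense <- function(tape, x, w, b) {
  out <- drop(crossprod(w$value, x$value)) + b$value
  ag_node(tape, out, list(x, w, b), function(g) {
    list(drop(w$value %*% g), outer(x$value, g), g)
  })
}

# Softmax + cross-entropy against an integer class label (1-based).
op_softmax_ce <- function(tape, logits, label) {
  z <- logits$value - max(logits$value)
  p <- exp(z) / sum(exp(z))
  loss <- -log(max(p[label], 1e-12))
  node <- ag_node(tape, loss, list(logits), function(g) {
    d <- p
    d[label] <- d[label] - 1
    list(g * d)
  })
  node$probs <- p
  node
}

# Mean of a list of scalar nodes.
op_mean_scalars <- function(tape, nodes) {
  n <- length(nodes)
  val <- mean(vapply(nodes, function(x) x$value, numeric(1)))
  ag_node(tape, val, nodes, function(g) rep(list(g / n), n))
}

# Equally weighted binary cross-entropy + soft-Dice loss between a
# predicted probability map p in (0,1) and a binary mask m (same dims).
op_bce_dice <- function(tape, p, mask) {
  eps <- 1e-7
  pv <- pmin(pmax(p$value, eps), 1 - eps)
  m <- mask
  n <- length(m)
  bce <- -mean(m * log(pv) + (1 - m) * log(1 - pv))
  sp <- sum(pv); sm <- sum(m); si <- sum(pv * m)
  dice <- (2 * si + eps) / (sp + sm + eps)
  loss <- 0.5 * bce + 0.5 * (1 - dice)
  ag_node(tape, loss, list(p), function(g) {
    dbce <- (pv - m) / (pv * (1 - pv)) / n
    ddice <- (2 * m * (sp + sm + eps) - (2 * si + eps)) / (sp + sm + eps)^2
    list(g * (0.5 * dbce - 0.5 * ddice))
  })
}
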