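# Encoder-decoder producing the raw global attention map: a U-Net-style
# downsampling path to a latent map, then an upsampling path with skip
# connections restoring the input resolution. Upsampling is
# nearest-neighbour + convolution (no transposed convolutions), which
# avoids checkerboard artifacts in the attention maps.

#' Encoder-decoder configuration
#'
#' @param depth Number of downsampling levels; the input side must be
#'   divisible by `2^depth`.
#' @param base_channels Channels at the first level; doubled per level.
#' @param in_channels Input image channels.
#' @param out_channels Channels of the raw attention map.
#' @param skip_connections Wire encoder levels into the decoder.
#' @return Object of class `encdec_config`.
#' @export
encdec_config <- function(depth = 4L, base_channels = 16L, in_channels = 1L,
                          out_channels = 1L, skip_connections = TRUE) {
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 skip_connections = isTRUE(skip_connections)),
            class = "encdec_config")
}

check_divisible <- function(size, depth, what = "input size") {
  if (size %% 2^depth != 0) {
    stop(what, " ", size, " is not divisible by 2^depth = ", 2^depth,
         call. = FALSE)
  }
  invisible(size)
}

# He-normal initialization for a conv kernel (k, k, c_in, c_out).
init_conv <- function(k, c_in, c_out) {
  array(stats::rnorm(k * k * c_in * c_out, sd = sqrt(2 / (k * k * c_in))),
        dim = c(k, k, c_in, c_out))
}

encdec_channels <- function(cfg) cfg$base_channels * 2^(seq_len(cfg$depth) - 1L)

#' Initialize encoder-decoder parameters
#'
#' @param cfg An [encdec_config()].
#' @param seed RNG seed for the He-normal draws.
#' @return Named list of parameter arrays (names prefixed `encdec.`).
#' @export
encdec_init <- function(cfg, seed = 0L) {
  with_local_seed(as.integer(seed) + 271L, {
    ch <- encdec_channels(cfg)
    p <- list()
    prev <- cfg$in_channels
    for (i in seq_len(cfg$depth)) {
      p[[sprintf("encdec.enc%d.W", i)]] <- init_conv(3L, prev, ch[i])
      p[[sprintf("encdec.enc%d.b", i)]] <- numeric(ch[i])
      prev <- ch[i]
    }
    p[["encdec.bottleneck.W"]] <- init_conv(3L, prev, prev)
    p[["encdec.bottleneck.b"]] <- numeric(prev)
    for (i in rev(seq_len(cfg$depth))) {
      p[[sprintf("encdec.dec%d.upW", i)]] <- init_conv(3L, prev, ch[i])
      p[[sprintf("encdec.dec%d.upb", i)]] <- numeric(ch[i])
      cin <- if (cfg$skip_connections) 2L * ch[i] else ch[i]
      p[[sprintf("encdec.dec%d.W", i)]] <- init_conv(3L, cin, ch[i])
      p[[sprintf("encdec.dec%d.b", i)]] <- numeric(ch[i])
      prev <- ch[i]
    }
    p[["encdec.out.W"]] <- init_conv(1L, prev, cfg$out_channels)
    p[["encdec.out.b"]] <- numeric(cfg$out_channels)
    p
  })
}

# Build the encoder subgraph on a tape. `pn(name)` returns the leaf node
# for a parameter. Returns list(latent, skips).
encoder_graph <- function(tape, xnode, pn, cfg) {
  skips <- vector("list", cfg$depth)
  cur <- xnode
  for (i in seq_len(cfg$depth)) {
    cur <- op_relu(tape, op_conv2d(tape, cur,
                                   pn(sprintf("encdec.enc%d.W", i)),
                                   pn(sprintf("encdec.enc%d.b", i))))
    skips[[i]] <- cur
    cur <- op_maxpool2(tape, cur)
  }
  latent <- op_relu(tape, op_conv2d(tape, cur, pn("encdec.bottleneck.W"),
                                    pn("encdec.bottleneck.b")))
  list(latent = latent, skips = skips)
}

decoder_graph <- function(tape, latent, skips, pn, cfg) {
  cur <- latent
  for (i in rev(seq_len(cfg$depth))) {
    cur <- op_upnearest2(tape, cur)
    cur <- op_relu(tape, op_conv2d(tape, cur,
                                   pn(sprintf("encdec.dec%d.upW", i)),
                                   pn(sprintf("encdec.dec%d.upb", i))))
    if (cfg$skip_connections) {
      sk <- skips[[i]]
      if (!identical(dim(sk$value)[1:2], dim(cur$value)[1:2])) {
        stop("decoder: skip tensor at level ", i, " has spatial dims ",
             paste(dim(sk$value)[1:2], collapse = "x"),
             " but the decoder path has ",
             paste(dim(cur$value)[1:2], collapse = "x"), call. = FALSE)
      }
      cur <- op_concat_c(tape, cur, sk)
    }
    cur <- op_relu(tape, op_conv2d(tape, cur,
                                   pn(sprintf("encdec.dec%d.W", i)),
                                   pn(sprintf("encdec.dec%d.b", i))))
  }
  op_conv2d(tape, cur, pn("encdec.out.W"), pn("encdec.out.b"))
}

encdec_graph <- function(tape, xnode, pn, cfg) {
  enc <- encoder_graph(tape, xnode, pn, cfg)
  raw <- decoder_graph(tape, enc$latent, enc$skips, pn, cfg)
  list(raw = raw, latent = enc$latent, skips = enc$skips)
}

# Leaf-node cache over a parameter list; grads are read back by name.
param_nodes <- function(tape, params) {
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    if (is.null(params[[name]])) stop("unknown parameter: ", name, call. = FALSE)
    cache[[name]] <- ag_leaf(tape, params[[name]])
    cache[[name]]
  }
}

#' Encode an image to the latent map
#'
#' @param x (h, w, c) image array; side divisible by `2^depth`.
#' @param params Parameters from [encdec_init()] (or pretraining).
#' @param cfg The matching [encdec_config()].
#' @return List with `latent` ((h/2^depth, w/2^depth, c') array) and
#'   `skips` (one array per level).
#' @export
encode <- function(x, params, cfg) {
  x <- as_hwc(x)
  check_divisible(dim(x)[1], cfg$depth)
  check_divisible(dim(x)[2], cfg$depth)
  tape <- ag_tape()
  pn <- param_nodes(tape, params)
  enc <- encoder_graph(tape, ag_leaf(tape, x), pn, cfg)
  list(latent = enc$latent$value,
       skips = lapply(enc$skips, function(s) s$value))
}

#' Decode a latent map into the raw global attention map
#'
#' @param z Latent array from [encode()].
#' @param skips Skip tensors from [encode()] (one per level).
#' @param params,cfg As in [encode()].
#' @return Raw attention map with the original input's spatial dims and
#'   `out_channels` channels.
#' @export
decode <- function(z, skips, params, cfg) {
  if (length(skips) != cfg$depth) {
    stop("decode: got ", length(skips), " skip tensors for depth ", cfg$depth,
         call. = FALSE)
  }
  tape <- ag_tape()
  pn <- param_nodes(tape, params)
  sk <- lapply(skips, function(s) ag_leaf(tape, as_hwc(s)))
  decoder_graph(tape, ag_leaf(tape, as_hwc(z)), sk, pn, cfg)$value
}

#' Full encoder-decoder forward pass
#'
#' @inheritParams encode
#' @return Raw (pre-logistic) global attention map, dim `(h, w, out_channels)`.
#' @export
global_forward <- function(x, params, cfg) {
  x <- as_hwc(x)
  check_divisible(dim(x)[1], cfg$depth)
  tape <- ag_tape()
  pn <- param_nodes(tape, params)
  raw <- encdec_graph(tape, ag_leaf(tape, x), pn, cfg)$raw$value
  if (any(!is.finite(raw))) {
    stop("global_forward: non-finite values in the decoder output", call. = FALSE)
  }
  raw
}
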