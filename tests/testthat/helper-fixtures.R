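# Shared fixtures. Heavy objects are memoized so several test files can
# reuse one computation.

tiny_spec <- function(size = 32L) phantom_spec(image_size = size)

tiny_config <- function(...) {
  run_config(image_size = 32L, encdec_depth = 2L, encdec_base_channels = 4L,
             backbone_channels = c(4L, 8L), batch_size = 4L,
             learning_rate = 1e-2, epochs = 4L, ...)
}

tiny_samples <- function(n, size = 32L, seed0 = 0L, labels = NULL) {
  spec <- tiny_spec(size)
  lapply(seq_len(n), function(i) {
    lab <- if (is.null(labels)) (i %% 2L) else labels[i]
    generate_sample(spec, seed0 + i, label = lab)
  })
}

# Independent direct evaluation of the half-pixel-center bilinear formula.
bilinear_oracle <- function(x, th, tw) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, th, tw)
  for (i in seq_len(th)) {
    for (j in seq_len(tw)) {
      sy <- min(max((i - 0.5) * H / th - 0.5, 0), H - 1)
      sx <- min(max((j - 0.5) * W / tw - 0.5, 0), W - 1)
      i0 <- floor(sy); i1 <- min(i0 + 1, H - 1); wy <- sy - i0
      j0 <- floor(sx); j1 <- min(j0 + 1, W - 1); wx <- sx - j0
      out[i, j] <- (1 - wy) * (1 - wx) * x[i0 + 1, j0 + 1] +
        wy * (1 - wx) * x[i1 + 1, j0 + 1] +
        (1 - wy) * wx * x[i0 + 1, j1 + 1] +
        wy * wx * x[i1 + 1, j1 + 1]
    }
  }
  out
}

# Independent convolution-sum oracle: same padding, stride 1.
conv_oracle <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Ci <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Co <- dim(w)[4]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  out <- array(0, dim = c(H, W, Co))
  for (co in seq_len(Co)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- b[co]
    for (ci in seq_len(Ci)) for (a in seq_len(kh)) for (d in seq_len(kw)) {
      ii <- i + a - 1 - ph; jj <- j + d - 1 - pw
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
        acc <- acc + x[ii, jj, ci] * w[a, d, ci, co]
      }
    }
    out[i, j, co] <- acc
  }
  out
}

# Memoized phantom dataset on disk, shared across test files.
shared_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "medusa-shared-ds")
      spec <- tiny_spec(32L)
      manifest <- generate_dataset(24, 0.5, spec, seed = 42, out_dir = dir)
      cache <<- list(manifest = manifest, dir = dir, spec = spec)
    }
    cache
  }
})
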