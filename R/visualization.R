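# Attention visualizations: blue-to-red heat-map overlays of the bounded
# global attention map, and per-block normalized attention-enforced
# activation panels (whiter = higher attention-enforced activation).

#' Attention colormap
#'
#' @param name `"blue_red"` (jet-like blue -> cyan -> yellow -> red) or
#'   `"gray"`.
#' @return A function mapping values in \[0, 1\] to an (n, 3) RGB matrix
#'   in \[0, 1\].
#' @export
attention_colormap <- function(name = "blue_red") {
  ramp <- switch(name,
    blue_red = grDevices::colorRamp(c("#00007F", "blue", "cyan", "yellow",
                                      "red", "#7F0000")),
    gray = grDevices::colorRamp(c("black", "white")),
    stop("attention_colormap: unknown colormap '", name, "'", call. = FALSE))
  function(v) ramp(pmin(pmax(v, 0), 1)) / 255
}

#' Heat-map overlay of the global attention map
#'
#' Rescales the bounded map to span \[0, 1\] (so the most-attended pixel
#' maps to the colormap's top, red, entry), applies a blue-to-red
#' colormap and alpha-blends it over the grayscale image. Red regions
#' indicate higher global attention, blue regions lower.
#'
#' @param image (h, w, 1) array or matrix in \[0, 1\].
#' @param map Bounded attention map; resized to the image dims if needed.
#' @param alpha Blend factor of the colormap layer.
#' @param colormap Colormap name, see [attention_colormap()].
#' @return (h, w, 3) RGB array in \[0, 1\].
#' @export
global_heatmap_overlay <- function(image, map, alpha = 0.5,
                                   colormap = "blue_red") {
  img <- as_hwc(image)[, , 1]
  m <- as_hwc(map)
  if (dim(m)[3] > 1L) m <- array(apply(m, c(1, 2), mean), dim = c(dim(m)[1:2], 1L))
  if (!identical(dim(m)[1:2], dim(img))) {
    m <- array(resize_bilinear(m, dim(img)), dim = c(dim(img), 1L))
  }
  v <- m[, , 1]
  rng <- range(v)
  if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1])
  cmap <- attention_colormap(colormap)
  rgb <- cmap(as.vector(v))
  out <- array(0, dim = c(dim(img), 3L))
  for (k in 1:3) {
    out[, , k] <- (1 - alpha) * img + alpha * matrix(rgb[, k], nrow(img), ncol(img))
  }
  pmin(pmax(out, 0), 1)
}

#' Normalize an activation map for display
#'
#' Channel-mean (or channel-max) reduction followed by min-max
#' normalization to \[0, 1\]; a spatially constant map normalizes to all
#' zeros. Invariant under positive affine transforms of the input.
#'
#' @param activation (h, w, c) array, e.g. an attended feature map.
#' @param reduce `"mean"` (default) or `"max"` across channels.
#' @return (h, w) matrix in \[0, 1\].
#' @export
normalize_activation <- function(activation, reduce = c("mean", "max")) {
  reduce <- match.arg(reduce)
  a <- as_hwc(activation)
  if (any(!is.finite(a))) stop("normalize_activation: non-finite input", call. = FALSE)
  r <- apply(a, c(1, 2), if (reduce == "mean") mean else max)
  rng <- range(r)
  if (rng[2] - rng[1] <= 0) return(matrix(0, nrow(r), ncol(r)))
  (r - rng[1]) / (rng[2] - rng[1])
}

#' Write the attention panel for one image
#'
#' Runs the model on one image and writes the global heat-map overlay
#' plus one normalized attention-enforced activation map per attention
#' head (at the head's native spatial dims), with an index JSON listing
#' the files.
#'
#' @param model A `medusa_model` (ablation mode `full`).
#' @param image (h, w, 1) array at the model's input size.
#' @param out_dir Output directory.
#' @param alpha,colormap Overlay options, see [global_heatmap_overlay()].
#' @param source `"attended"` (default: the gated feature maps) or
#'   `"local"` (the raw scale-specific attention maps).
#' @return Invisibly, the list of files written (global overlay first).
#' @export
attention_panel <- function(model, image, out_dir, alpha = 0.5,
                            colormap = "blue_red",
                            source = c("attended", "local")) {
  source <- match.arg(source)
  if (model$ablation_mode != "full") {
    stop("attention_panel: model must be in ablation mode 'full'", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("attention_panel: cannot create output directory ", out_dir, call. = FALSE)
  }
  b <- forward(model, image, detail = TRUE)
  overlay <- global_heatmap_overlay(image, b$global_maps[[1]], alpha, colormap)
  files <- file.path(out_dir, "global_overlay.png")
  png::writePNG(overlay, files[1])
  maps <- if (source == "attended") b$detail[[1]]$attended else b$detail[[1]]$locals
  for (j in model$attachment_stages) {
    nm <- normalize_activation(maps[[j]])
    f <- file.path(out_dir, sprintf("block%d_%s.png", j, source))
    png::writePNG(round(nm * 255) / 255, f)
    files <- c(files, f)
  }
  jsonlite::write_json(list(files = basename(files), source = source,
                            alpha = alpha, colormap = colormap),
                       file.path(out_dir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

#' Plot a training history
#'
#' @param history History data frame from [train_alternating()].
#' @return A ggplot object (loss and accuracies per epoch).
#' @export
plot_history <- function(history) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_history requires ggplot2", call. = FALSE)
  }
  df <- rbind(
    data.frame(epoch = history$epoch, value = history$mean_loss, what = "loss"),
    data.frame(epoch = history$epoch, value = history$train_acc, what = "train_acc"),
    data.frame(epoch = history$epoch, value = history$val_acc, what = "val_acc"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}
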