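# Image readers, resizing/normalization, manifests and run configuration.

#' Run configuration
#'
#' Holds the training/inference defaults: 480x480 inputs, Adam with
#' learning rate 8e-5 and batch size 16, per-epoch alternation. Any field
#' can be overridden; unknown fields are rejected.
#'
#' @param image_size Square input side in pixels.
#' @param learning_rate Optimizer step size (> 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param optimizer Optimizer name; only `"adam"` is implemented.
#' @param alternation_period_epochs Epochs per alternation phase (>= 1).
#' @param attachment_stages Backbone stage indices carrying attention
#'   heads; `NULL` = every stage.
#' @param seed Base RNG seed.
#' @param encdec_depth Number of downsampling levels in the
#'   encoder-decoder (input size must be divisible by `2^depth`).
#' @param encdec_base_channels Channels of the first encoder level
#'   (doubled per level).
#' @param attention_channels Channels of the global attention map.
#' @param backbone_channels Per-stage channel widths of the `small_cnn`
#'   backbone.
#' @param head_kernel Spatial kernel size of the per-scale projection
#'   convolution (1 or 3).
#' @param heads_train_with Which alternation side owns the per-scale
#'   projections: `"attention"` (default) or `"main"`.
#' @param epochs Default number of training epochs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(image_size = 480L,
                       learning_rate = 0.00008,
                       batch_size = 16L,
                       optimizer = "adam",
                       alternation_period_epochs = 1L,
                       attachment_stages = NULL,
                       seed = 0L,
                       encdec_depth = 4L,
                       encdec_base_channels = 16L,
                       attention_channels = 1L,
                       backbone_channels = c(8L, 16L, 32L),
                       head_kernel = 1L,
                       heads_train_with = "attention",
                       epochs = 10L) {
  cfg <- structure(list(
    image_size = as.integer(image_size),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    optimizer = optimizer,
    alternation_period_epochs = as.integer(alternation_period_epochs),
    attachment_stages = attachment_stages,
    seed = as.integer(seed),
    encdec_depth = as.integer(encdec_depth),
    encdec_base_channels = as.integer(encdec_base_channels),
    attention_channels = as.integer(attention_channels),
    backbone_channels = as.integer(backbone_channels),
    head_kernel = as.integer(head_kernel),
    heads_train_with = heads_train_with,
    epochs = as.integer(epochs)
  ), class = "run_config")
  if (cfg$learning_rate <= 0) stop("run_config: learning_rate must be > 0", call. = FALSE)
  if (cfg$batch_size < 1) stop("run_config: batch_size must be >= 1", call. = FALSE)
  if (cfg$alternation_period_epochs < 1) {
    stop("run_config: alternation_period_epochs must be >= 1", call. = FALSE)
  }
  if (!cfg$optimizer %in% "adam") stop("run_config: unsupported optimizer", call. = FALSE)
  if (!cfg$heads_train_with %in% c("attention", "main")) {
    stop("run_config: heads_train_with must be 'attention' or 'main'", call. = FALSE)
  }
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Unspecified keys take the package defaults; unknown keys raise a
#' validation error rather than being silently ignored.
#'
#' @param path Path to a YAML key-value file, or `NULL` for pure defaults.
#' @param ... Further overrides applied after the file.
#' @return A [run_config()].
#' @export
load_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals <- utils::modifyList(vals, list(...))
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) {
    cat(sprintf("  %-26s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  }
  invisible(x)
}

to_gray <- function(px) {
  d <- dim(px)
  if (is.null(d) || length(d) == 2L) return(as.matrix(px))
  if (d[3] == 1L) return(px[, , 1])
  if (d[3] == 2L) return(px[, , 1])                       # gray + alpha
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

#' Load an image and resize it to a square
#'
#' Reads a PNG (or, via EBImage when installed, a JPEG), converts to a
#' single luminance channel in \[0, 1\] and resizes with the package's
#' half-pixel-center bilinear convention -- the same resampling used for
#' the attention priors.
#'
#' @param path Image file path.
#' @param size Target side length in pixels (default 480).
#' @return An array of shape `(size, size, 1)` with values in \[0, 1\].
#' @export
load_and_resize <- function(path, size = 480L) {
  if (!file.exists(path)) {
    stop("load_and_resize: cannot read image file: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    tryCatch(png::readPNG(path),
             error = function(e) stop("load_and_resize: corrupt PNG: ", path,
                                      call. = FALSE))
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("load_and_resize: JPEG support requires the EBImage package",
           call. = FALSE)
    }
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img)
    if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
  } else {
    stop("load_and_resize: unsupported image format: ", path, call. = FALSE)
  }
  g <- to_gray(px)
  g <- pmin(pmax(g, 0), 1)
  if (all(dim(g) == c(size, size))) {
    return(array(g, dim = c(size, size, 1L)))
  }
  resize_bilinear(array(g, dim = c(dim(g), 1L)), c(size, size))
}

#' Read a dataset manifest
#'
#' @param csv_path CSV file with header `path,mask_path,label,split`
#'   (`mask_path` and `split` optional).
#' @return Data frame with rows in file order and integer labels in
#'   `{0, 1}`.
#' @export
read_manifest <- function(csv_path) {
  if (!file.exists(csv_path)) {
    stop("read_manifest: no such file: ", csv_path, call. = FALSE)
  }
  m <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("path", "label")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop("read_manifest: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(m$label %in% c(0, 1)))
  if (length(bad)) {
    stop("read_manifest: label outside {0,1} at row ", bad[1],
         " (value '", m$label[bad[1]], "')", call. = FALSE)
  }
  m$label <- as.integer(m$label)
  m
}

# Append one JSON record to a JSON-lines run log.
write_run_log <- function(path, record) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

# 8-bit quantization helpers (PNG round-trip exactness).
to_uint8 <- function(x) as.integer(round(x * 255))
from_uint8 <- function(x) x / 255

# Load manifest rows into in-memory samples (image + optional mask/label).
load_manifest_samples <- function(manifest, dir, size, with_masks = FALSE) {
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- load_and_resize(file.path(dir, manifest$path[i]), size)
    mask <- NULL
    if (with_masks) {
      if (is.null(manifest$mask_path) || is.na(manifest$mask_path[i])) {
        stop("manifest row ", i, " has no mask_path", call. = FALSE)
      }
      mk <- load_and_resize(file.path(dir, manifest$mask_path[i]), size)
      mask <- (mk[, , 1] >= 128 / 255) * 1L    # 0/255 PNG thresholded at 128
    }
    list(image = img, lung_mask = mask, label = manifest$label[i])
  })
}
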