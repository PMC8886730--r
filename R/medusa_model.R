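# Classifier assembly: a convolutional backbone whose stage outputs are
# gated by scale-specific attention heads, all fed by one shared
# encoder-decoder global attention map, plus the ablation modes used to
# quantify the mechanism's contribution.

#' Build an attention-gated classifier
#'
#' Assembles a backbone (`small_cnn`: conv-relu-pool stages with the
#' configured widths; `resnet50`: a normalization-free bottleneck-residual
#' backbone with the canonical 3-4-6-3 stage recipe), one attention head
#' per attachment stage, the shared encoder-decoder, and a 2-class
#' softmax head. Heads are attached to stage *outputs*; the gated result
#' feeds the next stage.
#'
#' @param config A [run_config()].
#' @param backbone `"small_cnn"` or `"resnet50"`.
#' @param seed RNG seed for parameter initialization.
#' @param encdec_params Optional pretrained encoder-decoder parameters
#'   (from [pretrain_encoder_decoder()]); default fresh initialization.
#' @return An object of class `medusa_model`.
#' @export
build_model <- function(config = run_config(), backbone = c("small_cnn", "resnet50"),
                        seed = 0L, encdec_params = NULL) {
  backbone <- match.arg(backbone)
  size <- config$image_size
  check_divisible(size, config$encdec_depth, "image_size")

  if (backbone == "small_cnn") {
    widths <- config$backbone_channels
    n_stages <- length(widths)
    check_divisible(size, n_stages, "image_size")
    stage_dims <- size / 2^seq_len(n_stages)
    stage_channels <- widths
  } else {
    blocks <- c(3L, 4L, 6L, 3L)
    widths <- c(64L, 128L, 256L, 512L)
    n_stages <- 4L
    check_divisible(size, 5L, "image_size")   # stem /4 then three stride-2 stages
    stage_dims <- size / c(4L, 8L, 16L, 32L)
    stage_channels <- widths * 4L
  }

  attachment <- config$attachment_stages
  if (is.null(attachment)) attachment <- seq_len(n_stages)
  bad <- setdiff(attachment, seq_len(n_stages))
  if (length(bad)) {
    stop("build_model: attachment stage(s) ", paste(bad, collapse = ", "),
         " out of range; valid stages are 1..", n_stages, call. = FALSE)
  }

  params <- with_local_seed(as.integer(seed) + 7L, {
    p <- list()
    if (backbone == "small_cnn") {
      prev <- 1L
      for (j in seq_len(n_stages)) {
        p[[sprintf("backbone.stage%d.W", j)]] <- init_conv(3L, prev, widths[j])
        p[[sprintf("backbone.stage%d.b", j)]] <- numeric(widths[j])
        prev <- widths[j]
      }
    } else {
      p[["backbone.stem.W"]] <- init_conv(7L, 1L, 64L)
      p[["backbone.stem.b"]] <- numeric(64L)
      prev <- 64L
      for (k in seq_len(4L)) {
        w <- widths[k]; out <- 4L * w
        for (i in seq_len(blocks[k])) {
          nm <- sprintf("backbone.s%db%d", k, i)
          p[[paste0(nm, ".c1.W")]] <- init_conv(1L, prev, w)
          p[[paste0(nm, ".c1.b")]] <- numeric(w)
          p[[paste0(nm, ".c2.W")]] <- init_conv(3L, w, w)
          p[[paste0(nm, ".c2.b")]] <- numeric(w)
          p[[paste0(nm, ".c3.W")]] <- init_conv(1L, w, out)
          p[[paste0(nm, ".c3.b")]] <- numeric(out)
          if (i == 1L) {
            p[[paste0(nm, ".sc.W")]] <- init_conv(1L, prev, out)
            p[[paste0(nm, ".sc.b")]] <- numeric(out)
          }
          prev <- out
        }
      }
    }
    for (j in attachment) {
      # zero-initialized gating: the residual gate starts as the identity,
      # so a pretrained global map is not disturbed before the heads learn
      p[[sprintf("head.%d.W", j)]] <- array(0, dim = c(config$head_kernel,
                                                       config$head_kernel,
                                                       config$attention_channels,
                                                       stage_channels[j]))
      p[[sprintf("head.%d.b", j)]] <- numeric(stage_channels[j])
    }
    c_last <- stage_channels[n_stages]
    p[["classifier.W"]] <- matrix(stats::rnorm(c_last * 2L, sd = sqrt(2 / c_last)),
                                  c_last, 2L)
    p[["classifier.b"]] <- numeric(2L)
    p
  })

  ecfg <- encdec_config(depth = config$encdec_depth,
                        base_channels = config$encdec_base_channels,
                        in_channels = 1L,
                        out_channels = config$attention_channels)
  if (is.null(encdec_params)) encdec_params <- encdec_init(ecfg, seed)
  params <- c(params, encdec_params)

  model <- structure(list(
    backbone = backbone,
    n_stages = n_stages,
    stage_channels = stage_channels,
    stage_dims = stage_dims,
    blocks = if (backbone == "resnet50") blocks else NULL,
    attachment_stages = attachment,
    params = params,
    config = config,
    encdec_cfg = ecfg,
    ablation_mode = "full",
    seed = as.integer(seed)
  ), class = "medusa_model")
  model$n_params <- sum(vapply(params, length, integer(1)))
  model
}

ablation_modes <- c("full", "attention_disabled", "seg_input_only",
                    "seg_input_additive")

#' Set the model's ablation mode
#'
#' `attention_disabled` bypasses every residual gate (attended = features);
#' `seg_input_only` feeds `image * lung_mask`; `seg_input_additive` feeds
#' `clip(image + image * lung_mask, 0, 1)` -- both segmentation-input
#' modes run the bare backbone without attention heads. `full` restores
#' normal operation.
#'
#' @param model A `medusa_model`.
#' @param mode One of `r paste0('"', ablation_modes, '"', collapse = ", ")`.
#' @return The model with the mode set.
#' @export
set_ablation <- function(model, mode) {
  if (!mode %in% ablation_modes) {
    stop("set_ablation: unknown mode '", mode, "'; expected one of ",
         paste(ablation_modes, collapse = ", "), call. = FALSE)
  }
  model$ablation_mode <- mode
  model
}

# Run one backbone stage (pre-gate) on the tape.
run_stage <- function(model, tape, pn, cur, j) {
  if (model$backbone == "small_cnn") {
    cur <- op_relu(tape, op_conv2d(tape, cur,
                                   pn(sprintf("backbone.stage%d.W", j)),
                                   pn(sprintf("backbone.stage%d.b", j))))
    return(op_maxpool2(tape, cur))
  }
  if (j == 1L) {
    cur <- op_relu(tape, op_conv2d(tape, cur, pn("backbone.stem.W"),
                                   pn("backbone.stem.b"), stride = 2L))
    cur <- op_maxpool2(tape, cur)
  }
  stride1 <- if (j == 1L) 1L else 2L
  for (i in seq_len(model$blocks[j])) {
    nm <- sprintf("backbone.s%db%d", j, i)
    s <- if (i == 1L) stride1 else 1L
    sc <- if (i == 1L) {
      op_conv2d(tape, cur, pn(paste0(nm, ".sc.W")), pn(paste0(nm, ".sc.b")),
                stride = s)
    } else cur
    h <- op_relu(tape, op_conv2d(tape, cur, pn(paste0(nm, ".c1.W")),
                                 pn(paste0(nm, ".c1.b"))))
    h <- op_relu(tape, op_conv2d(tape, h, pn(paste0(nm, ".c2.W")),
                                 pn(paste0(nm, ".c2.b")), stride = s))
    h <- op_conv2d(tape, h, pn(paste0(nm, ".c3.W")), pn(paste0(nm, ".c3.b")))
    cur <- op_relu(tape, op_add(tape, h, sc))
  }
  cur
}

# Apply the configured ablation mode to an input image (plain arrays).
transform_input <- function(model, x, mask) {
  mode <- model$ablation_mode
  if (mode %in% c("seg_input_only", "seg_input_additive")) {
    if (is.null(mask)) {
      stop("forward: ablation mode '", mode, "' requires a lung mask per sample",
           call. = FALSE)
    }
    m <- array(mask, dim = dim(x))
    x <- if (mode == "seg_input_only") x * m else pmin(x + x * m, 1)
  }
  x
}

# Build the full per-sample graph. Returns nodes.
model_graph <- function(model, tape, pn, x, mask = NULL) {
  x <- transform_input(model, as_hwc(x), mask)
  xin <- ag_leaf(tape, x)
  use_attn <- model$ablation_mode == "full"
  sig <- NULL
  if (use_attn) {
    ed <- encdec_graph(tape, xin, pn, model$encdec_cfg)
    sig <- op_sigmoid(tape, ed$raw)
  }
  locals <- stats::setNames(vector("list", model$n_stages), NULL)
  attended <- vector("list", model$n_stages)
  features <- vector("list", model$n_stages)
  cur <- xin
  for (j in seq_len(model$n_stages)) {
    cur <- run_stage(model, tape, pn, cur, j)
    features[[j]] <- cur
    if (use_attn && j %in% model$attachment_stages) {
      d <- dim(cur$value)
      prior <- op_bilinear(tape, sig, d[1], d[2])
      aj <- op_conv2d(tape, prior, pn(sprintf("head.%d.W", j)),
                      pn(sprintf("head.%d.b", j)))
      stopifnot(identical(dim(aj$value), d))   # shape law at every pass
      cur <- op_gate(tape, aj, cur)
      locals[[j]] <- aj
      attended[[j]] <- cur
    }
  }
  pooled <- op_gap(tape, cur)
  logits <- op_dense(tape, pooled, pn("classifier.W"), pn("classifier.b"))
  list(logits = logits, sig = sig, locals = locals, attended = attended,
       features = features, input = xin)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Forward pass through the classifier
#'
#' @param model A `medusa_model`.
#' @param images One (h, w, 1) array or a list of them; the side must
#'   equal `config$image_size`.
#' @param masks Optional list of binary lung masks (required by the
#'   segmentation-input ablation modes).
#' @param detail Also return per-stage feature, local-attention and
#'   attended maps (used by the visualization functions).
#' @return A `forward_bundle`: `logits` and `probs` (n x 2 matrices, rows
#'   summing to 1), `global_maps` (list of bounded attention maps, or
#'   `NULL` when attention is bypassed), and with `detail = TRUE` the
#'   per-stage tensors.
#' @export
forward <- function(model, images, masks = NULL, detail = FALSE) {
  if (!is.list(images)) images <- list(images)
  n <- length(images)
  size <- model$config$image_size
  logits <- matrix(0, n, 2L)
  probs <- matrix(0, n, 2L)
  globals <- if (model$ablation_mode == "full") vector("list", n) else NULL
  det <- if (detail) vector("list", n) else NULL
  for (i in seq_len(n)) {
    x <- as_hwc(images[[i]])
    if (!identical(dim(x)[1:2], c(size, size))) {
      stop("forward: image ", i, " has dims ", paste(dim(x)[1:2], collapse = "x"),
           " but the model expects ", size, "x", size, call. = FALSE)
    }
    tape <- ag_tape()
    pn <- param_nodes(tape, model$params)
    mk <- if (is.null(masks)) NULL else masks[[i]]
    g <- model_graph(model, tape, pn, x, mask = mk)
    logits[i, ] <- g$logits$value
    probs[i, ] <- softmax_vec(g$logits$value)
    if (!is.null(globals)) globals[[i]] <- g$sig$value
    if (detail) {
      det[[i]] <- list(
        features = lapply(g$features, function(n) n$value),
        locals = lapply(g$locals, function(n) if (is.null(n)) NULL else n$value),
        attended = lapply(g$attended, function(n) if (is.null(n)) NULL else n$value))
    }
  }
  structure(list(logits = logits, probs = probs, global_maps = globals,
                 detail = det, ablation_mode = model$ablation_mode),
            class = "forward_bundle")
}

#' @export
predict.medusa_model <- function(object, images, masks = NULL, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  b <- forward(object, images, masks)
  if (type == "prob") b$probs else max.col(b$probs) - 1L
}

#' @export
print.medusa_model <- function(x, ...) {
  cat("medusa_model:", x$backbone, "backbone,", x$n_stages, "stages,",
      length(x$attachment_stages), "attention head(s) at stage(s)",
      paste(x$attachment_stages, collapse = ","), "\n")
  cat("  input", x$config$image_size, "x", x$config$image_size,
      "| encoder-decoder depth", x$encdec_cfg$depth,
      "| parameters", format(x$n_params, big.mark = ","),
      "| ablation mode:", x$ablation_mode, "\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized archive of parameters and
#' configuration, with a JSON sidecar (`<path>.json`) recording the
#' backbone, sizes and training provenance for inspection without
#' loading.
#'
#' @param model A `medusa_model`.
#' @param path Destination file.
#' @param provenance Optional list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, provenance = NULL) {
  saveRDS(model, path)
  side <- list(backbone = model$backbone,
               image_size = model$config$image_size,
               n_params = model$n_params,
               attachment_stages = model$attachment_stages,
               ablation_mode = model$ablation_mode,
               encdec_depth = model$encdec_cfg$depth,
               provenance = provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("load_checkpoint: no such file: ", path, call. = FALSE)
  readRDS(path)
}
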