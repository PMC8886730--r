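# Training procedure: segmentation pretraining of the encoder-decoder
# (transfer learning) and alternating freeze/train optimization of the
# attention block vs the main network.

#' Alternating training schedule
#'
#' @param period_epochs Epochs per phase before switching (>= 1).
#' @param first_component Component trained first: `"attention"` or
#'   `"main"`.
#' @param total_epochs Total epochs of the run.
#' @return Object of class `alternating_schedule`.
#' @export
alternating_schedule <- function(period_epochs = 1L,
                                 first_component = c("attention", "main"),
                                 total_epochs = 10L) {
  first_component <- match.arg(first_component)
  if (period_epochs < 1) {
    stop("alternating_schedule: period_epochs must be >= 1", call. = FALSE)
  }
  structure(list(period_epochs = as.integer(period_epochs),
                 first_component = first_component,
                 total_epochs = as.integer(total_epochs)),
            class = "alternating_schedule")
}

#' Component trained at a given epoch
#'
#' Pure function of the 0-based epoch index and the schedule: phases of
#' `period_epochs` epochs alternate between the two components, starting
#' with `first_component`.
#'
#' @param epoch 0-based epoch index.
#' @param schedule An [alternating_schedule()].
#' @return `"attention"` or `"main"`.
#' @export
component_for_epoch <- function(epoch, schedule) {
  if (epoch < 0) stop("component_for_epoch: epoch must be >= 0", call. = FALSE)
  other <- setdiff(c("attention", "main"), schedule$first_component)
  if ((epoch %/% schedule$period_epochs) %% 2L == 0L) {
    schedule$first_component
  } else other
}

# Parameter names belonging to each alternation side.
param_side_names <- function(model, component) {
  nms <- names(model$params)
  heads_attn <- identical(model$config$heads_train_with, "attention")
  is_attn <- startsWith(nms, "encdec.") | (heads_attn & startsWith(nms, "head."))
  if (component == "attention") nms[is_attn] else nms[!is_attn]
}

# --- Adam ---------------------------------------------------------------

adam_new <- function() list(m = list(), v = list(), t = list())

adam_step <- function(params, grads, state, lr, names,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
      state$t[[nm]] <- 0L
    }
    state$t[[nm]] <- state$t[[nm]] + 1L
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t[[nm]])
    vh <- state$v[[nm]] / (1 - beta2^state$t[[nm]])
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# Read accumulated gradients for the named parameters off a pn() cache.
grads_from_cache <- function(pn_cache, names) {
  out <- list()
  for (nm in names) {
    node <- pn_cache[[nm]]
    if (!is.null(node) && !is.null(node$grad)) out[[nm]] <- node$grad
  }
  out
}

# param_nodes variant that exposes its cache for gradient readback.
param_nodes_cached <- function(tape, params) {
  cache <- new.env(parent = emptyenv())
  pn <- function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    if (is.null(params[[name]])) stop("unknown parameter: ", name, call. = FALSE)
    cache[[name]] <- ag_leaf(tape, params[[name]])
    cache[[name]]
  }
  list(pn = pn, cache = cache)
}

#' Pretrain the encoder-decoder on lung segmentation
#'
#' Minimizes an equally weighted binary cross-entropy + soft-Dice loss
#' between the bounded attention map and the binary lung mask -- the
#' transfer-learning initialization that steers global attention toward
#' the lung fields before classification training begins.
#'
#' @param samples List of samples, each with `image` ((h, w, 1) array)
#'   and `lung_mask` (binary matrix); e.g. from [generate_sample()].
#' @param cfg An [encdec_config()] matching the sample size.
#' @param epochs Training epochs; 0 returns the untouched initialization.
#' @param seed RNG seed (initialization + shuffling).
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @return List with `params` (named encoder-decoder parameters ready for
#'   [build_model()]'s `encdec_params`), `history` (per-epoch mean loss),
#'   and `cfg`.
#' @export
pretrain_encoder_decoder <- function(samples, cfg, epochs, seed = 0L,
                                     lr = 1e-3, batch_size = 16L) {
  if (!length(samples) || is.null(samples[[1]]$lung_mask)) {
    stop("pretrain_encoder_decoder: samples must carry lung masks", call. = FALSE)
  }
  params <- encdec_init(cfg, seed)
  state <- adam_new()
  hist <- data.frame(epoch = integer(), mean_loss = numeric())
  if (epochs > 0) {
    with_local_seed(as.integer(seed) + 911L, {
      for (ep in seq_len(epochs)) {
        ord <- sample(length(samples))
        losses <- c()
        for (b0 in seq(1, length(ord), by = batch_size)) {
          idx <- ord[seq(b0, min(b0 + batch_size - 1L, length(ord)))]
          tape <- ag_tape()
          pc <- param_nodes_cached(tape, params)
          per <- lapply(idx, function(i) {
            s <- samples[[i]]
            g <- encdec_graph(tape, ag_leaf(tape, as_hwc(s$image)), pc$pn, cfg)
            op_bce_dice(tape, op_sigmoid(tape, g$raw), as_hwc(s$lung_mask * 1.0))
          })
          loss <- op_mean_scalars(tape, per)
          if (!is.finite(loss$value)) {
            stop("pretrain: non-finite loss at epoch ", ep, call. = FALSE)
          }
          ag_backward(tape, loss)
          gr <- grads_from_cache(pc$cache, names(params))
          upd <- adam_step(params, gr, state, lr, names(params))
          params <- upd$params
          state <- upd$state
          losses <- c(losses, loss$value)
        }
        hist <- rbind(hist, data.frame(epoch = ep, mean_loss = mean(losses)))
      }
    })
  }
  list(params = params, history = hist, cfg = cfg)
}

#' Dice overlap of a probability map against a binary mask
#'
#' @param pred Probability map (matrix or (h, w, 1) array).
#' @param mask Binary mask of the same spatial dims.
#' @param threshold Binarization threshold for `pred`.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_score <- function(pred, mask, threshold = 0.5) {
  p <- as_hwc(pred)[, , 1] >= threshold
  m <- mask > 0.5
  denom <- sum(p) + sum(m)
  if (denom == 0) return(1)
  2 * sum(p & m) / denom
}

#' Mean held-out Dice of a (pre)trained encoder-decoder
#'
#' @param params Encoder-decoder parameters.
#' @param cfg Matching [encdec_config()].
#' @param samples Held-out samples with lung masks.
#' @return Mean Dice coefficient.
#' @export
segmentation_dice <- function(params, cfg, samples) {
  mean(vapply(samples, function(s) {
    dice_score(sigmoid_map(global_forward(s$image, params, cfg)), s$lung_mask)
  }, numeric(1)))
}

#' Copy pretrained encoder-decoder weights into a model
#'
#' The weights initialize the global attention block and keep training
#' (they are not frozen) during the subsequent alternating phase.
#'
#' @param model A `medusa_model`.
#' @param pretrained Result of [pretrain_encoder_decoder()] (or its
#'   `$params`).
#' @return The model with the encoder-decoder parameters replaced.
#' @export
init_from_pretrained <- function(model, pretrained) {
  params <- if (!is.null(pretrained$params)) pretrained$params else pretrained
  nms <- names(params)
  if (!all(startsWith(nms, "encdec."))) {
    stop("init_from_pretrained: expected encoder-decoder parameters", call. = FALSE)
  }
  missing <- setdiff(nms, names(model$params))
  if (length(missing)) {
    stop("init_from_pretrained: parameter shape/config mismatch (",
         missing[1], " not in model)", call. = FALSE)
  }
  for (nm in nms) model$params[[nm]] <- params[[nm]]
  model
}

#' Alternating freeze/train optimization
#'
#' Trains the classifier with 2-class cross-entropy, freezing one
#' component per epoch according to the schedule: during a `main` epoch
#' every encoder-decoder (and, by default, head-projection) parameter is
#' left bit-identical; during an `attention` epoch every backbone and
#' classifier-head parameter is. Freezing is enforced by excluding the
#' frozen side from the optimizer.
#'
#' @param model A `medusa_model`.
#' @param train_samples,val_samples Lists of samples with `image` and
#'   `label` (masks optional); `val_samples` may be `NULL`.
#' @param schedule An [alternating_schedule()].
#' @param seed RNG seed (shuffling).
#' @param lr Adam learning rate; defaults to the model config's.
#' @param encdec_lr_factor Multiplier on `lr` for the encoder-decoder
#'   parameters (default 0.1): discriminative fine-tuning, stepping a
#'   pretrained component more gently than the freshly initialized
#'   projection heads and backbone. Set to 1 for a uniform rate.
#' @param stop_train_acc Optional early-stop threshold on the running
#'   training accuracy of an epoch (e.g. `1.0`).
#' @param verbose Print one line per epoch.
#' @return List with `model` (final), `best_model` (highest validation
#'   accuracy, or final if no validation set), `history` data frame
#'   (epoch, component, mean_loss, train_acc, val_acc, seconds, seed).
#' @export
train_alternating <- function(model, train_samples, val_samples = NULL,
                              schedule = alternating_schedule(
                                model$config$alternation_period_epochs,
                                total_epochs = model$config$epochs),
                              seed = 0L, lr = model$config$learning_rate,
                              encdec_lr_factor = 0.1,
                              stop_train_acc = NULL, verbose = FALSE) {
  batch_size <- model$config$batch_size
  state <- adam_new()
  hist <- NULL
  best_acc <- -Inf
  best_params <- model$params
  with_local_seed(as.integer(seed) + 4242L, {
    for (ep in seq_len(schedule$total_epochs) - 1L) {
      t0 <- proc.time()[["elapsed"]]
      comp <- component_for_epoch(ep, schedule)
      trainable <- param_side_names(model, comp)
      ord <- sample(length(train_samples))
      losses <- c(); n_correct <- 0L
      for (b0 in seq(1, length(ord), by = batch_size)) {
        idx <- ord[seq(b0, min(b0 + batch_size - 1L, length(ord)))]
        tape <- ag_tape()
        pc <- param_nodes_cached(tape, model$params)
        per <- lapply(idx, function(i) {
          s <- train_samples[[i]]
          g <- model_graph(model, tape, pc$pn, s$image, mask = s$lung_mask)
          ce <- op_softmax_ce(tape, g$logits, s$label + 1L)
          if (which.max(ce$probs) == s$label + 1L) {
            n_correct <<- n_correct + 1L
          }
          ce
        })
        loss <- op_mean_scalars(tape, per)
        if (!is.finite(loss$value)) {
          stop("train_alternating: non-finite loss at epoch ", ep,
               ", batch starting at sample ", b0, call. = FALSE)
        }
        ag_backward(tape, loss)
        gr <- grads_from_cache(pc$cache, trainable)
        enc <- trainable[startsWith(trainable, "encdec.")]
        oth <- setdiff(trainable, enc)
        upd <- adam_step(model$params, gr, state, lr, oth)
        upd <- adam_step(upd$params, gr, upd$state, lr * encdec_lr_factor, enc)
        model$params <- upd$params
        state <- upd$state
        losses <- c(losses, loss$value)
      }
      train_acc <- n_correct / length(train_samples)
      val_acc <- NA_real_
      if (!is.null(val_samples)) {
        pred <- predict(model, lapply(val_samples, `[[`, "image"),
                        masks = lapply(val_samples, `[[`, "lung_mask"))
        val_acc <- mean(pred == vapply(val_samples, `[[`, integer(1), "label"))
        if (val_acc > best_acc) {    # strict: retain the earliest best epoch
          best_acc <- val_acc
          best_params <- model$params
        }
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, component = comp, mean_loss = mean(losses),
        train_acc = train_acc, val_acc = val_acc,
        seconds = proc.time()[["elapsed"]] - t0, seed = as.integer(seed)))
      if (verbose) {
        message(sprintf("epoch %d [%s] loss %.4f train_acc %.3f val_acc %s",
                        ep, comp, mean(losses), train_acc, format(val_acc)))
      }
      if (!is.null(stop_train_acc) && train_acc >= stop_train_acc) break
    }
  })
  best_model <- model
  best_model$params <- best_params
  if (is.null(val_samples)) best_model <- model
  list(model = model, best_model = best_model, history = hist)
}
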