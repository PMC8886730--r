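test_that("the epoch-to-component map follows the schedule definition", {
  s1 <- alternating_schedule(1, "attention", 6)
  expect_equal(vapply(0:2, component_for_epoch, character(1), schedule = s1),
               c("attention", "main", "attention"))
  s2 <- alternating_schedule(2, "main", 8)
  expect_equal(vapply(0:3, component_for_epoch, character(1), schedule = s2),
               c("main", "main", "attention", "attention"))
  expect_error(alternating_schedule(0, "main", 4), "period_epochs")
  expect_error(component_for_epoch(-1, s1), "epoch")
})

test_that("zero pretraining epochs return the untouched initialization", {
  cfg <- encdec_config(depth = 2, base_channels = 4)
  samples <- tiny_samples(4)
  res <- pretrain_encoder_decoder(samples, cfg, epochs = 0, seed = 11)
  expect_identical(res$params, encdec_init(cfg, seed = 11))
  expect_equal(nrow(res$history), 0)
  no_masks <- lapply(samples, function(s) list(image = s$image))
  expect_error(pretrain_encoder_decoder(no_masks, cfg, 1), "masks")
})

test_that("segmentation pretraining reduces its loss", {
  cfg <- encdec_config(depth = 2, base_channels = 4)
  res <- pretrain_encoder_decoder(tiny_samples(8), cfg, epochs = 4, seed = 0,
                                  lr = 3e-3, batch_size = 4)
  expect_lt(res$history$mean_loss[4], res$history$mean_loss[1])
})

test_that("dice_score matches its set definition", {
  m <- matrix(0, 4, 4); m[1:2, 1:2] <- 1
  expect_equal(dice_score(m, m), 1)
  expect_equal(dice_score(1 - m, m), 0)
  p <- matrix(0, 4, 4); p[1:2, 1] <- 1       # half the mask
  expect_equal(dice_score(p, m), 2 * 2 / (2 + 4))
})

test_that("the frozen side is bit-identical across an epoch, both ways", {
  model <- build_model(tiny_config(), seed = 1)
  tr <- tiny_samples(8)
  attn <- grep("^(encdec|head)\\.", names(model$params), value = TRUE)
  main <- setdiff(names(model$params), attn)

  fit_m <- train_alternating(model, tr, NULL,
                             alternating_schedule(1, "main", 1), seed = 0)
  for (nm in attn) expect_identical(fit_m$model$params[[nm]], model$params[[nm]])
  expect_false(all(vapply(main, function(nm)
    identical(fit_m$model$params[[nm]], model$params[[nm]]), logical(1))))

  fit_a <- train_alternating(model, tr, NULL,
                             alternating_schedule(1, "attention", 1), seed = 0)
  for (nm in main) expect_identical(fit_a$model$params[[nm]], model$params[[nm]])
})

test_that("training is reproducible under a fixed seed", {
  model <- build_model(tiny_config(), seed = 2)
  tr <- tiny_samples(8)
  sched <- alternating_schedule(1, "main", 3)
  f1 <- train_alternating(model, tr, tr[1:4], sched, seed = 5)
  f2 <- train_alternating(model, tr, tr[1:4], sched, seed = 5)
  expect_equal(f1$history$mean_loss, f2$history$mean_loss, tolerance = 1e-7)
  expect_equal(f1$model$params, f2$model$params, tolerance = 1e-7)
  f3 <- train_alternating(model, tr, tr[1:4], sched, seed = 6)
  expect_false(isTRUE(all.equal(f1$history$mean_loss, f3$history$mean_loss)))
})

test_that("attention-frozen alternating training reduces to backbone training", {
  cfg <- tiny_config()
  full <- build_model(cfg, seed = 3)
  bare <- set_ablation(full, "attention_disabled")
  tr <- tiny_samples(8)
  sched <- alternating_schedule(4, "main", 4)   # main-only phases
  ff <- train_alternating(full, tr, NULL, sched, seed = 1)
  fb <- train_alternating(bare, tr, NULL, sched, seed = 1)
  expect_equal(ff$history$mean_loss, fb$history$mean_loss, tolerance = 1e-12)
  for (nm in grep("^(backbone|classifier)", names(full$params), value = TRUE)) {
    expect_equal(ff$model$params[[nm]], fb$model$params[[nm]], tolerance = 1e-12)
  }
})

test_that("gradients reach both components through the gates", {
  model <- build_model(tiny_config(), seed = 4)
  set.seed(1)
  for (j in model$attachment_stages) {
    nm <- sprintf("head.%d.W", j)
    model$params[[nm]] <- array(rnorm(length(model$params[[nm]]), sd = 0.1),
                                dim = dim(model$params[[nm]]))
  }
  s <- tiny_samples(1, labels = 1L)[[1]]
  tape <- medusa:::ag_tape()
  pc <- medusa:::param_nodes_cached(tape, model$params)
  g <- medusa:::model_graph(model, tape, pc$pn, s$image)
  ce <- medusa:::op_softmax_ce(tape, g$logits, s$label + 1L)
  medusa:::ag_backward(tape, ce)
  expect_gt(max(abs(pc$cache[["backbone.stage1.W"]]$grad)), 0)
  expect_gt(max(abs(pc$cache[["encdec.out.W"]]$grad)), 0)
  expect_gt(max(abs(pc$cache[["classifier.W"]]$grad)), 0)
})

test_that("pretrained weights transfer into the model and keep training", {
  cfg <- tiny_config()
  ecfg <- encdec_config(depth = cfg$encdec_depth,
                        base_channels = cfg$encdec_base_channels)
  pre <- pretrain_encoder_decoder(tiny_samples(4), ecfg, epochs = 1, seed = 0)
  model <- init_from_pretrained(build_model(cfg, seed = 0), pre)
  expect_identical(model$params[["encdec.out.W"]], pre$params[["encdec.out.W"]])
  bad <- pre
  names(bad$params)[1] <- "encdec.nonexistent.W"
  expect_error(init_from_pretrained(build_model(cfg, seed = 0), bad), "mismatch")
  expect_error(init_from_pretrained(build_model(cfg, seed = 0),
                                    list(x = 1)), "encoder-decoder")
})
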