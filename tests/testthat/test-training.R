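tiny_training_setup <- function(seed = 7L) {
  sp <- phantom_spec(shape = c(4, 16, 16), radius_range = c(0.25, 0.4),
                     deform_amplitude = 0.5, seed = seed)
  ph <- generate_phantom(sp)
  vol <- window_normalize(ph$volume)
  trips <- make_triplets(vol)
  lapply(trips, function(t) list(stack = t$stack,
                                 mask = ph$mask[t$center_index, , ]))
}

tiny_train_config <- function(...) {
  defaults <- list(n_critic = 2L, batch_size = 2L, max_steps = 6L, seed = 5L,
                   lr_generator = 1e-3, lr_critic = 1e-4,
                   loss = loss_config(alpha = 0.1, adv_weight = 0.01),
                   model = arch_spec(stage_channels = c(2, 2, 2, 2, 2),
                                     dropout_rate = 0),
                   critic = critic_spec(channels = c(2, 2, 2, 2), fc_width = 2,
                                        input_hw = c(16, 16)))
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

test_that("training history bookkeeping matches the loop structure", {
  ds <- tiny_training_setup()
  cfg <- tiny_train_config()
  res <- train_adversarial(ds, cfg)
  gh <- res$history$generator
  ch <- res$history$critic
  expect_equal(nrow(gh), 6)
  expect_equal(nrow(ch), 6 * 2)   # n_critic records per generator step
  expect_true(all(is.finite(unlist(gh[-1]))))
  expect_true(all(is.finite(ch$critic_loss)))
  # logged total recomposes exactly from the logged parts
  expect_equal(gh$total,
               0.1 * gh$dice_part + 0.9 * gh$boundary_part + 0.01 * gh$adv_part,
               tolerance = 1e-12)
  # critic weights inside the clip box after every single update
  expect_true(all(ch$max_abs_w <= cfg$clip_c + 1e-15))
  expect_lte(max_abs_weight(res$critic), cfg$clip_c)
})

test_that("training is deterministic given the seed", {
  ds <- tiny_training_setup()
  cfg <- tiny_train_config(max_steps = 3L)
  r1 <- train_adversarial(ds, cfg)
  r2 <- train_adversarial(ds, cfg)
  expect_identical(r1$history$generator, r2$history$generator)
  expect_identical(r1$history$critic, r2$history$critic)
  p1 <- liverseg:::nn_param_refs(r1$generator)
  p2 <- liverseg:::nn_param_refs(r2$generator)
  for (i in seq_along(p1)) {
    expect_identical(p1[[i]]$env$params[[p1[[i]]$name]],
                     p2[[i]]$env$params[[p2[[i]]$name]])
  }
})

test_that("with alpha = 1 and lambda = 0 the logged total is the Dice part alone", {
  ds <- tiny_training_setup()
  cfg <- tiny_train_config(loss = loss_config(alpha = 1, adv_weight = 0),
                           max_steps = 3L)
  res <- train_adversarial(ds, cfg)
  gh <- res$history$generator
  expect_equal(gh$total, gh$dice_part, tolerance = 1e-12)
  expect_true(all(gh$adv_part == 0))
})

test_that("ablation loss modes train and log coherently", {
  ds <- tiny_training_setup()
  for (type in c("dice", "boundary", "iou", "bce")) {
    cfg <- tiny_train_config(max_steps = 3L,
                             loss = loss_config(alpha = 0.1, adv_weight = 0,
                                                type = type))
    res <- train_adversarial(ds, cfg)
    gh <- res$history$generator
    expect_equal(nrow(gh), 3)
    expect_true(all(is.finite(gh$total)))
    expect_equal(gh$total, gh$seg_part, tolerance = 1e-12)
    if (type == "dice") expect_equal(gh$seg_part, gh$dice_part)
    if (type == "boundary") expect_equal(gh$seg_part, gh$boundary_part)
  }
})

test_that("conditioning the critic on the CT slice trains with a 3-channel stack", {
  ds <- tiny_training_setup()
  cfg <- tiny_train_config(max_steps = 2L,
                           critic = critic_spec(channels = c(2, 2, 2, 2),
                                                fc_width = 2,
                                                input_hw = c(16, 16),
                                                in_channels = 3L))
  res <- train_adversarial(ds, cfg)
  expect_equal(res$critic$spec$in_channels, 3L)
  expect_true(all(is.finite(res$history$critic$critic_loss)))
  expect_true(all(is.finite(res$history$generator$adv_part)))
})

test_that("non-finite losses abort with a diagnostic naming the term", {
  ds <- tiny_training_setup()
  cfg <- tiny_train_config(max_steps = 2L)
  set.seed(44)
  bad_gen <- build_generator(cfg$model)
  ref <- liverseg:::nn_param_refs(bad_gen)[[1]]
  ref$env$params$W[1] <- Inf
  expect_error(train_adversarial(ds, cfg, generator = bad_gen),
               "critic loss|generator forward output")
})

test_that("predict_volume reassembles a binary mask of identical shape, deterministically", {
  set.seed(41)
  gen <- build_generator(arch_spec(stage_channels = c(2, 2, 2, 2, 2),
                                   dropout_rate = 0))
  sp <- phantom_spec(shape = c(5, 16, 16), seed = 9L)
  ph <- generate_phantom(sp)
  m1 <- predict_volume(gen, ph$volume, window = window_spec(), batch_size = 2)
  expect_equal(dim(m1), c(5, 16, 16))
  expect_true(all(m1 %in% c(0L, 1L)))
  m2 <- predict_volume(gen, ph$volume, window = window_spec(), batch_size = 4)
  expect_identical(m1, m2)
  expect_error(predict_volume(gen, ph$volume, threshold = 0), "threshold")
})

test_that("thresholding splits probabilities at the configured cut", {
  # the documented rule: probability 0.4 -> 0 and 0.6 -> 1 at threshold 0.5
  prob <- c(0.4, 0.6)
  expect_equal((prob >= 0.5) * 1L, c(0L, 1L))
  set.seed(42)
  gen <- build_generator(arch_spec(stage_channels = c(2, 2, 2, 2, 2),
                                   dropout_rate = 0))
  sp <- phantom_spec(shape = c(4, 16, 16), seed = 10L)
  ph <- generate_phantom(sp)
  lo <- predict_volume(gen, ph$volume, threshold = 0.01, window = window_spec())
  hi <- predict_volume(gen, ph$volume, threshold = 0.99, window = window_spec())
  expect_gte(sum(lo), sum(hi))
})

test_that("checkpoints round trip the model exactly", {
  set.seed(43)
  gen <- build_generator(arch_spec(stage_channels = c(2, 2, 2, 2, 2),
                                   dropout_rate = 0))
  x <- array(runif(1 * 3 * 16 * 16), c(1, 3, 16, 16))
  p <- generator_forward(gen, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(gen, path)
  gen2 <- load_checkpoint(path)
  expect_identical(generator_forward(gen2, x), p)
})

test_that("yaml config round trips into a train_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "train:", "  n_critic: 3", "  batch_size: 2", "  max_steps: 7",
    "  seed: 99", "  lr_generator: 1.0e-4",
    "loss:", "  alpha: 0.25", "  adv_weight: 0.0",
    "model:", "  stage_channels: [2, 2, 2, 2, 2]", "  dropout_rate: 0.0",
    "critic:", "  channels: [2, 2, 2, 2]", "  fc_width: 2",
    "  input_hw: [16, 16]"
  ), path)
  cfg <- load_train_config(path)
  expect_equal(cfg$n_critic, 3L)
  expect_equal(cfg$max_steps, 7L)
  expect_equal(cfg$loss$alpha, 0.25)
  expect_equal(cfg$model$stage_channels, rep(2L, 5))
  expect_equal(cfg$critic$input_hw, c(16L, 16L))
})
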