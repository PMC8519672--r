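# The adversarial optimization loop: n_critic Wasserstein critic updates
# (each followed by weight clipping), then one generator update minimizing
# alpha * L_Dice + (1 - alpha) * L_BD + lambda * L_adv. RMSProp throughout.

#' Training configuration
#'
#' @param n_critic Critic updates per generator update; >= 1. Default 5.
#' @param clip_c Critic weight-clipping constant; default 0.01.
#' @param lr_generator,lr_critic RMSProp learning rates; default 5e-5.
#' @param batch_size Mini-batch size; >= 1.
#' @param max_steps Number of generator updates.
#' @param seed Integer seed governing initialization, batch sampling,
#'   dropout and noise; runs with identical configs are identical.
#' @param loss A [loss_config()].
#' @param model An [arch_spec()] for the generator.
#' @param critic A [critic_spec()] for the critic, or `NULL` to derive the
#'   input size from the data with default widths.
#' @param checkpoint_path Optional path prefix; when set, a checkpoint is
#'   written every `checkpoint_every` steps.
#' @param checkpoint_every Interval in generator steps.
#' @return A `train_config` list.
#' @export
train_config <- function(n_critic = 5L, clip_c = 0.01, lr_generator = 5e-5,
                         lr_critic = 5e-5, batch_size = 4L, max_steps = 100L,
                         seed = 1L, loss = loss_config(), model = arch_spec(),
                         critic = NULL, checkpoint_path = NULL,
                         checkpoint_every = 100L) {
  stopifnot(n_critic >= 1L, batch_size >= 1L, max_steps >= 1L,
            lr_generator > 0, lr_critic > 0, clip_c > 0,
            inherits(loss, "loss_config"), inherits(model, "arch_spec"))
  structure(list(n_critic = as.integer(n_critic), clip_c = clip_c,
                 lr_generator = lr_generator, lr_critic = lr_critic,
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps), seed = as.integer(seed),
                 loss = loss, model = model, critic = critic,
                 checkpoint_path = checkpoint_path,
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "train_config")
}

#' Load a training configuration from YAML
#'
#' Recognized top-level keys: `train` (scalar fields of [train_config()]),
#' `loss` (`alpha`, `reduction`, `adv_weight`), `model` (fields of
#' [arch_spec()]) and `critic` (fields of [critic_spec()]).
#'
#' @param path YAML file path.
#' @return A `train_config`.
#' @export
load_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- if (is.null(y$train)) list() else y$train
  if (!is.null(y$loss)) args$loss <- do.call(loss_config, y$loss)
  if (!is.null(y$model)) args$model <- do.call(arch_spec, y$model)
  if (!is.null(y$critic)) args$critic <- do.call(critic_spec, y$critic)
  do.call(train_config, args)
}

check_finite_loss <- function(value, term, step) {
  if (!is.finite(value)) {
    stop("non-finite ", term, " at generator step ", step,
         ": training aborted (value = ", value, ")")
  }
  value
}

stash_grads <- function(model) {
  lapply(nn_collect(model), function(ly) ly$grads)
}

add_stashed_grads <- function(model, stash) {
  lys <- nn_collect(model)
  for (i in seq_along(lys)) {
    g0 <- stash[[i]]
    if (length(g0) == 0L) next
    for (nm in names(g0)) {
      cur <- lys[[i]]$grads[[nm]]
      lys[[i]]$grads[[nm]] <- if (is.null(cur)) g0[[nm]] else cur + g0[[nm]]
    }
  }
  invisible(model)
}

samples_to_batch <- function(dataset, idx) {
  s1 <- dataset[[idx[1L]]]
  d <- dim(s1$stack)
  x <- array(0, c(length(idx), d[1L], d[2L], d[3L]))
  masks <- array(0, c(length(idx), d[2L], d[3L]))
  for (i in seq_along(idx)) {
    x[i, , , ] <- dataset[[idx[i]]]$stack
    masks[i, , ] <- dataset[[idx[i]]]$mask
  }
  list(x = x, masks = masks)
}

fuse_batch <- function(cand, annot, ct = NULL) {
  d <- dim(cand)
  nch <- if (is.null(ct)) 2L else 3L
  out <- array(0, c(d[1L], nch, d[2L], d[3L]))
  out[, 1L, , ] <- cand
  out[, 2L, , ] <- annot
  if (!is.null(ct)) out[, 3L, , ] <- ct
  out
}

#' Adversarial training of the segmentation generator
#'
#' For each of `max_steps` generator updates: `n_critic` critic updates on
#' (annotation, prediction) score pairs, each followed by weight clipping;
#' then one generator update on the composite segmentation loss plus
#' `adv_weight` times the adversarial term. Signed distance maps of the
#' ground-truth slices are precomputed once; slices whose mask has no
#' boundary (all background or all foreground) contribute the Dice term only.
#'
#' @param dataset List of samples, each with `stack` (`slices x H x W`) and
#'   `mask` (`H x W` binary); see [load_triplet_dataset()].
#' @param config A [train_config()].
#' @param generator,critic Optional prebuilt models; built from `config`
#'   when `NULL`.
#' @return List with `generator`, `critic` and `history` (list of two data
#'   frames: `generator` with one row per generator step holding the loss
#'   parts `total`, `seg_part`, `dice_part`, `boundary_part`, `adv_part`;
#'   and `critic` with one row per critic update holding `critic_loss` and
#'   `max_abs_w`, the largest absolute critic weight after that update's
#'   clipping).
#' @export
train_adversarial <- function(dataset, config = train_config(),
                              generator = NULL, critic = NULL) {
  stopifnot(length(dataset) >= 1L, inherits(config, "train_config"))
  hw <- dim(dataset[[1L]]$mask)
  with_seed(config$seed, {
    if (is.null(generator)) generator <- build_generator(config$model)
    if (is.null(critic)) {
      cspec <- if (is.null(config$critic)) critic_spec(input_hw = hw) else config$critic
      critic <- build_discriminator(cspec)
    }
    clip_weights(critic, config$clip_c)
    phis <- lapply(dataset, function(s) {
      m <- s$mask
      if (all(m == 0) || all(m == 1)) NULL else signed_distance_map(m)
    })
    gen_opt <- rmsprop_init(generator)
    critic_opt <- rmsprop_init(critic)
    alpha <- config$loss$alpha
    lambda <- config$loss$adv_weight
    n <- length(dataset)
    gen_hist <- vector("list", config$max_steps)
    critic_hist <- vector("list", config$max_steps * config$n_critic)
    ci <- 0L
    for (step in seq_len(config$max_steps)) {
      # ---- critic phase ----
      conditioned <- critic$spec$in_channels >= 3L
      for (t in seq_len(config$n_critic)) {
        idx <- sample.int(n, config$batch_size, replace = n < config$batch_size)
        b <- samples_to_batch(dataset, idx)
        pred <- generator_forward(generator, b$x, training = FALSE)
        ct_ch <- if (conditioned) array(b$x[, 2L, , ], dim(b$masks)) else NULL
        fake <- fuse_batch(array(pred[, 1L, , ], dim(b$masks)), b$masks, ct_ch)
        real <- fuse_batch(b$masks, b$masks, ct_ch)
        nb <- length(idx)
        rs <- critic_score(critic, real, training = TRUE)
        nn_backward(critic, matrix(rep(-1 / nb, nb), nrow = 1L))
        stash <- stash_grads(critic)
        fs <- critic_score(critic, fake, training = TRUE)
        nn_backward(critic, matrix(rep(1 / nb, nb), nrow = 1L))
        add_stashed_grads(critic, stash)
        closs <- check_finite_loss(critic_loss(rs, fs), "critic loss", step)
        critic_opt <- rmsprop_step(critic_opt, config$lr_critic)
        clip_weights(critic, config$clip_c)
        ci <- ci + 1L
        critic_hist[[ci]] <- data.frame(step = step, update = t, critic_loss = closs,
                                        max_abs_w = max_abs_weight(critic))
      }
      # ---- generator phase ----
      idx <- sample.int(n, config$batch_size, replace = n < config$batch_size)
      b <- samples_to_batch(dataset, idx)
      pred <- generator_forward(generator, b$x, training = TRUE)
      if (!all(is.finite(pred))) {
        check_finite_loss(NaN, "generator forward output", step)
      }
      nb <- length(idx)
      grad <- array(0, dim(pred))
      ltype <- config$loss$type
      dice_parts <- numeric(nb)
      bd_parts <- numeric(0)
      other_parts <- numeric(nb)
      for (i in seq_len(nb)) {
        p_i <- pred[i, 1L, , ]
        m_i <- b$masks[i, , ]
        if (ltype %in% c("composite", "dice")) {
          dice_parts[i] <- dice_loss(p_i, m_i)
          wd <- if (ltype == "composite") alpha else 1
          grad[i, 1L, , ] <- grad[i, 1L, , ] + wd * dice_loss_grad(p_i, m_i) / nb
        }
        if (ltype %in% c("composite", "boundary")) {
          phi_i <- phis[[idx[i]]]
          if (!is.null(phi_i)) {
            bd_parts <- c(bd_parts, boundary_loss(p_i, phi_i, config$loss$reduction))
            wb <- if (ltype == "composite") 1 - alpha else 1
            grad[i, 1L, , ] <- grad[i, 1L, , ] +
              wb * boundary_loss_grad(phi_i, config$loss$reduction) / nb
          }
        }
        if (ltype == "iou") {
          other_parts[i] <- iou_loss(p_i, m_i)
          grad[i, 1L, , ] <- iou_loss_grad(p_i, m_i) / nb
        } else if (ltype == "bce") {
          other_parts[i] <- bce_loss(p_i, m_i)
          grad[i, 1L, , ] <- bce_loss_grad(p_i, m_i) / nb
        }
      }
      dice_part <- check_finite_loss(mean(dice_parts), "Dice loss", step)
      bd_part <- if (length(bd_parts)) mean(bd_parts) else 0
      check_finite_loss(bd_part, "boundary loss", step)
      seg_part <- switch(ltype,
        composite = alpha * dice_part + (1 - alpha) * bd_part,
        dice = dice_part,
        boundary = bd_part,
        mean(other_parts))
      check_finite_loss(seg_part, paste(ltype, "segmentation loss"), step)
      adv_part <- 0
      if (lambda > 0) {
        ct_ch <- if (conditioned) array(b$x[, 2L, , ], dim(b$masks)) else NULL
        fused <- fuse_batch(array(pred[, 1L, , ], dim(b$masks)), b$masks, ct_ch)
        fsc <- critic_score(critic, fused, training = TRUE)
        adv_part <- check_finite_loss(generator_adv_loss(fsc), "adversarial loss", step)
        dinput <- critic_backward_input(critic, rep(-1 / nb, nb))
        grad <- grad + lambda * array(dinput[, 1L, , ], dim(grad))
      }
      generator_backward(generator, grad)
      gen_opt <- rmsprop_step(gen_opt, config$lr_generator)
      total <- seg_part + lambda * adv_part
      check_finite_loss(total, "generator total loss", step)
      gen_hist[[step]] <- data.frame(step = step, total = total,
                                     seg_part = seg_part,
                                     dice_part = dice_part,
                                     boundary_part = bd_part,
                                     adv_part = adv_part)
      if (!is.null(config$checkpoint_path) &&
          step %% config$checkpoint_every == 0L) {
        save_checkpoint(generator,
                        paste0(config$checkpoint_path, "-gen-", step, ".rds"))
        save_checkpoint(critic,
                        paste0(config$checkpoint_path, "-critic-", step, ".rds"))
      }
    }
    list(generator = generator, critic = critic,
         history = list(generator = do.call(rbind, gen_hist),
                        critic = do.call(rbind, critic_hist)))
  })
}

#' Segment a full volume
#'
#' Builds the slice triplets of the volume, forwards each through the
#' generator in evaluation mode, thresholds the centre-slice probabilities
#' and reassembles a mask volume of identical shape.
#'
#' @param generator A trained (or initialized) `vnet_generator`.
#' @param vol A [ct_volume()]; windowed with `window` first when supplied.
#' @param threshold Foreground threshold in `(0, 1)`; default 0.5.
#' @param window Optional [window_spec()] applied before inference.
#' @param batch_size Triplets forwarded per batch.
#' @return Integer mask array with the shape of `vol`.
#' @export
predict_volume <- function(generator, vol, threshold = 0.5, window = NULL,
                           batch_size = 8L) {
  stopifnot(inherits(generator, "vnet_generator"),
            threshold > 0, threshold < 1)
  if (!is.null(window)) vol <- window_normalize(vol, window)
  vox <- if (inherits(vol, "ct_volume")) vol$voxels else vol
  d <- dim(vox)
  trips <- make_triplets(vox)
  out <- array(0L, d)
  for (start in seq(1L, length(trips), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(trips))
    x <- array(0, c(length(idx), 3L, d[2L], d[3L]))
    for (i in seq_along(idx)) x[i, , , ] <- trips[[idx[i]]]$stack
    prob <- generator_forward(generator, x, training = FALSE)
    for (i in seq_along(idx)) {
      out[trips[[idx[i]]]$center_index, , ] <- (prob[i, 1L, , ] >= threshold) * 1L
    }
  }
  out
}

#' Compute training-set Dice of a generator
#'
#' Convenience wrapper: thresholded predictions on every sample, pooled
#' confusion counts, Dice coefficient.
#'
#' @param generator A `vnet_generator`.
#' @param dataset Samples as in [train_adversarial()].
#' @param threshold Foreground threshold.
#' @return List with `dice`, `accuracy` and the pooled `counts`.
#' @export
dataset_dice <- function(generator, dataset, threshold = 0.5) {
  tp <- fp <- fn <- tn <- 0
  for (s in dataset) {
    d <- dim(s$stack)
    x <- array(s$stack, c(1L, d))
    prob <- generator_forward(generator, x, training = FALSE)
    pred <- (prob[1L, 1L, , ] >= threshold) * 1
    cc <- confusion_counts(pred, s$mask)
    tp <- tp + cc$TP; fp <- fp + cc$FP; fn <- fn + cc$FN; tn <- tn + cc$TN
  }
  pooled <- structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
                      class = "confusion_counts")
  list(dice = dice_coefficient(pooled), accuracy = accuracy(pooled),
       counts = pooled)
}

# ---- checkpoints ----------------------------------------------------------

#' Save model weights
#'
#' Serializes the model's parameters, normalization statistics and embedded
#' architecture spec so the model can be rebuilt exactly.
#'
#' @param model A `vnet_generator` or `wgan_critic`.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  type <- if (inherits(model, "vnet_generator")) "generator"
          else if (inherits(model, "wgan_critic")) "critic"
          else stop("unsupported model type")
  layers <- nn_collect(model)
  state <- lapply(layers, function(ly) {
    list(params = ly$params,
         running_mean = if (inherits(ly, "batchnorm")) ly$running_mean,
         running_var = if (inherits(ly, "batchnorm")) ly$running_var,
         initialized = if (inherits(ly, "batchnorm")) ly$initialized)
  })
  saveRDS(list(type = type, spec = model$spec, state = state), path)
  invisible(path)
}

#' Load model weights
#'
#' @param path Path written by [save_checkpoint()].
#' @return The rebuilt model.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- if (ck$type == "generator") build_generator(ck$spec)
           else build_discriminator(ck$spec)
  layers <- nn_collect(model)
  stopifnot(length(layers) == length(ck$state))
  for (i in seq_along(layers)) {
    st <- ck$state[[i]]
    if (length(st$params)) layers[[i]]$params <- st$params
    if (inherits(layers[[i]], "batchnorm")) {
      layers[[i]]$running_mean <- st$running_mean
      layers[[i]]$running_var <- st$running_var
      layers[[i]]$initialized <- st$initialized
    }
  }
  model
}
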