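# Two-stage optimization: supervised pretraining on labeled thick
# slices (SGD, linearly decaying learning rate), then joint training
# where every step draws one thick and one thin batch and minimizes
# L = L_S + lambda * L_T in a single summed update.

#' Training schedule configuration
#'
#' Defaults follow the full-scale schedule (SGD, 200 supervised epochs
#' at lr 1e-3 with linear decay, then 100 joint epochs at lr 1e-4,
#' weight decay 1e-5, 80/20 case-level split). [desk_config()] is the
#' scaled-down preset the test suite exercises.
#'
#' @param stage1_epochs,stage1_lr Supervised pretraining epochs and
#'   initial learning rate (linear decay to ~0 across epochs).
#' @param stage2_epochs,stage2_lr Joint-stage epochs and initial
#'   learning rate.
#' @param weight_decay L2 weight decay applied in both stages.
#' @param momentum SGD momentum.
#' @param batch_size Slices per batch (per stream in stage 2).
#' @param test_fraction Held-out fraction for [split_dataset()].
#' @param lambda Weight of the entropy term in stage 2.
#' @param entropy_on_thick Also apply the entropy loss to thick-slice
#'   predictions in stage 2 (default FALSE: thin-only).
#' @param update_mode `"summed"` (one update from both losses) or
#'   `"alternating"` (separate consecutive updates per stream).
#' @param seed RNG seed governing initialization, augmentation and
#'   batch order.
#' @return Object of class `train_config`.
#' @export
train_config <- function(stage1_epochs = 200L, stage1_lr = 1e-3,
                         stage2_epochs = 100L, stage2_lr = 1e-4,
                         weight_decay = 1e-5, momentum = 0.9,
                         batch_size = 8L, test_fraction = 0.2,
                         lambda = 1, entropy_on_thick = FALSE,
                         update_mode = c("summed", "alternating"),
                         seed = 1L) {
  update_mode <- match.arg(update_mode)
  if (stage1_epochs < 1L) stop("stage1_epochs must be >= 1")
  if (stage2_epochs < 0L) stop("stage2_epochs must be >= 0")
  if (stage1_lr <= 0 || stage2_lr <= 0) stop("learning rates must be > 0")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly between 0 and 1")
  structure(list(stage1_epochs = as.integer(stage1_epochs), stage1_lr = stage1_lr,
                 stage2_epochs = as.integer(stage2_epochs), stage2_lr = stage2_lr,
                 weight_decay = weight_decay, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 test_fraction = test_fraction, lambda = lambda,
                 entropy_on_thick = entropy_on_thick,
                 update_mode = update_mode, seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training preset
#'
#' The configuration used by the package's own end-to-end tests:
#' 64 x 64 slices, small widths, tens of epochs -- minutes on one CPU
#' rather than GPU-hours. The learning rates are higher than the
#' full-scale defaults because the desk network is far smaller and
#' trains from far fewer slices; the schedule shape (SGD + momentum,
#' linear decay, two stages) is unchanged.
#' @param seed RNG seed.
#' @param stage1_epochs,stage2_epochs Scaled-down epoch counts.
#' @return A [train_config()].
#' @export
desk_config <- function(seed = 1L, stage1_epochs = 60L, stage2_epochs = 6L) {
  train_config(stage1_epochs = stage1_epochs, stage1_lr = 0.25,
               stage2_epochs = stage2_epochs, stage2_lr = 3e-5,
               batch_size = 4L, seed = seed)
}

#' Linearly decaying learning rate
#'
#' @param lr0 Initial learning rate.
#' @param epoch 1-based epoch index.
#' @param n_epochs Total epochs in the stage.
#' @return `lr0 * (1 - (epoch - 1) / n_epochs)`: `lr0` at the first
#'   epoch, `lr0 / n_epochs` at the last.
#' @export
lr_linear <- function(lr0, epoch, n_epochs) lr0 * (1 - (epoch - 1) / n_epochs)

#' Case-level train/test split
#'
#' Splits at the case (subject) level, never the slice level, so no
#' slice of a held-out subject is ever seen in training.
#'
#' @param cases List of cases (any list; elements are returned as-is).
#' @param test_fraction Fraction held out; `round(n * fraction)`,
#'   clamped to at least 1, must leave a nonempty training set.
#' @param seed RNG seed; the same seed always gives the same split.
#' @return List with `train` and `test` (disjoint, exhaustive).
#' @export
split_dataset <- function(cases, test_fraction = 0.2, seed = 1L) {
  n <- length(cases)
  if (n < 2L) stop("need at least 2 cases to split")
  n_test <- max(1L, round(n * test_fraction))
  if (n_test >= n) stop("test_fraction leaves an empty training set")
  idx <- with_seed(seed, sample.int(n, n_test))
  list(train = cases[-idx], test = cases[idx])
}

# ---- slice datasets ---------------------------------------------------

# Flatten cases into a pool of preprocessed training slices.
# `target` picks the supervision signal: multi-class ventricle labels
# or the binary brain mask. Returns list of list(x = HxW matrix, y).
slice_pool <- function(cases, stack = "thick", target = c("ventricle", "brain"),
                       labeled = TRUE) {
  target <- match.arg(target)
  pool <- list()
  for (cs in cases) {
    vol <- cs[[stack]]
    img <- preprocess_volume(vol$image)
    lab <- vol$labels
    for (i in seq_len(n_slices(img))) {
      y <- NULL
      if (labeled && !is.null(lab)) {
        y <- if (target == "ventricle") lab$labels[i, , ] else lab$brain_mask[i, , ]
        storage.mode(y) <- "integer"
      }
      pool[[length(pool) + 1L]] <- list(x = img$data[i, , ], y = y)
    }
  }
  pool
}

# ---- SGD machinery ----------------------------------------------------

# Parameters are named lists of layers; each layer holds conv kernel
# `w`, bias `b` and, for normalized layers, instance-norm gain `g` and
# shift `be`. The helpers below iterate whatever fields a layer has.

zero_like <- function(w) {
  lapply(w, function(p) lapply(p, function(v) {
    z <- v; z[] <- 0; z
  }))
}

acc_grads <- function(acc, g) {
  for (nm in names(g))
    for (f in names(g[[nm]]))
      acc[[nm]][[f]] <- acc[[nm]][[f]] + g[[nm]][[f]]
  acc
}

scale_grads <- function(g, s) lapply(g, function(p) lapply(p, function(v) v * s))

# SGD with momentum; L2 weight decay applies to conv kernels only
# (never to biases or normalization parameters).
sgd_update <- function(w, g, vel, lr, momentum, wd) {
  for (nm in names(w)) {
    for (f in names(g[[nm]])) {
      gf <- g[[nm]][[f]] + if (f == "w") wd * w[[nm]][[f]] else 0
      vel[[nm]][[f]] <- momentum * vel[[nm]][[f]] - lr * gf
      w[[nm]][[f]] <- w[[nm]][[f]] + vel[[nm]][[f]]
    }
  }
  list(w = w, vel = vel)
}

# Forward + supervised backward for one labeled slice.
step_supervised <- function(w, cfg, slice, aug) {
  x3 <- to_3channel(slice$x)
  y <- slice$y
  if (!is.null(aug)) {
    a <- augment(x3, y, aug)
    x3 <- a$image; y <- a$mask
  }
  fw <- forward_net(w, x3, cfg)
  p <- softmax_probs(fw$logits)
  loss <- suppressWarnings(supervised_loss(p, y))
  if (!is.finite(loss)) stop("training diverged: supervised loss is not finite")
  g <- backward_net(w, fw$cache, ce_grad_logits(p, y), cfg)
  list(loss = loss, g = g)
}

# Forward + entropy backward for one unlabeled slice.
step_entropy <- function(w, cfg, slice, aug, lambda) {
  x3 <- to_3channel(slice$x)
  if (!is.null(aug)) x3 <- augment(x3, NULL, aug)$image
  fw <- forward_net(w, x3, cfg)
  p <- softmax_probs(fw$logits)
  loss <- entropy_loss(p)
  if (!is.finite(loss)) stop("training diverged: entropy loss is not finite")
  g <- backward_net(w, fw$cache, lambda * entropy_grad_logits(p), cfg)
  list(loss = loss, g = g)
}

# ---- the fitting function --------------------------------------------

#' Fit the thickness-agnostic segmenter
#'
#' Two-stage training. Stage 1 ("pretrain"): supervised cross-entropy
#' on labeled thick-slice cases, SGD with momentum, learning rate
#' decaying linearly from `stage1_lr` to ~0. Stage 2 ("joint", run when
#' unlabeled thin cases are supplied and `stage2_epochs > 0`): every
#' step draws one thick batch and one thin batch and minimizes
#' `L = L_S + lambda * L_T` -- by default in a single summed update.
#' All randomness (weight init, augmentation, batch order) derives from
#' `config$seed`, so identical calls give identical weights.
#'
#' @param thick_cases List of labeled cases; each case needs
#'   `$thick$image` ([image_volume()]) and `$thick$labels`
#'   ([label_volume()]), as produced by [make_cohort()].
#' @param thin_cases Optional list of cases with `$thin$image`
#'   (labels, if present, are ignored: thin slices are unlabeled in
#'   training).
#' @param config A [train_config()].
#' @param model_cfg A [model_config()]; its `n_classes` must match the
#'   target (5 for `"ventricle"`, 2 for `"brain"`).
#' @param target `"ventricle"` (classes 0-4) or `"brain"` (binary
#'   intracranial mask); both run the same code path.
#' @param augment_cfg [augment_params()] for training-time
#'   augmentation, or `NULL` to disable. The default turns horizontal
#'   flipping off: classes 1 and 2 are lateralized (right/left lateral
#'   ventricle), and a flip that moves the anatomy while keeping the
#'   class ids would make the two classes statistically
#'   indistinguishable. Brightness scaling stays on.
#' @param run_dir Optional directory: config snapshot (YAML), per-epoch
#'   history (CSV), final checkpoint and a run log are written there.
#' @param pretrained Optional `ventseg` fit whose weights seed the
#'   model; stage 1 is then skipped and only the joint stage runs
#'   (resuming a supervised pretrain without repeating it).
#' @param verbose Print per-epoch losses.
#' @return Object of class `ventseg` with elements `weights`,
#'   `model_cfg`, `config`, `target` and `history` (one row per epoch
#'   across both stages: stage, epoch, lr, L_S, L_T, L).
#' @seealso [predict.ventseg()], [summary.ventseg()], [plot.ventseg()]
#' @export
ventseg_fit <- function(thick_cases, thin_cases = NULL,
                        config = train_config(),
                        model_cfg = model_config(),
                        target = c("ventricle", "brain"),
                        augment_cfg = augment_params(flip_prob = 0),
                        run_dir = NULL, pretrained = NULL, verbose = FALSE) {
  target <- match.arg(target)
  if (length(thick_cases) < 1L) stop("need at least one labeled thick case")
  expected_c <- if (target == "ventricle") 5L else 2L
  if (model_cfg$n_classes != expected_c)
    stop(sprintf("target '%s' needs n_classes = %d", target, expected_c))

  thick_pool <- slice_pool(thick_cases, "thick", target, labeled = TRUE)
  thin_pool <- if (!is.null(thin_cases))
    slice_pool(thin_cases, "thin", target, labeled = FALSE) else NULL

  if (!is.null(pretrained)) {
    stopifnot(inherits(pretrained, "ventseg"))
    if (pretrained$model_cfg$n_classes != model_cfg$n_classes)
      stop("pretrained fit has a different number of classes")
    model_cfg <- pretrained$model_cfg
  }

  hist_rows <- list()
  fit <- with_seed(config$seed, {
    w <- if (is.null(pretrained)) init_weights(model_cfg) else pretrained$weights
    vel <- zero_like(w)
    nb <- config$batch_size
    stage1_epochs <- if (is.null(pretrained)) config$stage1_epochs else 0L

    # stage 1: supervised pretraining on thick labeled slices
    for (ep in seq_len(stage1_epochs)) {
      lr <- lr_linear(config$stage1_lr, ep, config$stage1_epochs)
      ord <- sample.int(length(thick_pool))
      losses <- c()
      for (start in seq(1L, length(ord), by = nb)) {
        bidx <- ord[start:min(start + nb - 1L, length(ord))]
        acc <- zero_like(w)
        for (si in bidx) {
          st <- step_supervised(w, model_cfg, thick_pool[[si]], augment_cfg)
          acc <- acc_grads(acc, st$g)
          losses <- c(losses, st$loss)
        }
        upd <- sgd_update(w, scale_grads(acc, 1 / length(bidx)), vel, lr,
                          config$momentum, config$weight_decay)
        w <- upd$w; vel <- upd$vel
      }
      hist_rows[[length(hist_rows) + 1L]] <-
        data.frame(stage = 1L, epoch = ep, lr = lr,
                   L_S = mean(losses), L_T = NA_real_, L = mean(losses))
      if (verbose)
        message(sprintf("stage 1 epoch %d/%d  lr %.2e  L_S %.4f",
                        ep, config$stage1_epochs, lr, mean(losses)))
    }

    # stage 2: joint thick + thin training
    if (!is.null(thin_pool) && config$stage2_epochs > 0L) {
      vel <- zero_like(w)  # fresh momentum for the new schedule
      steps_per_epoch <- max(1L, ceiling(length(thick_pool) / nb))
      for (ep in seq_len(config$stage2_epochs)) {
        lr <- lr_linear(config$stage2_lr, ep, config$stage2_epochs)
        ord <- sample.int(length(thick_pool))
        ls_ep <- c(); lt_ep <- c()
        for (step in seq_len(steps_per_epoch)) {
          b0 <- (step - 1L) * nb
          bidx <- ord[(b0 + 1L):min(b0 + nb, length(ord))]
          tidx <- sample.int(length(thin_pool), min(nb, length(thin_pool)))
          acc_s <- zero_like(w); ns <- 0L
          for (si in bidx) {
            st <- step_supervised(w, model_cfg, thick_pool[[si]], augment_cfg)
            acc_s <- acc_grads(acc_s, st$g); ns <- ns + 1L
            ls_ep <- c(ls_ep, st$loss)
            if (config$entropy_on_thick) {
              se <- step_entropy(w, model_cfg, thick_pool[[si]], augment_cfg,
                                 config$lambda)
              acc_s <- acc_grads(acc_s, se$g)
            }
          }
          acc_t <- zero_like(w); nt <- 0L
          for (ti in tidx) {
            se <- step_entropy(w, model_cfg, thin_pool[[ti]], augment_cfg,
                               config$lambda)
            acc_t <- acc_grads(acc_t, se$g); nt <- nt + 1L
            lt_ep <- c(lt_ep, se$loss)
          }
          if (config$update_mode == "summed") {
            g <- acc_grads(scale_grads(acc_s, 1 / ns), scale_grads(acc_t, 1 / nt))
            upd <- sgd_update(w, g, vel, lr, config$momentum, config$weight_decay)
            w <- upd$w; vel <- upd$vel
          } else {
            upd <- sgd_update(w, scale_grads(acc_s, 1 / ns), vel, lr,
                              config$momentum, config$weight_decay)
            w <- upd$w; vel <- upd$vel
            upd <- sgd_update(w, scale_grads(acc_t, 1 / nt), vel, lr,
                              config$momentum, config$weight_decay)
            w <- upd$w; vel <- upd$vel
          }
        }
        hist_rows[[length(hist_rows) + 1L]] <-
          data.frame(stage = 2L, epoch = ep, lr = lr, L_S = mean(ls_ep),
                     L_T = mean(lt_ep), L = mean(ls_ep) + config$lambda * mean(lt_ep))
        if (verbose)
          message(sprintf("stage 2 epoch %d/%d  lr %.2e  L_S %.4f  L_T %.4f",
                          ep, config$stage2_epochs, lr, mean(ls_ep), mean(lt_ep)))
      }
    }
    w
  })

  history <- do.call(rbind, hist_rows)
  obj <- structure(list(weights = fit, model_cfg = model_cfg, config = config,
                        target = target, history = history),
                   class = "ventseg")
  if (!is.null(run_dir)) save_run(obj, run_dir)
  obj
}

save_run <- function(obj, run_dir) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(list(model = unclass(obj$model_cfg),
                        train = unclass(obj$config),
                        target = obj$target),
                   file.path(run_dir, "config.yaml"))
  write.csv(obj$history, file.path(run_dir, "history.csv"), row.names = FALSE)
  save_checkpoint(obj, file.path(run_dir, "checkpoint.rds"))
  writeLines(c(sprintf("seed: %d", obj$config$seed),
               sprintf("R: %s", R.version.string),
               sprintf("ventseg: %s",
                       as.character(utils::packageVersion("ventseg"))),
               sprintf("finished: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(run_dir, "run.log"))
  invisible(run_dir)
}

#' Save / load a fitted segmenter checkpoint
#'
#' Weights plus both configs in a single RDS container, with the model
#' config additionally serialized as YAML next to it.
#' @param obj A `ventseg` fit.
#' @param path Checkpoint file path (`.rds`).
#' @return `path`, invisibly (`load_checkpoint` returns the fit).
#' @export
save_checkpoint <- function(obj, path) {
  stopifnot(inherits(obj, "ventseg"))
  saveRDS(obj, path)
  yaml::write_yaml(unclass(obj$model_cfg),
                   paste0(sub("\\.rds$", "", path), "_model.yaml"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "ventseg")) stop("not a ventseg checkpoint: ", path)
  obj
}

# ---- S3 methods -------------------------------------------------------

#' @export
print.ventseg <- function(x, ...) {
  cat(sprintf("<ventseg> %s segmenter (%d classes), widths %s\n",
              x$target, x$model_cfg$n_classes,
              paste(x$model_cfg$widths, collapse = "/")))
  s1 <- subset(x$history, x$history$stage == 1L)
  cat(sprintf("  stage 1: %d epochs, final L_S %.4f\n",
              nrow(s1), s1$L_S[nrow(s1)]))
  s2 <- subset(x$history, x$history$stage == 2L)
  if (nrow(s2) > 0)
    cat(sprintf("  stage 2: %d epochs, final L_S %.4f, L_T %.4f\n",
                nrow(s2), s2$L_S[nrow(s2)], s2$L_T[nrow(s2)]))
  invisible(x)
}

#' Summarize a fitted segmenter
#' @param object A `ventseg` fit.
#' @param ... Unused.
#' @export
summary.ventseg <- function(object, ...) {
  np <- sum(vapply(object$weights,
                   function(p) sum(lengths(p)), numeric(1)))
  structure(list(target = object$target, n_classes = object$model_cfg$n_classes,
                 n_parameters = np, history = object$history),
            class = "summary.ventseg")
}

#' @export
print.summary.ventseg <- function(x, ...) {
  cat(sprintf("ventseg %s model: %d classes, %d parameters\n",
              x$target, x$n_classes, x$n_parameters))
  cat("training history (last rows):\n")
  print(utils::tail(x$history, 4), row.names = FALSE)
  invisible(x)
}

#' Predict segmentation for a new volume
#'
#' @param object A `ventseg` fit.
#' @param newdata An [image_volume()].
#' @param type `"labels"` (stacked argmax label array, the default) or
#'   `"prob"` (list of per-slice probability maps).
#' @param ... Unused.
#' @return For `"labels"`, a list with `labels` and `spacing` (see
#'   [predict_volume()]); for `"prob"`, a list of `H x W x C` arrays.
#' @export
predict.ventseg <- function(object, newdata, type = c("labels", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "image_volume"))
  if (type == "labels") return(predict_volume(object$weights, newdata))
  img <- preprocess_volume(newdata)
  lapply(seq_len(n_slices(img)),
         function(i) forward_slice(object$weights, to_3channel(img$data[i, , ])))
}

#' @export
coef.ventseg <- function(object, ...) object$weights

#' Plot training-loss history
#' @param x A `ventseg` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ventseg <- function(x, ...) {
  h <- x$history
  idx <- seq_len(nrow(h))
  graphics::plot(idx, h$L_S, type = "l", xlab = "epoch (both stages)",
                 ylab = "loss", col = "firebrick", ...)
  if (any(!is.na(h$L_T)))
    graphics::lines(idx, h$L_T, col = "steelblue")
  if (any(h$stage == 2L))
    graphics::abline(v = sum(h$stage == 1L) + 0.5, lty = 3)
  graphics::legend("topright", c("L_S", "L_T"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Pooled ventricle Dice of a fit over a cohort
#'
#' Segments each case's chosen stack and reports, per case, the Dice
#' overlap of the predicted against the true foreground: the union of
#' the four ventricle classes for a ventricle model, the brain mask for
#' a brain model.
#'
#' @param object A `ventseg` fit.
#' @param cases Cohort cases (as from [make_cohort()]).
#' @param stack `"thick"` or `"thin"`.
#' @return Numeric vector of per-case Dice coefficients.
#' @export
cohort_dice <- function(object, cases, stack = c("thick", "thin")) {
  stack <- match.arg(stack)
  vapply(cases, function(cs) {
    pred <- predict_volume(object$weights, cs[[stack]]$image)
    truth <- if (object$target == "ventricle") cs[[stack]]$labels$labels > 0L
             else cs[[stack]]$labels$brain_mask > 0L
    dice(pred$labels > 0L, truth)
  }, numeric(1))
}
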