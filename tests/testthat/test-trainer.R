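test_that("dataset splitting is case-level, seeded, and exhaustive", {
  cases <- lapply(1:10, function(i) list(case_id = sprintf("c%02d", i)))
  sp <- split_dataset(cases, 0.2, seed = 3)
  expect_length(sp$test, 2)
  expect_length(sp$train, 8)
  ids <- function(x) vapply(x, `[[`, "", "case_id")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(cases))
  # reproducible
  sp2 <- split_dataset(cases, 0.2, seed = 3)
  expect_identical(ids(sp$test), ids(sp2$test))
  # errors
  expect_error(split_dataset(cases[1], 0.2), "at least 2")
  expect_error(split_dataset(cases, 0.96), "empty training")
  expect_error(train_config(test_fraction = 0), "strictly between")
})

test_that("the learning rate decays linearly from lr0 toward zero", {
  expect_equal(lr_linear(1e-3, 1, 200), 1e-3)
  expect_equal(lr_linear(1e-3, 200, 200), 1e-3 / 200)
  lrs <- sapply(1:50, lr_linear, lr0 = 0.1, n_epochs = 50)
  expect_true(all(diff(lrs) < 0))
  expect_gt(min(lrs), 0)
})

test_that("training configs carry the full-scale schedule as defaults", {
  cfg <- train_config()
  expect_identical(cfg$stage1_epochs, 200L)
  expect_equal(cfg$stage1_lr, 1e-3)
  expect_identical(cfg$stage2_epochs, 100L)
  expect_equal(cfg$stage2_lr, 1e-4)
  expect_equal(cfg$weight_decay, 1e-5)
  expect_equal(cfg$test_fraction, 0.2)
  expect_error(train_config(stage1_epochs = 0), "stage1_epochs")
  expect_error(train_config(stage1_lr = -1), "learning rates")
})

test_that("a short fit runs both stages, logs history, and is deterministic", {
  co <- tiny_cohort(3, seed = 20)
  cfg <- train_config(stage1_epochs = 3L, stage1_lr = 0.05,
                      stage2_epochs = 2L, stage2_lr = 0.01,
                      batch_size = 4L, seed = 5L)
  f1 <- ventseg_fit(co, thin_cases = co, config = cfg, target = "ventricle")
  expect_s3_class(f1, "ventseg")
  expect_identical(nrow(f1$history), 5L)  # stage1 + stage2 epochs
  expect_identical(f1$history$stage, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(f1$history$lr[1], 0.05)
  expect_true(all(is.na(f1$history$L_T[1:3])))
  expect_true(all(is.finite(f1$history$L_T[4:5])))
  # identical seeds give bit-identical weights
  f2 <- ventseg_fit(co, thin_cases = co, config = cfg, target = "ventricle")
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
  # different seed moves the weights
  cfg2 <- cfg; cfg2$seed <- 6L
  f3 <- ventseg_fit(co, thin_cases = co, config = cfg2, target = "ventricle")
  expect_false(identical(f1$weights$head$w, f3$weights$head$w))
  # a 1-epoch run has a 1-row history
  cfg1 <- train_config(stage1_epochs = 1L, stage2_epochs = 0L,
                       stage1_lr = 0.05, batch_size = 4L, seed = 1L)
  expect_identical(nrow(ventseg_fit(co[1], config = cfg1)$history), 1L)
})

test_that("the entropy loss trends downward when thin equals thick unlabeled", {
  # joint training where the unlabeled stream is the thick stack with
  # its labels hidden: no domain gap, so entropy minimization should
  # make the L_T trajectory nonincreasing in trend
  co <- tiny_cohort(4, seed = 31)
  hidden <- lapply(co, function(cs) {
    cs$thin <- list(image = cs$thick$image, labels = NULL)
    cs
  })
  cfg <- train_config(stage1_epochs = 8L, stage1_lr = 0.1,
                      stage2_epochs = 6L, stage2_lr = 5e-3,
                      batch_size = 4L, seed = 13L)
  fit <- ventseg_fit(co, thin_cases = hidden, config = cfg)
  lt <- fit$history$L_T[fit$history$stage == 2L]
  expect_length(lt, 6L)
  expect_lte(median(tail(lt, 3)), median(head(lt, 3)))
})

test_that("a zero-weight entropy term makes thin data irrelevant", {
  co <- tiny_cohort(4, seed = 21)
  cfg <- train_config(stage1_epochs = 2L, stage1_lr = 0.05,
                      stage2_epochs = 2L, stage2_lr = 0.01,
                      batch_size = 4L, lambda = 0, seed = 9L)
  f_a <- ventseg_fit(co[1:2], thin_cases = co[1:2], config = cfg)
  f_b <- ventseg_fit(co[1:2], thin_cases = co[3:4], config = cfg)
  # same thin-pool size, different content: with lambda = 0 the final
  # weights coincide exactly
  expect_identical(f_a$weights, f_b$weights)
})

test_that("resuming from a pretrained fit skips stage 1", {
  co <- tiny_cohort(2, seed = 22)
  cfg1 <- train_config(stage1_epochs = 2L, stage1_lr = 0.05,
                       stage2_epochs = 0L, batch_size = 4L, seed = 2L)
  f1 <- ventseg_fit(co, config = cfg1)
  cfg2 <- train_config(stage1_epochs = 2L, stage1_lr = 0.05,
                       stage2_epochs = 1L, stage2_lr = 0.01,
                       batch_size = 4L, seed = 2L)
  f2 <- ventseg_fit(co, thin_cases = co, config = cfg2, pretrained = f1)
  expect_identical(nrow(f2$history), 1L)
  expect_identical(f2$history$stage, 2L)
})

test_that("fit objects expose the standard modelling methods", {
  co <- tiny_cohort(2, seed = 23)
  cfg <- train_config(stage1_epochs = 2L, stage1_lr = 0.05,
                      stage2_epochs = 0L, batch_size = 4L, seed = 3L)
  fit <- ventseg_fit(co, config = cfg)
  expect_output(print(fit), "ventricle segmenter")
  s <- summary(fit)
  expect_gt(s$n_parameters, 1000)
  expect_output(print(s), "parameters")
  expect_named(coef(fit), names(fit$weights))
  pred <- predict(fit, co[[1]]$thin$image)
  expect_identical(dim(pred$labels), dim(co[[1]]$thin$image$data))
  probs <- predict(fit, co[[1]]$thick$image, type = "prob")
  expect_length(probs, dim(co[[1]]$thick$image$data)[1])
  expect_identical(dim(probs[[1]])[3], 5L)
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
  # dice helper returns one value per case, all in [0, 1]
  d <- cohort_dice(fit, co, "thick")
  expect_length(d, 2)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("run directories capture config, history, checkpoint and log", {
  co <- tiny_cohort(2, seed = 24)
  cfg <- train_config(stage1_epochs = 1L, stage1_lr = 0.05,
                      stage2_epochs = 0L, batch_size = 4L, seed = 4L)
  rd <- file.path(tempdir(), "ventseg-run-test")
  fit <- ventseg_fit(co, config = cfg, run_dir = rd)
  expect_true(file.exists(file.path(rd, "config.yaml")))
  expect_true(file.exists(file.path(rd, "history.csv")))
  expect_true(file.exists(file.path(rd, "checkpoint.rds")))
  expect_true(any(grepl("seed: 4", readLines(file.path(rd, "run.log")))))
  h <- read.csv(file.path(rd, "history.csv"))
  expect_identical(nrow(h), 1L)
  reloaded <- load_checkpoint(file.path(rd, "checkpoint.rds"))
  expect_identical(reloaded$weights, fit$weights)
  unlink(rd, recursive = TRUE)
})

test_that("mismatched targets and class counts are rejected", {
  co <- tiny_cohort(2, seed = 25)
  expect_error(ventseg_fit(co, config = train_config(),
                           model_cfg = model_config(n_classes = 2),
                           target = "ventricle"), "n_classes")
  expect_error(ventseg_fit(list(), config = train_config()), "at least one")
})
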