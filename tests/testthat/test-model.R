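test_that("sub-pixel rearrangement places channel blocks row-major", {
  x <- array(c(10, 20, 30, 40), c(1, 1, 4))
  y <- subpixel_rearrange(x, 2)
  expect_identical(dim(y), c(2L, 2L, 1L))
  expect_equal(y[, , 1], matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE))
  # r = 1 identity
  z <- array(rnorm(12), c(2, 2, 3))
  expect_identical(subpixel_rearrange(z, 1), z)
})

test_that("sub-pixel rearrangement is a bijection with an exact inverse", {
  set.seed(2)
  x <- array(rnorm(3 * 3 * 8), c(3, 3, 8))
  y <- subpixel_rearrange(x, 2)
  expect_identical(dim(y), c(6L, 6L, 2L))
  expect_equal(sort(as.vector(y)), sort(as.vector(x)))  # multiset equality
  expect_equal(subpixel_collapse(y, 2), x)
  expect_error(subpixel_rearrange(array(0, c(2, 2, 6)), 2), "C = 6.*r\\^2 = 4")
})

test_that("sub-pixel placement matches its definition exhaustively (H,W,r <= 3)", {
  for (H in 1:3) for (W in 1:3) for (r in 1:3) for (C in 1:2) {
    x <- array(seq_len(H * W * C * r^2), c(H, W, C * r^2))
    y <- subpixel_rearrange(x, r)
    expect_identical(dim(y), c(r * H, r * W, C))
    for (i in 0:(H - 1)) for (j in 0:(W - 1)) for (c in 0:(C - 1))
      for (a in 0:(r - 1)) for (b in 0:(r - 1))
        expect_identical(y[r * i + a + 1, r * j + b + 1, c + 1],
                         x[i + 1, j + 1, c * r^2 + a * r + b + 1])
    expect_equal(subpixel_collapse(y, r), x)
  }
})

test_that("decoder block is convolution followed by rearrangement", {
  set.seed(5)
  x <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
  # identity 1x1 convolution with zero bias = pure rearrangement
  C <- 2; r <- 2
  k_id <- array(0, c(1, 1, 2, C * r^2))
  # map input channel ci to output channels so that the conv output
  # equals an [x replicated across r^2 blocks] tensor
  for (ci in 1:2) for (blk in 1:(r^2)) k_id[1, 1, ci, (ci - 1) * r^2 + blk] <- 1
  y <- decoder_block(x, k_id, numeric(C * r^2), r)
  expect_identical(dim(y), c(8L, 12L, 2L))
  # each input value fills its whole r x r patch
  expect_equal(y[1:2, 1:2, 1], matrix(x[1, 1, 1], 2, 2))
  # zero kernel, bias b: output is the rearranged constant-b map
  b <- seq_len(C * r^2)
  y0 <- decoder_block(x, array(0, c(3, 3, 2, C * r^2)), b, r)
  expect_equal(y0[1:2, 1:2, 1], matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  # shape contract over random configurations
  for (rr in c(1, 2)) for (Cc in c(1, 3)) {
    xx <- array(rnorm(5 * 7 * 4), c(5, 7, 4))
    kk <- array(rnorm(3 * 3 * 4 * Cc * rr^2, 0, 0.1), c(3, 3, 4, Cc * rr^2))
    yy <- decoder_block(xx, kk, rnorm(Cc * rr^2), rr)
    expect_identical(dim(yy), as.integer(c(5 * rr, 7 * rr, Cc)))
  }
  expect_error(decoder_block(x, array(0, c(3, 3, 5, 8)), numeric(8), 2),
               "channels")
})

test_that("forward pass yields a valid probability map, deterministically", {
  set.seed(21)
  w <- init_weights(model_config())
  ph <- make_phantom(phantom_spec(seed = 3))
  img <- preprocess_volume(ph$image)
  sl <- to_3channel(img$data[10, , ])
  p1 <- forward_slice(w, sl)
  expect_identical(dim(p1), c(64L, 64L, 5L))
  sums <- apply(p1, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(p1 >= 0))
  # repeated evaluation is bit-identical
  expect_identical(forward_slice(w, sl), p1)
  # random init spreads mass over all classes
  expect_true(all(apply(p1, 3, sum) > 0))
  expect_error(forward_slice(w, img$data[10, , ]), "channels")
})

test_that("forward pass pads odd spatial sizes and crops the output back", {
  set.seed(22)
  w <- init_weights(model_config())
  sl <- array(rnorm(33 * 50 * 3), c(33, 50, 3))
  p <- forward_slice(w, sl)
  expect_identical(dim(p), c(33L, 50L, 5L))
})

test_that("argmax labeling breaks ties toward the lowest class", {
  p <- array(1 / 5, c(2, 2, 5))        # uniform everywhere
  expect_true(all(prob_to_labels(p) == 0L))
  p[1, 1, ] <- c(0.1, 0.4, 0.4, 0.05, 0.05)  # tie between classes 1 and 2
  expect_identical(prob_to_labels(p)[1, 1], 1L)
})

test_that("volume prediction stacks slices and copies spacing", {
  set.seed(23)
  w <- init_weights(model_config())
  ph <- make_phantom(tiny_spec(seed = 4))
  pred <- predict_volume(w, ph$image)
  expect_identical(dim(pred$labels), dim(ph$image$data))
  expect_identical(pred$spacing, ph$image$spacing)
  # single-slice volume stays single-slice
  one <- image_volume(ph$image$data[1, , , drop = FALSE], ph$image$spacing, "CT")
  p1 <- predict_volume(w, one)
  expect_identical(dim(p1$labels)[1], 1L)
  # uniform-probability model (zero head) assigns class 0 everywhere
  w0 <- w; w0$head$w[] <- 0; w0$head$b[] <- 0
  pu <- predict_volume(w0, ph$image)
  expect_true(all(pu$labels == 0L))
})

test_that("model configuration is validated", {
  expect_error(model_config(n_classes = 1), "n_classes")
  expect_error(model_config(upscale_factors = c(2, 2, 1)), "product")
  expect_error(model_config(widths = c(8, 16)), "3 positive")
  cfg <- model_config(n_classes = 2)
  w <- with(list(), { set.seed(1); init_weights(cfg) })
  expect_identical(dim(w$head$w)[4], 2L)
})

test_that("whole-brain and ventricle models share the code path", {
  set.seed(24)
  wb <- init_weights(model_config(n_classes = 2))
  ph <- make_phantom(tiny_spec(seed = 4))
  p <- forward_slice(wb, to_3channel(preprocess_volume(ph$image)$data[5, , ]))
  expect_identical(dim(p)[3], 2L)
  expect_true(all(abs(apply(p, c(1, 2), sum) - 1) < 1e-5))
})
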