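# Slice-wise encoder-decoder segmenter: residual convolutional encoder,
# sub-pixel-convolution decoder with skip connections, softmax head.
# Forward and backward passes are explicit (no autodiff framework);
# convolutions run through the im2col/GEMM kernels in src/conv.cpp.

#' Segmenter architecture configuration
#'
#' The network is a three-stage residual encoder (stride-2 stem, then
#' two stride-2 downsamplings, one residual block per stage) and a
#' three-stage sub-pixel-convolution decoder (each stage convolves to
#' `C * r^2` channels and rearranges to `r`-times the resolution;
#' decoder stages 1-2 add skip connections from the matching encoder
#' stage). A 1x1 convolution and softmax produce per-pixel class
#' probabilities. The product of the upscale factors equals the total
#' encoder stride, so output resolution equals input resolution.
#'
#' @param n_classes Number of output classes (>= 2): 5 for the
#'   ventricle model (background + 4 ventricles), 2 for the whole-brain
#'   model.
#' @param widths Integer length-3, channel widths of the encoder stages.
#'   The default `(8, 16, 32)` is the desk-scale preset.
#' @param upscale_factors Integer length-3, per-decoder-stage sub-pixel
#'   factors `r`; their product must equal 8 (the encoder stride).
#' @param in_channels Input channels (3: replicated grayscale).
#' @param use_pretrained_encoder If `TRUE`, encoder weights are expected
#'   to be loaded from a checkpoint instead of randomly initialized
#'   (off by default; no weights ship with the package).
#' @return Object of class `model_config`.
#' @export
model_config <- function(n_classes = 5L, widths = c(8L, 16L, 32L),
                         upscale_factors = c(2L, 2L, 2L),
                         in_channels = 3L,
                         use_pretrained_encoder = FALSE) {
  n_classes <- as.integer(n_classes)
  widths <- as.integer(widths)
  upscale_factors <- as.integer(upscale_factors)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (length(widths) != 3L || any(widths < 1L))
    stop("widths must be 3 positive integers")
  if (any(upscale_factors < 1L)) stop("all upscale factors must be >= 1")
  if (prod(upscale_factors) != 8L)
    stop("product of upscale_factors must equal the encoder stride (8)")
  structure(list(n_classes = n_classes, widths = widths,
                 upscale_factors = upscale_factors,
                 in_channels = as.integer(in_channels),
                 use_pretrained_encoder = use_pretrained_encoder),
            class = "model_config")
}

#' Sub-pixel rearrangement (pixel shuffle)
#'
#' Bijectively rearranges an `H x W x (C * r^2)` tensor into
#' `rH x rW x C`: the channel block `c*r^2 .. c*r^2 + r^2 - 1` (0-based)
#' at spatial position `(i, j)` fills the r-by-r output patch at rows
#' `r*i .. r*i + r - 1`, columns `r*j .. r*j + r - 1` of output channel
#' `c`, row-major within the patch. This is the upsampling primitive of
#' the sub-pixel-convolution decoder.
#'
#' @param feature `H x W x C3` numeric array with `C3` divisible by
#'   `r^2`.
#' @param r Integer upscale factor >= 1.
#' @return `rH x rW x (C3 / r^2)` array.
#' @export
subpixel_rearrange <- function(feature, r) {
  stopifnot(length(dim(feature)) == 3L)
  r <- as.integer(r)
  if (r < 1L) stop("r must be >= 1")
  if (r == 1L) return(feature)
  d <- dim(feature)
  if (d[3] %% (r * r) != 0L)
    stop(sprintf("channel count C = %d is not divisible by r^2 = %d", d[3], r * r))
  C <- d[3] %/% (r * r)
  x5 <- feature
  dim(x5) <- c(d[1], d[2], r, r, C)          # [i, j, b, a, c], patch col b fastest
  out <- aperm(x5, c(4L, 1L, 3L, 2L, 5L))    # [a, i, b, j, c]
  dim(out) <- c(r * d[1], r * d[2], C)
  out
}

#' Inverse of [subpixel_rearrange()]
#'
#' @param feature `rH x rW x C` array with both spatial dims divisible
#'   by `r`.
#' @param r Integer upscale factor >= 1.
#' @return `H x W x (C * r^2)` array; composing with
#'   [subpixel_rearrange()] gives back the input.
#' @export
subpixel_collapse <- function(feature, r) {
  stopifnot(length(dim(feature)) == 3L)
  r <- as.integer(r)
  if (r < 1L) stop("r must be >= 1")
  if (r == 1L) return(feature)
  d <- dim(feature)
  if (d[1] %% r != 0L || d[2] %% r != 0L)
    stop("spatial dimensions must be divisible by r")
  H <- d[1] %/% r; W <- d[2] %/% r; C <- d[3]
  y5 <- feature
  dim(y5) <- c(r, H, r, W, C)                # [a, i, b, j, c]
  out <- aperm(y5, c(2L, 4L, 3L, 1L, 5L))    # [i, j, b, a, c]
  dim(out) <- c(H, W, C * r * r)
  out
}

#' One sub-pixel decoder block: convolution then rearrangement
#'
#' Computes `SP(W * F + b)`: convolves the feature map to `C * r^2`
#' channels (same padding, stride 1) and applies
#' [subpixel_rearrange()], so the output has `r`-times the spatial
#' resolution. This is the plain building block; the fitted network
#' additionally normalizes and adds skip connections.
#'
#' @param feature `H x W x Cin` array.
#' @param kernel `kh x kw x Cin x (C * r^2)` convolution kernel.
#' @param bias Length `C * r^2` bias vector.
#' @param r Integer upscale factor.
#' @return `rH x rW x C` array.
#' @export
decoder_block <- function(feature, kernel, bias, r) {
  if (length(dim(feature)) != 3L) stop("feature must be H x W x C")
  dk <- dim(kernel)
  if (length(dk) != 4L || dk[3] != dim(feature)[3])
    stop(sprintf("kernel input channels (%d) must match feature channels (%d)",
                 if (length(dk) == 4L) dk[3] else NA_integer_, dim(feature)[3]))
  y <- conv_fwd(feature, list(w = kernel, b = bias))
  subpixel_rearrange(y, r)
}

# ---- layer primitives -------------------------------------------------

conv_param <- function(kh, kw, ci, co, init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- sqrt(2 / (kh * kw * ci))  # He init
  list(w = array(stats::rnorm(kh * kw * ci * co, 0, init_sd), c(kh, kw, ci, co)),
       b = numeric(co))
}

conv_fwd <- function(x, p, stride = 1L, pad = NULL) {
  d <- dim(p$w)
  if (is.null(pad)) pad <- (d[1] - 1L) %/% 2L
  cpp_conv2d_fwd(x, matrix(p$w, d[1] * d[2] * d[3], d[4]), p$b,
                 d[1], d[2], stride, pad)
}

conv_bwd <- function(x, p, dy, stride = 1L, pad = NULL) {
  d <- dim(p$w)
  if (is.null(pad)) pad <- (d[1] - 1L) %/% 2L
  g <- cpp_conv2d_bwd(x, matrix(p$w, d[1] * d[2] * d[3], d[4]), dy,
                      d[1], d[2], stride, pad)
  dim(g$dw) <- d
  g
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Numerically stable per-pixel softmax over the channel axis
#' @param z `H x W x C` logits.
#' @return `H x W x C` probabilities summing to 1 at every pixel.
#' @export
softmax_probs <- function(z) {
  d <- dim(z)
  m <- matrix(z, d[1] * d[2], d[3])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  array(p, d)
}

# ---- the network ------------------------------------------------------

# ---- instance normalization ------------------------------------------
# Each channel of a feature map is standardized over its spatial
# extent, then rescaled by learned per-channel gain/shift (gamma,
# beta). This is the batch-size-agnostic, eval-deterministic
# counterpart of the batch normalization inside standard residual
# encoders; without any normalization the 13-conv stack is too badly
# conditioned to train in reasonable time.

inorm_fwd <- function(x, g, b, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xh <- sweep(xc, 2, inv, "*")
  y <- sweep(sweep(xh, 2, g, "*"), 2, b, "+")
  list(y = array(y, d), xh = xh, inv = inv)
}

inorm_bwd <- function(cache, g, dy) {
  d <- dim(dy)
  dym <- matrix(dy, d[1] * d[2], d[3])
  dg <- colSums(dym * cache$xh)
  db <- colSums(dym)
  dxh <- sweep(dym, 2, g, "*")
  mdxh <- colMeans(dxh)
  mdxhxh <- colMeans(dxh * cache$xh)
  dx <- sweep(dxh, 2, mdxh) - sweep(cache$xh, 2, mdxhxh, "*")
  dx <- sweep(dx, 2, cache$inv, "*")
  list(dx = array(dx, d), dg = dg, db = db)
}

# conv -> instance norm, with cache for the backward pass
cin_fwd <- function(x, p, stride = 1L) {
  h <- conv_fwd(x, p, stride = stride)
  nrm <- inorm_fwd(h, p$g, p$be)
  list(y = nrm$y, x = x, h = h, nrm = nrm)
}

cin_bwd <- function(cache, p, dy, stride = 1L) {
  nb <- inorm_bwd(cache$nrm, p$g, dy)
  cb <- conv_bwd(cache$x, p, nb$dx, stride = stride)
  list(dx = cb$dx, g = list(w = cb$dw, b = cb$db, g = nb$dg, be = nb$db))
}

#' Initialize segmenter weights
#'
#' He-normal random initialization of every convolution; every conv
#' except the head is followed by instance normalization whose
#' per-channel gain/shift start at (1, 0) -- except the second conv of
#' each residual block, whose gain starts at 0 so the block begins as
#' the identity -- and the classification head is scaled down so
#' initial logits are near zero (near-uniform softmax). Call inside a
#' seeded context for reproducibility.
#' @param cfg A [model_config()].
#' @return Named list of layer parameters (class `ventseg_weights`):
#'   each layer has conv kernel `w`, bias `b` and, for normalized
#'   layers, instance-norm gain `g` and shift `be`.
#' @export
init_weights <- function(cfg) {
  f <- cfg$widths; C <- cfg$n_classes
  r <- cfg$upscale_factors
  cp <- function(kh, kw, ci, co) {
    p <- conv_param(kh, kw, ci, co)
    p$g <- rep(1, co); p$be <- rep(0, co)
    p
  }
  w <- list(
    stem  = cp(3, 3, cfg$in_channels, f[1]),
    res1a = cp(3, 3, f[1], f[1]), res1b = cp(3, 3, f[1], f[1]),
    down1 = cp(3, 3, f[1], f[2]),
    res2a = cp(3, 3, f[2], f[2]), res2b = cp(3, 3, f[2], f[2]),
    down2 = cp(3, 3, f[2], f[3]),
    res3a = cp(3, 3, f[3], f[3]), res3b = cp(3, 3, f[3], f[3]),
    up1   = cp(3, 3, f[3] + 2L, f[2] * r[1]^2),
    up2   = cp(3, 3, f[2] + 2L, f[1] * r[2]^2),
    up3   = cp(3, 3, f[1] + 2L, f[1] * r[3]^2),
    head  = conv_param(1, 1, f[1], C)
  )
  for (nm in c("res1b", "res2b", "res3b")) w[[nm]]$g[] <- 0
  w$head$w <- w$head$w * 0.05
  structure(w, class = "ventseg_weights", config = cfg)
}

# Append two fixed channels holding the normalized (y, x) coordinates
# of each position, in [-1, 1].
append_coords <- function(x) {
  d <- dim(x)
  yc <- if (d[1] > 1) seq(-1, 1, length.out = d[1]) else 0
  xc <- if (d[2] > 1) seq(-1, 1, length.out = d[2]) else 0
  out <- array(0, c(d[1], d[2], d[3] + 2L))
  out[, , seq_len(d[3])] <- x
  out[, , d[3] + 1L] <- matrix(yc, d[1], d[2])
  out[, , d[3] + 2L] <- matrix(xc, d[1], d[2], byrow = TRUE)
  out
}

res_block_fwd <- function(x, pa, pb) {
  c1 <- cin_fwd(x, pa); a1 <- relu(c1$y)
  c2 <- cin_fwd(a1, pb)
  out <- relu(c2$y + x)
  list(out = out, x = x, c1 = c1, a1 = a1, c2 = c2, pre = c2$y + x)
}

res_block_bwd <- function(cache, pa, pb, dout) {
  dpre <- dout * (cache$pre > 0)
  bb <- cin_bwd(cache$c2, pb, dpre)
  da1 <- bb$dx * (cache$c1$y > 0)
  ba <- cin_bwd(cache$c1, pa, da1)
  list(dx = ba$dx + dpre, ga = ba$g, gb = bb$g)
}

#' Forward pass: one 3-channel slice to per-pixel logits
#' @noRd
forward_net <- function(w, x, cfg) {
  r <- cfg$upscale_factors
  cache <- list(x = x)
  cache$stem <- cin_fwd(x, w$stem, stride = 2L)
  s0 <- relu(cache$stem$y)
  cache$r1 <- res_block_fwd(s0, w$res1a, w$res1b)       # skip 1
  cache$d1 <- cin_fwd(cache$r1$out, w$down1, stride = 2L)
  d1 <- relu(cache$d1$y)
  cache$r2 <- res_block_fwd(d1, w$res2a, w$res2b)       # skip 2
  cache$d2 <- cin_fwd(cache$r2$out, w$down2, stride = 2L)
  d2 <- relu(cache$d2$y)
  cache$r3 <- res_block_fwd(d2, w$res3a, w$res3b)

  # coordinate channels at the deepest stage: ventricle classes are
  # defined by where they sit (left/right of midline, inferior fourth),
  # and a fully convolutional net has no other access to absolute
  # position at desk scale
  cache$u1 <- cin_fwd(append_coords(cache$r3$out), w$up1)  # deepest
  u1 <- subpixel_rearrange(cache$u1$y, r[1])
  cache$u1_pre <- u1 + cache$r2$out                     # skip add
  a_u1 <- relu(cache$u1_pre)
  cache$u2 <- cin_fwd(append_coords(a_u1), w$up2)
  u2 <- subpixel_rearrange(cache$u2$y, r[2])
  cache$u2_pre <- u2 + cache$r1$out
  a_u2 <- relu(cache$u2_pre)
  cache$u3 <- cin_fwd(append_coords(a_u2), w$up3)
  u3 <- subpixel_rearrange(cache$u3$y, r[3])
  cache$u3_pre <- u3
  a_u3 <- relu(u3)
  cache$a_u3 <- a_u3
  logits <- conv_fwd(a_u3, w$head, pad = 0L)
  list(logits = logits, cache = cache)
}

#' Backward pass: gradient of a scalar loss w.r.t. all weights
#' @noRd
backward_net <- function(w, cache, dlogits, cfg) {
  r <- cfg$upscale_factors
  g <- list()
  gh <- conv_bwd(cache$a_u3, w$head, dlogits, pad = 0L)
  g$head <- list(w = gh$dw, b = gh$db)
  d_u3 <- gh$dx * (cache$u3_pre > 0)
  b_u3 <- cin_bwd(cache$u3, w$up3, subpixel_collapse(d_u3, r[3]))
  g$up3 <- b_u3$g
  nc2 <- dim(cache$u2_pre)[3]
  d_u2pre <- b_u3$dx[, , seq_len(nc2), drop = FALSE] * (cache$u2_pre > 0)
  b_u2 <- cin_bwd(cache$u2, w$up2, subpixel_collapse(d_u2pre, r[2]))
  g$up2 <- b_u2$g
  nc1 <- dim(cache$u1_pre)[3]
  d_u1pre <- b_u2$dx[, , seq_len(nc1), drop = FALSE] * (cache$u1_pre > 0)
  b_u1 <- cin_bwd(cache$u1, w$up1, subpixel_collapse(d_u1pre, r[1]))
  g$up1 <- b_u1$g
  nf3 <- dim(cache$r3$out)[3]
  d_r3 <- b_u1$dx[, , seq_len(nf3), drop = FALSE]  # coords carry no gradient

  # decoder skip adds feed gradient back into encoder stages
  b3 <- res_block_bwd(cache$r3, w$res3a, w$res3b, d_r3)
  g$res3a <- b3$ga; g$res3b <- b3$gb
  dd2 <- b3$dx * (cache$d2$y > 0)
  b_d2 <- cin_bwd(cache$d2, w$down2, dd2, stride = 2L)
  g$down2 <- b_d2$g
  b2 <- res_block_bwd(cache$r2, w$res2a, w$res2b, b_d2$dx + d_u1pre)
  g$res2a <- b2$ga; g$res2b <- b2$gb
  dd1 <- b2$dx * (cache$d1$y > 0)
  b_d1 <- cin_bwd(cache$d1, w$down1, dd1, stride = 2L)
  g$down1 <- b_d1$g
  b1 <- res_block_bwd(cache$r1, w$res1a, w$res1b, b_d1$dx + d_u2pre)
  g$res1a <- b1$ga; g$res1b <- b1$gb
  ds0 <- b1$dx * (cache$stem$y > 0)
  b_stem <- cin_bwd(cache$stem, w$stem, ds0, stride = 2L)
  g$stem <- b_stem$g
  g
}

# Pad a 3-channel slice so both spatial dims are multiples of `m`;
# returns the padded slice and the original dims for cropping back.
pad_to_multiple <- function(x, m = 8L) {
  d <- dim(x)
  H2 <- as.integer(ceiling(d[1] / m) * m)
  W2 <- as.integer(ceiling(d[2] / m) * m)
  if (H2 == d[1] && W2 == d[2]) return(list(x = x, hw = d[1:2]))
  out <- array(0, c(H2, W2, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x
  list(x = out, hw = d[1:2])
}

#' Run the segmenter on one slice
#'
#' @param weights A `ventseg_weights` object (see [init_weights()]).
#' @param image_slice `H x W x 3` array (replicated grayscale,
#'   preprocessed). Spatial dims are zero-padded to a multiple of the
#'   encoder stride and the output cropped back.
#' @return `H x W x C` probability map (per-pixel softmax).
#' @export
forward_slice <- function(weights, image_slice) {
  cfg <- attr(weights, "config")
  if (length(dim(image_slice)) != 3L || dim(image_slice)[3] != cfg$in_channels)
    stop(sprintf("input slice must have %d channels", cfg$in_channels))
  pd <- pad_to_multiple(image_slice, 8L)
  out <- forward_net(weights, pd$x, cfg)
  p <- softmax_probs(out$logits)
  p[seq_len(pd$hw[1]), seq_len(pd$hw[2]), , drop = FALSE]
}

#' Hard per-pixel labels from a probability map
#'
#' Argmax over the class axis; ties break toward the lowest class
#' index. Classes are returned 0-based (0 = background).
#' @param p `H x W x C` probability map.
#' @return `H x W` integer matrix.
#' @export
prob_to_labels <- function(p) {
  d <- dim(p)
  m <- matrix(p, d[1] * d[2], d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  matrix(as.integer(lab), d[1], d[2])
}

#' Segment a whole volume slice by slice
#'
#' Applies the deterministic evaluation path: per-volume preprocessing
#' (quantile clip then z-score), channel replication, per-slice forward
#' pass and argmax, stacked into a 3-D label map aligned with the
#' input; spacing is copied from the input.
#'
#' @param weights A `ventseg_weights` object.
#' @param img An [image_volume()].
#' @param preprocess Apply [preprocess_volume()] first (default TRUE;
#'   set FALSE if the volume is already preprocessed).
#' @return `H x W`-per-slice integer label array of dim `(nz, ny, nx)`
#'   wrapped with the input's spacing: a list with `labels` (array) and
#'   `spacing`.
#' @export
predict_volume <- function(weights, img, preprocess = TRUE) {
  stopifnot(inherits(img, "image_volume"))
  if (n_slices(img) < 1L) stop("empty volume")
  if (preprocess) img <- preprocess_volume(img)
  d <- dim(img$data)
  out <- array(0L, d)
  for (i in seq_len(d[1])) {
    p <- forward_slice(weights, to_3channel(img$data[i, , ]))
    out[i, , ] <- prob_to_labels(p)
  }
  list(labels = out, spacing = img$spacing)
}
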