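# Slice/volume preprocessing: quantile clipping, z-score normalization,
# stochastic training augmentations, and bicubic/nearest resizing.

#' Z-score normalize an image volume
#'
#' Subtracts the volume mean and divides by the population (1/N)
#' standard deviation, so the output has mean 0 and SD 1. Statistics are
#' computed per volume. A zero-variance volume maps to all zeros with a
#' warning rather than an error.
#'
#' @param img An [image_volume()] (or bare numeric array).
#' @return Same type as the input, normalized; metadata unchanged.
#' @export
zscore_normalize <- function(img) {
  x <- if (inherits(img, "image_volume")) img$data else img
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))  # population SD
  if (sigma == 0) {
    warning("zero-variance volume: z-score output is all zeros")
    out <- array(0, dim(x))
  } else {
    out <- (x - mu) / sigma
  }
  if (inherits(img, "image_volume")) {
    img$data <- out
    img
  } else out
}

#' Clip intensities to a quantile band
#'
#' Clamps voxel intensities to the `[lo, hi]` empirical quantiles of the
#' volume (defaults: 2.5% and 97.5%), suppressing anomalous pixels.
#' Values strictly inside the band are untouched. Quantiles are computed
#' per volume, using the inverse-ECDF convention (an order statistic of
#' the data), which makes clipping exactly idempotent.
#'
#' @param img An [image_volume()] (or bare numeric array).
#' @param lo,hi Quantile probabilities, `0 <= lo < hi <= 1`.
#' @return Same type as the input, clipped.
#' @export
quantile_clip <- function(img, lo = 0.025, hi = 0.975) {
  if (!(lo >= 0 && lo < hi && hi <= 1)) stop("need 0 <= lo < hi <= 1")
  x <- if (inherits(img, "image_volume")) img$data else img
  q <- stats::quantile(x, c(lo, hi), names = FALSE, type = 1)
  out <- pmin(pmax(x, q[1]), q[2])
  dim(out) <- dim(x)
  if (inherits(img, "image_volume")) {
    img$data <- out
    img
  } else out
}

#' Training-time augmentation parameters
#'
#' @param flip_prob Probability of a horizontal (left-right, x-axis)
#'   flip; the same draw is applied to image and mask.
#' @param photometric_range Closed interval of multiplicative scale
#'   factors for hue/saturation/brightness; both ends > 0.
#' @return Object of class `augment_params`.
#' @export
augment_params <- function(flip_prob = 0.5, photometric_range = c(0.8, 1.2)) {
  if (flip_prob < 0 || flip_prob > 1) stop("flip_prob must be in [0, 1]")
  pr <- as.numeric(photometric_range)
  if (length(pr) != 2L || pr[1] > pr[2] || any(pr <= 0))
    stop("photometric_range must be an interval 0 < lower <= upper")
  structure(list(flip_prob = flip_prob, photometric_range = pr),
            class = "augment_params")
}

#' Replicate a grayscale slice into 3 identical channels
#'
#' The segmenter consumes slices in `H x W x 3` form (the format of
#' natural-image encoders); CT/MRI slices are grayscale, so the single
#' channel is replicated.
#' @param slice `H x W` numeric matrix.
#' @return `H x W x 3` array.
#' @export
to_3channel <- function(slice) {
  stopifnot(is.matrix(slice))
  array(rep(slice, 3L), c(dim(slice), 3L))
}

#' Randomly augment an image slice and its mask
#'
#' Applies (a) a horizontal flip with probability `flip_prob`, the same
#' draw flipping image and mask together, and (b) random photometric
#' scaling of hue, saturation and brightness by factors drawn uniformly
#' from `photometric_range`, applied to the image only. With the three
#' channels identical (grayscale replicated), saturation is 0 and hue
#' undefined, so the hue/saturation factors act as no-ops and the
#' photometric step reduces to a brightness (multiplicative) scale; the
#' three draws are still consumed to keep the RNG stream layout stable.
#' Masks never gain labels.
#'
#' @param image_slice `H x W x 3` numeric array.
#' @param mask_slice `H x W` integer matrix (or `NULL`).
#' @param params An [augment_params()].
#' @return List with `image` and `mask`.
#' @export
augment <- function(image_slice, mask_slice = NULL, params = augment_params()) {
  stopifnot(length(dim(image_slice)) == 3L, dim(image_slice)[3] == 3L)
  do_flip <- stats::runif(1) < params$flip_prob
  scales <- stats::runif(3, params$photometric_range[1], params$photometric_range[2])
  if (do_flip) {
    image_slice <- image_slice[, rev(seq_len(dim(image_slice)[2])), , drop = FALSE]
    if (!is.null(mask_slice))
      mask_slice <- mask_slice[, rev(seq_len(ncol(mask_slice))), drop = FALSE]
  }
  # scales = (hue, saturation, brightness); only brightness acts on a
  # replicated-grayscale slice (saturation 0, hue undefined)
  image_slice <- image_slice * scales[3]
  list(image = image_slice, mask = mask_slice)
}

# Catmull-Rom (Keys, a = -0.5) cubic interpolation kernel.
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# Row-interpolation matrix mapping n_in samples to n_out samples with
# the cubic kernel; edge samples are clamped (replicated).
resize_weights <- function(n_in, n_out) {
  if (n_out == n_in) return(diag(n_in))
  # align centers: output pixel i (1-based) sits at source coordinate
  # (i - 0.5) * n_in/n_out + 0.5
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    base <- floor(src[i])
    for (k in (base - 1):(base + 2)) {
      w <- cubic_kernel(src[i] - k)
      if (w == 0) next
      kk <- min(max(k, 1), n_in)  # clamp at the borders
      W[i, kk] <- W[i, kk] + w
    }
  }
  sweep(W, 1, rowSums(W), "/")  # renormalize (kernel sums ~1 already)
}

#' Resize an image slice with bicubic interpolation
#'
#' Separable Catmull-Rom bicubic resampling (the classic a = -0.5
#' kernel), with clamped borders.
#'
#' @param image_slice `H x W` matrix or `H x W x C` array.
#' @param target_hw Integer length-2 `(H', W')`, both >= 1.
#' @return Resized slice, same number of channels.
#' @export
resize_image <- function(image_slice, target_hw) {
  target_hw <- as.integer(target_hw)
  if (length(target_hw) != 2L || any(target_hw < 1L))
    stop("target dimensions must be two positive integers")
  d <- dim(image_slice)
  Wr <- resize_weights(d[1], target_hw[1])
  Wc <- resize_weights(d[2], target_hw[2])
  if (length(d) == 2L) return(Wr %*% image_slice %*% t(Wc))
  out <- array(0, c(target_hw, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Wr %*% image_slice[, , ch] %*% t(Wc)
  out
}

#' Resize a label mask with nearest-neighbor interpolation
#'
#' @param mask_slice `H x W` integer matrix.
#' @param target_hw Integer length-2 `(H', W')`, both >= 1.
#' @return Resized integer mask; contains only labels present in the
#'   input.
#' @export
resize_mask <- function(mask_slice, target_hw) {
  target_hw <- as.integer(target_hw)
  if (length(target_hw) != 2L || any(target_hw < 1L))
    stop("target dimensions must be two positive integers")
  d <- dim(mask_slice)
  ri <- pmin(pmax(ceiling((seq_len(target_hw[1]) - 0.5) * d[1] / target_hw[1]), 1L), d[1])
  ci <- pmin(pmax(ceiling((seq_len(target_hw[2]) - 0.5) * d[2] / target_hw[2]), 1L), d[2])
  out <- mask_slice[ri, ci, drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Deterministic evaluation-path preprocessing for one volume
#'
#' Quantile clip then z-score normalize (the default order; set
#' `order = "normalize_clip"` to z-score first and clip on z-scores).
#'
#' @param img An [image_volume()].
#' @param lo,hi Clipping quantiles.
#' @param order `"clip_normalize"` (default) or `"normalize_clip"`.
#' @return Preprocessed [image_volume()].
#' @export
preprocess_volume <- function(img, lo = 0.025, hi = 0.975,
                              order = c("clip_normalize", "normalize_clip")) {
  order <- match.arg(order)
  if (order == "clip_normalize") zscore_normalize(quantile_clip(img, lo, hi))
  else quantile_clip(zscore_normalize(img), lo, hi)
}
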