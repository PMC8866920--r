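# The training objective: L = L_S + L_T, where L_S is per-pixel
# cross-entropy on labeled (thick) slices and L_T is the entropy loss
# -(1/C) sum_c f(C p_c), f(x) = x^2 - 1, on unlabeled (thin) slices.
# L_T is 0 at the uniform prediction and -(C-1) at a one-hot one, so
# minimizing it pushes unlabeled predictions toward confidence.

#' Supervised cross-entropy loss
#'
#' Mean over all pixels of `-log p` at the true class:
#' `L_S = -(1/HW) sum_n sum_c y_{n,c} log p_{n,c}` with one-hot `y`.
#' Zero iff the prediction is exactly one-hot correct everywhere.
#' Probabilities of 0 at a true class are clamped at 1e-12 (with a
#' warning) so the loss stays finite.
#'
#' @param p `H x W x C` probability map.
#' @param y `H x W` integer matrix of 0-based class labels (0..C-1).
#' @param eps Clamp for log arguments.
#' @return Scalar loss >= 0.
#' @export
supervised_loss <- function(p, y, eps = 1e-12) {
  d <- dim(p)
  if (!all(dim(y) == d[1:2])) stop("label map shape must match the probability map")
  if (any(y < 0L | y >= d[3])) stop("labels must lie in 0..C-1")
  idx <- cbind(as.vector(row(y)), as.vector(col(y)), as.vector(y) + 1L)
  ptrue <- p[idx]
  if (any(ptrue < eps)) {
    warning("probability ~0 at a true class; clamped at 1e-12")
    ptrue <- pmax(ptrue, eps)
  }
  -mean(log(ptrue))
}

#' Entropy loss for unlabeled predictions
#'
#' Per pixel, `-(1/C) sum_c f(C p_c)` with `f(x) = x^2 - 1`, averaged
#' over pixels (the same 1/HW convention as the supervised loss).
#' Equals 0 iff every pixel predicts the uniform distribution and
#' `-(C-1)` iff every pixel is one-hot; its range is `[-(C-1), 0]`.
#'
#' @param p `H x W x C` probability map.
#' @return Scalar in `[-(C-1), 0]`.
#' @export
entropy_loss <- function(p) {
  d <- dim(p)
  C <- d[3]
  m <- matrix(p, d[1] * d[2], C)
  # -(1/C) sum_c ((C p_c)^2 - 1) = 1 - C sum_c p_c^2
  mean(1 - C * rowSums(m^2))
}

#' Combined two-stream training objective
#'
#' `L = L_S(p_s, y_s) + lambda * L_T(p_t)`. In stage-1 (supervised
#' pretraining) no thin batch exists and the entropy term is omitted.
#'
#' @param p_s Probability map(s) for labeled thick slices: one
#'   `H x W x C` array or a list of them.
#' @param y_s Matching label map(s), 0-based.
#' @param p_t Probability map(s) for unlabeled thin slices, or `NULL`.
#' @param lambda Weight of the entropy term (default 1: the plain sum).
#' @return List (class `loss_values`) with `L_S`, `L_T` (NA when no
#'   thin batch) and `L`.
#' @export
total_loss <- function(p_s = NULL, y_s = NULL, p_t = NULL, lambda = 1) {
  if (is.null(p_s) && is.null(p_t)) stop("both batches empty: nothing to optimize")
  as_list <- function(x) if (is.list(x)) x else list(x)
  L_S <- 0
  if (!is.null(p_s)) {
    ps <- as_list(p_s); ys <- as_list(y_s)
    L_S <- mean(mapply(supervised_loss, ps, ys))
  }
  L_T <- NA_real_
  if (!is.null(p_t)) L_T <- mean(vapply(as_list(p_t), entropy_loss, numeric(1)))
  L <- L_S + if (is.na(L_T)) 0 else lambda * L_T
  structure(list(L_S = L_S, L_T = L_T, L = L), class = "loss_values")
}

#' @export
print.loss_values <- function(x, ...) {
  cat(sprintf("L = %.6f  (L_S = %.6f, L_T = %s)\n", x$L, x$L_S,
              if (is.na(x$L_T)) "-" else sprintf("%.6f", x$L_T)))
  invisible(x)
}

# ---- analytic gradients w.r.t. logits (used by the trainer) ----------

# d L_S / d z for p = softmax(z): (p - onehot) / HW.
ce_grad_logits <- function(p, y) {
  d <- dim(p)
  g <- p
  idx <- cbind(as.vector(row(y)), as.vector(col(y)), as.vector(y) + 1L)
  g[idx] <- g[idx] - 1
  g / (d[1] * d[2])
}

# d L_T / d z for p = softmax(z). dL/dp_c = -2 C p_c / HW; chain through
# softmax: dz = p * (g - sum_c g_c p_c).
entropy_grad_logits <- function(p) {
  d <- dim(p)
  C <- d[3]
  m <- matrix(p, d[1] * d[2], C)
  gp <- -2 * C * m / (d[1] * d[2])
  dot <- rowSums(gp * m)
  array(m * (gp - dot), d)
}
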