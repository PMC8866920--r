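# Agreement statistics between manual and automatic measurements:
# Dice overlap, ICC(2,1), Pearson correlation, Bland-Altman analysis,
# and the summary-table assembly (mean +/- SD strings).

#' Dice similarity coefficient of two binary masks
#'
#' `DSC = 2|A intersect B| / (|A| + |B|)`, in `[0, 1]`, symmetric.
#' When both masks are empty the DSC is 1 by convention (perfect
#' agreement on absence).
#'
#' @param a,b Logical/0-1 arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("masks must have identical shape")
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Per-class and pooled Dice of two multi-class label maps
#'
#' Computes the DSC of each ventricle class 1-4 plus the pooled
#' "all-ventricle" DSC of the union of the four classes (the single
#' number reported as the VV DSC). A class absent from both maps gets
#' `NA` and is excluded from averaging.
#'
#' @param a,b Integer label arrays (values 0-4) of identical shape, or
#'   [label_volume()]s.
#' @return Named numeric vector: `class1..class4`, `pooled`.
#' @export
multiclass_dice <- function(a, b) {
  if (inherits(a, "label_volume")) a <- a$labels
  if (inherits(b, "label_volume")) b <- b$labels
  if (!identical(dim(a), dim(b))) stop("label maps must have identical shape")
  per <- vapply(1:4, function(cl) {
    if (sum(a == cl) + sum(b == cl) == 0) return(NA_real_)
    dice(a == cl, b == cl)
  }, numeric(1))
  c(class1 = per[1], class2 = per[2], class3 = per[3], class4 = per[4],
    pooled = dice(a > 0L, b > 0L))
}

#' Pearson correlation of paired measurements
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform (via [stats::cor.test()]). Zero variance in either
#' argument is an error, never a silent NaN.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return List with `r` and `p`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from
#' the standard mean-squares decomposition over an n-subjects x
#' 2-raters table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`,
#' with k = 2 raters. Unlike Pearson's r, a constant offset between
#' raters lowers the ICC. If all 2n values are identical the ICC is 1
#' by convention (with a warning).
#'
#' @param x,y Paired measurements from the two raters, `n >= 3`.
#' @return Scalar ICC, `<= 1`.
#' @export
icc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  dat <- cbind(x, y)
  if (stats::sd(as.vector(dat)) == 0) {
    warning("all measurements identical: ICC set to 1")
    return(1)
  }
  k <- 2
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences are taken manual minus auto. Reports the bias (mean
#' difference), the sample SD of the differences, and the limits of
#' agreement `bias +/- 1.96 * SD`.
#'
#' @param manual,auto Paired numeric vectors (ml), `n >= 2`.
#' @return List with `bias`, `sd`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(manual, auto) {
  if (length(manual) != length(auto)) stop("manual and auto must be paired")
  if (length(manual) < 2L) stop("need at least 2 pairs")
  d <- manual - auto
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       n = length(d))
}

fmt_pm <- function(m, s, digits = 2) sprintf("%.*f ± %.*f", digits, m, digits, s)

#' Assemble the agreement report for one measurement
#'
#' Combines the per-case Dice values and the paired manual/automatic
#' volumes of a validation set into the summary row layout used for
#' reporting: DSC mean +/- SD, ICC(2,1), Pearson r (with p), and
#' Bland-Altman bias +/- SD with limits of agreement.
#'
#' @param name Measurement name, e.g. `"VV"` or `"ICV"`.
#' @param dsc Per-case Dice coefficients.
#' @param manual,auto Paired per-case volumes (ml).
#' @return Object of class `agreement_report`: a list with `name`,
#'   `n`, `dsc_mean`, `dsc_sd`, `icc`, `pearson_r`, `pearson_p`,
#'   `bias`, `bias_sd`, `loa_low`, `loa_high`, plus formatted strings
#'   in `$table_row`.
#' @export
agreement_report <- function(name, dsc, manual, auto) {
  if (any(dsc < 0 | dsc > 1, na.rm = TRUE)) stop("DSC values must lie in [0, 1]")
  # correlation statistics need n >= 3 and nonzero variance; on smaller
  # or degenerate samples they are reported as NA rather than failing
  # the whole report
  pr <- tryCatch(pearson(manual, auto),
                 error = function(e) list(r = NA_real_, p = NA_real_))
  icc_v <- tryCatch(icc(manual, auto), error = function(e) NA_real_)
  ba <- tryCatch(bland_altman(manual, auto),
                 error = function(e) list(bias = NA_real_, sd = NA_real_,
                                          loa_low = NA_real_,
                                          loa_high = NA_real_))
  out <- list(name = name, n = length(manual),
              dsc_mean = mean(dsc, na.rm = TRUE), dsc_sd = stats::sd(dsc),
              icc = icc_v,
              pearson_r = pr$r, pearson_p = pr$p,
              bias = ba$bias, bias_sd = ba$sd,
              loa_low = ba$loa_low, loa_high = ba$loa_high)
  out$table_row <- data.frame(
    measurement = name,
    DSC = fmt_pm(out$dsc_mean, out$dsc_sd),
    ICC = sprintf("%.2f", out$icc),
    Pearson = sprintf("%.2f", out$pearson_r),
    bias = fmt_pm(out$bias, out$bias_sd, 1),
    manual = fmt_pm(mean(manual), stats::sd(manual), 1),
    auto = fmt_pm(mean(auto), stats::sd(auto), 1),
    stringsAsFactors = FALSE)
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("%s (n = %d): DSC %s, ICC %.3f, Pearson r %.3f (p %.2g), bias %s ml, LoA [%.2f, %.2f]\n",
              x$name, x$n, fmt_pm(x$dsc_mean, x$dsc_sd), x$icc,
              x$pearson_r, x$pearson_p, fmt_pm(x$bias, x$bias_sd),
              x$loa_low, x$loa_high))
  invisible(x)
}

#' Evaluate predicted against reference label volumes
#'
#' For paired lists of predicted and reference [label_volume()]s,
#' computes per-case multiclass Dice and volumetry, then summarizes VV
#' and ICV agreement.
#'
#' @param pred,truth Equal-length lists of [label_volume()]s.
#' @param case_ids Case identifiers.
#' @return List with `per_case` (data frame: case, pooled and per-class
#'   DSC, manual/auto VV and ICV) and `summary` (two
#'   [agreement_report()]s, `VV` and `ICV`).
#' @export
evaluate_pairs <- function(pred, truth, case_ids = NULL) {
  if (length(pred) != length(truth)) stop("pred and truth must be paired lists")
  n <- length(pred)
  if (is.null(case_ids)) case_ids <- sprintf("case%03d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    md <- multiclass_dice(pred[[i]], truth[[i]])
    rp <- report_from_labels(pred[[i]]$labels, pred[[i]]$brain_mask,
                             pred[[i]]$spacing, case_ids[i], "auto")
    rt <- report_from_labels(truth[[i]]$labels, truth[[i]]$brain_mask,
                             truth[[i]]$spacing, case_ids[i], "manual")
    data.frame(case_id = case_ids[i],
               dsc_pooled = md[["pooled"]], dsc_c1 = md[["class1"]],
               dsc_c2 = md[["class2"]], dsc_c3 = md[["class3"]],
               dsc_c4 = md[["class4"]],
               dsc_brain = dice(pred[[i]]$brain_mask, truth[[i]]$brain_mask),
               vv_manual = rt$vv_total, vv_auto = rp$vv_total,
               icv_manual = rt$icv, icv_auto = rp$icv,
               stringsAsFactors = FALSE)
  })
  per_case <- do.call(rbind, rows)
  summary <- list(
    VV = agreement_report("VV", per_case$dsc_pooled,
                          per_case$vv_manual, per_case$vv_auto),
    ICV = agreement_report("ICV", per_case$dsc_brain,
                           per_case$icv_manual, per_case$icv_auto))
  list(per_case = per_case, summary = summary)
}
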