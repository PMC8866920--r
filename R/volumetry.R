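# Exact voxel-counting volumetry: per-class ventricular volume (VV),
# intracranial volume (ICV) and the relative VV/ICV, from predicted or
# reference label maps. Volume = voxel count * r_x*r_y*r_z, reported in
# ml (1 ml = 1000 mm^3).

#' Volume of one ventricle class
#'
#' `VV_c = r_x * r_y * r_z * #\{voxels with label c\} / 1000` ml --
#' exact voxel counting, no interpolation.
#'
#' @param lab A [label_volume()], or a bare integer array of labels.
#' @param r Spacing `(r_x, r_y, r_z)` in mm (taken from `lab` when it
#'   is a `label_volume`).
#' @param c Ventricle class, one of 1..4.
#' @return Volume in ml, with the raw voxel count in attribute
#'   `"count"`.
#' @export
class_volume <- function(lab, r = NULL, c) {
  if (inherits(lab, "label_volume")) {
    if (is.null(r)) r <- lab$spacing
    labels <- lab$labels
  } else labels <- lab
  r <- check_spacing(r)
  c <- as.integer(c)
  if (length(c) != 1L || is.na(c) || c < 1L || c > 4L)
    stop("ventricle class must be one of 1, 2, 3, 4")
  count <- cpp_label_counts(as.integer(labels), 4L)[c + 1L]
  structure(count * prod(r) / 1000, count = count)
}

#' Intracranial volume from the binary brain mask
#'
#' Same voxel counting as [class_volume()], applied to the mask's
#' foreground (value 1).
#'
#' @param brain_mask A [label_volume()] (its `brain_mask` is used) or a
#'   binary 3-D array.
#' @param r Spacing `(r_x, r_y, r_z)` in mm.
#' @return Volume in ml, voxel count in attribute `"count"`.
#' @export
intracranial_volume <- function(brain_mask, r = NULL) {
  if (inherits(brain_mask, "label_volume")) {
    if (is.null(r)) r <- brain_mask$spacing
    brain_mask <- brain_mask$brain_mask
  }
  r <- check_spacing(r)
  count <- sum(brain_mask == 1L)
  structure(count * prod(r) / 1000, count = count)
}

#' Relative ventricular volume VV/ICV
#'
#' `(sum_c VV_c / ICV) * 100` percent. Undefined (an error, never a
#' silent NaN) when ICV is 0.
#'
#' @param report A `volumetry_report` row (see [measure_case()]), or a
#'   list with `vv_total` and `icv` in ml.
#' @return Percentage.
#' @export
vv_icv_ratio <- function(report) {
  vv <- report$vv_total; icv <- report$icv
  if (is.null(vv) || is.null(icv)) stop("report must carry vv_total and icv")
  if (icv <= 0) stop("ICV is 0: VV/ICV is undefined")
  100 * vv / icv
}

# Assemble the one-row volumetry report from a label array + mask.
report_from_labels <- function(labels, brain_mask, r, case_id, source) {
  counts <- cpp_label_counts(as.integer(labels), 4L)[2:5]
  voxml <- prod(r) / 1000
  vv <- counts * voxml
  icv <- sum(brain_mask == 1L) * voxml
  out <- data.frame(case_id = case_id, source = source,
                    vv1 = vv[1], vv2 = vv[2], vv3 = vv[3], vv4 = vv[4],
                    vv_total = sum(vv), icv = icv,
                    vv_icv_pct = if (icv > 0) 100 * sum(vv) / icv else NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("volumetry_report", class(out))
  out
}

#' Measure VV, ICV and VV/ICV for one scan
#'
#' Runs the ventricle model (5 classes) and the whole-brain model
#' (binary) over the volume and assembles the per-case volumetry
#' report. Spacing is taken from the image volume (i.e. from the NIfTI
#' header when the volume was read from file), never assumed. Predicted
#' ventricle voxels falling outside the predicted brain mask are
#' counted but flagged with a warning, since the two models are
#' independent.
#'
#' Either model may be replaced by an [oracle_model()] wrapping
#' reference labels, which turns the pipeline into an identity
#' pass-through (useful for validation).
#'
#' @param img An [image_volume()].
#' @param model_v Ventricle segmenter: a `ventseg` fit or an oracle.
#' @param model_b Whole-brain segmenter: a `ventseg` fit or an oracle.
#' @param case_id Identifier recorded in the report.
#' @return A one-row `volumetry_report` data frame: `case_id`,
#'   `source` (`"auto"`), per-class `vv1..vv4`, `vv_total`, `icv`
#'   (ml) and `vv_icv_pct`.
#' @export
measure_case <- function(img, model_v, model_b, case_id = "case") {
  stopifnot(inherits(img, "image_volume"))
  pv <- run_segmenter(model_v, img)
  pb <- run_segmenter(model_b, img)
  outside <- sum(pv$labels > 0L & pb$labels == 0L)
  if (outside > 0)
    warning(sprintf("%d predicted ventricle voxels lie outside the predicted brain mask", outside))
  report_from_labels(pv$labels, pb$labels, img$spacing, case_id, "auto")
}

run_segmenter <- function(model, img) {
  if (inherits(model, "oracle_model")) return(model$fn(img))
  if (inherits(model, "ventseg")) return(predict_volume(model$weights, img))
  stop("model must be a ventseg fit or an oracle_model")
}

#' Oracle segmenter wrapping reference labels
#'
#' A stand-in "model" that returns fixed reference labels for the
#' volume it is given, letting the measurement/evaluation pipeline be
#' validated as an identity pass-through.
#'
#' @param lab A [label_volume()].
#' @param what `"ventricle"` (returns class labels) or `"brain"`
#'   (returns the binary brain mask).
#' @return Object of class `oracle_model`.
#' @export
oracle_model <- function(lab, what = c("ventricle", "brain")) {
  what <- match.arg(what)
  stopifnot(inherits(lab, "label_volume"))
  out <- if (what == "ventricle") lab$labels else lab$brain_mask
  structure(list(fn = function(img) list(labels = out, spacing = lab$spacing)),
            class = "oracle_model")
}

#' Reference (manual-analog) volumetry report from ground-truth labels
#'
#' @param lab A [label_volume()].
#' @param case_id Identifier recorded in the report.
#' @return A one-row `volumetry_report` with `source = "manual"`.
#' @export
measure_reference <- function(lab, case_id = "case") {
  stopifnot(inherits(lab, "label_volume"))
  report_from_labels(lab$labels, lab$brain_mask, lab$spacing, case_id, "manual")
}
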