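#' @useDynLib ventseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd cor aggregate
#' @importFrom utils write.csv read.csv modifyList
NULL

# Axis convention used throughout the package: volume arrays are indexed
# (z, y, x) -- axial slices along the first dimension -- while voxel
# spacing is reported as the physical ratio r = (r_x, r_y, r_z) in mm.
# Slice i of a volume `v` is the y-by-x matrix v[i, , ].

#' Slice-spacing threshold separating "thick" from "thin" volumes
#'
#' Volumes whose inter-slice spacing (r_z) is at or above this value are
#' classed as thick; below it, thin. Clinical thick acquisitions run
#' roughly 4.8-8 mm between slices while thin research acquisitions are
#' 3 mm or less, so the default boundary is 3 mm.
#' @return Numeric scalar, mm.
#' @export
thick_threshold_mm <- function() 3.0

#' Construct an image volume
#'
#' A 3-D grayscale scan plus the metadata every downstream stage needs:
#' per-axis voxel spacing and the acquisition modality. Arrays are
#' indexed `(z, y, x)` with axial slices along the first axis; `spacing`
#' is the physical ratio `(r_x, r_y, r_z)` in mm per voxel.
#'
#' @param data 3-D numeric array, dimensions `(nz, ny, nx)`, all finite.
#' @param spacing Numeric length-3, `(r_x, r_y, r_z)` in mm, all > 0.
#' @param modality `"CT"` or `"MRI"`.
#' @param thick_mm Thick/thin boundary in mm (see [thick_threshold_mm()]).
#' @return An object of class `image_volume` with fields `data`,
#'   `spacing` (named x/y/z), `modality` and `thickness_class`
#'   (`"thick"` or `"thin"`, derived from `r_z`).
#' @export
image_volume <- function(data, spacing, modality = c("CT", "MRI"),
                         thick_mm = thick_threshold_mm()) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array indexed (z, y, x)")
  if (!all(is.finite(data)))
    stop("image data must be finite")
  spacing <- check_spacing(spacing)
  structure(
    list(data = data, spacing = spacing, modality = modality,
         thickness_class = if (spacing[["z"]] >= thick_mm) "thick" else "thin"),
    class = "image_volume")
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values (r_x, r_y, r_z) in mm")
  names(spacing) <- c("x", "y", "z")
  spacing
}

#' Construct a label volume
#'
#' Integer class map aligned voxel-for-voxel with an [image_volume()]:
#' 0 = background, 1 = right lateral, 2 = left lateral, 3 = third,
#' 4 = fourth ventricle; plus a parallel binary intracranial (brain)
#' mask used for ICV. Every ventricle voxel must lie inside the brain
#' mask.
#'
#' @param labels 3-D integer array `(nz, ny, nx)`, values in `0:4`.
#' @param brain_mask 3-D binary array of the same dimensions.
#' @param spacing Numeric length-3, `(r_x, r_y, r_z)` in mm.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, brain_mask, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array indexed (z, y, x)")
  if (!identical(dim(labels), dim(brain_mask)))
    stop("`brain_mask` dimensions must match `labels`")
  storage.mode(labels) <- "integer"
  storage.mode(brain_mask) <- "integer"
  if (any(labels < 0L | labels > 4L))
    stop("labels must lie in 0..4")
  if (!all(brain_mask %in% c(0L, 1L)))
    stop("brain_mask must be binary")
  if (any(labels > 0L & brain_mask == 0L))
    stop("ventricle voxels found outside the brain mask (label > 0 requires brain_mask = 1)")
  spacing <- check_spacing(spacing)
  structure(list(labels = labels, brain_mask = brain_mask, spacing = spacing),
            class = "label_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %s, %s-slice, %d x %d x %d (z,y,x), spacing %.3g x %.3g x %.3g mm (x,y,z)\n",
              x$modality, x$thickness_class, d[1], d[2], d[3],
              x$spacing[["x"]], x$spacing[["y"]], x$spacing[["z"]]))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  tab <- tabulate(x$labels + 1L, nbins = 5L)
  cat(sprintf("<label_volume> %d x %d x %d (z,y,x); voxels per class 0..4: %s; brain voxels: %d\n",
              d[1], d[2], d[3], paste(tab, collapse = "/"),
              sum(x$brain_mask)))
  invisible(x)
}

n_slices <- function(vol) dim(if (inherits(vol, "label_volume")) vol$labels else vol$data)[1]

get_slice <- function(vol, i) {
  if (inherits(vol, "label_volume")) vol$labels[i, , ] else vol$data[i, , ]
}
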