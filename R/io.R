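# NIfTI-1 readers/writers and run configuration. Internally volumes
# are indexed (z, y, x); NIfTI stores (x, y, z), so axes are permuted
# on the way in and out and the voxel spacing travels in the header
# pixdim.

#' Read an image volume from a NIfTI-1 file
#'
#' Data are permuted to the package's `(z, y, x)` axis order; spacing
#' `(r_x, r_y, r_z)` is taken from the header pixdim (absolute values
#' of the per-axis scales), never assumed.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param modality `"CT"` or `"MRI"` (recorded on the volume; NIfTI
#'   headers do not carry modality).
#' @param spacing_override Optional length-3 spacing in mm that
#'   replaces the header values (for headerless fixtures); its use is
#'   reported with a warning so it is never silent.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, modality = c("CT", "MRI"),
                        spacing_override = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  nim <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("corrupt or unreadable NIfTI header in ",
                                           path, ": ", conditionMessage(e)))
  arr <- as.array(nim)
  if (length(dim(arr)) != 3L) stop("expected a 3-D volume in ", path)
  sp <- abs(RNifti::pixdim(nim))[1:3]
  if (!is.null(spacing_override)) {
    warning(sprintf("spacing override (%s) replaces header spacing in %s",
                    paste(spacing_override, collapse = "x"), path))
    sp <- as.numeric(spacing_override)
  }
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in header of ", path)
  image_volume(aperm(arr, c(3L, 2L, 1L)), sp, modality)
}

#' Read a label volume (labels + brain mask) from NIfTI-1 files
#'
#' @param path Path to the class-label file (integers 0-4).
#' @param brain_path Path to the binary brain-mask file; defaults to
#'   the label path with `_brain` inserted before the extension. If
#'   the file does not exist the mask falls back to `labels > 0`.
#' @return A [label_volume()].
#' @export
read_labels <- function(path, brain_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  nim <- RNifti::readNifti(path)
  labels <- aperm(as.array(nim), c(3L, 2L, 1L))
  storage.mode(labels) <- "integer"
  sp <- abs(RNifti::pixdim(nim))[1:3]
  if (any(sp <= 0)) stop("non-positive voxel spacing in header of ", path)
  if (is.null(brain_path)) brain_path <- brain_sibling(path)
  if (file.exists(brain_path)) {
    mask <- aperm(as.array(RNifti::readNifti(brain_path)), c(3L, 2L, 1L))
    storage.mode(mask) <- "integer"
  } else {
    mask <- array(as.integer(labels > 0L), dim(labels))
  }
  label_volume(labels, mask, sp)
}

brain_sibling <- function(path) sub("(\\.nii(\\.gz)?)$", "_brain\\1", path)

#' Write a volume to NIfTI-1
#'
#' Image volumes are written as float; label volumes as unsigned 8-bit
#' integers, with the brain mask in a sibling `*_brain.nii.gz` file.
#' Spacing is encoded in the header pixdim.
#'
#' @param vol An [image_volume()] or [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  if (inherits(vol, "image_volume")) {
    nim <- RNifti::asNifti(aperm(vol$data, c(3L, 2L, 1L)))
    RNifti::pixdim(nim) <- unname(vol$spacing)
    RNifti::writeNifti(nim, path)
  } else if (inherits(vol, "label_volume")) {
    nim <- RNifti::asNifti(aperm(vol$labels, c(3L, 2L, 1L)))
    RNifti::pixdim(nim) <- unname(vol$spacing)
    RNifti::writeNifti(nim, path, datatype = "uint8")
    bm <- RNifti::asNifti(aperm(vol$brain_mask, c(3L, 2L, 1L)))
    RNifti::pixdim(bm) <- unname(vol$spacing)
    RNifti::writeNifti(bm, brain_sibling(path), datatype = "uint8")
  } else stop("vol must be an image_volume or label_volume")
  invisible(path)
}

#' Export static orthogonal-plane views of a volume
#'
#' Writes a PNG with the central axial, coronal and sagittal planes,
#' optionally overlaying label contours.
#'
#' @param img An [image_volume()].
#' @param lab Optional [label_volume()] overlay.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
orthogonal_views <- function(img, lab = NULL, path) {
  d <- dim(img$data)
  mid <- pmax(1L, d %/% 2L)
  grDevices::png(path, width = 900, height = 320)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  planes <- list(axial = img$data[mid[1], , ],
                 coronal = img$data[, mid[2], ],
                 sagittal = img$data[, , mid[3]])
  overlays <- if (is.null(lab)) NULL else
    list(lab$labels[mid[1], , ], lab$labels[, mid[2], ], lab$labels[, , mid[3]])
  for (i in seq_along(planes)) {
    m <- planes[[i]]
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(128),
                    axes = FALSE, main = names(planes)[i])
    if (!is.null(overlays)) {
      ov <- overlays[[i]]
      for (cl in 1:4) if (any(ov == cl))
        graphics::contour(x = seq(0, 1, length.out = ncol(ov)),
                          y = seq(0, 1, length.out = nrow(ov)),
                          z = t(ov == cl)[, nrow(ov):1] * 1,
                          levels = 0.5, add = TRUE, drawlabels = FALSE,
                          col = c("red", "green3", "gold", "blue")[cl])
    }
  }
  invisible(path)
}

# ---- run configuration ------------------------------------------------

run_config_defaults <- function() {
  list(
    paths = list(data_dir = ".", run_dir = "run"),
    phantom = list(n = 16L, modality = "CT", jitter = 0.15, thick_k = 4L,
                   seed = 1L),
    preprocess = list(lo = 0.025, hi = 0.975, order = "clip_normalize",
                      flip_prob = 0.5, photometric = c(0.8, 1.2)),
    model = list(n_classes = 5L, widths = c(8L, 16L, 32L),
                 upscale_factors = c(2L, 2L, 2L),
                 use_pretrained_encoder = FALSE),
    train = list(stage1_epochs = 200L, stage1_lr = 1e-3,
                 stage2_epochs = 100L, stage2_lr = 1e-4,
                 weight_decay = 1e-5, momentum = 0.9, batch_size = 8L,
                 test_fraction = 0.2, lambda = 1, seed = 1L),
    evaluation = list(measures = c("VV", "ICV")))
}

#' Read and validate a run configuration file
#'
#' YAML with blocks `paths`, `phantom`, `preprocess`, `model`, `train`,
#' `evaluation`; every key has a documented default and unknown keys
#' are rejected (misspellings fail loudly instead of silently falling
#' back to a default).
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return Validated config list (class `run_config`).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    bad_blocks <- setdiff(names(user), names(cfg))
    if (length(bad_blocks) > 0)
      stop("unknown config block(s): ", paste(bad_blocks, collapse = ", "))
    for (blk in names(user)) {
      bad <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
      if (length(bad) > 0)
        stop(sprintf("unknown key(s) in block '%s': %s", blk,
                     paste(bad, collapse = ", ")))
      cfg[[blk]] <- utils::modifyList(cfg[[blk]], user[[blk]])
    }
  }
  structure(cfg, class = "run_config")
}
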