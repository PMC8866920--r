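# Synthetic head phantoms: ellipsoidal brain + four ellipsoidal
# ventricle compartments with analytically known volumes, rasterized on
# a voxel grid, with modality-dependent intensity statistics. These
# stand in for clinical scans so the whole pipeline is testable.

#' Run code with a temporarily fixed RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default per-compartment intensity statistics
#'
#' Means/SDs of voxel intensity for each compartment plus a global
#' additive noise SD. CT-like phantoms get a bright skull shell and
#' near-zero CSF-dark ventricles; MRI-like (T1-weighted analog) phantoms
#' get bright parenchyma and dark-intermediate CSF. Units are arbitrary
#' scanner units; the preprocessing stage z-scores them away.
#'
#' @param modality `"CT"` or `"MRI"`.
#' @return List with components `background`, `brain`, `ventricle`,
#'   `skull` (each `c(mean, sd)`) and `noise_sd`.
#' @export
default_intensity_model <- function(modality = c("CT", "MRI")) {
  modality <- match.arg(modality)
  if (modality == "CT")
    list(background = c(-1000, 20), brain = c(35, 4),
         ventricle  = c(6, 3),      skull = c(700, 40), noise_sd = 1)
  else
    list(background = c(20, 10),  brain = c(600, 50),
         ventricle  = c(180, 30), skull = c(250, 40), noise_sd = 10)
}

#' Specification of a synthetic head phantom
#'
#' Defines the geometry (mm) and intensity statistics of a phantom with
#' analytically known compartment volumes. The intracranial compartment
#' is an ellipsoid centered on the grid; the four ventricle compartments
#' are ellipsoids placed relative to the brain center (class 1 = right
#' lateral, 2 = left lateral, 3 = third, 4 = fourth). A ventricle with
#' all-zero semi-axes is absent.
#'
#' The defaults describe a desk-scale head: a 64 x 64 x 20 grid at
#' (2.4, 2.4, 2.0) mm spacing covering the ventricle-bearing slab
#' (40 mm about the ventricle plane) of a (60, 70, 28) mm-semi-axis
#' brain (about 440 ml inside the grid) with enlarged,
#' hydrocephalus-like ventricles (total about 35 ml, VV/ICV around
#' 8%). The grid deliberately stops short of the brain apex: near the
#' apex, thickness-averaged slices show central dark partial-volume
#' blobs that are indistinguishable in 2-D from ventricle, which no
#' slice-wise segmenter can resolve.
#'
#' @param grid_shape Integer length-3, voxels per axis `(nz, ny, nx)`.
#' @param spacing Numeric length-3, mm per voxel `(r_x, r_y, r_z)`.
#' @param brain_semiaxes Numeric length-3, mm, `(a_x, a_y, a_z)` of the
#'   intracranial ellipsoid; all > 0.
#' @param ventricle_params List of 4 (classes 1-4), each with `center`
#'   (mm offset from brain center, `(x, y, z)`) and `semiaxes` (mm,
#'   `(x, y, z)`; all zero means the class is absent).
#' @param modality `"CT"` or `"MRI"`.
#' @param intensity_model See [default_intensity_model()].
#' @param skull_mm Thickness of the CT skull shell outside the brain
#'   ellipsoid, mm.
#' @param seed RNG seed for the intensity draws.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(20L, 64L, 64L),
                         spacing = c(2.4, 2.4, 2.0),
                         brain_semiaxes = c(60, 70, 28),
                         ventricle_params = default_ventricles(),
                         modality = c("CT", "MRI"),
                         intensity_model = NULL,
                         skull_mm = 4,
                         seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(intensity_model)) intensity_model <- default_intensity_model(modality)
  spacing <- check_spacing(spacing)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers (nz, ny, nx)")
  if (length(brain_semiaxes) != 3L || any(brain_semiaxes <= 0))
    stop("brain semi-axes must all be > 0")
  if (length(ventricle_params) != 4L)
    stop("ventricle_params must list classes 1..4")
  for (v in ventricle_params) {
    sa <- v$semiaxes
    if (length(sa) != 3L || any(sa < 0) || (any(sa == 0) && any(sa > 0)))
      stop("ventricle semi-axes must be all > 0, or all 0 for an absent class")
  }
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 brain_semiaxes = as.numeric(brain_semiaxes),
                 ventricle_params = ventricle_params,
                 modality = modality, intensity_model = intensity_model,
                 skull_mm = skull_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default ventricle geometry (mm, relative to brain center)
#'
#' Enlarged lateral ventricles flanking the midline, a narrow midline
#' third ventricle, and a small posterior-inferior fourth ventricle.
#' @return List of 4 component definitions (classes 1-4).
#' @export
default_ventricles <- function() {
  list(
    list(center = c(-18, -2, 4),  semiaxes = c(12, 22, 14)),  # right lateral
    list(center = c(18, -2, 4),   semiaxes = c(12, 22, 14)),  # left lateral
    list(center = c(0, 2, 0),     semiaxes = c(5, 14, 10)),   # third
    list(center = c(0, 20, -12),  semiaxes = c(5, 7, 7))      # fourth
  )
}

# Voxel-center coordinates (mm) along one axis, centered on the grid.
axis_coords <- function(n, step) (seq_len(n) - (n + 1) / 2) * step

# Boolean mask of voxels whose centers fall inside an ellipsoid.
# Returns a (nz, ny, nx) logical array.
rasterize_ellipsoid <- function(grid_shape, spacing, center, semiaxes) {
  if (all(semiaxes == 0)) return(array(FALSE, grid_shape))
  zc <- axis_coords(grid_shape[1], spacing[["z"]])
  yc <- axis_coords(grid_shape[2], spacing[["y"]])
  xc <- axis_coords(grid_shape[3], spacing[["x"]])
  qz <- ((zc - center[3]) / semiaxes[3])^2
  qy <- ((yc - center[2]) / semiaxes[2])^2
  qx <- ((xc - center[1]) / semiaxes[1])^2
  q <- outer(outer(qz, qy, `+`), qx, `+`)
  q <= 1
}

#' Generate a synthetic head phantom
#'
#' Rasterizes the spec's ellipsoids (a voxel belongs to a compartment
#' iff its center lies inside the ellipsoid), draws per-compartment
#' intensities with the spec's seed, and records ground-truth volumes by
#' exact voxel counting: `count * r_x * r_y * r_z / 1000` ml.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` ([image_volume()]), `labels`
#'   ([label_volume()]) and `true_volumes`, a named numeric vector of ml
#'   for classes `"1".."4"`, `"vv"` (their sum) and `"icv"`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; sp <- spec$spacing
  brain <- rasterize_ellipsoid(gs, sp, c(0, 0, 0), spec$brain_semiaxes)
  labels <- array(0L, gs)
  for (cls in 1:4) {
    v <- spec$ventricle_params[[cls]]
    m <- rasterize_ellipsoid(gs, sp, v$center, v$semiaxes)
    if (any(m & !brain)) {
      bad <- which(m & !brain, arr.ind = TRUE)[1, ]
      stop(sprintf(paste0("ventricle class %d extends outside the brain ",
                          "ellipsoid (first offending voxel z=%d y=%d x=%d; ",
                          "center (%g,%g,%g) mm, semi-axes (%g,%g,%g) mm vs ",
                          "brain semi-axes (%g,%g,%g) mm)"),
                   cls, bad[1], bad[2], bad[3],
                   v$center[1], v$center[2], v$center[3],
                   v$semiaxes[1], v$semiaxes[2], v$semiaxes[3],
                   spec$brain_semiaxes[1], spec$brain_semiaxes[2],
                   spec$brain_semiaxes[3]))
    }
    if (any(m & labels > 0L))
      stop(sprintf("ventricle class %d overlaps an earlier class at voxel level", cls))
    labels[m] <- cls
  }
  skull <- rasterize_ellipsoid(gs, sp, c(0, 0, 0),
                               spec$brain_semiaxes + spec$skull_mm) & !brain

  im <- spec$intensity_model
  img <- with_seed(spec$seed, {
    x <- array(rnorm(prod(gs), im$background[1], im$background[2]), gs)
    nb <- sum(brain)
    x[brain] <- rnorm(nb, im$brain[1], im$brain[2])
    ns <- sum(skull)
    if (ns > 0) x[skull] <- rnorm(ns, im$skull[1], im$skull[2])
    nv <- sum(labels > 0L)
    if (nv > 0) x[labels > 0L] <- rnorm(nv, im$ventricle[1], im$ventricle[2])
    x + array(rnorm(prod(gs), 0, im$noise_sd), gs)
  })

  voxvol_ml <- prod(sp) / 1000
  counts <- tabulate(labels, nbins = 4L)
  tv <- c(counts * voxvol_ml, sum(counts) * voxvol_ml, sum(brain) * voxvol_ml)
  names(tv) <- c("1", "2", "3", "4", "vv", "icv")

  list(image = image_volume(img, sp, spec$modality),
       labels = label_volume(labels, array(as.integer(brain), gs), sp),
       true_volumes = tv)
}

#' Degrade a thin-slice stack to thick slices
#'
#' Emulates a thick-slice acquisition from a thin one: consecutive
#' groups of `k` thin image slices are averaged into one thick slice
#' (trailing slices that do not fill a group are dropped), labels take
#' the group's central slice (nearest-neighbor along z, index
#' `ceiling(k/2)` within the group), and the inter-slice spacing is
#' multiplied by `k`.
#'
#' @param img An [image_volume()].
#' @param lab The paired [label_volume()] (or `NULL`).
#' @param k Integer >= 1, number of thin slices per thick slice; must be
#'   smaller than the stack's z extent.
#' @param thick_mm Thick/thin boundary passed to [image_volume()].
#' @return List with `image` and `labels` (NULL if `lab` was NULL).
#' @export
degrade_thickness <- function(img, lab = NULL, k, thick_mm = thick_threshold_mm()) {
  stopifnot(inherits(img, "image_volume"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1")
  nz <- n_slices(img)
  if (k >= nz && k > 1L) stop(sprintf("k = %d must be smaller than the z extent (%d slices)", k, nz))
  sp <- img$spacing
  sp_out <- c(sp[["x"]], sp[["y"]], sp[["z"]] * k)
  if (k == 1L) {
    out_img <- image_volume(img$data, sp_out, img$modality, thick_mm)
    return(list(image = out_img, labels = lab))
  }
  ng <- nz %/% k
  d <- dim(img$data)
  newdata <- array(0, c(ng, d[2], d[3]))
  for (g in seq_len(ng)) {
    idx <- ((g - 1L) * k + 1L):(g * k)
    newdata[g, , ] <- apply(img$data[idx, , , drop = FALSE], c(2, 3), mean)
  }
  out_img <- image_volume(newdata, sp_out, img$modality, thick_mm)
  out_lab <- NULL
  if (!is.null(lab)) {
    stopifnot(inherits(lab, "label_volume"))
    central <- ((seq_len(ng) - 1L) * k) + as.integer(ceiling(k / 2))
    out_lab <- label_volume(lab$labels[central, , , drop = FALSE],
                            lab$brain_mask[central, , , drop = FALSE],
                            sp_out)
  }
  list(image = out_img, labels = out_lab)
}

#' Generate a reproducible phantom cohort
#'
#' Draws `n` phantom cases around a base spec, jittering each
#' ventricle's semi-axes and center plus the head size (brain semi-axes
#' at half the ventricle jitter, so ICV varies across subjects), and
#' returns paired thin + thick versions of every case with the
#' ground-truth volumes of both stacks. Draws that would push a
#' ventricle outside the brain are redrawn (deterministically, from
#' the same stream).
#'
#' @param n Number of cases, >= 1.
#' @param base_spec Base [phantom_spec()].
#' @param jitter Relative semi-axis jitter (uniform in `1 +- jitter`).
#' @param center_jitter_mm Max absolute center shift per axis, mm.
#' @param seed Cohort seed; together with `n` it fully determines every
#'   case.
#' @param thick_k Thickness-degradation factor for the thick twin.
#' @return List of `n` cases; each case is a list with `case_id`,
#'   `spec`, `thin` (image/labels), `thick` (image/labels),
#'   `true_volumes` (thin stack) and `true_volumes_thick`.
#' @export
make_cohort <- function(n, base_spec = phantom_spec(), jitter = 0.15,
                        center_jitter_mm = 3, seed = 1L, thick_k = 4L) {
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (attempt in 1:25) {
        vp <- lapply(base_spec$ventricle_params, function(v) {
          list(center = v$center + runif(3, -center_jitter_mm, center_jitter_mm),
               semiaxes = v$semiaxes * runif(3, 1 - jitter, 1 + jitter))
        })
        spec <- base_spec
        spec$brain_semiaxes <- base_spec$brain_semiaxes *
          runif(3, 1 - jitter / 2, 1 + jitter / 2)
        spec$ventricle_params <- vp
        spec$seed <- sample.int(.Machine$integer.max, 1L)
        ph <- tryCatch(make_phantom(spec), error = function(e) NULL)
        if (!is.null(ph)) {
          thick <- degrade_thickness(ph$image, ph$labels, thick_k)
          voxvol_ml <- prod(thick$labels$spacing) / 1000
          cth <- tabulate(thick$labels$labels, nbins = 4L)
          tvt <- c(cth * voxvol_ml, sum(cth) * voxvol_ml,
                   sum(thick$labels$brain_mask) * voxvol_ml)
          names(tvt) <- c("1", "2", "3", "4", "vv", "icv")
          return(list(case_id = sprintf("case%03d", i), spec = spec,
                      thin = list(image = ph$image, labels = ph$labels),
                      thick = list(image = thick$image, labels = thick$labels),
                      true_volumes = ph$true_volumes,
                      true_volumes_thick = tvt))
        }
      }
      stop(sprintf("case %d: no valid geometry found after 25 jitter draws", i))
    })
  })
}
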