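# Shared fixtures, all generated in code.

# Single spherical "ventricle" of radius r_mm centered in a brain
# ellipsoid, on an isotropic grid -- the analytic-volume fixture.
sphere_spec <- function(r_mm = 10, spacing = c(1, 1, 1), seed = 1L) {
  vents <- list(
    list(center = c(0, 0, 0), semiaxes = rep(r_mm, 3)),
    list(center = c(0, 0, 0), semiaxes = c(0, 0, 0)),
    list(center = c(0, 0, 0), semiaxes = c(0, 0, 0)),
    list(center = c(0, 0, 0), semiaxes = c(0, 0, 0))
  )
  n <- ceiling(2 * (r_mm + 6) / spacing) + 2
  phantom_spec(grid_shape = rev(n), spacing = spacing,
               brain_semiaxes = rep(r_mm + 4, 3),
               ventricle_params = vents, modality = "CT", seed = seed)
}

# A small, fast phantom for IO / CLI / trainer plumbing tests:
# quarter-scale grid, ventricles shrunk to fit.
tiny_spec <- function(seed = 1L, modality = "CT") {
  vents <- list(
    list(center = c(-9, -1, 1),  semiaxes = c(6, 10, 7)),
    list(center = c(9, -1, 1),   semiaxes = c(6, 10, 7)),
    list(center = c(0, 1, 0),    semiaxes = c(2.5, 7, 5)),
    list(center = c(0, 10, -6),  semiaxes = c(2.5, 3.5, 3.5))
  )
  phantom_spec(grid_shape = c(10L, 32L, 32L), spacing = c(2.4, 2.4, 2.0),
               brain_semiaxes = c(30, 35, 14), ventricle_params = vents,
               modality = modality, seed = seed)
}

tiny_cohort <- function(n, seed = 1L, thick_k = 2L) {
  make_cohort(n, tiny_spec(), jitter = 0.1, center_jitter_mm = 1.5,
              seed = seed, thick_k = thick_k)
}

# Independent brute-force volume oracle: rasterize an ellipsoid on a
# sub-voxel grid (step mm) by direct triple loop over subgrid centers.
subgrid_ellipsoid_volume <- function(semiaxes, step = 0.25, extent = NULL) {
  if (is.null(extent)) extent <- max(semiaxes) + 2
  g <- seq(-extent, extent, by = step)
  cnt <- 0
  for (z in g) {
    zz <- (z / semiaxes[3])^2
    if (zz > 1) next
    m <- outer((g / semiaxes[1])^2, (g / semiaxes[2])^2, `+`) + zz <= 1
    cnt <- cnt + sum(m)
  }
  cnt * step^3
}

# Naive triple-loop voxel counting oracle (no vectorization).
loop_count <- function(labels, cls) {
  d <- dim(labels)
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (labels[i, j, k] == cls) n <- n + 1L
  n
}
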