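# Coarse test geometry: fast to rasterize, fine enough for topology checks.
coarse_spec <- function(spacing = c(0.2, 0.2, 0.2), amplitude = 0,
                        headroom = 1) {
  fit_grid(phantom_spec(spacing = spacing),
           motion_trajectory(amplitude), headroom_cm = headroom)
}

# Random small mask on a fixed grid, kept away from the boundary so that
# moderate dilations stay inside.
random_mask <- function(n = 16L, p = 0.15, spacing = c(0.1, 0.1, 0.1),
                        pad = 4L) {
  m <- array(FALSE, c(n, n, n))
  core <- (pad + 1):(n - pad)
  m[core, core, core] <- stats::runif(length(core)^3) < p
  structure_mask(m, spacing)
}

# SI (z) extent of a mask in cm, measured across occupied voxel centres.
si_extent <- function(mask) {
  zs <- which(apply(mask$mask, 3, any))
  if (!length(zs)) return(0)
  (max(zs) - min(zs)) * mask$spacing[3]
}

axial_extent <- function(mask) {
  xs <- which(apply(mask$mask, 1, any))
  if (!length(xs)) return(0)
  (max(xs) - min(xs)) * mask$spacing[1]
}

# z coordinate of the mask centroid (cm).
centroid_z <- function(mask) {
  idx <- which(mask$mask, arr.ind = TRUE)
  mean(voxel_coords(mask, 3)[idx[, 3]])
}
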