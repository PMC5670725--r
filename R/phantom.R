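#' Digital respiratory phantom specification
#'
#' Describes a high-contrast spherical target embedded in a uniform
#' low-density lung medium, discretized on a regular voxel grid. The default
#' geometry mirrors a commercial respiratory motion phantom: a 1.5 cm radius
#' polystyrene sphere in a cedar lung insert, imaged at a 1.25 mm slice
#' width. Intensities are CT-number-like and unitless; only the lung-target
#' contrast matters because segmentation uses a relative threshold.
#'
#' @param target_radius Sphere radius in cm (default 1.5).
#' @param target_intensity Scalar intensity of the target (default 0).
#' @param lung_intensity Scalar intensity of the lung medium (default -700);
#'   must be below `target_intensity`.
#' @param spacing Voxel spacing in cm, default `c(0.1, 0.1, 0.125)` (the z
#'   spacing matches the 1.25 mm CT slice width).
#' @param grid_extent Integer length-3 voxel counts, or `NULL` to size the
#'   grid later with [fit_grid()].
#' @param target_rest_center Rest position of the sphere centre in cm.
#' @return An object of class `phantom_spec`.
#' @seealso [fit_grid()], [rasterize_phantom()]
#' @export
phantom_spec <- function(target_radius = 1.5,
                         target_intensity = 0,
                         lung_intensity = -700,
                         spacing = c(0.1, 0.1, 0.125),
                         grid_extent = NULL,
                         target_rest_center = c(0, 0, 0)) {
  if (!is.numeric(target_radius) || length(target_radius) != 1L ||
      !is.finite(target_radius) || target_radius <= 0)
    stop("`target_radius` must be a single positive length in cm")
  if (target_intensity <= lung_intensity)
    stop("`target_intensity` must exceed `lung_intensity`")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive lengths (cm)")
  if (!is.null(grid_extent)) {
    grid_extent <- as.integer(grid_extent)
    if (length(grid_extent) != 3L || any(grid_extent < 1L))
      stop("`grid_extent` must be three positive voxel counts")
  }
  structure(list(target_radius = target_radius,
                 target_intensity = target_intensity,
                 lung_intensity = lung_intensity,
                 spacing = spacing,
                 grid_extent = grid_extent,
                 target_rest_center = as.numeric(target_rest_center)),
            class = "phantom_spec")
}

#' Size the phantom grid to contain the moving target plus margins
#'
#' Chooses odd per-axis voxel counts so that the grid, centred on the target
#' rest position, contains the sphere at its maximum displacement plus a
#' headroom margin (room for the largest PTV expansion).
#'
#' @param spec A [phantom_spec()].
#' @param traj A [motion_trajectory()] (or `NULL` for a static target).
#' @param headroom_cm Extra clearance beyond target + motion, default 1.5 cm
#'   (covers the 1 cm SI margin plus expansion discretization).
#' @return The spec with `grid_extent` filled in.
#' @export
fit_grid <- function(spec, traj = NULL, headroom_cm = 1.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  amp <- c(0, 0, 0)
  if (!is.null(traj)) {
    stopifnot(inherits(traj, "motion_trajectory"))
    amp <- abs(c(traj$lateral_amplitude, traj$ap_amplitude, traj$amplitude_si))
    amp <- amp * (1 + 4 * traj$amplitude_jitter_sd / max(max(amp), 1e-9))
  }
  half <- spec$target_radius + amp + headroom_cm
  spec$grid_extent <- as.integer(2 * ceiling(half / spec$spacing) + 1)
  spec
}

# Physical origin implied by a centred grid.
grid_origin <- function(spec) {
  spec$target_rest_center - (spec$grid_extent - 1) / 2 * spec$spacing
}

#' Parametric respiratory motion trajectory
#'
#' Sinusoidal target motion, by default pure superior-inferior translation:
#' the SI displacement at time `t` is `A * cos(2*pi*t/T + phase_offset)`, so
#' `t = 0` (phase 0%) is maximum inhale and mid-cycle is maximum exhale. The
#' peak-to-peak SI range is `2 * amplitude_si`. Optional lateral and
#' anterior-posterior components (synchronous with the SI component) and
#' per-cycle amplitude/period jitter support irregular "virtual patient"
#' breathing.
#'
#' @param amplitude_si SI amplitude A in cm (half the peak-to-peak range).
#' @param period Respiratory period T in s; default 4 s (15 cycles/min).
#' @param phase_offset Phase offset in radians (default 0).
#' @param lateral_amplitude,ap_amplitude Optional lateral / AP amplitudes in
#'   cm (default 0).
#' @param period_jitter_sd,amplitude_jitter_sd Standard deviations of
#'   per-cycle Gaussian jitter on the period (s) and on the displacement
#'   vector scale (cm along the largest axis); defaults 0 (regular
#'   breathing).
#' @param seed Integer seed for the jitter draws; ignored when both jitter
#'   standard deviations are zero.
#' @return An object of class `motion_trajectory`.
#' @export
motion_trajectory <- function(amplitude_si,
                              period = 4,
                              phase_offset = 0,
                              lateral_amplitude = 0,
                              ap_amplitude = 0,
                              period_jitter_sd = 0,
                              amplitude_jitter_sd = 0,
                              seed = 1L) {
  stopifnot(is.numeric(amplitude_si), length(amplitude_si) == 1L,
            amplitude_si >= 0, is.finite(amplitude_si))
  if (period <= 0) stop("`period` must be positive (s)")
  if (period_jitter_sd < 0 || amplitude_jitter_sd < 0)
    stop("jitter standard deviations must be non-negative")
  structure(list(amplitude_si = amplitude_si, period = period,
                 phase_offset = phase_offset,
                 lateral_amplitude = lateral_amplitude,
                 ap_amplitude = ap_amplitude,
                 period_jitter_sd = period_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 seed = as.integer(seed)),
            class = "motion_trajectory")
}

has_jitter <- function(traj) {
  traj$period_jitter_sd > 0 || traj$amplitude_jitter_sd > 0
}

# Per-cycle jitter draws, reproducible for a given seed independent of call
# order. Returns list(scale, period) vectors covering cycles 0..(n-1).
cycle_jitter <- function(traj, n_cycles) {
  if (!has_jitter(traj))
    return(list(scale = rep(1, n_cycles), period = rep(traj$period, n_cycles)))
  amax <- max(abs(c(traj$amplitude_si, traj$lateral_amplitude,
                    traj$ap_amplitude)), 1e-9)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(traj$seed)
  scale <- 1 + stats::rnorm(n_cycles, 0, traj$amplitude_jitter_sd) / amax
  period <- traj$period + stats::rnorm(n_cycles, 0, traj$period_jitter_sd)
  period <- pmax(period, 0.1 * traj$period)
  list(scale = pmax(scale, 0), period = period)
}

#' Evaluate a trajectory: displacement of the target centre at given times
#'
#' @param traj A [motion_trajectory()].
#' @param t Numeric vector of times in s (non-negative).
#' @return A `length(t) x 3` matrix of displacements (cm): lateral, AP, SI.
#' @export
trajectory_displacement <- function(traj, t) {
  stopifnot(inherits(traj, "motion_trajectory"), all(is.finite(t)), all(t >= 0))
  amps <- c(traj$lateral_amplitude, traj$ap_amplitude, traj$amplitude_si)
  if (!has_jitter(traj)) {
    ph <- 2 * pi * t / traj$period + traj$phase_offset
    return(outer(cos(ph), amps))
  }
  cyc <- floor(t / traj$period)
  jit <- cycle_jitter(traj, max(cyc) + 1)
  tk <- jit$period[cyc + 1]
  ph <- 2 * pi * (t - cyc * traj$period) / tk + traj$phase_offset
  outer(cos(ph) * jit$scale[cyc + 1], rep(1, 3)) *
    matrix(amps, length(t), 3, byrow = TRUE)
}

#' 4DCT acquisition configuration
#'
#' Controls the retrospective phase sorting model: the number of phase bins
#' (10 in the standard protocol) and how residual motion within each bin is
#' integrated. `"average"` emulates reconstruction from projection data
#' spanning the bin by uniformly time-averaging rasterized snapshots taken
#' at the midpoints of equal sub-intervals of the bin; `"center"` takes a
#' single snapshot at the bin centre (no intra-bin motion).
#'
#' @param n_bins Number of respiratory phase bins; values other than 10 are
#'   allowed with a warning.
#' @param snapshots_per_bin Snapshots averaged per bin (>= 1; default 8).
#' @param integration `"average"` (default) or `"center"`.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(n_bins = 10L, snapshots_per_bin = 8L,
                               integration = c("average", "center")) {
  integration <- match.arg(integration)
  n_bins <- as.integer(n_bins)
  snapshots_per_bin <- as.integer(snapshots_per_bin)
  if (n_bins < 1L) stop("`n_bins` must be >= 1")
  if (snapshots_per_bin < 1L) stop("`snapshots_per_bin` must be >= 1")
  structure(list(n_bins = n_bins, snapshots_per_bin = snapshots_per_bin,
                 integration = integration),
            class = "acquisition_config")
}

#' Free-breathing helical scan model
#'
#' Sequential slab acquisition: the scanner images one axial slab at a time
#' while the target keeps moving, so the slab at couch position z holds the
#' phantom state at the time that slab was acquired. The default emulates a
#' 16-slice unit at 1.25 mm collimation: 2 cm slabs, 0.5 s per slab, couch
#' moving inferior to superior. The interleaving of couch translation and
#' target motion produces the interplay distortion characteristic of
#' free-breathing scans of moving targets.
#'
#' @param slab_thickness_cm Axial extent imaged per acquisition step (cm).
#' @param slab_time_s Time per slab (s); couch speed is
#'   `slab_thickness_cm / slab_time_s`.
#' @param direction `"inferior_to_superior"` (default) or the reverse.
#' @param start_phase Respiratory phase fraction in `[0, 1)` at which the
#'   scan starts; swept in experiments because a single physical scan has an
#'   unknowable start phase.
#' @param integration `"average"` (default): each slab is the uniform
#'   time-average of the phantom over its acquisition window, emulating
#'   reconstruction from projections collected during the tube rotation —
#'   this is what makes a fast-moving target lose apparent density at its
#'   periphery on free-breathing scans. `"snapshot"`: each slab holds the
#'   instantaneous phantom state at the start of its window.
#' @param snapshots_per_slab Snapshots averaged per slab window (default 8).
#' @return An object of class `scan_model`.
#' @export
scan_model <- function(slab_thickness_cm = 2,
                       slab_time_s = 0.5,
                       direction = c("inferior_to_superior",
                                     "superior_to_inferior"),
                       start_phase = 0,
                       integration = c("average", "snapshot"),
                       snapshots_per_slab = 8L) {
  direction <- match.arg(direction)
  integration <- match.arg(integration)
  if (slab_thickness_cm <= 0 || slab_time_s <= 0)
    stop("slab thickness and slab time must be positive (couch speed > 0)")
  if (start_phase < 0 || start_phase >= 1)
    stop("`start_phase` must lie in [0, 1)")
  snapshots_per_slab <- as.integer(snapshots_per_slab)
  if (snapshots_per_slab < 1L) stop("`snapshots_per_slab` must be >= 1")
  structure(list(slab_thickness_cm = slab_thickness_cm,
                 slab_time_s = slab_time_s,
                 direction = direction, start_phase = start_phase,
                 integration = integration,
                 snapshots_per_slab = snapshots_per_slab),
            class = "scan_model")
}

# Fractional per-voxel coverage of the union... no: mean inside-sphere
# indicator over a set of sphere centre positions (rows of `centers`, cm).
sphere_coverage <- function(spec, centers) {
  d <- spec$grid_extent
  org <- grid_origin(spec)
  xs <- org[1] + (seq_len(d[1]) - 1) * spec$spacing[1]
  ys <- org[2] + (seq_len(d[2]) - 1) * spec$spacing[2]
  zs <- org[3] + (seq_len(d[3]) - 1) * spec$spacing[3]
  r2 <- spec$target_radius^2
  cov <- array(0, dim = d)
  for (i in seq_len(nrow(centers))) {
    dx2 <- (xs - centers[i, 1])^2
    dy2 <- (ys - centers[i, 2])^2
    dz2 <- (zs - centers[i, 3])^2
    cov <- cov + (outer(outer(dx2, dy2, "+"), dz2, "+") <= r2)
  }
  cov / nrow(centers)
}

check_target_in_grid <- function(spec, displacement) {
  ctr <- spec$target_rest_center + displacement
  org <- grid_origin(spec)
  hi <- org + (spec$grid_extent - 1) * spec$spacing
  lo <- org
  if (any(ctr - spec$target_radius < lo) || any(ctr + spec$target_radius > hi))
    stop(sprintf(
      "displaced target (displacement %.3g, %.3g, %.3g cm) extends outside the grid",
      displacement[1], displacement[2], displacement[3]))
  invisible(TRUE)
}

#' Rasterize the phantom at a given target displacement
#'
#' Voxels whose centres lie inside (boundary inclusive) the displaced sphere
#' receive the target intensity; all others the lung intensity. With
#' `partial_volume = TRUE` each voxel is 2x2x2 supersampled and boundary
#' voxels receive an intensity proportional to their occupied fraction.
#'
#' @param spec A [phantom_spec()] with `grid_extent` set (see [fit_grid()]).
#' @param displacement Length-3 displacement of the target centre in cm.
#' @param partial_volume Logical; default `FALSE` (binary voxelization).
#' @return An [image_volume()].
#' @export
rasterize_phantom <- function(spec, displacement = c(0, 0, 0),
                              partial_volume = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(spec$grid_extent))
    stop("`spec$grid_extent` is unset; call fit_grid() first")
  displacement <- as.numeric(displacement)
  check_target_in_grid(spec, displacement)
  ctr <- spec$target_rest_center + displacement
  if (partial_volume) {
    sub <- as.matrix(expand.grid(x = c(-0.25, 0.25), y = c(-0.25, 0.25),
                                 z = c(-0.25, 0.25)))
    centers <- -sweep(sub, 2, spec$spacing, "*")  # shift sphere, not grid
    centers <- sweep(centers, 2, ctr, "+")
    cov <- sphere_coverage(spec, centers)
  } else {
    cov <- sphere_coverage(spec, matrix(ctr, 1))
  }
  vals <- spec$lung_intensity +
    cov * (spec$target_intensity - spec$lung_intensity)
  image_volume(vals, spec$spacing, grid_origin(spec))
}

#' Simulate a 10-bin phase-sorted 4DCT acquisition
#'
#' Emulates retrospective phase binning: the respiratory cycle is divided
#' into `n_bins` equal bins centred on the phase labels 0%, 10%, ..., with
#' phase 0% centred on the cosine maximum (maximum inhale) and phase 50% on
#' maximum exhale. Each phase image integrates the residual target motion
#' across its bin according to the acquisition config. With per-cycle jitter,
#' successive snapshots of a bin are drawn from successive breathing cycles.
#'
#' @param spec A [phantom_spec()] with grid set.
#' @param traj A [motion_trajectory()].
#' @param acq An [acquisition_config()].
#' @return A [phase_stack()].
#' @export
simulate_phase_stack <- function(spec, traj, acq = acquisition_config()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(traj, "motion_trajectory"),
            inherits(acq, "acquisition_config"))
  if (is.null(spec$grid_extent))
    stop("`spec$grid_extent` is unset; call fit_grid() first")
  n <- acq$n_bins
  J <- if (acq$integration == "center") 1L else acq$snapshots_per_bin
  w <- 1 / n
  labels <- (seq_len(n) - 1) / n
  phases <- vector("list", n)
  for (b in seq_len(n)) {
    if (J == 1L) {
      frac <- labels[b]
      tt <- frac * traj$period
    } else {
      frac <- labels[b] - w / 2 + (seq_len(J) - 0.5) * w / J
      # negative fractions wrap within the (periodic) cycle; with jitter,
      # spread the snapshots of one bin across successive cycles
      tt <- (frac %% 1) * traj$period
      if (has_jitter(traj)) tt <- tt + (seq_len(J) - 1) * traj$period
    }
    disp <- trajectory_displacement(traj, tt)
    cov <- sphere_coverage_displaced(spec, disp)
    vals <- spec$lung_intensity +
      cov * (spec$target_intensity - spec$lung_intensity)
    phases[[b]] <- image_volume(vals, spec$spacing, grid_origin(spec))
  }
  bounds <- c(labels - w / 2, labels[n] + w / 2)
  phase_stack(phases, labels, bounds)
}

sphere_coverage_displaced <- function(spec, disp) {
  for (i in seq_len(nrow(disp))) check_target_in_grid(spec, disp[i, ])
  centers <- sweep(disp, 2, spec$target_rest_center, "+")
  sphere_coverage(spec, centers)
}

#' Simulate a free-breathing helical scan
#'
#' Builds the free-breathing (FB) image by sequential slab acquisition: the
#' slab covering couch positions `[z, z + slab)` holds the phantom state at
#' the time that slab was imaged. A moving target is therefore sampled at a
#' different respiratory phase in each slab, producing the interplay
#' truncation/fragmentation distortion seen on real FB scans.
#'
#' @param spec A [phantom_spec()] with grid set.
#' @param traj A [motion_trajectory()].
#' @param scan A [scan_model()].
#' @return An [image_volume()].
#' @export
simulate_free_breathing <- function(spec, traj, scan = scan_model()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(traj, "motion_trajectory"),
            inherits(scan, "scan_model"))
  if (is.null(spec$grid_extent))
    stop("`spec$grid_extent` is unset; call fit_grid() first")
  d <- spec$grid_extent
  slices_per_slab <- max(1L, round(scan$slab_thickness_cm / spec$spacing[3]))
  slab_of <- (seq_len(d[3]) - 1L) %/% slices_per_slab
  slab_ids <- sort(unique(slab_of))
  if (scan$direction == "superior_to_inferior")
    slab_ids <- rev(slab_ids)
  vals <- array(spec$lung_intensity, dim = d)
  t0 <- scan$start_phase * traj$period
  for (m in seq_along(slab_ids)) {
    t_open <- t0 + (m - 1) * scan$slab_time_s
    tt <- if (scan$integration == "snapshot") t_open
          else t_open + (seq_len(scan$snapshots_per_slab) - 0.5) *
                 scan$slab_time_s / scan$snapshots_per_slab
    disp <- trajectory_displacement(traj, tt)
    snap <- sphere_coverage_displaced(spec, disp)
    zsel <- which(slab_of == slab_ids[m])
    vals[, , zsel] <- spec$lung_intensity +
      snap[, , zsel] * (spec$target_intensity - spec$lung_intensity)
  }
  image_volume(vals, spec$spacing, grid_origin(spec))
}

#' Generate a "virtual patient": 3-D / irregular motion through the pipeline
#'
#' Runs the full acquisition pipeline (phase-sorted stack plus free-breathing
#' scan) for a trajectory that may have lateral/AP components and per-cycle
#' jitter, and records the ground-truth motion of the target centroid: the
#' per-axis displacement extrema, the amplitude-vector norm `m_amplitude`,
#' and the peak-to-peak motion vector `m_peak_to_peak` (the Euclidean norm of
#' the per-axis peak-to-peak excursions, the quantity measured clinically
#' from centroid extrema across phases).
#'
#' @param traj A [motion_trajectory()] with at least one nonzero amplitude.
#' @param spec Optional [phantom_spec()]; by default a spec with default
#'   geometry is fitted to the trajectory.
#' @param acq An [acquisition_config()].
#' @param scan A [scan_model()].
#' @return A list with elements `stack` ([phase_stack()]), `fb`
#'   ([image_volume()]) and `ground_truth` (list of `extrema`, `m_amplitude`,
#'   `m_peak_to_peak`).
#' @export
generate_virtual_patient <- function(traj,
                                     spec = NULL,
                                     acq = acquisition_config(),
                                     scan = scan_model()) {
  stopifnot(inherits(traj, "motion_trajectory"))
  amps <- c(traj$lateral_amplitude, traj$ap_amplitude, traj$amplitude_si)
  if (all(amps == 0))
    stop("at least one trajectory amplitude component must be nonzero")
  if (is.null(spec)) spec <- fit_grid(phantom_spec(), traj)
  stack <- simulate_phase_stack(spec, traj, acq)
  fb <- simulate_free_breathing(spec, traj, scan)
  tt <- seq(0, 3 * traj$period, length.out = 601)
  disp <- trajectory_displacement(traj, tt)
  p2p <- apply(disp, 2, function(v) max(v) - min(v))
  gt <- list(extrema = rbind(min = apply(disp, 2, min),
                             max = apply(disp, 2, max)),
             m_amplitude = motion_vector(amps[1], amps[2], amps[3]),
             m_peak_to_peak = motion_vector(p2p[1], p2p[2], p2p[3]))
  list(stack = stack, fb = fb, ground_truth = gt)
}
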