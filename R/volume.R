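#' Image volume container
#'
#' A 3-D scalar intensity grid with uniform voxel spacing and a physical
#' origin. The axis convention is fixed: the first two array dimensions are
#' the axial plane (left-right, anterior-posterior) and the third dimension
#' is the superior-inferior (SI) axis.
#'
#' @param values 3-D numeric array of voxel intensities (finite).
#' @param spacing Numeric length-3, voxel spacing in cm per axis (positive).
#' @param origin Numeric length-3, physical position (cm) of the centre of
#'   voxel `[1, 1, 1]`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (!all(is.finite(values)))
    stop("`values` must be finite everywhere")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive lengths (cm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite coordinates (cm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g cm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) cm, intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Physical voxel-centre coordinates along one axis
#' @param vol An `image_volume` or `structure_mask`.
#' @param axis Integer 1-3 (3 = superior-inferior).
#' @return Numeric vector of voxel-centre coordinates in cm.
#' @export
voxel_coords <- function(vol, axis) {
  d <- if (inherits(vol, "structure_mask")) dim(vol$mask) else dim(vol$values)
  vol$origin[axis] + (seq_len(d[axis]) - 1) * vol$spacing[axis]
}

#' Volume of one voxel in cc
#' @param vol An `image_volume` or `structure_mask`.
#' @return Voxel volume in cubic centimetres.
#' @export
voxel_volume_cc <- function(vol) prod(vol$spacing)

# Geometry equality used by every boolean/overlap operation. Origins and
# spacings must agree within `tol` cm; no implicit resampling is performed.
same_geometry <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "structure_mask")) dim(a$mask) else dim(a$values)
  db <- if (inherits(b, "structure_mask")) dim(b$mask) else dim(b$values)
  identical(da, db) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

stop_if_geometry_mismatch <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    stop(sprintf("%s are not on the same grid (dim/spacing/origin mismatch)",
                 what))
  invisible(TRUE)
}

#' Ordered stack of respiratory phase volumes
#'
#' Ten (by convention) phase-binned image volumes sharing one grid, labelled
#' by the respiratory phase fraction: 0% is maximum inhale and 50% maximum
#' exhale.
#'
#' @param phases List of `image_volume` objects on one common grid.
#' @param phase_labels Numeric phase fractions in `[0, 1)`, e.g. `0, 0.1, ...`.
#' @param bin_boundaries Numeric vector of length `length(phases) + 1` giving
#'   the time-fraction boundaries of each bin (bins are centred on labels).
#' @return An object of class `phase_stack`.
#' @export
phase_stack <- function(phases, phase_labels, bin_boundaries = NULL) {
  if (!length(phases)) stop("empty phase list")
  if (length(phases) != length(phase_labels))
    stop("one label per phase required")
  for (p in phases) {
    if (!inherits(p, "image_volume")) stop("phases must be image_volume objects")
    stop_if_geometry_mismatch(phases[[1]], p, "phase volumes")
  }
  if (length(phases) != 10L)
    warning(sprintf("phase stack has %d bins; the standard protocol uses 10",
                    length(phases)))
  structure(list(phases = phases, phase_labels = as.numeric(phase_labels),
                 bin_boundaries = bin_boundaries),
            class = "phase_stack")
}

#' @export
print.phase_stack <- function(x, ...) {
  cat(sprintf("<phase_stack> %d phases: %s%%\n", length(x$phases),
              paste(round(100 * x$phase_labels), collapse = ", ")))
  invisible(x)
}

#' Extract one phase volume by its label
#' @param stack A `phase_stack`.
#' @param label Phase fraction (e.g. `0` for maximum inhale, `0.5` for
#'   maximum exhale).
#' @return The matching `image_volume`.
#' @export
get_phase <- function(stack, label) {
  i <- which(abs(stack$phase_labels - label) < 1e-9)
  if (length(i) != 1L) stop(sprintf("no phase with label %s", label))
  stack$phases[[i]]
}
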