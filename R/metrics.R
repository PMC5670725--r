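#' Structure volume in cubic centimetres
#'
#' Voxel-count volume: number of true voxels times the voxel volume.
#'
#' @param mask A `structure_mask`.
#' @return Volume in cc.
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$mask) * voxel_volume_cc(mask)
}

#' Dice similarity coefficient of two structure masks
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)` computed on voxel counts over a
#' common grid. A DSC of 1 means the volumes are identical; 0 means no
#' spatial overlap. Degenerate conventions (documented, used only for
#' degenerate inputs): both masks empty gives 1 (identical sets); exactly
#' one empty gives 0.
#'
#' @param a,b `structure_mask` objects on one common grid.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  stop_if_geometry_mismatch(a, b, "masks")
  na <- sum(a$mask); nb <- sum(b$mask)
  if (na + nb == 0L) return(1)
  2 * sum(a$mask & b$mask) / (na + nb)
}

#' Planning-target-volume ratio
#'
#' `R_x = PTV_x / PTV_GS`: the volume of a strategy's PTV relative to the
#' 10-phase gold-standard PTV. R does not encode position, so equal volumes
#' with no overlap still give R = 1 (with DSC = 0).
#'
#' @param v_x Strategy PTV volume (cc).
#' @param v_gs Gold-standard PTV volume (cc); must be positive.
#' @return Dimensionless ratio.
#' @export
ptv_ratio <- function(v_x, v_gs) {
  if (!is.finite(v_gs) || v_gs <= 0)
    stop("gold-standard volume must be positive")
  v_x / v_gs
}

#' Motion vector magnitude
#'
#' Euclidean norm of the per-axis tumor centroid displacement components
#' (medial-lateral, anterior-posterior, superior-inferior):
#' `M = sqrt(dx^2 + dy^2 + dz^2)`.
#'
#' @param dx,dy,dz Displacement components in cm.
#' @return M in cm.
#' @export
motion_vector <- function(dx, dy, dz) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(dz))
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Capsule (spherocylinder) volume: the analytic ITV oracle
#'
#' Volume of the solid swept by a sphere of radius `r` translating a
#' distance `L` along a line: `(4/3) pi r^3 + pi r^2 L`. For pure SI
#' sinusoidal motion with amplitude A the ideal ITV is the capsule with
#' `L = 2A`, and the ideal PTV (isotropic margin m) is the capsule of
#' radius r + m.
#'
#' @param r Sphere radius in cm (> 0); vectorized.
#' @param L Swept distance in cm (>= 0); vectorized.
#' @return Volume in cc.
#' @export
capsule_volume <- function(r, L) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("`r` must be positive")
  if (any(!is.finite(L)) || any(L < 0)) stop("`L` must be non-negative")
  (4 / 3) * pi * r^3 + pi * r^2 * L
}

#' Classify contour agreement from a Dice score
#'
#' Volumetric overlap is conventionally called "good agreement" when
#' DSC > 0.700 (strictly).
#'
#' @param dsc Dice similarity coefficient in `[0, 1]`.
#' @return `"good"` or `"poor"`.
#' @export
classify_agreement <- function(dsc) {
  if (!is.finite(dsc) || dsc < 0 || dsc > 1)
    stop("`dsc` must lie in [0, 1]")
  if (dsc > 0.700) "good" else "poor"
}

#' Overlap summary for one strategy against the gold standard
#'
#' @param ptv_x Strategy PTV (`structure_mask`).
#' @param ptv_gs Gold-standard PTV (`structure_mask`), same grid.
#' @return A list with `strategy`, `v_x`, `v_gs`, `intersection` (all cc),
#'   `r_ratio`, `dsc` and `agreement`.
#' @export
overlap_result <- function(ptv_x, ptv_gs) {
  stop_if_geometry_mismatch(ptv_x, ptv_gs, "masks")
  v_x <- volume_cc(ptv_x)
  v_gs <- volume_cc(ptv_gs)
  inter <- sum(ptv_x$mask & ptv_gs$mask) * voxel_volume_cc(ptv_x)
  d <- dice(ptv_x, ptv_gs)
  list(strategy = ptv_x$strategy, v_x = v_x, v_gs = v_gs,
       intersection = inter, r_ratio = ptv_ratio(v_x, v_gs), dsc = d,
       agreement = classify_agreement(d))
}
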