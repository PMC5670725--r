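#' Structure mask container
#'
#' A boolean voxel grid on the geometry of the image it was segmented from,
#' labelled by its role (GTV, ITV or PTV) and the delineation strategy that
#' produced it.
#'
#' @param mask Logical 3-D array.
#' @param spacing,origin Grid geometry (cm), as in [image_volume()].
#' @param label One of `"GTV"`, `"ITV"`, `"PTV"`.
#' @param strategy One of `"GS"`, `"FB"`, `"FB_AUG"`, `"AIP"`, `"MIP"`, or
#'   `NA` for masks not tied to a strategy.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(mask, spacing, origin = c(0, 0, 0),
                           label = c("GTV", "ITV", "PTV"),
                           strategy = NA_character_) {
  label <- match.arg(label)
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("`mask` must be a logical 3-D array")
  if (anyNA(mask)) stop("`mask` must not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive lengths (cm)")
  if (!is.na(strategy) &&
      !strategy %in% c("GS", "FB", "FB_AUG", "AIP", "MIP"))
    stop("unknown strategy label: ", strategy)
  structure(list(mask = mask, spacing = spacing, origin = as.numeric(origin),
                 label = label, strategy = strategy),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s%s: %.2f cc (%d voxels)\n", x$label,
              if (is.na(x$strategy)) "" else paste0(" [", x$strategy, "]"),
              volume_cc(x), sum(x$mask)))
  invisible(x)
}

#' Segment the gross tumor volume from an image
#'
#' Emulates manual contouring of a high-contrast target by thresholding and
#' keeping the largest 6-connected component. The default policy is a
#' relative threshold: a voxel is included when its intensity reaches
#' `threshold` (default 0.5) of the way from the image minimum (lung) to the
#' image maximum (target), boundary inclusive. An absolute intensity
#' threshold may be given instead.
#'
#' @param image An [image_volume()].
#' @param threshold Relative threshold in (0, 1); ignored when
#'   `absolute_threshold` is given.
#' @param absolute_threshold Optional absolute intensity cutoff.
#' @param strategy Optional strategy tag stored on the result.
#' @return A `structure_mask` with label `"GTV"`. If no voxel reaches the
#'   threshold an empty mask is returned with a warning (not an error).
#' @export
segment_gtv <- function(image, threshold = 0.5, absolute_threshold = NULL,
                        strategy = NA_character_) {
  stopifnot(inherits(image, "image_volume"))
  v <- image$values
  if (is.null(absolute_threshold)) {
    if (threshold <= 0 || threshold >= 1)
      stop("`threshold` must lie strictly between 0 and 1")
    lo <- min(v); hi <- max(v)
    if (hi - lo < 1e-9) {
      warning("image has no contrast; returning an empty GTV")
      return(structure_mask(array(FALSE, dim(v)), image$spacing, image$origin,
                            "GTV", strategy))
    }
    cut <- lo + threshold * (hi - lo)
  } else {
    cut <- absolute_threshold
  }
  above <- v >= cut
  if (!any(above)) {
    warning("no voxel reaches the segmentation threshold; returning an empty GTV")
    return(structure_mask(array(FALSE, dim(v)), image$spacing, image$origin,
                          "GTV", strategy))
  }
  keep <- largest_component(above)
  structure_mask(keep, image$spacing, image$origin, "GTV", strategy)
}

largest_component <- function(mask) {
  labels <- label_components_cpp(as.logical(mask), dim(mask))
  n <- attr(labels, "n_components")
  if (n <= 1L) return(array(labels == 1L, dim(mask)))
  counts <- tabulate(labels, nbins = n)
  array(labels == which.max(counts), dim(mask))
}

#' Voxelwise union of structure masks
#'
#' @param ... `structure_mask` objects on one common grid (or a single list
#'   of them).
#' @param label,strategy Labels for the result.
#' @return A `structure_mask` that is the Boolean OR of the inputs.
#' @export
mask_union <- function(..., label = "ITV", strategy = NA_character_) {
  masks <- list(...)
  if (length(masks) == 1L && !inherits(masks[[1]], "structure_mask"))
    masks <- masks[[1]]
  stopifnot(length(masks) >= 1L)
  ref <- masks[[1]]
  acc <- ref$mask
  for (m in masks[-1]) {
    stop_if_geometry_mismatch(ref, m, "masks")
    acc <- acc | m$mask
  }
  structure_mask(acc, ref$spacing, ref$origin, label, strategy)
}

#' Gold-standard ITV: Boolean union of the 10 phase GTVs
#'
#' The benchmark internal target volume is the Boolean "OR" of the gross
#' tumor volumes delineated on all 10 respiratory phase image sets.
#'
#' @param gtvs List of exactly 10 `structure_mask` GTVs on one grid.
#' @return A `structure_mask` with label `"ITV"`, strategy `"GS"`.
#' @export
build_itv_gold <- function(gtvs) {
  if (length(gtvs) != 10L)
    stop(sprintf("the gold-standard ITV requires exactly 10 phase GTVs (got %d)",
                 length(gtvs)))
  mask_union(gtvs, label = "ITV", strategy = "GS")
}

#' Augmented free-breathing ITV
#'
#' Union of the free-breathing GTV with the GTVs contoured on the maximum
#' inhale (phase 0%) and maximum exhale (phase 50%) image sets — the
#' fallback ITV used when full 4DCT delineation is impractical.
#'
#' @param fb_gtv,gtv_0,gtv_50 `structure_mask` GTVs on one common grid.
#' @return A `structure_mask` with label `"ITV"`, strategy `"FB_AUG"`.
#' @export
build_itv_fb_aug <- function(fb_gtv, gtv_0, gtv_50) {
  mask_union(list(fb_gtv, gtv_0, gtv_50), label = "ITV", strategy = "FB_AUG")
}

#' Margin specification for PTV expansion
#'
#' @param axial_mm Margin in the axial plane, mm.
#' @param si_mm Margin along the superior-inferior axis, mm.
#' @return An object of class `margin_spec`.
#' @export
margin_spec <- function(axial_mm = 5, si_mm = axial_mm) {
  if (axial_mm < 0 || si_mm < 0) stop("margins must be non-negative")
  structure(list(axial_mm = axial_mm, si_mm = si_mm,
                 isotropic = isTRUE(all.equal(axial_mm, si_mm))),
            class = "margin_spec")
}

# Integer voxel offsets of an ellipsoidal structuring element with physical
# semi-axes (axial, axial, si) in cm, boundary inclusive.
ellipsoid_offsets <- function(spacing, axial_cm, si_cm) {
  nx <- if (axial_cm > 0) floor(axial_cm / spacing[1]) else 0
  ny <- if (axial_cm > 0) floor(axial_cm / spacing[2]) else 0
  nz <- if (si_cm > 0) floor(si_cm / spacing[3]) else 0
  g <- expand.grid(x = -nx:nx, y = -ny:ny, z = -nz:nz)
  a <- max(axial_cm, 1e-12); c_ <- max(si_cm, 1e-12)
  keep <- (g$x * spacing[1] / a)^2 + (g$y * spacing[2] / a)^2 +
    (g$z * spacing[3] / c_)^2 <= 1 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' Expand a structure by a physical margin
#'
#' Morphological dilation of the mask with an ellipsoidal structuring
#' element whose semi-axes are the axial and SI margins in physical units,
#' discretized on the voxel grid. This reproduces the rounded corner
#' behaviour of treatment-planning-system expansions (as opposed to a
#' per-axis box dilation).
#'
#' With `surface_correction = TRUE` (the default) the structuring-element
#' semi-axes are inflated by half a voxel per axis. A binary mask
#' undersamples the structure it represents: boundary voxel centres lie on
#' average half a voxel inside the true surface, so measuring the margin
#' from voxel centre to voxel centre systematically under-expands (by a few
#' percent in volume at millimetre voxels). The correction measures the
#' margin from the structure surface instead, which matches contour-based
#' planning-system expansions; the uncorrected element is available for a
#' strict centre-to-centre convention.
#'
#' @param structure A `structure_mask` (ITV or GTV).
#' @param margin A [margin_spec()]; a zero margin is the identity.
#' @param label Label of the result, default `"PTV"`.
#' @param surface_correction Logical; inflate the element by the half-voxel
#'   surface offset (default `TRUE`).
#' @return A `structure_mask`, same strategy tag as the input.
#' @export
expand_margin <- function(structure, margin, label = "PTV",
                          surface_correction = TRUE) {
  stopifnot(inherits(structure, "structure_mask"),
            inherits(margin, "margin_spec"))
  ax <- margin$axial_mm / 10  # mm -> cm
  si <- margin$si_mm / 10
  if (ax == 0 && si == 0)
    return(structure_mask(structure$mask, structure$spacing, structure$origin,
                          label, structure$strategy))
  if (surface_correction) {
    ax <- ax + mean(structure$spacing[1:2]) / 2
    si <- si + structure$spacing[3] / 2
  }
  off <- ellipsoid_offsets(structure$spacing, ax, si)
  out <- dilate_mask_cpp(as.logical(structure$mask), dim(structure$mask), off)
  structure_mask(array(out, dim(structure$mask)), structure$spacing,
                 structure$origin, label, structure$strategy)
}

#' Build the PTV for one delineation strategy
#'
#' Applies the full delineation chain for the requested strategy:
#' \describe{
#'   \item{GS}{GTVs segmented on all 10 phases, Boolean union, + 5 mm
#'     isotropic margin (the 10-phase gold standard).}
#'   \item{FB}{GTV segmented on the free-breathing scan, + 5 mm axial /
#'     10 mm SI anisotropic margin (conventional non-4DCT protocol).}
#'   \item{FB_AUG}{Union of FB GTV with the phase-0% and phase-50% GTVs,
#'     + 5 mm isotropic margin.}
#'   \item{AIP/MIP}{GTV segmented on the projection volume, + 5 mm isotropic
#'     margin.}
#' }
#'
#' @param strategy One of `"GS"`, `"FB"`, `"FB_AUG"`, `"AIP"`, `"MIP"`.
#' @param stack [phase_stack()]; required for GS and FB_AUG.
#' @param fb_image Free-breathing [image_volume()]; required for FB and
#'   FB_AUG.
#' @param mip,aip Projection [image_volume()]s; required for MIP / AIP. If
#'   missing but `stack` is given they are computed from it.
#' @param threshold Relative segmentation threshold (see [segment_gtv()]).
#' @param axial_margin_mm,si_margin_mm 4DCT isotropic margin (default 5 mm)
#'   and FB SI margin (default 10 mm).
#' @return A `structure_mask` PTV; the pre-expansion ITV (or GTV for FB) is
#'   attached as attribute `"itv"`.
#' @export
run_strategy <- function(strategy = c("GS", "FB", "FB_AUG", "AIP", "MIP"),
                         stack = NULL, fb_image = NULL, mip = NULL, aip = NULL,
                         threshold = 0.5,
                         axial_margin_mm = 5, si_margin_mm = 10) {
  strategy <- match.arg(strategy)
  need <- function(x, what)
    if (is.null(x)) stop(sprintf("strategy %s requires `%s`", strategy, what))
  iso <- margin_spec(axial_margin_mm, axial_margin_mm)
  itv <- switch(strategy,
    GS = {
      need(stack, "stack")
      gtvs <- lapply(stack$phases, segment_gtv, threshold = threshold,
                     strategy = "GS")
      build_itv_gold(gtvs)
    },
    FB = {
      need(fb_image, "fb_image")
      segment_gtv(fb_image, threshold = threshold, strategy = "FB")
    },
    FB_AUG = {
      need(stack, "stack"); need(fb_image, "fb_image")
      build_itv_fb_aug(
        segment_gtv(fb_image, threshold = threshold, strategy = "FB"),
        segment_gtv(get_phase(stack, 0), threshold = threshold),
        segment_gtv(get_phase(stack, 0.5), threshold = threshold))
    },
    AIP = {
      if (is.null(aip)) { need(stack, "stack or aip"); aip <- build_aip(stack) }
      out <- segment_gtv(aip, threshold = threshold, strategy = "AIP")
      out$label <- "ITV"; out
    },
    MIP = {
      if (is.null(mip)) { need(stack, "stack or mip"); mip <- build_mip(stack) }
      out <- segment_gtv(mip, threshold = threshold, strategy = "MIP")
      out$label <- "ITV"; out
    })
  mar <- if (strategy == "FB") margin_spec(axial_margin_mm, si_margin_mm)
         else iso
  ptv <- expand_margin(itv, mar, label = "PTV")
  attr(ptv, "itv") <- itv
  ptv
}
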