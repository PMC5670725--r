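#' Intensity projections across respiratory phases
#'
#' Collapse a phase-sorted 4DCT stack into a single volume by taking, at
#' every voxel, either the maximum (MIP) or the arithmetic mean (AIP) of the
#' intensities across the phase bins. The MIP captures the full excursion of
#' a high-contrast target moving through low-density lung; the AIP retains
#' only positions occupied for a substantial fraction of the cycle.
#'
#' Projections are computed from the binned phases only (the standard
#' clinical workflow). Projecting over the pre-binning snapshots instead is
#' not implemented; see the package vignette for the trade-off.
#'
#' @param stack A [phase_stack()] (all phases on one grid).
#' @return An [image_volume()] with attribute `projection` set to `"MIP"` or
#'   `"AIP"`.
#' @export
build_mip <- function(stack) {
  project_stack(stack, "MIP")
}

#' @rdname build_mip
#' @export
build_aip <- function(stack) {
  project_stack(stack, "AIP")
}

project_stack <- function(stack, mode = c("MIP", "AIP")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "phase_stack"))
  ref <- stack$phases[[1]]
  for (p in stack$phases) stop_if_geometry_mismatch(ref, p, "phase volumes")
  acc <- stack$phases[[1]]$values
  if (mode == "MIP") {
    for (p in stack$phases[-1]) acc <- pmax(acc, p$values)
  } else {
    for (p in stack$phases[-1]) acc <- acc + p$values
    acc <- acc / length(stack$phases)
  }
  out <- image_volume(acc, ref$spacing, ref$origin)
  attr(out, "projection") <- mode
  out
}
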