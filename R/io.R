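#' Read and write volumes as NIfTI
#'
#' Volumes are stored in NIfTI-1 format with spacing and origin carried in
#' the sform/qform affine. Package geometry is in cm (the convention of the
#' phantom parameters); NIfTI files use mm, so coordinates are scaled by 10
#' on write and back on read. Masks are written with a 0/1 integer payload
#' and read back with a 0.5 cutoff.
#'
#' @param vol An [image_volume()] (or `structure_mask` for [write_mask()]).
#' @param path File path, conventionally ending in `.nii` or `.nii.gz`.
#' @return `write_*` return `path` invisibly; `read_volume()` returns an
#'   [image_volume()]; `read_mask()` a `structure_mask`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  nifti_write(vol$values, vol$spacing, vol$origin, path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  geo <- nifti_geometry(img)
  image_volume(array(as.numeric(img), dim(img)), geo$spacing, geo$origin)
}

#' @rdname write_volume
#' @param label,strategy Labels attached to the mask read back by
#'   [read_mask()].
#' @export
write_mask <- function(vol, path) {
  stopifnot(inherits(vol, "structure_mask"))
  nifti_write(array(as.integer(vol$mask), dim(vol$mask)), vol$spacing,
              vol$origin, path)
}

#' @rdname write_volume
#' @export
read_mask <- function(path, label = "GTV", strategy = NA_character_) {
  img <- RNifti::readNifti(path)
  geo <- nifti_geometry(img)
  structure_mask(array(as.numeric(img) > 0.5, dim(img)), geo$spacing,
                 geo$origin, label, strategy)
}

nifti_write <- function(values, spacing_cm, origin_cm, path) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing_cm * 10
  aff <- diag(c(spacing_cm * 10, 1))
  aff[1:3, 4] <- origin_cm * 10
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

nifti_geometry <- function(img) {
  aff <- RNifti::xform(img)
  list(spacing = abs(diag(aff)[1:3]) / 10, origin = aff[1:3, 4] / 10)
}

#' Read/write a flat key-value phantom configuration
#'
#' A minimal plain-text configuration format: one `key = value` pair per
#' line, `#` comments allowed. Numeric values (including vectors given as
#' comma-separated lists) are converted; everything else stays character.
#' Used by the command-line interface to describe the phantom, trajectory
#' and scan model.
#'
#' @param path File path.
#' @param config Named list to write.
#' @return `read_phantom_config()` returns a named list; the writer returns
#'   `path` invisibly.
#' @export
read_phantom_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}

#' @rdname read_phantom_config
#' @export
write_phantom_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(config[[k]], collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
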