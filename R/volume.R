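#' Construct a scalar volume
#'
#' A volume is a 3-D numeric array plus the physical metadata needed for
#' ray/volume geometry: per-axis voxel spacing in mm and the physical
#' coordinate of the centre of voxel (0,0,0). Voxel index `i` (0-based) maps
#' to physical coordinate `origin + i * spacing` (voxel-centre convention).
#'
#' @param data 3-D numeric array of scalar intensities (e.g. HU). All values
#'   must be finite.
#' @param spacing numeric length 3, physical voxel size per axis (mm), all
#'   positive.
#' @param origin numeric length 3, physical position (mm) of the centre of
#'   voxel (0,0,0).
#' @return An object of class `lumivox_volume`: a list with elements `data`,
#'   `spacing` and `origin`.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)))
#' dim(v$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3-D array")
  if (any(dim(data) < 1L))
    stop("volume dimensions must be >= 1")
  if (!all(is.finite(data)))
    stop("volume intensities must be finite (no NA/NaN/Inf)")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "lumivox_volume")
}

#' @export
print.lumivox_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lumivox_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%g, %g], origin (%g, %g, %g) mm\n",
              min(x$data), max(x$data), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.lumivox_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "lumivox_volume")

# physical bounding box including the outer half-voxel margin
vol_bounds <- function(vol) {
  d <- dim(vol$data)
  list(lo = vol$origin - 0.5 * vol$spacing,
       hi = vol$origin + (d - 1) * vol$spacing + 0.5 * vol$spacing)
}

#' Geometric centre and circumscribed-sphere radius of a volume
#'
#' The circumscribed sphere passes through the corners of the volume's
#' physical bounding box; light sources for the ambient-field precomputation
#' are placed on this sphere.
#'
#' @param vol a [volume()].
#' @return `volume_center`: physical centre (mm). `volume_rradius`: radius of
#'   the circumscribed sphere (mm), half the box diagonal.
#' @export
volume_center <- function(vol) {
  b <- vol_bounds(vol)
  (b$lo + b$hi) / 2
}

#' @rdname volume_center
#' @export
volume_rradius <- function(vol) {
  b <- vol_bounds(vol)
  sqrt(sum((b$hi - b$lo)^2)) / 2
}

raw_dtypes <- list(
  float32 = list(what = "double", size = 4L),
  float64 = list(what = "double", size = 8L),
  int16   = list(what = "integer", size = 2L)
)

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

guess_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti" else "raw"
}

#' Read a scalar volume from disk
#'
#' Supports NIfTI-1 (`.nii` / `.nii.gz`) and a raw little-endian binary
#' format with a JSON sidecar (`<stem>.json`) holding
#' `{dims, dtype, spacing, origin}`.
#'
#' @param path file path. For raw format, the `.raw` file; the sidecar is
#'   looked up next to it.
#' @param format `"auto"` (by extension), `"nifti"` or `"raw"`.
#' @return a [volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("volume file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    dat <- as.array(img)
    dat <- array(as.numeric(dat), dim(dat)[1:3])
    sp <- RNifti::pixdim(img)[1:3]
    xf <- try(RNifti::xform(img), silent = TRUE)
    org <- if (!inherits(xf, "try-error")) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
    vol <- volume(dat, spacing = sp, origin = org)
  } else {
    sc <- sidecar_path(path)
    if (!file.exists(sc))
      stop("raw volume sidecar not found: ", sc)
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    dt <- raw_dtypes[[meta$dtype]]
    if (is.null(dt)) stop("unsupported raw dtype: ", meta$dtype)
    n <- prod(meta$dims)
    con <- file(path, "rb"); on.exit(close(con))
    vals <- readBin(con, what = dt$what, n = n, size = dt$size,
                    endian = "little")
    if (length(vals) != n)
      stop("corrupt raw volume (expected ", n, " values): ", path)
    dat <- array(as.double(vals), dim = meta$dims)
    vol <- volume(dat, spacing = meta$spacing,
                  origin = if (!is.null(meta$origin)) meta$origin else c(0, 0, 0))
  }
  if (any(dim(vol$data) < 2L))
    stop("volume files must have all dimensions >= 2, got ",
         paste(dim(vol$data), collapse = "x"))
  vol
}

#' Write a scalar volume to disk
#'
#' @param vol a [volume()].
#' @param path destination; `.nii`/`.nii.gz` selects NIfTI, anything else the
#'   raw + JSON-sidecar format.
#' @param dtype storage scalar type for the raw format and NIfTI
#'   (`"float32"`, `"float64"` or `"int16"`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, dtype = "float32") {
  stopifnot(is_volume(vol))
  fmt <- guess_format(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    xf <- diag(c(vol$spacing, 1))
    xf[1:3, 4] <- vol$origin
    RNifti::`sform<-`(img, structure(xf, code = 2L))
    nd <- switch(dtype, float32 = "float", float64 = "double", int16 = "int16",
                 stop("unsupported dtype: ", dtype))
    RNifti::writeNifti(img, path, datatype = nd)
  } else {
    dt <- raw_dtypes[[dtype]]
    if (is.null(dt)) stop("unsupported dtype: ", dtype)
    vals <- as.vector(vol$data)
    if (dt$what == "integer") vals <- as.integer(round(vals))
    con <- file(path, "wb")
    writeBin(vals, con, size = dt$size, endian = "little")
    close(con)
    jsonlite::write_json(
      list(dims = dim(vol$data), dtype = dtype, spacing = vol$spacing,
           origin = vol$origin),
      sidecar_path(path), auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Ambient light field container
#'
#' A non-negative scalar grid co-registered with its source volume (same
#' dimensions, spacing and origin), holding the photon energy deposited per
#' cell by [precompute_field()], plus provenance metadata.
#'
#' @param data 3-D non-negative numeric array.
#' @param spacing,origin copied from the source volume.
#' @param provenance named list recording how the field was computed (light
#'   configuration, seed, transfer-function hash).
#' @return an object of class `lumivox_field`.
#' @export
light_field <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        provenance = list()) {
  if (length(dim(data)) != 3L) stop("field data must be a 3-D array")
  if (any(data < 0)) stop("ambient field cells must be >= 0")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), provenance = provenance),
            class = "lumivox_field")
}

#' @export
print.lumivox_field <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lumivox_field> %d x %d x %d cells, total energy %.6g\n",
              d[1], d[2], d[3], sum(x$data)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' Read/write an ambient light field
#'
#' Fields use the raw float32 + JSON sidecar dialect; the sidecar carries a
#' `provenance` block (light configuration, seed, transfer-function hash)
#' used by [run_pipeline()] to detect stale fields.
#'
#' @param path `.raw` file path.
#' @param field a `lumivox_field`.
#' @return `read_field`: a `lumivox_field`. `write_field`: `path`, invisibly.
#' @export
read_field <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(path) || !file.exists(sc))
    stop("field file or sidecar not found: ", path)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  con <- file(path, "rb"); on.exit(close(con))
  vals <- readBin(con, "double", n = prod(meta$dims), size = 4L,
                  endian = "little")
  light_field(array(vals, dim = meta$dims), spacing = meta$spacing,
              origin = meta$origin,
              provenance = as.list(meta$provenance))
}

#' @rdname read_field
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "lumivox_field"))
  con <- file(path, "wb")
  writeBin(as.vector(field$data), con, size = 4L, endian = "little")
  close(con)
  jsonlite::write_json(
    list(dims = dim(field$data), dtype = "float32", spacing = field$spacing,
         origin = field$origin, provenance = field$provenance),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Ambient-field grid dimensions for a volume
#'
#' In the default voxel-aligned mode the ambient field has one cell per
#' voxel, so its shape equals the volume's shape. The alternative physical
#' mode resamples the slice axis to in-plane pixel units:
#' `Vpz = (Vz - 1) * Ps`, where `Ps` is the slice spacing expressed in
#' multiples of the in-plane pixel spacing.
#'
#' @param vol a [volume()].
#' @param mode `"voxel"` (default) or `"physical"`.
#' @return integer vector (Vpx, Vpy, Vpz).
#' @export
field_dimensions <- function(vol, mode = c("voxel", "physical")) {
  mode <- match.arg(mode)
  d <- dim(vol$data)
  if (mode == "voxel") return(as.integer(d))
  ps <- vol$spacing[3] / vol$spacing[1]
  vpz <- max(1L, as.integer(round((d[3] - 1) * ps)))
  as.integer(c(d[1], d[2], vpz))
}
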