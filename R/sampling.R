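as_point_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3, byrow = TRUE)
  if (ncol(p) != 3) stop("points must have 3 columns (x, y, z)")
  storage.mode(p) <- "double"
  p
}

#' Trilinear sampling of a volume at physical points
#'
#' Interpolates the eight voxels surrounding each query point; a query at a
#' voxel centre returns that voxel's stored value exactly, and results are
#' always bounded by the local extrema.
#'
#' @param vol a [volume()].
#' @param p a physical point (length-3 vector) or an n x 3 matrix, in mm.
#' @param clamp if `TRUE`, points outside the volume's physical box return 0
#'   (rays leaving the box carry no material); if `FALSE` (default) such
#'   points are an error.
#' @return numeric vector of interpolated intensities.
#' @export
sample_trilinear <- function(vol, p, clamp = FALSE) {
  stopifnot(is_volume(vol))
  p <- as_point_matrix(p)
  out <- cpp_sample_trilinear(as.vector(vol$data), dim(vol$data),
                              vol$spacing, vol$origin, p, clamp)
  if (!clamp && anyNA(out))
    stop("sample point outside the volume's physical bounds")
  out
}

#' Intensity gradient at physical points
#'
#' Central differences of the trilinearly interpolated field, scaled by the
#' voxel spacing (one-sided at the volume faces). Units: intensity per mm.
#'
#' @inheritParams sample_trilinear
#' @return n x 3 numeric matrix of gradient vectors.
#' @export
gradient_at <- function(vol, p) {
  stopifnot(is_volume(vol))
  p <- as_point_matrix(p)
  cpp_gradient(as.vector(vol$data), dim(vol$data), vol$spacing, vol$origin, p)
}

#' Interpolate the ambient light field at physical points
#'
#' Inverse-distance weighting over the 8 cell centres surrounding the query
#' point: `L = sum(Li / Di) / sum(1 / Di)`. A query closer than 1e-9 mm to a
#' cell centre returns that cell's value exactly, so the scheme never divides
#' by zero and never lets isolated zero cells dominate. Points outside the
#' field return 0.
#'
#' @param field a `lumivox_field`.
#' @param p physical point(s), as in [sample_trilinear()].
#' @param mode `"inverse_distance"` (default) or `"trilinear"`.
#' @return numeric vector of interpolated light intensities.
#' @export
interpolate_ambient <- function(field, p,
                                mode = c("inverse_distance", "trilinear")) {
  stopifnot(inherits(field, "lumivox_field"))
  mode <- match.arg(mode)
  p <- as_point_matrix(p)
  cpp_interp_ambient(as.vector(field$data), dim(field$data), field$spacing,
                     field$origin, p, if (mode == "trilinear") 1L else 0L)
}
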