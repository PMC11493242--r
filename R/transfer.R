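#' Construct a transfer function
#'
#' Maps scalar intensity to colour and opacity via piecewise-linear
#' interpolation between control points, clamped to the first/last point
#' outside their range. Opacity `a` is the classification transmittance
#' driving both photon splitting and the transmitted-light update.
#'
#' @param v numeric vector of control intensities (sorted internally).
#' @param rgba numeric matrix with `length(v)` rows and 4 columns (r, g, b,
#'   a), every channel in \[0, 1\].
#' @return an object of class `lumivox_tf`.
#' @examples
#' tf <- transfer_function(c(0, 100), rbind(c(0, 0, 0, 0), c(1, 1, 1, 1)))
#' evaluate_tf(tf, 50)
#' @export
transfer_function <- function(v, rgba) {
  v <- as.numeric(v)
  rgba <- matrix(as.numeric(rgba), ncol = 4)
  if (length(v) < 1L) stop("transfer function needs at least one control point")
  if (nrow(rgba) != length(v))
    stop("rgba must have one row per control point")
  if (any(!is.finite(v)) || any(!is.finite(rgba)))
    stop("transfer function values must be finite")
  if (any(rgba < 0) || any(rgba > 1))
    stop("all rgba channels must lie in [0, 1]")
  ord <- order(v)
  structure(list(v = v[ord], rgba = rgba[ord, , drop = FALSE]),
            class = "lumivox_tf")
}

#' @export
print.lumivox_tf <- function(x, ...) {
  cat(sprintf("<lumivox_tf> %d control points on [%g, %g]\n",
              length(x$v), min(x$v), max(x$v)))
  invisible(x)
}

#' Evaluate a transfer function
#'
#' @param tf a [transfer_function()].
#' @param intensity numeric vector of scalar intensities.
#' @return numeric matrix with columns `r`, `g`, `b`, `a`, one row per query.
#' @export
evaluate_tf <- function(tf, intensity) {
  stopifnot(inherits(tf, "lumivox_tf"))
  out <- cpp_eval_tf(tf$v, tf$rgba, as.numeric(intensity))
  colnames(out) <- c("r", "g", "b", "a")
  out
}

#' Read/write a transfer function as JSON
#'
#' The on-disk form is `{"points": [{"v": value, "rgba": [r,g,b,a]}, ...]}`
#' sorted by `v`.
#'
#' @param path JSON file path.
#' @param tf a [transfer_function()].
#' @return `read_transfer_function`: a `lumivox_tf`.
#'   `write_transfer_function`: `path`, invisibly.
#' @export
read_transfer_function <- function(path) {
  if (!file.exists(path)) stop("transfer function file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- js$points
  if (is.null(pts) || length(pts$v) < 1L)
    stop("transfer function JSON has no points: ", path)
  rgba <- pts$rgba
  if (is.list(rgba)) rgba <- do.call(rbind, rgba)
  transfer_function(pts$v, rgba)
}

#' @rdname read_transfer_function
#' @export
write_transfer_function <- function(tf, path) {
  stopifnot(inherits(tf, "lumivox_tf"))
  pts <- list(v = tf$v,
              rgba = lapply(seq_along(tf$v), function(i) tf$rgba[i, ]))
  jsonlite::write_json(list(points = pts), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

# stable content hash of a tf (or any serializable object) via a temp file
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
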