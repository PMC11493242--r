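#' Camera specification
#'
#' @param eye camera position (mm).
#' @param view unit viewing direction.
#' @param up approximate up vector (must not be parallel to `view`).
#' @param width,height image size in pixels.
#' @param mode `"orthographic"` (default; pixel pitch in mm) or
#'   `"perspective"` (vertical field of view in degrees).
#' @param pitch physical pixel pitch, mm per pixel (orthographic). The
#'   default 1 mm matches typical in-plane voxel pitch, so the rendered
#'   image resolution follows the axial data.
#' @param fov vertical field of view in degrees (perspective).
#' @return a `lumivox_camera` list.
#' @export
camera <- function(eye, view, up = c(0, 0, 1), width = 128L, height = 128L,
                   mode = c("orthographic", "perspective"), pitch = 1,
                   fov = 45) {
  mode <- match.arg(mode)
  view <- as.numeric(view); up <- as.numeric(up)
  nv <- sqrt(sum(view^2))
  if (nv == 0) stop("view direction must be non-zero")
  view <- view / nv
  cr <- c(view[2] * up[3] - view[3] * up[2],
          view[3] * up[1] - view[1] * up[3],
          view[1] * up[2] - view[2] * up[1])
  if (sqrt(sum(cr^2)) < 1e-9) stop("view and up must not be parallel")
  if (width < 1L || height < 1L) stop("image dimensions must be >= 1")
  structure(list(mode = mode, eye = as.numeric(eye), view = view, up = up,
                 width = as.integer(width), height = as.integer(height),
                 pitch = pitch, fov = fov),
            class = "lumivox_camera")
}

#' Orbiting camera aimed at a volume's centre
#'
#' Convenience constructor for axial/azimuthal views: the eye sits outside
#' the circumscribed sphere along `(cos az cos el, sin az cos el, sin el)`
#' and looks at the volume centre.
#'
#' @param vol a [volume()].
#' @param azimuth,elevation view angles in degrees.
#' @param width,height image size (pixels).
#' @param pitch pixel pitch in mm (default: smallest voxel spacing).
#' @return a [camera()].
#' @export
orbit_camera <- function(vol, azimuth = 0, elevation = 0, width = 128L,
                         height = 128L, pitch = NULL) {
  ctr <- volume_center(vol)
  rr <- volume_rradius(vol)
  az <- azimuth * pi / 180; el <- elevation * pi / 180
  d <- c(cos(az) * cos(el), sin(az) * cos(el), sin(el))
  up <- if (abs(el) > 60) c(1, 0, 0) else c(0, 0, 1)
  camera(eye = ctr + 2 * rr * d, view = -d, up = up, width = width,
         height = height,
         pitch = if (is.null(pitch)) min(vol$spacing) else pitch)
}

#' Render settings
#'
#' @param dim1,dim2 brightness adjustment coefficients weighting the
#'   interpolated ambient light and the transmitted light in the fusion
#'   equation; both >= 0, not both 0.
#' @param step ray-march step, as a fraction of the smallest voxel spacing.
#' @param background background RGB for rays that meet no material.
#' @param interpolation ambient-field interpolation: `"inverse_distance"`
#'   (default) or `"trilinear"`.
#' @return a `lumivox_render_settings` list.
#' @export
render_settings <- function(dim1 = 0.5, dim2 = 0.5, step = 0.5,
                            background = c(0, 0, 0),
                            interpolation = c("inverse_distance",
                                              "trilinear")) {
  interpolation <- match.arg(interpolation)
  if (dim1 < 0 || dim2 < 0 || dim1 + dim2 <= 0)
    stop("dim1 and dim2 must be >= 0 with dim1 + dim2 > 0")
  if (step <= 0) stop("step must be positive")
  structure(list(dim1 = dim1, dim2 = dim2, step = step,
                 background = as.numeric(background),
                 interpolation = interpolation),
            class = "lumivox_render_settings")
}

#' Transmitted-light update at one sample
#'
#' With no refraction on the view ray (F0 = 0), a sample of opacity `alpha`
#' absorbs `LCT = E * alpha` and passes on `E * (1 - alpha)`; the two sum to
#' the input energy exactly.
#'
#' @param energy remaining transmitted energy (>= 0).
#' @param alpha sample opacity in \[0, 1\].
#' @return named vector `c(LCT, remaining)`.
#' @export
transmitted_update <- function(energy, alpha) {
  if (any(energy < 0)) stop("energy must be >= 0")
  if (any(alpha < 0) || any(alpha > 1)) stop("alpha must lie in [0, 1]")
  c(LCT = energy * alpha, remaining = energy * (1 - alpha))
}

#' Fuse ambient and transmitted light at one sample
#'
#' `Cfusion = C * alpha * (Linterp * dim1 + LCT * dim2)`, per channel.
#'
#' @param C rgb colour of the classified sample (length 3, in \[0, 1\]).
#' @param alpha sample opacity.
#' @param Linterp interpolated ambient light intensity at the sample.
#' @param LCT transmitted light absorbed at the sample.
#' @param settings a [render_settings()] (supplies dim1, dim2).
#' @return rgb contribution (length 3).
#' @export
fuse_sample <- function(C, alpha, Linterp, LCT,
                        settings = render_settings()) {
  as.numeric(C) * alpha * (Linterp * settings$dim1 + LCT * settings$dim2)
}

#' Cast a single view ray
#'
#' Marches through the volume, classifying each trilinear sample with the
#' transfer function, fusing ambient and transmitted light per sample, and
#' summing the contributions; terminates when the accumulated opacity
#' reaches 1 or the ray leaves the volume. Rays meeting no material return
#' the background colour.
#'
#' @param origin,direction ray origin (mm) and direction (normalised
#'   internally).
#' @param vol a [volume()].
#' @param tf a [transfer_function()].
#' @param field a `lumivox_field` co-registered with `vol`.
#' @param settings a [render_settings()].
#' @param clamp clamp the summed colour into \[0, 1\] (default `TRUE`).
#' @return rgb vector (length 3).
#' @export
cast_ray <- function(origin, direction, vol, tf, field,
                     settings = render_settings(), clamp = TRUE) {
  nd <- sqrt(sum(direction^2))
  if (!is.finite(nd) || nd == 0) stop("degenerate ray direction")
  res <- render_core(vol, tf, field, matrix(origin, ncol = 3),
                     matrix(direction / nd, ncol = 3), settings)
  rgb <- as.numeric(res$rgb[1, ])
  if (!res$hit[1]) rgb <- settings$background
  if (clamp) rgb <- pmin(pmax(rgb, 0), 1)
  rgb
}

render_core <- function(vol, tf, field, origins, dirs, settings) {
  if (!identical(dim(field$data), dim(vol$data)))
    stop("ambient field shape must match the volume shape")
  cpp_render(as.vector(vol$data), dim(vol$data), vol$spacing, vol$origin,
             tf$v, tf$rgba, as.vector(field$data), origins, dirs,
             settings$step * min(vol$spacing), settings$dim1, settings$dim2,
             if (settings$interpolation == "trilinear") 1L else 0L)
}

camera_rays <- function(cam) {
  w <- cam$width; h <- cam$height
  right <- c(cam$view[2] * cam$up[3] - cam$view[3] * cam$up[2],
             cam$view[3] * cam$up[1] - cam$view[1] * cam$up[3],
             cam$view[1] * cam$up[2] - cam$view[2] * cam$up[1])
  right <- right / sqrt(sum(right^2))
  upv <- c(right[2] * cam$view[3] - right[3] * cam$view[2],
           right[3] * cam$view[1] - right[1] * cam$view[3],
           right[1] * cam$view[2] - right[2] * cam$view[1])
  px <- rep(seq_len(w), each = h)   # column index
  py <- rep(seq_len(h), times = w)  # row index, top of image first
  sx <- (px - (w + 1) / 2)
  sy <- ((h + 1) / 2 - py)
  if (cam$mode == "orthographic") {
    off <- outer(sx * cam$pitch, right) + outer(sy * cam$pitch, upv)
    origins <- sweep(off, 2, cam$eye, "+")
    dirs <- matrix(rep(cam$view, each = nrow(origins)), ncol = 3)
  } else {
    half <- tan(cam$fov * pi / 360)
    dirs <- matrix(rep(cam$view, each = w * h), ncol = 3) +
      outer(sx / (h / 2) * half, right) + outer(sy / (h / 2) * half, upv)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    origins <- matrix(rep(cam$eye, each = w * h), ncol = 3)
  }
  list(origins = origins, dirs = dirs)
}

#' Render an image by fusion ray casting
#'
#' One [cast_ray()] per pixel. Deterministic: identical inputs give
#' bit-identical images.
#'
#' @param cam a [camera()].
#' @inheritParams cast_ray
#' @param clamp if `TRUE` (default) clamp channels into \[0, 1\]; `FALSE`
#'   returns the raw fusion sums (useful for checking linearity in
#'   dim1/dim2).
#' @return height x width x 3 numeric array of class `lumivox_image`, with
#'   attribute `hit` (logical height x width mask of rays that met
#'   material).
#' @export
render_image <- function(cam, vol, tf, field, settings = render_settings(),
                         clamp = TRUE) {
  stopifnot(inherits(cam, "lumivox_camera"))
  rays <- camera_rays(cam)
  res <- render_core(vol, tf, field, rays$origins, rays$dirs, settings)
  h <- cam$height; w <- cam$width
  img <- array(0, c(h, w, 3))
  hit <- matrix(res$hit, nrow = h)
  for (c_ in 1:3) {
    ch <- matrix(res$rgb[, c_], nrow = h)
    bg <- settings$background[c_]
    ch[!hit] <- bg
    img[, , c_] <- ch
  }
  if (clamp) img <- pmin(pmax(img, 0), 1)
  maxn <- max(res$nsamples)
  structure(img, hit = hit, max_samples = maxn, class = "lumivox_image")
}

#' @export
print.lumivox_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<lumivox_image> %d x %d px, channel range [%.3g, %.3g]\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' Write an image as 8-bit PNG
#'
#' Channels are clamped into \[0, 1\] before quantisation.
#'
#' @param img a `lumivox_image` (or any h x w x 3 array in \[0, 1\]).
#' @param path destination `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  arr <- pmin(pmax(unclass(img), 0), 1)
  attributes(arr) <- list(dim = dim(img))
  png::writePNG(arr, path)
  invisible(path)
}
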