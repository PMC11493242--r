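luminance <- function(img) {
  (unclass(img)[, , 1] + unclass(img)[, , 2] + unclass(img)[, , 3]) / 3
}

image_stats <- function(img) {
  lum <- luminance(img)
  c(mean_brightness = mean(lum), rms_contrast = sd(as.vector(lum)))
}

field_provenance_matches <- function(field, vol, tf, cfg) {
  p <- field$provenance
  length(p) > 0 &&
    identical(p$tf_hash, content_hash(tf)) &&
    identical(p$volume_hash, content_hash(vol$data)) &&
    isTRUE(all.equal(p$n_lights, cfg$n_lights)) &&
    isTRUE(all.equal(p$rays_per_light, cfg$rays_per_light)) &&
    isTRUE(all.equal(p$epsilon, cfg$epsilon)) &&
    isTRUE(all.equal(p$F0, cfg$F0)) &&
    isTRUE(all.equal(p$step, cfg$step)) &&
    isTRUE(all.equal(p$disk_radius_scale, cfg$disk_radius_scale)) &&
    isTRUE(all.equal(p$seed, cfg$seed))
}

#' Run the full precompute-and-render pipeline
#'
#' Loads or generates the volume and transfer function, precomputes the
#' ambient light field (reusing a cached field in `outdir` when its
#' provenance matches the current inputs), renders one image, and writes a
#' manifest recording input hashes, seed and package version so the run is
#' reproducible.
#'
#' @param outdir output directory (created if missing).
#' @param vol a [volume()], or a path readable by [read_volume()], or `NULL`
#'   to generate `phantom`.
#' @param tf a [transfer_function()], a JSON path, or the name of a
#'   [make_test_tf()] preset.
#' @param phantom a [phantom_spec()] used when `vol` is `NULL`.
#' @param dims,spacing grid for a generated phantom.
#' @param cfg a [precompute_config()].
#' @param settings a [render_settings()].
#' @param cam a [camera()]; default is an axial [orbit_camera()] sized to
#'   the volume.
#' @param field_path optional path to an existing ambient-field file; if its
#'   provenance does not match the volume/transfer function the pipeline
#'   refuses to render rather than produce a stale-field image.
#' @return named list of artifact paths (`volume`, `tf`, `field`, `image`,
#'   `manifest`), invisibly.
#' @export
run_pipeline <- function(outdir, vol = NULL, tf = "opaque_surface",
                         phantom = phantom_spec("solid_sphere"),
                         dims = c(64, 64, 64), spacing = c(1, 1, 1),
                         cfg = precompute_config(),
                         settings = render_settings(), cam = NULL,
                         field_path = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  generated <- is.null(vol)
  if (generated) {
    vol <- make_phantom(phantom, dims = dims, spacing = spacing)$volume
  } else if (is.character(vol)) {
    vol <- read_volume(vol)
  }
  if (is.character(tf)) {
    tf <- if (file.exists(tf)) read_transfer_function(tf) else make_test_tf(tf)
  }
  vol_path <- file.path(outdir, "volume.nii.gz")
  write_volume(vol, vol_path)
  tf_path <- file.path(outdir, "tf.json")
  write_transfer_function(tf, tf_path)

  out_field <- if (is.null(field_path)) file.path(outdir, "field.raw")
               else field_path
  cached <- FALSE
  field <- NULL
  if (file.exists(out_field) && file.exists(sidecar_path(out_field))) {
    candidate <- read_field(out_field)
    if (field_provenance_matches(candidate, vol, tf, cfg)) {
      field <- candidate
      cached <- TRUE
    } else if (!is.null(field_path)) {
      stop("ambient field provenance does not match the volume/transfer ",
           "function; refusing to render from a stale field: ", field_path)
    }
  } else if (!is.null(field_path)) {
    stop("ambient field not found: ", field_path)
  }
  if (is.null(field)) {
    field <- precompute_field(vol, tf, cfg)
    write_field(field, out_field)
  }

  if (is.null(cam))
    cam <- orbit_camera(vol, azimuth = 0, elevation = 0,
                        width = 2L * dim(vol$data)[2],
                        height = 2L * dim(vol$data)[3])
  img <- render_image(cam, vol, tf, field, settings)
  img_path <- file.path(outdir, "render.png")
  write_image(img, img_path)

  manifest <- list(
    package = "lumivox",
    version = as.character(packageVersion("lumivox")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = cfg$seed,
    cached_field = cached,
    precompute = cfg[setdiff(names(cfg), NULL)],
    render = list(dim1 = settings$dim1, dim2 = settings$dim2,
                  step = settings$step,
                  interpolation = settings$interpolation),
    inputs = list(volume_md5 = unname(tools::md5sum(vol_path)),
                  tf_md5 = unname(tools::md5sum(tf_path))),
    outputs = list(field = basename(out_field), image = basename(img_path)))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(volume = vol_path, tf = tf_path, field = out_field,
                 image = img_path, manifest = manifest_path,
                 cached_field = cached))
}

#' Ablation of the fusion equation
#'
#' Renders the ambient-only arm (`dim2 = 0`), the transmitted-only arm
#' (`dim1 = 0`) and the fused arm from the same camera, and tabulates mean
#' brightness and RMS contrast per arm. Because the fusion equation is
#' linear in (dim1, dim2), the fused raw image equals
#' `dim1 * ambient + dim2 * transmitted` before clamping.
#'
#' @param vol a [volume()].
#' @param tf a [transfer_function()].
#' @param field a `lumivox_field` for `vol`/`tf`.
#' @param cam a [camera()]; default axial orbit view.
#' @param settings a [render_settings()] supplying the fused (dim1, dim2).
#' @param outdir optional directory: writes the three PNGs and `stats.csv`.
#' @return list with `images` (named list of `lumivox_image`s: ambient,
#'   transmitted, fused) and `stats` (data.frame with one row per arm).
#' @export
run_ablation <- function(vol, tf, field, cam = NULL,
                         settings = render_settings(), outdir = NULL) {
  if (is.null(cam)) cam <- orbit_camera(vol)
  arms <- list(
    ambient = render_settings(dim1 = settings$dim1, dim2 = 0,
                              step = settings$step,
                              background = settings$background,
                              interpolation = settings$interpolation),
    transmitted = render_settings(dim1 = 0, dim2 = settings$dim2,
                                  step = settings$step,
                                  background = settings$background,
                                  interpolation = settings$interpolation),
    fused = settings)
  images <- lapply(arms, function(s) render_image(cam, vol, tf, field, s))
  stats <- do.call(rbind, lapply(names(images), function(nm) {
    st <- image_stats(images[[nm]])
    data.frame(arm = nm, mean_brightness = st[["mean_brightness"]],
               rms_contrast = st[["rms_contrast"]])
  }))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(images))
      write_image(images[[nm]], file.path(outdir, paste0(nm, ".png")))
    write.csv(stats, file.path(outdir, "stats.csv"), row.names = FALSE)
  }
  list(images = images, stats = stats)
}
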