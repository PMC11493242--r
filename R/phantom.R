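#' Specify a synthetic phantom
#'
#' Phantoms are analytic volumes used to exercise and validate both the
#' photon-tracing precompute and the renderer without any medical dataset:
#' geometry, material intensities and voxel counts are known in closed form.
#'
#' @param kind one of `"uniform"`, `"solid_sphere"`, `"spherical_shell"`,
#'   `"two_material_block"`, `"single_column"`.
#' @param level material intensity (background is 0). For
#'   `two_material_block`, the first material; `level2` is the second.
#' @param level2 second material intensity (two_material_block only).
#' @param radius sphere / shell outer radius in voxel units. Defaults:
#'   0.3 * min(dims) for `solid_sphere`; 0.45 * min(dims) for
#'   `spherical_shell` (a cranial-vault-like shell nearly filling the grid).
#' @param thickness shell wall thickness in voxel units (default 4).
#' @param center phantom centre in 0-based voxel coordinates; default is the
#'   grid centre.
#' @param noise_sigma standard deviation of additive Gaussian intensity
#'   noise applied before classification (default 0: analytic predicates
#'   stay exact).
#' @param seed RNG seed controlling the noise; the phantom is a
#'   deterministic function of the spec.
#' @return a `lumivox_phantom_spec` list.
#' @export
phantom_spec <- function(kind = c("uniform", "solid_sphere", "spherical_shell",
                                  "two_material_block", "single_column"),
                         level = 100, level2 = 200, radius = NULL,
                         thickness = 4, center = NULL, noise_sigma = 0,
                         seed = 0L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, level = level, level2 = level2, radius = radius,
                 thickness = thickness, center = center,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "lumivox_phantom_spec")
}

#' Generate a synthetic phantom volume
#'
#' @param spec a [phantom_spec()].
#' @param dims integer length 3, grid size in voxels (all >= 4, except
#'   `single_column` which allows degenerate 1-voxel axes).
#' @param spacing voxel spacing in mm.
#' @return a list of class `lumivox_phantom` with elements `volume` (a
#'   [volume()]) and `truth`: per-material voxel counts, the analytic
#'   inside/outside predicate (a function of an n x 3 matrix of 0-based voxel
#'   indices), and the spec.
#' @examples
#' ph <- make_phantom(phantom_spec("solid_sphere", radius = 8), dims = c(32, 32, 32))
#' ph$truth$counts
#' @export
make_phantom <- function(spec, dims = c(64, 64, 64), spacing = c(1, 1, 1)) {
  stopifnot(inherits(spec, "lumivox_phantom_spec"))
  dims <- as.integer(dims)
  if (spec$kind != "single_column" && any(dims < 4L))
    stop("phantom grids need all dimensions >= 4")
  ctr <- if (is.null(spec$center)) (dims - 1) / 2 else as.numeric(spec$center)
  idx <- as.matrix(expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                               k = 0:(dims[3] - 1)))
  predicate <- NULL
  dat <- array(0, dims)
  if (spec$kind == "uniform") {
    dat[] <- spec$level
    predicate <- function(ijk) rep(TRUE, nrow(ijk))
  } else if (spec$kind == "solid_sphere") {
    r <- if (is.null(spec$radius)) 0.3 * min(dims) else spec$radius
    if (r > min(ctr, dims - 1 - ctr) + 0.5)
      stop("sphere radius ", r, " does not fit inside the grid")
    predicate <- function(ijk) {
      sqrt((ijk[, 1] - ctr[1])^2 + (ijk[, 2] - ctr[2])^2 +
           (ijk[, 3] - ctr[3])^2) <= r
    }
    dat <- array(ifelse(predicate(idx), spec$level, 0), dims)
  } else if (spec$kind == "spherical_shell") {
    r <- if (is.null(spec$radius)) 0.45 * min(dims) else spec$radius
    if (r > min(ctr, dims - 1 - ctr) + 0.5)
      stop("shell radius ", r, " does not fit inside the grid")
    rin <- r - spec$thickness
    predicate <- function(ijk) {
      d <- sqrt((ijk[, 1] - ctr[1])^2 + (ijk[, 2] - ctr[2])^2 +
                (ijk[, 3] - ctr[3])^2)
      d <= r & d > rin
    }
    dat <- array(ifelse(predicate(idx), spec$level, 0), dims)
  } else if (spec$kind == "two_material_block") {
    # two axis-aligned slabs split along x, separated by background gaps
    q <- dims[1] %/% 4
    in1 <- function(ijk) ijk[, 1] >= q %/% 2 & ijk[, 1] < q %/% 2 + q
    in2 <- function(ijk) ijk[, 1] >= 2 * q + q %/% 2 & ijk[, 1] < 2 * q + q %/% 2 + q
    predicate <- function(ijk) in1(ijk) | in2(ijk)
    dat <- array(ifelse(in1(idx), spec$level,
                        ifelse(in2(idx), spec$level2, 0)), dims)
  } else if (spec$kind == "single_column") {
    # 1-voxel-wide material chain along z, clear end caps for entry/exit
    ci <- as.integer(round(ctr[1:2]))
    predicate <- function(ijk) {
      ijk[, 1] == ci[1] & ijk[, 2] == ci[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= dims[3] - 2
    }
    dat <- array(ifelse(predicate(idx), spec$level, 0), dims)
  }
  counts <- c(background = sum(dat == 0),
              material = sum(dat == spec$level))
  if (spec$kind == "two_material_block")
    counts["material2"] <- sum(dat == spec$level2)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    dat <- dat + array(rnorm(length(dat), 0, spec$noise_sigma), dims)
  }
  structure(list(volume = volume(dat, spacing = spacing),
                 truth = list(counts = counts, predicate = predicate,
                              center_vox = ctr, spec = spec)),
            class = "lumivox_phantom")
}

#' Test transfer-function presets
#'
#' Presets matched to the phantom intensity levels: `opaque_surface` maps
#' the material to opacity 1 (surface rendering), `semi_transparent` to
#' opacity 0.3 (transparent-tissue rendering), `two_band` assigns distinct
#' colours/opacities to two intensity bands. Background (intensity 0) is
#' always fully transparent.
#'
#' @param kind preset name.
#' @param material intensity of the (first) material band.
#' @param material2 intensity of the second band (two_band only).
#' @return a [transfer_function()].
#' @export
make_test_tf <- function(kind = c("opaque_surface", "semi_transparent",
                                  "two_band"),
                         material = 100, material2 = 200) {
  kind <- match.arg(kind)
  if (kind == "opaque_surface") {
    transfer_function(
      c(0, 0.45 * material, 0.55 * material, material),
      rbind(c(0, 0, 0, 0), c(1, 1, 1, 0), c(1, 1, 1, 1), c(1, 1, 1, 1)))
  } else if (kind == "semi_transparent") {
    transfer_function(
      c(0, 0.45 * material, 0.55 * material, material),
      rbind(c(0, 0, 0, 0), c(1, 0.85, 0.7, 0), c(1, 0.85, 0.7, 0.3),
            c(1, 0.85, 0.7, 0.3)))
  } else {
    transfer_function(
      c(0, 0.5 * material, material, 0.5 * (material + material2), material2),
      rbind(c(0, 0, 0, 0), c(0, 0, 0, 0), c(1, 0.2, 0.2, 0.4),
            c(0.6, 0.1, 0.6, 0.6), c(0.2, 0.2, 1, 0.8)))
  }
}
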