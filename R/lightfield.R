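#' Precomputation configuration
#'
#' Parameters of the ambient-light-field precomputation. The defaults are
#' the package's study conditions: 72 light sources (a spherical arrangement
#' dense enough to emulate a shadowless lamp), 1024 photons per source,
#' termination energy 1e-3, reflection recursion capped at depth 8, Schlick
#' normal-incidence reflectance F0 = 0.04 (the conventional dielectric
#' value), march step half the smallest voxel spacing, and a source disk 5%
#' larger than the volume's circumscribed sphere so every ray bundle covers
#' the whole volume.
#'
#' @param n_lights number of circular area light sources on the
#'   circumscribed sphere.
#' @param rays_per_light photons emitted per source.
#' @param epsilon termination threshold, as a fraction of each photon's
#'   initial energy: a photon (or reflected child) whose remaining energy
#'   falls below `epsilon * initial` is dropped. Expressing it relatively
#'   keeps the traced split tree identical whatever the per-photon energy
#'   normalisation.
#' @param max_depth maximum reflection recursion depth.
#' @param F0 Fresnel reflectance at normal incidence, in \[0, 1\].
#' @param gradient_threshold minimum gradient magnitude (intensity/mm) for a
#'   defined reflection normal; below it the reflected share is folded into
#'   the deposit.
#' @param step ray-march step as a fraction of the smallest voxel spacing.
#' @param disk_radius_scale source disk radius as a multiple of the
#'   volume's circumscribed-sphere radius; values below 1 under-cover the
#'   volume (useful only for coverage experiments).
#' @param seed integer seed controlling ray origins on the source disks.
#' @return a `lumivox_precompute_config` list.
#' @export
precompute_config <- function(n_lights = 72L, rays_per_light = 1024L,
                              epsilon = 1e-3, max_depth = 8L, F0 = 0.04,
                              gradient_threshold = 1e-6, step = 0.5,
                              disk_radius_scale = 1.05, seed = 0L) {
  if (n_lights < 1L) stop("n_lights must be >= 1")
  if (rays_per_light < 1L) stop("rays_per_light must be >= 1")
  if (!(epsilon > 0 && epsilon < 1)) stop("epsilon must lie in (0, 1)")
  if (F0 < 0 || F0 > 1) stop("F0 must lie in [0, 1]")
  if (step <= 0) stop("step must be positive")
  if (disk_radius_scale <= 0) stop("disk_radius_scale must be positive")
  structure(list(n_lights = as.integer(n_lights),
                 rays_per_light = as.integer(rays_per_light),
                 epsilon = epsilon, max_depth = as.integer(max_depth),
                 F0 = F0, gradient_threshold = gradient_threshold,
                 step = step, disk_radius_scale = disk_radius_scale,
                 seed = as.integer(seed)),
            class = "lumivox_precompute_config")
}

golden_angle <- pi * (3 - sqrt(5))

#' Near-uniform directions on the unit sphere
#'
#' Deterministic spherical Fibonacci lattice: points are evenly spread for
#' any n, and for n >= 12 the vector sum nearly cancels (the arrangement is
#' close to antipodally balanced). The seed rotates the lattice about the
#' z-axis; it does not change the spacing structure.
#'
#' @param n number of directions (>= 1).
#' @param seed integer seed for the azimuthal rotation.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_directions <- function(n, seed = 0L) {
  if (n < 1L) stop("n must be >= 1")
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  set.seed(as.integer(seed))
  phi0 <- runif(1, 0, 2 * pi)
  th <- i * golden_angle + phi0
  m <- cbind(r * cos(th), r * sin(th), z)
  m / sqrt(rowSums(m^2))
}

#' Place circular area light sources around a volume
#'
#' One source per Fibonacci direction, centred on the volume's circumscribed
#' sphere at `Rcenter + Rradius * D`, pointing back at the centre
#' (`L = -D`). All sources share the same disk radius and the same
#' intensity, normalised so the summed emission is 1.
#'
#' @param vol a [volume()].
#' @param cfg a [precompute_config()].
#' @return data.frame with one row per source: centre (`cx, cy, cz`),
#'   direction (`dx, dy, dz`), `disk_radius` (mm) and `intensity`.
#' @export
build_lights <- function(vol, cfg = precompute_config()) {
  stopifnot(is_volume(vol))
  ctr <- volume_center(vol)
  rr <- volume_rradius(vol)
  dirs <- sphere_directions(cfg$n_lights, cfg$seed)
  centers <- sweep(rr * dirs, 2, ctr, "+")
  data.frame(cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
             dx = -dirs[, 1], dy = -dirs[, 2], dz = -dirs[, 3],
             disk_radius = cfg$disk_radius_scale * rr,
             intensity = 1 / cfg$n_lights)
}

#' Ray origins on a source disk
#'
#' Low-discrepancy (golden-angle spiral) points on the circular emitter,
#' in the plane through its centre perpendicular to its direction; all rays
#' from a source share the source direction. Deterministic for a fixed seed
#' (the seed rotates the spiral).
#'
#' @param src one light source: a list or single-row data.frame with fields
#'   `cx, cy, cz, dx, dy, dz, disk_radius` (as produced by [build_lights()]).
#' @param k number of origins (>= 1).
#' @param seed integer seed.
#' @return k x 3 matrix of physical ray origins (mm).
#' @export
disk_ray_origins <- function(src, k, seed = 0L) {
  if (k < 1L) stop("k must be >= 1")
  d <- c(src$dx, src$dy, src$dz)
  d <- d / sqrt(sum(d^2))
  # orthonormal in-plane basis
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  i <- seq_len(k)
  rad <- src$disk_radius * sqrt((i - 0.5) / k)
  set.seed(as.integer(seed))
  th <- i * golden_angle + runif(1, 0, 2 * pi)
  ctr <- c(src$cx, src$cy, src$cz)
  t(ctr + t(outer(rad * cos(th), e1) + outer(rad * sin(th), e2)))
}

#' Schlick approximation to Fresnel reflectance
#'
#' `F = F0 + (1 - F0) * (1 - cos_hv)^5`: equals `F0` at normal incidence and
#' 1 in the grazing limit, decreasing monotonically in `cos_hv`.
#'
#' @param cos_hv cosine of the angle between the surface normal and the ray
#'   direction; clamped into \[0, 1\].
#' @param F0 reflectance at normal incidence, in \[0, 1\].
#' @return reflectance in \[F0, 1\].
#' @export
schlick <- function(cos_hv, F0) {
  if (any(F0 < 0) || any(F0 > 1)) stop("F0 must lie in [0, 1]")
  c_ <- pmin(pmax(cos_hv, 0), 1)
  F0 + (1 - F0) * (1 - c_)^5
}

#' Split a photon at an interaction event
#'
#' At a sample with opacity `alpha` and Fresnel reflectance `F`, the photon
#' energy divides into a transmitted share `LT = E * (1 - alpha)`, a
#' reflected share `LR = E * F'` and a deposited share `LC = E - LR - LT`,
#' where `F' = min(F, alpha)` keeps the deposit non-negative. The three
#' shares sum to the input energy exactly.
#'
#' @param energy photon energy (>= 0).
#' @param alpha opacity at the sample, in (0, 1].
#' @param F Fresnel reflectance, in \[0, 1\].
#' @return named numeric vector `c(LT, LR, LC)`.
#' @export
split_photon <- function(energy, alpha, F) {
  if (any(energy < 0)) stop("photon energy must be >= 0")
  if (any(alpha <= 0) || any(alpha > 1)) stop("alpha must lie in (0, 1]")
  if (any(F < 0) || any(F > 1)) stop("F must lie in [0, 1]")
  Fp <- pmin(F, alpha)
  LT <- energy * (1 - alpha)
  LR <- energy * Fp
  LC <- pmax(0, energy - LR - LT)
  c(LT = LT, LR = LR, LC = LC)
}

tf_arrays <- function(tf) list(v = tf$v, rgba = tf$rgba)

#' Trace one photon through a classified volume
#'
#' Marches the photon from its box entry point at the configured step; each
#' sample with positive opacity splits the energy ([split_photon()]) using
#' the Schlick reflectance of the local gradient normal, deposits the `LC`
#' share into the ambient-field cell containing the sample, continues the
#' transmitted share along the same direction and recurses on the reflected
#' share (mirrored about the gradient normal). Photons fall below
#' `cfg$epsilon` or exceed `cfg$max_depth` reflections are dropped.
#'
#' @param vol a [volume()].
#' @param tf a [transfer_function()].
#' @param field a `lumivox_field` accumulator co-registered with `vol`.
#' @param origin,direction photon start (mm) and unit direction.
#' @param energy initial photon energy.
#' @param cfg a [precompute_config()].
#' @return list with the updated `field` and the energy balance:
#'   `deposited`, `exited`, `dropped` (their sum equals `energy` up to
#'   floating-point roundoff below 1e-9).
#' @export
trace_photon <- function(vol, tf, field, origin, direction, energy = 1,
                         cfg = precompute_config()) {
  stopifnot(is_volume(vol), inherits(tf, "lumivox_tf"),
            inherits(field, "lumivox_field"))
  direction <- direction / sqrt(sum(direction^2))
  fdat <- as.vector(field$data)
  res <- cpp_trace_photon(as.vector(vol$data), dim(vol$data), vol$spacing,
                          vol$origin, tf$v, tf$rgba, fdat,
                          as.numeric(origin), as.numeric(direction), energy,
                          cfg$step * min(vol$spacing), cfg$epsilon, cfg$F0,
                          cfg$max_depth, cfg$gradient_threshold)
  field$data <- array(fdat, dim(field$data))
  list(field = field, deposited = res$deposited, exited = res$exited,
       dropped = res$dropped)
}

#' Precompute the global ambient light field
#'
#' Traces `rays_per_light` photons from each of `n_lights` circular sources
#' arranged on the volume's circumscribed sphere, each photon carrying
#' `1 / (n_lights * rays_per_light)` of the unit total emission, and
#' accumulates the deposited energy per voxel-aligned cell. Deterministic
#' for a fixed seed.
#'
#' @param vol a [volume()].
#' @param tf a [transfer_function()].
#' @param cfg a [precompute_config()].
#' @return a `lumivox_field` whose provenance records the light
#'   configuration, seed and transfer-function hash; the attribute
#'   `energy_balance` holds total deposited / exited / dropped energy.
#' @export
precompute_field <- function(vol, tf, cfg = precompute_config()) {
  stopifnot(is_volume(vol), inherits(tf, "lumivox_tf"))
  lights <- build_lights(vol, cfg)
  k <- cfg$rays_per_light
  origins <- vector("list", nrow(lights))
  dirs <- vector("list", nrow(lights))
  for (l in seq_len(nrow(lights))) {
    src <- lights[l, ]
    origins[[l]] <- disk_ray_origins(src, k, seed = cfg$seed + l)
    dirs[[l]] <- matrix(rep(c(src$dx, src$dy, src$dz), each = k), ncol = 3)
  }
  origins <- do.call(rbind, origins)
  dirs <- do.call(rbind, dirs)
  energies <- rep(lights$intensity[1] / k, nrow(origins))
  res <- cpp_precompute(as.vector(vol$data), dim(vol$data), vol$spacing,
                        vol$origin, tf$v, tf$rgba, origins, dirs, energies,
                        cfg$step * min(vol$spacing), cfg$epsilon, cfg$F0,
                        cfg$max_depth, cfg$gradient_threshold)
  prov <- list(n_lights = cfg$n_lights, rays_per_light = cfg$rays_per_light,
               epsilon = cfg$epsilon, max_depth = cfg$max_depth, F0 = cfg$F0,
               gradient_threshold = cfg$gradient_threshold, step = cfg$step,
               disk_radius_scale = cfg$disk_radius_scale, seed = cfg$seed,
               tf_hash = content_hash(tf), volume_hash = content_hash(vol$data))
  fld <- light_field(array(res$field, dim(vol$data)), spacing = vol$spacing,
                     origin = vol$origin, provenance = prov)
  attr(fld, "energy_balance") <- list(deposited = res$deposited,
                                      exited = res$exited,
                                      dropped = res$dropped)
  fld
}
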