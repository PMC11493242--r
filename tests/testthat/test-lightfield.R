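test_that("sphere directions are unit, balanced and well separated", {
  expect_error(sphere_directions(0), ">= 1")
  d1 <- sphere_directions(1, seed = 1)
  expect_equal(sqrt(sum(d1^2)), 1, tolerance = 1e-12)

  d72 <- sphere_directions(72, seed = 0)
  expect_identical(nrow(d72), 72L)
  expect_true(all(abs(sqrt(rowSums(d72^2)) - 1) < 1e-12))

  for (n in c(12, 72, 100)) {
    dn <- sphere_directions(n, seed = 5)
    expect_lt(sqrt(sum(colSums(dn)^2)), 0.05 * n)
  }

  # brute-force pairwise angle scan: minimum separation is a healthy
  # fraction of the ideal equal-area spacing sqrt(4*pi/n)
  d100 <- sphere_directions(100, seed = 2)
  cosmat <- tcrossprod(d100)
  diag(cosmat) <- -1
  min_angle <- acos(max(cosmat))
  expect_gt(min_angle, 0.6 * sqrt(4 * pi / 100))
})

test_that("lights sit on the circumscribed sphere, face the centre, sum to 1", {
  v <- volume(array(0, c(64, 64, 64)))
  cfg <- precompute_config(n_lights = 24, seed = 3)
  lights <- build_lights(v, cfg)
  rr <- volume_rradius(v)
  expect_equal(rr, sqrt(3 * 64^2) / 2, tolerance = 1e-12)
  ctr <- volume_center(v)
  cdist <- sqrt((lights$cx - ctr[1])^2 + (lights$cy - ctr[2])^2 +
                  (lights$cz - ctr[3])^2)
  expect_equal(cdist, rep(rr, 24), tolerance = 1e-9)
  face <- (ctr[1] - lights$cx) * lights$dx + (ctr[2] - lights$cy) * lights$dy +
    (ctr[3] - lights$cz) * lights$dz
  expect_true(all(face > 0))
  expect_equal(sum(lights$intensity), 1, tolerance = 1e-12)
  expect_true(all(lights$disk_radius >= rr))  # default 1.05 * Rradius
})

test_that("disk ray origins are in-plane, deterministic and centred", {
  v <- volume(array(0, c(32, 32, 32)))
  src <- build_lights(v, precompute_config(n_lights = 7, seed = 9))[3, ]
  o1 <- disk_ray_origins(src, 1, seed = 1)
  expect_identical(dim(o1), c(1L, 3L))
  k <- 400
  o <- disk_ray_origins(src, k, seed = 4)
  ctr <- as.numeric(src[c("cx", "cy", "cz")])
  d <- as.numeric(src[c("dx", "dy", "dz")])
  rel <- sweep(o, 2, ctr)
  expect_lt(max(abs(rel %*% d)), 1e-9)                       # in-plane
  expect_true(all(sqrt(rowSums(rel^2)) <= src$disk_radius + 1e-9))
  expect_lt(sqrt(sum(colMeans(rel)^2)), 2 * src$disk_radius / sqrt(k))
  expect_identical(o, disk_ray_origins(src, k, seed = 4))    # deterministic
  expect_false(identical(o, disk_ray_origins(src, k, seed = 5)))
  expect_error(disk_ray_origins(src, 0), ">= 1")
})

test_that("Schlick reflectance has the right limits and slope", {
  expect_equal(schlick(1, 0.04), 0.04)
  expect_equal(schlick(0, 0.04), 1)
  expect_equal(schlick(0.5, 0.04), 0.04 + 0.96 * 0.5^5)
  grid <- seq(0, 1, length.out = 500)
  f <- schlick(grid, 0.04)
  expect_true(all(diff(f) < 0))
  expect_error(schlick(0.5, 1.2), "\\[0, 1\\]")
})

test_that("photon splitting conserves energy with the reflectance clamp", {
  expect_equal(split_photon(1, 1, 0), c(LT = 0, LR = 0, LC = 1))
  expect_equal(split_photon(1, 0.5, 0.1), c(LT = 0.5, LR = 0.1, LC = 0.4))
  s <- split_photon(2, 0.25, 0.5)  # F clamped to alpha
  expect_equal(s, c(LT = 1.5, LR = 0.5, LC = 0))
  expect_identical(sum(s), 2)
  set.seed(8)
  for (i in 1:50) {
    E <- runif(1, 0, 3); a <- runif(1); F <- runif(1)
    s <- split_photon(E, a, F)
    expect_true(all(s >= 0))
    expect_equal(sum(s), E, tolerance = 1e-12)
  }
  expect_error(split_photon(-1, 0.5, 0), ">= 0")
})

test_that("a photon missing the volume deposits nothing", {
  v <- random_volume(c(8, 8, 8), seed = 1)
  res <- trace_photon(v, ramp_tf(), empty_field(v),
                      origin = c(-100, -100, 3), direction = c(0, 0, 1))
  expect_identical(res$deposited, 0)
  expect_identical(res$exited, 1)
  expect_true(all(res$field$data == 0))
})

test_that("the 1x1x4 column phantom reproduces the hand-computed trace", {
  vol <- column_volume()
  cfg <- precompute_config(F0 = 0, step = 1.0)  # one sample per voxel
  res <- trace_photon(vol, column_tf(0.5), empty_field(vol),
                      origin = c(0, 0, -5), direction = c(0, 0, 1),
                      energy = 1, cfg = cfg)
  expect_identical(as.vector(res$field$data), c(0, 0.5, 0.25, 0))
  expect_identical(res$exited, 0.25)
  expect_identical(res$dropped, 0)
})

test_that("per-photon energy balance closes on random phantoms", {
  cfg <- precompute_config(F0 = 0.3, max_depth = 6, seed = 0)
  for (s in 1:10) {
    v <- random_volume(c(8, 8, 8), seed = 100 + s)
    fld <- empty_field(v)
    set.seed(200 + s)
    total_dep <- 0
    for (j in 1:10) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      org <- c(3.5, 3.5, 3.5) - 30 * dir + runif(3, -2, 2)
      res <- trace_photon(v, ramp_tf(), fld, org, dir, energy = 1, cfg = cfg)
      fld <- res$field
      total_dep <- total_dep + res$deposited
      expect_lt(abs(res$deposited + res$exited + res$dropped - 1), 1e-9)
    }
    expect_equal(sum(fld$data), total_dep, tolerance = 1e-9)
    expect_true(all(fld$data >= 0))
  }
})

test_that("recursive tracer matches exhaustive split-tree enumeration", {
  cfg <- precompute_config(F0 = 0.3, max_depth = 4, epsilon = 1e-3,
                           step = 0.5)
  cfg_ref <- list(step = 0.5 * 1, epsilon = cfg$epsilon, F0 = cfg$F0,
                  max_depth = cfg$max_depth,
                  gradient_threshold = cfg$gradient_threshold)
  set.seed(31)
  for (s in 1:5) {
    v <- random_volume(c(4, 4, 4), seed = 300 + s)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    org <- c(1.5, 1.5, 1.5) - 20 * dir
    res <- trace_photon(v, ramp_tf(), empty_field(v), org, dir,
                        energy = 1, cfg = cfg)
    ref <- ref_trace_enumerate(v, ramp_tf(), org, dir, 1, cfg_ref)
    expect_lt(max(abs(res$field$data - ref$deposits)), 1e-9)
    expect_lt(abs(res$deposited - ref$deposited), 1e-9)
    expect_lt(abs(res$exited - ref$exited), 1e-9)
    expect_lt(abs(res$dropped - ref$dropped), 1e-9)
  }
})

test_that("precomputed fields obey occlusion, conservation and determinism", {
  # no interaction events in an all-transparent volume
  v0 <- volume(array(0, c(12, 12, 12)))
  cfg <- precompute_config(n_lights = 6, rays_per_light = 32, seed = 2)
  f0 <- precompute_field(v0, make_test_tf("opaque_surface"), cfg)
  expect_true(all(f0$data == 0))

  # opaque sphere: lit surface shell, dark core, empty exterior
  ph <- make_phantom(phantom_spec("solid_sphere", radius = 10),
                     dims = c(32, 32, 32))
  # enough photons that every surface cell expects ~5 hits
  cfg2 <- precompute_config(n_lights = 24, rays_per_light = 2048, seed = 6)
  f <- precompute_field(ph$volume, make_test_tf("opaque_surface"), cfg2)
  idx <- as.matrix(expand.grid(0:31, 0:31, 0:31))
  r <- sqrt(rowSums(sweep(idx, 2, c(15.5, 15.5, 15.5))^2))
  vals <- as.vector(f$data)
  surface <- r > 9 & r <= 10
  core <- r < 6
  exterior <- r > 14
  expect_gt(mean(vals[surface] > 0), 0.95)
  expect_identical(sum(vals[core]), 0)
  expect_identical(sum(vals[exterior]), 0)
  expect_lte(sum(vals), 1 + 1e-6)

  # bit-identical rerun
  f2 <- precompute_field(ph$volume, make_test_tf("opaque_surface"), cfg2)
  expect_identical(f$data, f2$data)
})
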