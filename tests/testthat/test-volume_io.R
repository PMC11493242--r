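test_that("raw volume round-trips are lossless and keep geometry", {
  td <- withr::local_tempdir()

  zero <- volume(array(0, c(4, 4, 4)))
  p <- file.path(td, "zero.raw")
  write_volume(zero, p, dtype = "int16")
  back <- read_volume(p)
  expect_identical(dim(back$data), c(4L, 4L, 4L))
  expect_true(all(back$data == 0))

  v <- random_volume(c(8, 8, 8), seed = 11)
  v$spacing <- c(0.5, 0.5, 2.0)
  v$origin <- c(-3, 2, 7)
  p2 <- file.path(td, "rand.raw")
  write_volume(v, p2, dtype = "float64")
  b2 <- read_volume(p2)
  expect_identical(b2$data, v$data)
  expect_identical(b2$spacing, c(0.5, 0.5, 2.0))
  expect_identical(b2$origin, c(-3, 2, 7))

  # float32 quantises but must round-trip its own stored values exactly
  p3 <- file.path(td, "rand32.raw")
  write_volume(v, p3, dtype = "float32")
  b3 <- read_volume(p3)
  write_volume(b3, file.path(td, "again.raw"), dtype = "float32")
  expect_identical(read_volume(file.path(td, "again.raw"))$data, b3$data)
})

test_that("NIfTI round-trip preserves a seeded phantom and its counts", {
  td <- withr::local_tempdir()
  ph <- make_phantom(phantom_spec("solid_sphere", radius = 9, seed = 3),
                     dims = c(28, 28, 28), spacing = c(1, 1, 1.5))
  p <- file.path(td, "sphere.nii.gz")
  write_volume(ph$volume, p)
  back <- read_volume(p)
  expect_equal(back$spacing, c(1, 1, 1.5))
  expect_identical(sum(back$data > 50), unname(ph$truth$counts["material"]))
  expect_equal(back$data, ph$volume$data)
})

test_that("volume validation rejects bad input", {
  td <- withr::local_tempdir()
  expect_error(read_volume(file.path(td, "absent.nii")), "not found")
  expect_error(volume(array(c(1, NA), c(1, 1, 2))), "finite")
  expect_error(volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)), "spacing")
  # files with a degenerate axis are rejected at load
  thin <- volume(array(1, c(1, 4, 4)))
  p <- file.path(td, "thin.raw")
  write_volume(thin, p)
  expect_error(read_volume(p), ">= 2")
})

test_that("transfer function evaluation is piecewise-linear and clamped", {
  one <- transfer_function(100, matrix(c(1, 1, 1, 1), 1))
  expect_equal(unname(evaluate_tf(one, 50)[1, ]), c(1, 1, 1, 1))

  two <- transfer_function(c(0, 100),
                           rbind(c(0, 0, 0, 0), c(1, 1, 1, 1)))
  expect_equal(evaluate_tf(two, 50)[1, "a"], c(a = 0.5))
  expect_equal(evaluate_tf(two, -10)[1, "a"], c(a = 0))   # clamp below
  expect_equal(evaluate_tf(two, 999)[1, "a"], c(a = 1))   # clamp above

  # arbitrary three-point tf vs direct linear arithmetic
  v <- c(10, 40, 90)
  rgba <- rbind(c(0.1, 0.2, 0.3, 0.0), c(0.9, 0.4, 0.1, 0.6),
                c(0.2, 0.8, 0.5, 1.0))
  tf <- transfer_function(v, rgba)
  q <- 65  # between the 2nd and 3rd points
  t <- (q - 40) / (90 - 40)
  expect_equal(unname(evaluate_tf(tf, q)[1, ]),
               rgba[2, ] + t * (rgba[3, ] - rgba[2, ]))
  expect_error(transfer_function(c(0, 1), rbind(c(0, 0, 0, 0),
                                                c(2, 0, 0, 1))), "\\[0, 1\\]")
})

test_that("transfer function JSON round-trips", {
  td <- withr::local_tempdir()
  tf <- make_test_tf("two_band")
  p <- file.path(td, "tf.json")
  write_transfer_function(tf, p)
  back <- read_transfer_function(p)
  expect_equal(back$v, tf$v)
  expect_equal(back$rgba, tf$rgba)
})

test_that("trilinear sampling hits voxel centres and stays bounded", {
  v <- random_volume(c(5, 6, 7), seed = 21, spacing = c(1, 1.5, 2))
  # exact voxel-centre queries return stored values
  for (ijk in list(c(0, 0, 0), c(2, 3, 4), c(4, 5, 6))) {
    p <- v$origin + ijk * v$spacing
    expect_identical(sample_trilinear(v, p),
                     v$data[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1])
  }
  # constant volume is constant everywhere
  cv <- volume(array(3.7, c(4, 4, 4)))
  set.seed(1)
  pts <- matrix(runif(30, 0, 3), ncol = 3)
  expect_equal(sample_trilinear(cv, pts), rep(3.7, 10))
  # 2x2x2 with corners 0..7: cell-centre query equals the mean 3.5
  cube <- volume(array(0:7, c(2, 2, 2)))
  expect_equal(sample_trilinear(cube, c(0.5, 0.5, 0.5)), 3.5)
  # boundedness property over random queries
  set.seed(2)
  q <- matrix(runif(300, 0, 1) *
                rep((dim(v$data) - 1) * v$spacing, each = 100), ncol = 3)
  s <- sample_trilinear(v, q)
  expect_true(all(s >= min(v$data) - 1e-12 & s <= max(v$data) + 1e-12))
  # out-of-bounds behaviour
  expect_error(sample_trilinear(v, c(-50, 0, 0)), "outside")
  expect_identical(sample_trilinear(v, c(-50, 0, 0), clamp = TRUE), 0)
})

test_that("gradients recover analytic slopes and radial directions", {
  # constant volume: zero gradient
  cv <- volume(array(1, c(4, 4, 4)))
  expect_equal(gradient_at(cv, c(1.5, 1.5, 1.5))[1, ], c(0, 0, 0))
  # linear ramp f = 2x per mm, exact at interior points
  d <- c(8, 6, 6)
  ramp <- volume(array(rep(2 * (0:7) * 0.5, times = 36), d),
                 spacing = c(0.5, 1, 1))
  g <- gradient_at(ramp, c(1.5, 2, 3))
  expect_equal(g[1, ], c(2, 0, 0))
  # sphere phantom: boundary gradient points radially within 15 degrees
  ph <- make_phantom(phantom_spec("solid_sphere", radius = 10),
                     dims = c(32, 32, 32))
  ctr <- (dim(ph$volume$data) - 1) / 2
  for (dir in list(c(1, 0, 0), c(0, 1, 0), c(0.6, 0.64, 0.48))) {
    p <- ctr + 10 * dir / sqrt(sum(dir^2))
    g <- gradient_at(ph$volume, p)[1, ]
    cosang <- sum(-g * dir) / sqrt(sum(g^2) * sum(dir^2))
    expect_gt(cosang, cos(15 * pi / 180))  # gradient points inward (-radial)
  }
})

test_that("field dimensions follow voxel-aligned and physical modes", {
  v5 <- volume(array(0, c(4, 4, 5)), spacing = c(1, 1, 2))
  expect_identical(field_dimensions(v5), c(4L, 4L, 5L))
  expect_identical(field_dimensions(v5, "physical"), c(4L, 4L, 8L))
  v2 <- volume(array(0, c(4, 4, 2)), spacing = c(1, 1, 1))
  expect_identical(field_dimensions(v2, "physical"), c(4L, 4L, 1L))
})

test_that("ambient field files carry provenance and data intact", {
  td <- withr::local_tempdir()
  f <- light_field(array(runif(4^3), c(4, 4, 4)), spacing = c(1, 1, 2),
                   provenance = list(seed = 5L, n_lights = 12L,
                                     tf_hash = "abc"))
  p <- file.path(td, "field.raw")
  write_field(f, p)
  back <- read_field(p)
  expect_equal(max(abs(back$data - f$data)), 0, tolerance = 1e-7)  # float32
  expect_equal(back$provenance$seed, 5L)
  expect_equal(back$provenance$tf_hash, "abc")
  expect_error(light_field(array(-1, c(2, 2, 2))), ">= 0")
})
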