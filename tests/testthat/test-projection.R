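test_that("projections of a centered disk conserve mass and are symmetric", {
  disk <- disk_phantom(64, radius = 18)
  sino <- radon_project(disk, full_rotation_angles(36))
  mass <- colSums(sino$data)
  expect_lt((max(mass) - min(mass)) / mean(mass), 0.005)
  expect_equal(mean(mass), sum(disk), tolerance = 1e-10)
  # rotational symmetry: all columns agree to discretization tolerance
  spread <- apply(sino$data, 1, function(r) max(r) - min(r))
  expect_lt(max(spread) / max(sino$data), 0.03)
})

test_that("the projector matches the brute-force ray-marching oracle", {
  set.seed(10)
  for (k in 1:3) {
    img <- random_supported_image(8L, border = 2L)
    ang <- seq(0, 330, by = 30)
    expect_lt(rel_l2(radon_project(img, ang)$data, radon_oracle(img, ang)),
              0.05)
  }
})

test_that("the projector is linear", {
  set.seed(11)
  ang <- c(0, 33.5, 90, 121, 270)
  for (k in 1:5) {
    x1 <- random_supported_image(16L)
    x2 <- random_supported_image(16L)
    a <- runif(1, 0.1, 3); b <- runif(1, 0.1, 3)
    lhs <- radon_project(a * x1 + b * x2, ang)$data
    rhs <- a * radon_project(x1, ang)$data + b * radon_project(x2, ang)$data
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("back_project is the exact adjoint of radon_project", {
  set.seed(12)
  ang <- full_rotation_angles(13)
  for (k in 1:20) {
    x <- random_supported_image(16L)
    y <- matrix(runif(16 * 13), 16)
    lhs <- sum(radon_project(x, ang)$data * y)
    rhs <- sum(x * back_project(sinogram(y, ang)))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-3)
  }
})

test_that("sinogram construction validates its invariants", {
  expect_error(sinogram(matrix(1, 4, 3), c(0, 10)), "columns")
  expect_error(sinogram(matrix(1, 4, 2), c(10, 5)), "increasing")
  expect_error(sinogram(matrix(1, 4, 2), c(0, 400)), "360")
  expect_error(radon_project(matrix(1, 4, 4), numeric(0)), "empty")
})

test_that("additive Gaussian noise has the configured moments", {
  sino <- radon_project(disk_phantom(64), full_rotation_angles(50))
  expect_identical(add_noise(sino, noise_model(0)), sino)
  noisy <- add_noise(sino, noise_model(0.1, seed = 3))
  eps <- noisy$data - sino$data
  n <- length(eps)
  expect_lt(abs(sd(eps) - 0.1) / 0.1, 0.02)
  expect_lt(abs(mean(eps)), 3 * 0.1 / sqrt(n))
  # deterministic given the seed
  expect_identical(add_noise(sino, noise_model(0.1, seed = 3))$data, noisy$data)
})

test_that("subsampling indices are equally spaced with round-half-up", {
  s <- subsample_indices(400, 64)
  expect_identical(s$indices[1:5], c(1L, 7L, 14L, 20L, 26L))
  expect_length(s$indices, 64)
  expect_true(all(diff(s$indices) > 0))
  expect_true(all(s$indices >= 1 & s$indices <= 400))
  expect_identical(subsample_indices(5, 5)$indices, 1:5)
  expect_identical(subsample_indices(8, 4)$indices, c(1L, 3L, 5L, 7L))
  expect_error(subsample_indices(4, 5), "N > P")
  expect_error(subsample_indices(4, 0), "N")
})

test_that("apply_scheme restricts columns and angles consistently", {
  sino <- radon_project(disk_phantom(32), full_rotation_angles(16))
  ident <- subsample_indices(16, 16)
  expect_equal(apply_scheme(sino, ident), sino)
  sub <- apply_scheme(sino, subsample_indices(16, 4))
  expect_equal(ncol(sub$data), 4)
  expect_length(sub$angles_deg, 4)
  expect_error(apply_scheme(sub, subsample_indices(16, 4)), "columns")
})

test_that("nested subsampling equals direct subsampling when counts divide", {
  sino <- radon_project(disk_phantom(16) +
                          random_supported_image(16L) * 0.2,
                        full_rotation_angles(24))
  for (NM in list(c(12L, 4L), c(8L, 4L), c(12L, 6L), c(6L, 3L))) {
    N <- NM[1]; M <- NM[2]
    two_step <- apply_scheme(apply_scheme(sino, subsample_indices(24, N)),
                             subsample_indices(N, M))
    direct <- apply_scheme(sino, subsample_indices(24, M))
    expect_equal(two_step$data, direct$data, info = paste(N, M))
    expect_equal(two_step$angles_deg, direct$angles_deg)
  }
})

test_that("start-angle shifts are circular and commute with rotation", {
  ph <- generate_slice(phantom_config(image_size = 64), 3)
  sino <- radon_project(ph, full_rotation_angles(360))
  expect_identical(shift_start_angle(sino, 0), sino)
  expect_identical(shift_start_angle(sino, 360)$data, sino$data)
  # shifting by 90 projections (= 90 degrees here) rotates the FBP
  # reconstruction by 90 degrees counterclockwise
  rec0 <- fbp(sino)
  rec90 <- fbp(shift_start_angle(sino, 90))
  rot_ccw <- t(rec0)[rev(seq_len(ncol(rec0))), ]
  expect_lt(mean(abs(rec90 - rot_ccw)) / max(rec0), 0.02)
  # non-uniform angle sets are rejected
  irregular <- sinogram(matrix(1, 8, 3), c(0, 10, 30))
  expect_error(shift_start_angle(irregular, 1), "full-revolution")
})
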