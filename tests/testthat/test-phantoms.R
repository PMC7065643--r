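test_that("an empty scene renders an all-zero image", {
  cfg <- phantom_config(n_blobs_range = c(0L, 0L), n_tubes_range = c(0L, 0L),
                        background_level = 0)
  expect_identical(generate_slice(cfg, 1L), matrix(0, 128, 128))
})

test_that("generation is deterministic in (config, seed)", {
  cfg <- phantom_config(image_size = 64)
  expect_identical(generate_slice(cfg, 42L), generate_slice(cfg, 42L))
  expect_false(identical(generate_slice(cfg, 42L), generate_slice(cfg, 43L)))
  v1 <- generate_volume(cfg, 4, seed = 7)
  v2 <- generate_volume(cfg, 4, seed = 7)
  expect_identical(v1, v2)
})

test_that("non-overlapping blob placement yields the requested component count", {
  skip_if_not_installed("EBImage")
  cfg <- phantom_config(image_size = 96, n_blobs_range = c(5L, 5L),
                        blob_radius_range = c(2, 5),
                        intensity_range = c(0.8, 0.8),
                        n_tubes_range = c(0L, 0L), allow_overlap = FALSE)
  for (seed in 1:5) {
    img <- generate_slice(cfg, seed)
    # threshold at half the (shared) blob peak; count connected components
    lab <- EBImage::bwlabel(img > 0.4)
    expect_equal(max(lab), 5, info = paste("seed", seed))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(image_size = -4), "image_size")
  expect_error(phantom_config(n_blobs_range = c(5, 2)), "n_blobs_range")
  expect_error(phantom_config(intensity_range = numeric(0)), "intensity_range")
  expect_error(generate_volume(phantom_config(), 0, seed = 1), "n_slices")
})

test_that("signal support stays inside the inscribed circle minus the margin", {
  cfg <- phantom_config(image_size = 96)
  H <- cfg$image_size; c0 <- (H - 1) / 2
  rr <- outer(((seq_len(H) - 1) - c0)^2, ((seq_len(H) - 1) - c0)^2, "+")
  allowed <- (H / 2 - cfg$support_margin)^2
  for (seed in 1:20) {
    img <- generate_slice(cfg, seed)
    expect_true(all(img[rr > allowed] <= cfg$background_level),
                info = paste("seed", seed))
    expect_true(all(img >= 0) && all(img <= max(cfg$intensity_range)))
  }
})

test_that("default phantoms are sparse", {
  cfg <- phantom_config()
  frac <- vapply(1:100, function(seed) {
    img <- generate_slice(cfg, seed)
    mean(img > 0.1 * max(img))
  }, numeric(1))
  expect_true(all(frac < 0.15))
})

test_that("slice_correlation = 1 repeats the scene and 0 draws independently", {
  cfg1 <- phantom_config(image_size = 64, slice_correlation = 1)
  v <- generate_volume(cfg1, 3, seed = 5)
  expect_identical(v[[1]], v[[2]])
  expect_identical(v[[2]], v[[3]])

  # at correlation 0 the within-volume slice correlation must be
  # indistinguishable from that of independent draws
  cfg0 <- phantom_config(image_size = 64, slice_correlation = 0)
  within <- vapply(1:50, function(s) {
    v <- generate_volume(cfg0, 2, seed = s)
    cor(c(v[[1]]), c(v[[2]]))
  }, numeric(1))
  across <- vapply(1:50, function(s)
    cor(c(generate_slice(cfg0, 1000 + s)), c(generate_slice(cfg0, 2000 + s))),
    numeric(1))
  expect_gt(t.test(within, across)$p.value, 0.01)
})

test_that("similarity of correlated slices decays with slice distance", {
  cfg <- phantom_config(image_size = 64)
  adjacent <- numeric(0); apart <- numeric(0)
  for (s in 1:20) {
    v <- generate_volume(cfg, 10, seed = 300 + s)
    adjacent <- c(adjacent, mean(vapply(1:9, function(i)
      cor(c(v[[i]]), c(v[[i + 1]])), numeric(1))))
    apart <- c(apart, mean(vapply(1:5, function(i)
      cor(c(v[[i]]), c(v[[i + 5]])), numeric(1))))
  }
  expect_gt(mean(adjacent), mean(apart))
})

test_that("the disk phantom has the requested plateau and an anti-aliased rim", {
  d <- disk_phantom(64, radius = 20, intensity = 2)
  expect_equal(max(d), 2)
  expect_equal(d[32, 32], 2)
  expect_true(all(d >= 0))
  expect_true(any(d > 0 & d < 2)) # rim pixels are fractional
})
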