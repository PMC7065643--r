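test_that("total variation matches hand-computed values", {
  expect_equal(tv_norm(matrix(3, 5, 7)), 0)
  # left half 0 / right half 1: one unit edge of length 4
  x <- cbind(matrix(0, 4, 2), matrix(1, 4, 2))
  expect_equal(tv_norm(x), 4)
  # positive homogeneity
  set.seed(20)
  y <- matrix(rnorm(36), 6)
  for (a in c(0.5, 2, -3)) expect_equal(tv_norm(a * y), abs(a) * tv_norm(y))
})

test_that("the TV proximal operator denoises toward lower TV", {
  set.seed(21)
  u <- matrix(rnorm(64 * 64), 64)
  v <- optrecon:::cpp_tv_prox(u, 0.5, 50L)
  expect_lt(tv_norm(v), tv_norm(u))
  # lambda = 0 returns the input
  expect_equal(optrecon:::cpp_tv_prox(u, 0, 10L), u)
  # prox optimality: objective at the prox point is below nearby points
  obj <- function(x) 0.5 * sum((x - u)^2) + 0.5 * tv_norm(x)
  expect_lt(obj(v), obj(u))
})

test_that("monotone TwIST yields a non-increasing objective trace", {
  set.seed(22)
  for (k in 1:20) {
    img <- random_supported_image(16L)
    ang <- full_rotation_angles(sample(6:12, 1))
    sino <- radon_project(img, ang)
    res <- twist_reconstruct(sino, twist_config(tau = 10^runif(1, -4, -1),
                                                max_iters = 15L))
    expect_true(all(diff(res$objective_trace) <= 1e-12),
                info = paste("instance", k))
  }
})

test_that("with tau = 0 TwIST descends below the FBP initialization", {
  ph <- generate_slice(phantom_config(image_size = 64), 31)
  sino <- radon_project(ph, full_rotation_angles(64))
  res <- twist_reconstruct(sino, twist_config(tau = 0, max_iters = 30L))
  tr <- res$objective_trace
  expect_lte(tr[length(tr)], tr[1])
  expect_equal(res$iterations_run + 1L, length(tr))
})

test_that("overwhelming regularization collapses the total variation", {
  ph <- generate_slice(phantom_config(image_size = 64), 3)
  sino <- radon_project(ph, full_rotation_angles(40))
  ref <- fbp(sino)
  res <- twist_reconstruct(sino, twist_config(tau = 4, tv_inner_iters = 600L,
                                              max_iters = 200L, rel_tol = 1e-7))
  expect_lt(tv_norm(res$image), 0.01 * tv_norm(ref))
})

test_that("TwIST beats undersampled FBP on a sparse phantom", {
  ph <- generate_slice(phantom_config(), 17)
  sino <- radon_project(ph, full_rotation_angles(400))
  gt <- fbp(sino, filter_spec("hann", 0.4))
  sub <- apply_scheme(sino, subsample_indices(400, 32))
  p_fbp <- psnr(fbp(sub), gt)
  p_cs <- psnr(twist_reconstruct(sub)$image, gt)
  expect_gt(p_cs, p_fbp + 2)
})

test_that("twist configuration is validated", {
  expect_error(twist_config(tau = -1), "tau")
  expect_error(twist_config(max_iters = 0), "max_iters")
})
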