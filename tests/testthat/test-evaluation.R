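test_that("PSNR matches its closed form and the direct-summation oracle", {
  # I_MAX = 1, MSE = 0.01 -> 20 dB
  ref <- matrix(c(1, 0, 0, 0), 2)
  est <- ref + 0.1
  expect_equal(psnr(est, ref), 20)
  # scale invariance of the squared-peak form
  set.seed(40)
  a <- matrix(runif(64), 8); b <- matrix(runif(64), 8)
  expect_equal(psnr(3.7 * a, 3.7 * b), psnr(a, b), tolerance = 1e-12)
  # brute-force oracle agreement
  for (k in 1:5)
    expect_equal(psnr(a + k * 0.01 * b, b), psnr_oracle(a + k * 0.01 * b, b),
                 tolerance = 1e-9)
  expect_error(psnr(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("identical images give the infinite-PSNR sentinel, kept out of averages", {
  x <- matrix(runif(16), 4)
  expect_identical(psnr(x, x), Inf)
  r <- optrecon:::new_psnr_report("FBP", 10L, c(20, Inf, 22))
  expect_equal(r$mean_psnr, 21)
  expect_equal(r$n_infinite, 1L)
  expect_equal(r$n_slices, 2L)
  expect_true(r$mean_psnr >= min(20, 22) && r$mean_psnr <= 22)
  expect_equal(r$standard_error, sd(c(20, 22)) / sqrt(2))
})

test_that("the benchmark harness scores every slice for every method and N", {
  pc <- phantom_config(image_size = 48, n_blobs_range = c(2L, 4L),
                       blob_radius_range = c(1.5, 4), n_tubes_range = c(0L, 0L))
  vol <- generate_volume(pc, 3, seed = 2)
  bench <- benchmark_methods(vol, P = 48, N_list = c(16L, 8L),
                             methods = c("FBP", "CS"),
                             twist = twist_config(max_iters = 20L))
  expect_s3_class(bench, "psnr_benchmark")
  expect_length(bench, 4L)
  for (r in unclass(bench)) expect_length(r$per_slice_psnr, 3L)
  df <- as.data.frame(bench)
  expect_identical(nrow(df), 4L)
  expect_identical(sort(unique(df$N)), c(8L, 16L))

  # N = P with the ground-truth filter reproduces the ground truth exactly:
  # every slice hits the sentinel
  ident <- benchmark_methods(vol, P = 48, N_list = 48L, methods = "FBP",
                             filter_input = filter_spec("hann", 0.4))
  expect_true(all(is.infinite(ident[[1]]$per_slice_psnr)))

  # a CNN request without a model for some N is a configuration error
  expect_error(benchmark_methods(vol, P = 48, N_list = 16L, methods = "CNN",
                                 models = list()), "N = 16")
})

test_that("benchmark reports serialize to CSV and reload losslessly", {
  r1 <- optrecon:::new_psnr_report("FBP", 16L, c(18.5, 20.25, 19))
  r2 <- optrecon:::new_psnr_report("CS", 16L, c(24, 25.5, 23.125))
  bench <- structure(list(FBP_16 = r1, CS_16 = r2), class = "psnr_benchmark")
  f <- tempfile(fileext = ".csv"); fl <- tempfile(fileext = ".csv")
  write_benchmark_csv(bench, f, fl)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back, as.data.frame(bench), ignore_attr = TRUE)
  long <- read.csv(fl)
  expect_equal(nrow(long), 6L)
  expect_equal(long$psnr[long$method == "CS"], r2$per_slice_psnr)
})
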