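test_that("channel bookkeeping follows the doubling and quartering rules", {
  plan <- unet_channel_plan(unet_spec(4, 64))
  expect_identical(plan$contracting, c(64L, 128L, 256L, 512L))
  expect_identical(plan$concat, c(1024L, 512L, 256L, 128L))
  expect_identical(plan$expanding, c(256L, 128L, 64L, 32L))
  plan8 <- unet_channel_plan(unet_spec(4, 8))
  expect_identical(plan8$contracting, c(8L, 16L, 32L, 64L))
  # property: for any base, expanding outputs are a quarter of the
  # concatenation and half a conventional U-net's widths
  for (base in c(4L, 8L, 16L, 64L)) {
    p <- unet_channel_plan(unet_spec(4, base))
    expect_identical(p$expanding * 4L, p$concat)
    expect_identical(p$expanding, rev(c(base %/% 2L, base, 2L * base, 4L * base)))
  }
  expect_error(unet_spec(4, 6), "multiple of 4")
})

test_that("the built network preserves spatial shape", {
  model <- build_unet(unet_spec(2, 4), seed = 1)
  x <- array(rnorm(24 * 24 * 2), dim = c(24, 24, 1, 2))
  out <- optrecon:::unet_forward(model, x, training = FALSE)$out
  expect_identical(dim(out), c(24L, 24L, 1L, 2L))
  expect_error(optrecon:::unet_forward(model, array(0, c(10, 10, 1, 1))),
               "multiples")
})

test_that("backpropagation matches numerical gradients", {
  set.seed(42)
  model <- build_unet(unet_spec(2, 4), seed = 7)
  x <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 1, 2))
  y <- array(rnorm(16 * 16 * 2), dim = c(16, 16, 1, 2))
  loss_of <- function(m) {
    out <- optrecon:::unet_forward(m, x, training = TRUE)$out
    mean(abs(out - y))
  }
  fw <- optrecon:::unet_forward(model, x, training = TRUE)
  dout <- sign(fw$out - y) / length(fw$out)
  gr <- optrecon:::unet_backward(model, fw$cache, dout)
  eps <- 1e-6
  for (probe in list(c("enc1a", "w"), c("dec2b", "gamma"), c("head", "w"))) {
    p <- model$params[[probe[1]]][[probe[2]]]
    ks <- sample(length(p), min(3, length(p)))
    for (k in ks) {
      m2 <- model
      m2$params[[probe[1]]][[probe[2]]][k] <- p[k] + eps
      up <- loss_of(m2)
      m2$params[[probe[1]]][[probe[2]]][k] <- p[k] - eps
      num <- (up - loss_of(m2)) / (2 * eps)
      expect_equal(gr[[probe[1]]][[probe[2]]][k], num, tolerance = 1e-4,
                   info = paste(probe[1], probe[2], k))
    }
  }
})

test_that("a zeroed network outputs the input's mean through the affine contract", {
  model <- build_unet(unet_spec(4, 8), seed = 1)
  model$params <- rapply(model$params, function(x) x * 0, how = "replace")
  I0 <- matrix(rnorm(64 * 64, mean = 3, sd = 2), 64)
  out <- cnn_reconstruct(model, I0)
  expect_equal(out, matrix(mean(I0), 64, 64), tolerance = 1e-9)
})

test_that("odd input sizes are reflect-padded and cropped back", {
  model <- build_unet(unet_spec(4, 8), seed = 2)
  I0 <- matrix(rnorm(130 * 130), 130)
  out <- cnn_reconstruct(model, I0)
  expect_identical(dim(out), c(130L, 130L))
  # depth-4 padding arithmetic: 130 -> 144
  expect_identical(16L * as.integer(ceiling(130 / 16)), 144L)
  expect_error(cnn_reconstruct(model, matrix(5, 32, 32)), "variance")
})
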