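#' Reconstruction filter specification
#'
#' The ramp (`|f|`) filter of filtered back projection, optionally apodized
#' by a Hann window. `frequency_scale` compresses the filter's support: with
#' scale `s` the response is identically zero above `s` times the Nyquist
#' frequency and the Hann lobe is rescaled to span `[0, s * Nyquist]`. Fully
#' sampled ground-truth reconstructions in this package use the Hann window
#' at scale 0.4; plain ramp (scale 1) is the default for undersampled inputs.
#'
#' @param window `"none"` (pure ramp) or `"hann"`.
#' @param frequency_scale Fraction of Nyquist in (0, 1].
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(window = c("none", "hann"), frequency_scale = 1) {
  window <- match.arg(window)
  assert_scalar_num(frequency_scale, "frequency_scale", lower = 1e-6, upper = 1)
  structure(list(base = "ramp", window = window,
                 frequency_scale = frequency_scale),
            class = "filter_spec")
}

#' Frequency response of a reconstruction filter
#'
#' @param spec A [filter_spec()].
#' @param n Filter length (number of FFT samples, >= 2).
#' @return Nonnegative numeric vector of length `n`, ordered like R's FFT
#'   frequencies (`0, 1/n, ..., -1/n` cycles/sample); the response at
#'   frequency `f` is `|f|` times the window, zero above
#'   `frequency_scale * Nyquist`.
#' @export
build_filter <- function(spec, n) {
  stopifnot(inherits(spec, "filter_spec"))
  assert_scalar_num(n, "n", lower = 2)
  n <- as.integer(n)
  f <- fft_freq(n) # cycles/sample, |f| <= 0.5
  cutoff <- spec$frequency_scale * 0.5
  resp <- abs(f)
  if (spec$window == "hann")
    resp <- resp * 0.5 * (1 + cos(pi * abs(f) / cutoff))
  resp[abs(f) > cutoff] <- 0
  resp
}

#' Filtered back projection
#'
#' Each projection is filtered in the frequency domain (zero-padded to at
#' least four times the detector length, which keeps the discrete ramp
#' accurate at low frequencies) and smeared back across the image by the
#' interpolating backprojector, with the `pi / n_angles` normalization
#' appropriate for equally spaced angles; a full 360-degree acquisition is
#' handled by the same normalization since opposing views each contribute
#' half weight. The operation is linear in the sinogram.
#'
#' @param sino A [sinogram()].
#' @param spec A [filter_spec()] (default: pure ramp).
#' @param output_size Side length of the reconstructed image
#'   (default and maximum: `detector_count`).
#' @return `output_size` x `output_size` numeric matrix.
#' @examples
#' disk <- matrix(0, 64, 64)
#' disk[(row(disk) - 32.5)^2 + (col(disk) - 32.5)^2 < 15^2] <- 1
#' rec <- fbp(radon_project(disk, full_rotation_angles(128)))
#' @export
fbp <- function(sino, spec = filter_spec(), output_size = sino$detector_count) {
  stopifnot(inherits(sino, "sinogram"), inherits(spec, "filter_spec"))
  if (length(sino$angles_deg) == 0L || length(sino$data) == 0L)
    stop("empty sinogram", call. = FALSE)
  det <- sino$detector_count
  assert_scalar_num(output_size, "output_size", lower = 1, upper = det)
  pad <- max(64L, next_pow2(4L * det))
  resp <- build_filter(spec, pad)
  P <- rbind(sino$data, matrix(0, pad - det, ncol(sino$data)))
  Q <- Re(mvfft(mvfft(P) * resp, inverse = TRUE)) / pad
  Q <- Q[seq_len(det), , drop = FALSE]
  recon <- cpp_backproject(Q, sino$angles_deg * pi / 180, det) *
    (pi / length(sino$angles_deg))
  crop_center(recon, as.integer(output_size))
}

crop_center <- function(x, size) {
  H <- nrow(x)
  if (size == H) return(x)
  off <- (H - size) %/% 2L
  x[off + seq_len(size), off + seq_len(size), drop = FALSE]
}
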