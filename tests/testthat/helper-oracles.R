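# Independent oracles, written against the definitions rather than the
# package implementation.

# Brute-force ray-marching line integrals: for every detector bin, march
# along the ray in small steps, bilinearly interpolating the image (zero
# outside). Deliberately slow and simple.
radon_oracle <- function(img, angles_deg, step = 0.25) {
  H <- nrow(img)
  c0 <- (H - 1) / 2
  out <- matrix(0, H, length(angles_deg))
  # bilinear interpolation at (col, row) coordinate vectors, 0-based, zero
  # outside the grid
  bilin <- function(x, y) {
    v <- numeric(length(x))
    ok <- x >= 0 & x <= H - 1 & y >= 0 & y <= H - 1
    if (!any(ok)) return(v)
    x <- x[ok]; y <- y[ok]
    j0 <- floor(x); i0 <- floor(y)
    dj <- x - j0; di <- y - i0
    j1 <- pmin(j0 + 1, H - 1); i1 <- pmin(i0 + 1, H - 1)
    at <- function(i, j) img[cbind(i + 1, j + 1)]
    v[ok] <- (1 - di) * (1 - dj) * at(i0, j0) + di * (1 - dj) * at(i1, j0) +
      (1 - di) * dj * at(i0, j1) + di * dj * at(i1, j1)
    v
  }
  ss <- seq(-H, H, by = step)
  for (a in seq_along(angles_deg)) {
    th <- angles_deg[a] * pi / 180
    co <- cos(th); si <- sin(th)
    for (b in seq_len(H)) {
      t <- (b - 1) - c0
      out[b, a] <- sum(bilin(c0 + t * co - ss * si, c0 + t * si + ss * co)) * step
    }
  }
  out
}

# Direct-summation PSNR, loops and all.
psnr_oracle <- function(estimate, reference) {
  imax <- -Inf
  for (v in reference) if (v > imax) imax <- v
  sse <- 0
  for (k in seq_along(reference)) sse <- sse + (estimate[k] - reference[k])^2
  10 * log10(imax^2 / (sse / length(reference)))
}

# A small random nonnegative image with an empty border (signal inside the
# inscribed circle), for projector comparisons.
random_supported_image <- function(H, border = 3L) {
  img <- matrix(runif(H * H), H)
  img[c(seq_len(border), (H - border + 1):H), ] <- 0
  img[, c(seq_len(border), (H - border + 1):H)] <- 0
  img
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# Tiny, fast phantom/training fixtures shared by the unet tests.
tiny_pairs <- function(n = 12L, size = 32L, P = 32L, N = 8L, seed = 99L) {
  pc <- phantom_config(image_size = size, n_blobs_range = c(2L, 4L),
                       blob_radius_range = c(1.5, 4), n_tubes_range = c(0L, 1L))
  slices <- generate_volume(pc, n, seed = seed)
  seeds <- seq_len(n) + 1000L
  lapply(seq_len(n), function(i)
    make_training_pair(slices[[i]], P, N, seed = seeds[i]))
}
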