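#' Construct a sinogram object
#'
#' A sinogram is the (detector bin x rotation angle) matrix of line integrals
#' of one slice, the measured quantity of the parallel-beam forward model
#' `Y = R X + n`.
#'
#' @param data Numeric matrix, `detector_count` rows x `n_angles` columns.
#' @param angles_deg Acquisition angles in degrees, strictly increasing,
#'   in `[0, 360)`.
#' @return An object of class `sinogram` with fields `data`, `angles_deg`,
#'   `detector_count`.
#' @export
sinogram <- function(data, angles_deg) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix", call. = FALSE)
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) != ncol(data))
    stop("number of sinogram columns must equal length(angles_deg)",
         call. = FALSE)
  if (length(angles_deg) == 0L) stop("empty angle list", call. = FALSE)
  if (any(angles_deg < 0 | angles_deg >= 360))
    stop("angles must lie in [0, 360)", call. = FALSE)
  if (length(angles_deg) > 1L && any(diff(angles_deg) <= 0))
    stop("angles must be strictly increasing within one revolution",
         call. = FALSE)
  structure(list(data = data, angles_deg = angles_deg,
                 detector_count = nrow(data)),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d detector bins x %d angles [%.2f..%.2f deg]\n",
              x$detector_count, length(x$angles_deg),
              min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

#' Equally spaced acquisition angles over a full rotation
#'
#' @param n_angles Number of projections.
#' @return Numeric vector `(0, 360/n, ..., 360(n-1)/n)` degrees.
#' @export
full_rotation_angles <- function(n_angles) {
  assert_scalar_num(n_angles, "n_angles", lower = 1)
  (seq_len(n_angles) - 1) * 360 / n_angles
}

#' Parallel-beam Radon transform of a slice
#'
#' Computes line integrals of the image along rays perpendicular to the
#' detector at each requested angle (pixel-driven, linear splatting onto
#' detector bins). The detector has as many bins as the image side length and
#' the rotation axis sits at the pixel center `((H-1)/2, (W-1)/2)`; angles
#' are measured counterclockwise from the image x axis.
#'
#' @param slice Square nonnegative numeric matrix. Signal should lie inside
#'   the inscribed circle (a warning is emitted otherwise: mass outside the
#'   circle leaves the detector at some angles).
#' @param angles_deg Projection angles in degrees in `[0, 360)`.
#' @return A [sinogram()].
#' @export
radon_project <- function(slice, angles_deg) {
  if (!is_square_matrix(slice)) stop("`slice` must be a square matrix", call. = FALSE)
  if (length(angles_deg) == 0L) stop("empty angle list", call. = FALSE)
  if (any(slice < 0)) warning("negative intensities in slice")
  H <- nrow(slice)
  c0 <- (H - 1) / 2
  rr <- outer(((seq_len(H) - 1) - c0)^2, ((seq_len(H) - 1) - c0)^2, "+")
  if (any(slice[rr > (H / 2)^2] != 0))
    warning("signal outside the inscribed circle; projections will be truncated")
  data <- cpp_radon(slice, as.numeric(angles_deg) * pi / 180)
  sinogram(data, angles_deg)
}

#' Adjoint of the Radon transform (unfiltered backprojection)
#'
#' The exact matrix adjoint of [radon_project()]: smears each projection back
#' across the image with the same interpolation weights used by the forward
#' model. This is the `R^T` operator used inside the iterative TV solver; it
#' is not a reconstruction by itself (see [fbp()]).
#'
#' @param sino A [sinogram()].
#' @param size Output image side length (defaults to `detector_count`).
#' @return A `size` x `size` matrix.
#' @export
back_project <- function(sino, size = sino$detector_count) {
  stopifnot(inherits(sino, "sinogram"))
  cpp_backproject(sino$data, sino$angles_deg * pi / 180, as.integer(size))
}

#' Additive Gaussian measurement-noise model
#'
#' @param sigma Standard deviation, in the sinogram's units (>= 0).
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma, seed = 1L) {
  assert_scalar_num(sigma, "sigma", lower = 0)
  structure(list(kind = "gaussian", sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

#' Add measurement noise to a sinogram
#'
#' @param sino A [sinogram()].
#' @param noise A [noise_model()].
#' @return A [sinogram()] with element-wise Gaussian perturbation;
#'   deterministic given the model's seed.
#' @export
add_noise <- function(sino, noise) {
  stopifnot(inherits(sino, "sinogram"), inherits(noise, "noise_model"))
  if (noise$sigma == 0) return(sino)
  eps <- with_seed(noise$seed,
                   matrix(rnorm(length(sino$data), 0, noise$sigma),
                          nrow(sino$data)))
  sinogram(sino$data + eps, sino$angles_deg)
}

#' Equally spaced angular subsampling scheme
#'
#' Selects `N` of `P` acquired projections "as equally as the subsampling
#' allows": the k-th retained 1-based index is `round_half_up(k * P / N) + 1`
#' for `k = 0, ..., N-1`. Subsampling 400 projections to 64 retains the 1st,
#' 7th, 14th, 20th, 26th, ... projections.
#'
#' @param P Total number of acquired projections.
#' @param N Number to retain, `1 <= N <= P`.
#' @return An object of class `angular_scheme` with fields
#'   `total_projections`, `retained`, `indices`.
#' @examples
#' subsample_indices(400, 64)$indices[1:5]
#' @export
subsample_indices <- function(P, N) {
  assert_scalar_num(P, "P", lower = 1)
  assert_scalar_num(N, "N", lower = 1)
  P <- as.integer(P); N <- as.integer(N)
  if (N > P) stop("cannot retain more projections than acquired (N > P)",
                  call. = FALSE)
  k <- 0:(N - 1)
  idx <- as.integer(floor(k * P / N + 0.5)) + 1L # round half up
  structure(list(total_projections = P, retained = N, indices = idx),
            class = "angular_scheme")
}

#' Restrict a sinogram to the retained projections of a scheme
#'
#' @param sino A [sinogram()] with `scheme$total_projections` columns.
#' @param scheme An [subsample_indices()] scheme.
#' @return The subsampled [sinogram()].
#' @export
apply_scheme <- function(sino, scheme) {
  stopifnot(inherits(sino, "sinogram"), inherits(scheme, "angular_scheme"))
  if (ncol(sino$data) != scheme$total_projections)
    stop(sprintf("sinogram has %d columns but scheme expects %d",
                 ncol(sino$data), scheme$total_projections), call. = FALSE)
  sinogram(sino$data[, scheme$indices, drop = FALSE],
           sino$angles_deg[scheme$indices])
}

#' Relabel a random start angle (training-data augmentation)
#'
#' Circularly shifts the columns of a full-revolution sinogram by `offset`
#' projections and relabels the angles to start at 0 degrees, emulating an
#' acquisition that started at a different rotary position. Reconstructing
#' the shifted sinogram yields the in-plane rotation of the original
#' reconstruction.
#'
#' @param sino A [sinogram()] covering a full 360 degree revolution at equal
#'   spacing (the circular shift is only meaningful then).
#' @param offset Integer number of projections to shift by.
#' @return The shifted [sinogram()] (angle grid unchanged).
#' @export
shift_start_angle <- function(sino, offset) {
  stopifnot(inherits(sino, "sinogram"))
  n <- length(sino$angles_deg)
  d <- diff(sino$angles_deg)
  full <- n > 1 && max(abs(d - d[1])) < 1e-9 &&
    abs((sino$angles_deg[n] + d[1]) - (sino$angles_deg[1] + 360)) < 1e-6
  if (!full)
    stop("start-angle shift requires an equally spaced full-revolution sinogram",
         call. = FALSE)
  offset <- as.integer(offset) %% n
  if (offset == 0L) return(sino)
  perm <- c((offset + 1L):n, 1L:offset)
  sinogram(sino$data[, perm, drop = FALSE], sino$angles_deg)
}
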