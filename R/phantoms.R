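#' Configuration for synthetic sparse-fluorescence phantoms
#'
#' Describes the statistical structure of the synthetic slices used throughout
#' the package: a small number of bright, compact "islet-like" blobs and
#' curvilinear "vessel-like" tubes on a near-zero background, with all signal
#' confined to the inscribed circle of the image (a rotating sample never
#' carries signal outside the field of view swept by the rotation).
#'
#' @param image_size Side length in pixels of the square slice (H = W).
#' @param n_blobs_range Integer interval `c(min, max)` for the number of
#'   Gaussian blobs per scene.
#' @param blob_radius_range Interval in pixels for blob radii; the rendered
#'   profile is `exp(-r^2 / (2 * (radius/2)^2))`, truncated at `3 * radius`.
#' @param n_tubes_range Integer interval for the number of curvilinear tubes.
#' @param tube_width_range Interval in pixels for tube widths (full width of
#'   the Gaussian cross-section).
#' @param intensity_range Interval of peak intensities, arbitrary
#'   fluorescence units.
#' @param background_level Background as a fraction of `max(intensity_range)`.
#' @param slice_correlation Number in \[0, 1\]: how much consecutive slices of
#'   a volume share structure. 1 repeats the same scene; 0 draws independent
#'   scenes; intermediate values perturb blob/tube parameters with noise of
#'   magnitude `1 - slice_correlation`.
#' @param support_margin Pixels kept empty between the signal support and the
#'   inscribed circle (default 10\% of `image_size`).
#' @param allow_overlap If `FALSE`, blob placement is rejection-sampled so
#'   that blob supports are well separated (used e.g. to count structures).
#'
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L,
                           n_blobs_range = c(3L, 12L),
                           blob_radius_range = c(2, 8),
                           n_tubes_range = c(0L, 4L),
                           tube_width_range = c(1, 3),
                           intensity_range = c(0.3, 1.0),
                           background_level = 0,
                           slice_correlation = 0.8,
                           support_margin = NULL,
                           allow_overlap = TRUE) {
  assert_scalar_num(image_size, "image_size", lower = 8)
  if (is.null(support_margin)) support_margin <- round(0.1 * image_size)
  assert_scalar_num(support_margin, "support_margin", lower = 0,
                    upper = image_size / 2)
  assert_scalar_num(background_level, "background_level", lower = 0, upper = 1)
  assert_scalar_num(slice_correlation, "slice_correlation", lower = 0, upper = 1)
  check_range <- function(r, name, lower = 0) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] || r[1] < lower)
      stop(sprintf("`%s` must be a non-empty interval c(min, max) with min >= %g",
                   name, lower), call. = FALSE)
  }
  check_range(n_blobs_range, "n_blobs_range")
  check_range(blob_radius_range, "blob_radius_range", lower = 0.5)
  check_range(n_tubes_range, "n_tubes_range")
  check_range(tube_width_range, "tube_width_range", lower = 0.5)
  check_range(intensity_range, "intensity_range")
  structure(list(
    image_size = as.integer(image_size),
    n_blobs_range = as.integer(round(n_blobs_range)),
    blob_radius_range = as.numeric(blob_radius_range),
    n_tubes_range = as.integer(round(n_tubes_range)),
    tube_width_range = as.numeric(tube_width_range),
    intensity_range = as.numeric(intensity_range),
    background_level = background_level,
    slice_correlation = slice_correlation,
    support_margin = as.numeric(support_margin),
    allow_overlap = isTRUE(allow_overlap)
  ), class = "phantom_config")
}

# Radius of the disk that may carry signal.
allowed_radius <- function(config) {
  config$image_size / 2 - config$support_margin
}

# Draw one scene description (blobs + tubes) from the config. Rendering is
# separate so that correlated neighboring slices can perturb a scene instead
# of resampling it.
sample_scene <- function(config) {
  R <- allowed_radius(config)
  nb <- sample_int_range(config$n_blobs_range)
  blobs <- NULL
  if (nb > 0) {
    radius <- runif(nb, config$blob_radius_range[1], config$blob_radius_range[2])
    xy <- matrix(NA_real_, nb, 2)
    for (b in seq_len(nb)) {
      for (try in 1:200) {
        cand <- random_point_in_disk(R - 3 * radius[b])
        ok <- TRUE
        if (!config$allow_overlap && b > 1) {
          d <- sqrt(colSums((t(xy[seq_len(b - 1), , drop = FALSE]) - cand)^2))
          ok <- all(d > 1.5 * (radius[seq_len(b - 1)] + radius[b]))
        }
        if (ok) { xy[b, ] <- cand; break }
      }
      if (anyNA(xy[b, ]))
        stop("could not place non-overlapping blobs; reduce count or radii",
             call. = FALSE)
    }
    blobs <- data.frame(x = xy[, 1], y = xy[, 2], radius = radius,
                        intensity = runif(nb, config$intensity_range[1],
                                          config$intensity_range[2]))
  }
  nt <- sample_int_range(config$n_tubes_range)
  tubes <- vector("list", nt)
  for (t in seq_len(nt)) {
    width <- runif(1, config$tube_width_range[1], config$tube_width_range[2])
    tubes[[t]] <- list(
      path = random_walk_path(R - 3 * width,
                              n_steps = sample(config$image_size %/% 4, 1) +
                                config$image_size %/% 4),
      width = width,
      intensity = runif(1, config$intensity_range[1], config$intensity_range[2]))
  }
  list(blobs = blobs, tubes = tubes)
}

sample_int_range <- function(r) {
  if (r[1] == r[2]) return(r[1])
  r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
}

random_point_in_disk <- function(R) {
  if (R <= 0) return(c(0, 0))
  repeat {
    p <- runif(2, -R, R)
    if (sum(p^2) <= R^2) return(p)
  }
}

# Smoothed random walk confined to a disk of radius R (coordinates relative
# to the image center), unit steps with angular diffusion.
random_walk_path <- function(R, n_steps) {
  R <- max(R, 1)
  pos <- random_point_in_disk(0.8 * R)
  ang <- runif(1, 0, 2 * pi)
  path <- matrix(NA_real_, n_steps, 2)
  for (s in seq_len(n_steps)) {
    ang <- ang + rnorm(1, 0, 0.25)
    cand <- pos + c(cos(ang), sin(ang))
    if (sum(cand^2) > R^2) { # turn back toward the center
      ang <- atan2(-pos[2], -pos[1]) + rnorm(1, 0, 0.25)
      cand <- pos + c(cos(ang), sin(ang))
    }
    pos <- cand
    path[s, ] <- pos
  }
  path
}

# Perturb a scene for the next slice of a correlated volume. `amount` in
# [0, 1]: 0 keeps the scene identical, larger values drift blob centers and
# tube positions and jitter radii/intensities.
perturb_scene <- function(scene, config, amount) {
  if (amount <= 0) return(scene)
  R <- allowed_radius(config)
  drift <- amount * config$image_size / 8
  if (!is.null(scene$blobs) && nrow(scene$blobs) > 0) {
    b <- scene$blobs
    b$x <- b$x + rnorm(nrow(b), 0, drift)
    b$y <- b$y + rnorm(nrow(b), 0, drift)
    b$radius <- pmin(pmax(b$radius * exp(rnorm(nrow(b), 0, 0.2 * amount)),
                          config$blob_radius_range[1]),
                     config$blob_radius_range[2])
    b$intensity <- pmin(pmax(b$intensity * exp(rnorm(nrow(b), 0, 0.2 * amount)),
                             config$intensity_range[1]),
                        config$intensity_range[2])
    # keep the (truncated) support inside the allowed disk
    for (i in seq_len(nrow(b))) {
      rmax <- R - 3 * b$radius[i]
      d <- sqrt(b$x[i]^2 + b$y[i]^2)
      if (d > rmax && d > 0) {
        b$x[i] <- b$x[i] * rmax / d
        b$y[i] <- b$y[i] * rmax / d
      }
    }
    scene$blobs <- b
  }
  for (t in seq_along(scene$tubes)) {
    tube <- scene$tubes[[t]]
    shift <- rnorm(2, 0, drift)
    path <- sweep(tube$path, 2, -shift)
    rmax <- R - 3 * tube$width
    d <- sqrt(rowSums(path^2))
    over <- d > rmax
    if (any(over)) path[over, ] <- path[over, ] * (rmax / d[over])
    tube$path <- path
    scene$tubes[[t]] <- tube
  }
  scene
}

# Rasterize a scene on the pixel grid. Structures are combined with a
# pointwise maximum so intensities never exceed max(intensity_range).
render_scene <- function(scene, config) {
  H <- config$image_size
  c0 <- (H - 1) / 2
  img <- matrix(0, H, H)
  xs <- (seq_len(H) - 1) - c0 # column coordinate
  ys <- (seq_len(H) - 1) - c0 # row coordinate
  if (!is.null(scene$blobs)) {
    for (i in seq_len(nrow(scene$blobs))) {
      b <- scene$blobs[i, ]
      sigma <- b$radius / 2
      cut <- 3 * b$radius
      jr <- which(abs(xs - b$x) <= cut)
      ir <- which(abs(ys - b$y) <= cut)
      if (!length(ir) || !length(jr)) next
      d2 <- outer((ys[ir] - b$y)^2, (xs[jr] - b$x)^2, "+")
      bump <- b$intensity * exp(-d2 / (2 * sigma^2))
      bump[d2 > cut^2] <- 0
      img[ir, jr] <- pmax(img[ir, jr], bump)
    }
  }
  for (tube in scene$tubes) {
    sigma <- tube$width / 2
    cut <- ceiling(3 * tube$width)
    for (s in seq_len(nrow(tube$path))) {
      px <- tube$path[s, 1]; py <- tube$path[s, 2]
      jr <- which(abs(xs - px) <= cut)
      ir <- which(abs(ys - py) <= cut)
      if (!length(ir) || !length(jr)) next
      d2 <- outer((ys[ir] - py)^2, (xs[jr] - px)^2, "+")
      img[ir, jr] <- pmax(img[ir, jr], tube$intensity * exp(-d2 / (2 * sigma^2)))
    }
  }
  if (config$background_level > 0)
    img <- pmax(img, config$background_level * max(config$intensity_range))
  # hard guarantee of the support invariant
  rr <- outer(ys^2, xs^2, "+")
  img[rr > allowed_radius(config)^2] <- 0
  img
}

#' Uniform disk test image
#'
#' A centered uniform disk with an anti-aliased (pixel coverage) rim: pixel
#' values ramp linearly from 1 to 0 across one pixel at the boundary, the
#' correct discretization of a continuous uniform disk. Used as the standard
#' deterministic test object for projector and FBP fidelity checks.
#'
#' @param image_size Side length in pixels.
#' @param radius Disk radius in pixels (default 25\% of the side length).
#' @param intensity Plateau intensity.
#' @return An `image_size` x `image_size` matrix.
#' @export
disk_phantom <- function(image_size = 128L, radius = 0.25 * image_size,
                         intensity = 1) {
  H <- as.integer(image_size)
  c0 <- (H - 1) / 2
  rr <- sqrt(outer(((seq_len(H) - 1) - c0)^2, ((seq_len(H) - 1) - c0)^2, "+"))
  intensity * pmin(pmax(radius + 0.5 - rr, 0), 1)
}

#' Generate one synthetic sparse-fluorescence slice
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; the same (config, seed) pair always yields a
#'   bit-identical image.
#' @return An `image_size` x `image_size` nonnegative matrix.
#' @examples
#' img <- generate_slice(phantom_config(image_size = 64), seed = 1)
#' range(img)
#' @export
generate_slice <- function(config, seed) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, render_scene(sample_scene(config), config))
}

#' Generate a stack of correlated phantom slices
#'
#' Consecutive slices share structure: the scene of slice *s + 1* is a
#' perturbation of the scene of slice *s*, with perturbation magnitude
#' `1 - slice_correlation`. At `slice_correlation = 0` every slice is an
#' independent draw; at 1 all slices are identical.
#'
#' @inheritParams generate_slice
#' @param n_slices Number of slices (>= 1).
#' @return A list of `n_slices` matrices, in slice order.
#' @export
generate_volume <- function(config, n_slices, seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.numeric(n_slices) || length(n_slices) != 1L || n_slices < 1)
    stop("`n_slices` must be >= 1", call. = FALSE)
  n_slices <- as.integer(n_slices)
  amount <- 1 - config$slice_correlation
  with_seed(seed, {
    out <- vector("list", n_slices)
    scene <- sample_scene(config)
    out[[1L]] <- render_scene(scene, config)
    for (s in seq_len(n_slices - 1L)) {
      scene <- if (config$slice_correlation == 0) sample_scene(config)
               else perturb_scene(scene, config, amount)
      out[[s + 1L]] <- render_scene(scene, config)
    }
    out
  })
}
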