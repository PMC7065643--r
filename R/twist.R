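#' Isotropic discrete total variation
#'
#' Sum over pixels of `sqrt(dx^2 + dy^2)` with forward differences and
#' replicate boundary (the difference is taken as zero at the last
#' row/column). Small for piecewise-constant images, which is what makes it
#' an effective streak-suppressing regularizer for sparse samples.
#'
#' @param x Numeric matrix.
#' @return Nonnegative scalar.
#' @export
tv_norm <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix",
                                            call. = FALSE)
  cpp_tv_norm(x)
}

#' Configuration of the TwIST compressed-sensing solver
#'
#' Controls the two-step iterative shrinkage/thresholding solver for
#' `min_X 1/2 ||Y' - R' X||^2 + tau * TV(X)`, where `R'` and `Y'` are the
#' projector and sinogram rescaled so the operator has unit spectral norm
#' (the regularization weight is always quoted in this normalized convention,
#' with the default `tau = 0.004` used for all reconstructions).
#'
#' @param tau Regularization weight (>= 0), default 0.004.
#' @param max_iters Maximum number of iterations (default 200).
#' @param rel_tol Stop when the relative objective change falls below this
#'   (default 1e-4).
#' @param tv_inner_iters Dual (Chambolle) iterations of the TV proximal
#'   subsolver per outer step (default 10).
#' @param monotone Force a non-increasing objective by falling back to a
#'   (damped) IST step whenever the two-step update would increase it
#'   (default TRUE).
#' @param nonnegativity Clip iterates at zero (fluorescence is nonnegative;
#'   default TRUE).
#' @param lam1 Assumed smallest eigenvalue of the normalized `R^T R`, the
#'   severely ill-conditioned default 1e-4; together with the assumed largest
#'   eigenvalue 1 it sets the two-step weights.
#' @return An object of class `twist_config`.
#' @export
twist_config <- function(tau = 0.004, max_iters = 200L, rel_tol = 1e-4,
                         tv_inner_iters = 10L, monotone = TRUE,
                         nonnegativity = TRUE, lam1 = 1e-4) {
  assert_scalar_num(tau, "tau", lower = 0)
  assert_scalar_num(max_iters, "max_iters", lower = 1)
  assert_scalar_num(rel_tol, "rel_tol", lower = 0)
  assert_scalar_num(tv_inner_iters, "tv_inner_iters", lower = 1)
  assert_scalar_num(lam1, "lam1", lower = 1e-12, upper = 1)
  structure(list(tau = tau, max_iters = as.integer(max_iters),
                 rel_tol = rel_tol, tv_inner_iters = as.integer(tv_inner_iters),
                 monotone = isTRUE(monotone),
                 nonnegativity = isTRUE(nonnegativity), lam1 = lam1),
            class = "twist_config")
}

# Spectral norm of the projector for a given geometry, by power iteration on
# R^T R (deterministic start). Cached per (size, angle-set) within a session.
projector_norm_env <- new.env(parent = emptyenv())
projector_spectral_norm <- function(size, angles_deg, iters = 15L) {
  key <- paste0(size, ":", paste0(signif(angles_deg, 10), collapse = ","))
  hit <- projector_norm_env[[digest_key(key)]]
  if (!is.null(hit)) return(hit)
  ang <- angles_deg * pi / 180
  v <- matrix(1, size, size)
  lam <- 1
  for (i in seq_len(iters)) {
    w <- cpp_backproject(cpp_radon(v, ang), ang, size)
    lam <- sqrt(sum(w^2)) / sqrt(sum(v^2))
    v <- w / sqrt(sum(w^2))
  }
  s <- sqrt(lam) # ||R||_2 = sqrt(lambda_max(R^T R))
  projector_norm_env[[digest_key(key)]] <- s
  s
}

digest_key <- function(key) {
  # environments cannot index on arbitrary-length strings efficiently; md5
  f <- tempfile(); on.exit(unlink(f))
  writeLines(key, f)
  unname(tools::md5sum(f))
}

#' Total-variation compressed-sensing reconstruction with TwIST
#'
#' Approximately minimizes `1/2 ||Y' - R' X||^2 + tau TV(X)` with the
#' two-step iterative shrinkage/thresholding algorithm: each step applies the
#' TV proximal operator to a gradient step, and the new iterate combines the
#' two previous iterates with weights `alpha`, `beta` derived from assumed
#' extreme eigenvalues of `R'^T R'`. The projector/backprojector pair is an
#' exact adjoint pair and the operator is rescaled to unit spectral norm;
#' initialization is the plain-ramp FBP reconstruction.
#'
#' @param sino A [sinogram()].
#' @param config A [twist_config()].
#' @param output_size Reconstruction side length (default `detector_count`).
#' @return An object of class `twist_result`: `image`, `objective_trace`
#'   (objective of the initial and of each accepted iterate), `iterations_run`,
#'   `converged`.
#' @export
twist_reconstruct <- function(sino, config = twist_config(),
                              output_size = sino$detector_count) {
  stopifnot(inherits(sino, "sinogram"), inherits(config, "twist_config"))
  size <- as.integer(output_size)
  angles_rad <- sino$angles_deg * pi / 180
  s <- projector_spectral_norm(size, sino$angles_deg)
  y <- sino$data / s
  obj <- function(x) {
    resid <- y - cpp_radon(x, angles_rad) / s
    0.5 * sum(resid^2) + config$tau * cpp_tv_norm(x)
  }
  prox <- function(u, lambda) {
    v <- if (lambda > 0) cpp_tv_prox(u, lambda, config$tv_inner_iters) else u
    if (config$nonnegativity) v[v < 0] <- 0
    v
  }
  grad_step <- function(x) {
    resid <- y - cpp_radon(x, angles_rad) / s
    x + cpp_backproject(resid, angles_rad, size) / s
  }
  # two-step weights from the assumed eigenvalue range [lam1, 1]
  rho0 <- (1 - config$lam1) / (1 + config$lam1)
  alpha <- 2 / (1 + sqrt(1 - rho0^2))
  beta <- alpha * 2 / (config$lam1 + 1)

  x_prev <- fbp(sino, filter_spec("none", 1), size)
  if (config$nonnegativity) x_prev[x_prev < 0] <- 0
  trace <- obj(x_prev)
  # first step: plain IST
  x <- prox(grad_step(x_prev), config$tau)
  f <- obj(x)
  if (config$monotone && f > trace[1]) { x <- x_prev; f <- trace[1] }
  trace <- c(trace, f)
  converged <- FALSE
  iters <- 1L
  stalls <- 0L
  while (iters < config$max_iters) {
    z <- prox(grad_step(x), config$tau)
    x_new <- (1 - alpha) * x_prev + (alpha - beta) * x + beta * z
    if (config$nonnegativity) x_new[x_new < 0] <- 0
    f_new <- obj(x_new)
    if (config$monotone && f_new > f) {
      # fall back to a damped IST step
      kappa <- 1
      repeat {
        x_new <- prox(x + kappa * (grad_step(x) - x), config$tau * kappa)
        f_new <- obj(x_new)
        if (f_new <= f || kappa < 1 / 32) break
        kappa <- kappa / 2
      }
      if (f_new > f) { # could not descend: keep iterate
        x_new <- x; f_new <- f; stalls <- stalls + 1L
      } else stalls <- 0L
    } else stalls <- 0L
    if (!config$monotone && f_new > 10 * trace[1])
      stop(structure(class = c("twist_divergence", "error", "condition"),
                     list(message = "TwIST objective exceeded 10x its initial value",
                          call = sys.call(-1), trace = c(trace, f_new))))
    x_prev <- x; x <- x_new
    rel <- abs(f - f_new) / max(abs(f), .Machine$double.eps)
    f <- f_new
    trace <- c(trace, f)
    iters <- iters + 1L
    if (rel < config$rel_tol || stalls >= 2L) { converged <- TRUE; break }
  }
  structure(list(image = x, objective_trace = trace, iterations_run = iters,
                 converged = converged),
            class = "twist_result")
}

#' @export
print.twist_result <- function(x, ...) {
  cat(sprintf("<twist_result> %d x %d image, %d iterations, %s, objective %.6g -> %.6g\n",
              nrow(x$image), ncol(x$image), x$iterations_run,
              if (x$converged) "converged" else "max iterations",
              x$objective_trace[1], x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}
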