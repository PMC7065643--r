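#' Peak signal-to-noise ratio
#'
#' `10 * log10(I_MAX^2 / MSE)` in dB, where `I_MAX` is the peak pixel value
#' of the reference and MSE the mean squared error between the two images.
#' The squared-peak form is used so the metric is invariant under joint
#' rescaling of both images.
#'
#' @param estimate Reconstruction to score.
#' @param reference Ground-truth image of the same shape.
#' @return PSNR in dB; `Inf` when the images are identical (MSE = 0). The
#'   infinite value is a sentinel: [benchmark_methods()] flags it and keeps
#'   it out of averages.
#' @export
psnr <- function(estimate, reference) {
  if (!identical(dim(estimate), dim(reference)))
    stop("`estimate` and `reference` must have identical shape", call. = FALSE)
  imax <- max(reference)
  mse <- mean((estimate - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(imax^2 / mse)
}

new_psnr_report <- function(method, N, per_slice) {
  finite <- per_slice[is.finite(per_slice)]
  structure(list(method = method, projection_count = as.integer(N),
                 per_slice_psnr = per_slice,
                 mean_psnr = mean(finite),
                 standard_error = if (length(finite) > 1)
                   stats::sd(finite) / sqrt(length(finite)) else 0,
                 n_slices = length(finite),
                 n_infinite = sum(is.infinite(per_slice))),
            class = "psnr_report")
}

#' @export
print.psnr_report <- function(x, ...) {
  cat(sprintf("<psnr_report> %s, N = %d: %.2f +/- %.2f dB (n = %d%s)\n",
              x$method, x$projection_count, x$mean_psnr, x$standard_error,
              x$n_slices,
              if (x$n_infinite) sprintf(", %d infinite excluded", x$n_infinite)
              else ""))
  invisible(x)
}

#' @export
as.data.frame.psnr_report <- function(x, ...) {
  data.frame(method = x$method, N = x$projection_count,
             mean_psnr = x$mean_psnr, standard_error = x$standard_error,
             n_slices = x$n_slices)
}

#' Benchmark FBP, compressed sensing and CNN reconstructions
#'
#' For every slice of `volume` and every undersampling level in `N_list`,
#' reconstructs the slice from an `N`-projection subsampled sinogram with the
#' requested methods and scores each result by [psnr()] against the ground
#' truth, defined as the FBP reconstruction of the full `P`-projection
#' sinogram with `filter_gt`. Slices whose ground truth is entirely
#' non-positive carry no usable peak value and are excluded (with a message).
#'
#' @param volume List of square slices (e.g. [generate_volume()]), or a list
#'   of precomputed full sinograms.
#' @param P Total number of simulated projections.
#' @param N_list Integer vector of retained projection counts.
#' @param methods Subset of `c("FBP", "CS", "CNN")`.
#' @param models Named list of trained models, one per `N` (names are the `N`
#'   values); required when `"CNN"` is requested.
#' @param filter_gt Ground-truth filter (default Hann at 0.4).
#' @param filter_input Filter for undersampled FBP (default pure ramp).
#' @param twist A [twist_config()] for the `"CS"` method.
#' @return A list of `psnr_report` objects, one per (method, N), with class
#'   `psnr_benchmark`.
#' @export
benchmark_methods <- function(volume, P, N_list,
                              methods = c("FBP", "CS", "CNN"),
                              models = list(),
                              filter_gt = filter_spec("hann", 0.4),
                              filter_input = filter_spec("none", 1),
                              twist = twist_config()) {
  methods <- match.arg(methods, several.ok = TRUE)
  if ("CNN" %in% methods) {
    missing_n <- setdiff(as.character(N_list), names(models))
    if (length(missing_n))
      stop("no trained model supplied for N = ",
           paste(missing_n, collapse = ", "), call. = FALSE)
  }
  sinos <- lapply(volume, function(s) {
    if (inherits(s, "sinogram")) s else radon_project(s, full_rotation_angles(P))
  })
  gts <- lapply(sinos, fbp, spec = filter_gt)
  usable <- vapply(gts, function(g) max(g) > 0, logical(1))
  if (any(!usable))
    message(sum(!usable), " slice(s) with non-positive ground truth excluded")
  sinos <- sinos[usable]; gts <- gts[usable]
  reports <- list()
  for (N in N_list) {
    scheme <- subsample_indices(P, N)
    subs <- lapply(sinos, apply_scheme, scheme = scheme)
    fbps <- lapply(subs, fbp, spec = filter_input)
    for (method in methods) {
      recs <- switch(method,
        FBP = fbps,
        CS = lapply(subs, function(s) twist_reconstruct(s, twist)$image),
        CNN = lapply(fbps, cnn_reconstruct, model = models[[as.character(N)]]))
      per_slice <- mapply(psnr, recs, gts)
      reports[[paste(method, N, sep = "_")]] <-
        new_psnr_report(method, N, as.numeric(per_slice))
    }
  }
  structure(reports, class = "psnr_benchmark")
}

#' @export
as.data.frame.psnr_benchmark <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}

#' Write benchmark results as CSV
#'
#' Writes the summary table (method, N, mean_psnr, standard_error, n_slices)
#' and, optionally, a long-form per-slice table.
#'
#' @param bench A `psnr_benchmark` from [benchmark_methods()].
#' @param path Summary CSV path.
#' @param per_slice_path Optional long-form CSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark_csv <- function(bench, path, per_slice_path = NULL) {
  write.csv(as.data.frame(bench), path, row.names = FALSE)
  if (!is.null(per_slice_path)) {
    long <- do.call(rbind, lapply(unclass(bench), function(r)
      data.frame(method = r$method, N = r$projection_count,
                 slice = seq_along(r$per_slice_psnr),
                 psnr = r$per_slice_psnr)))
    write.csv(long, per_slice_path, row.names = FALSE)
  }
  invisible(path)
}
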