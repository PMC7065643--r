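#' Pipeline run configuration
#'
#' A fully resolved description of an end-to-end run: phantom synthesis,
#' projection, classical reconstruction, CNN training and benchmarking.
#' Serializes to and from YAML with round-trip equality; every run writes the
#' resolved configuration and the seeds it used next to its outputs, so a run
#' can be reproduced from its output directory alone.
#'
#' @param output_dir Directory for all artifacts.
#' @param seed Master seed for every stochastic stage.
#' @param stages Character vector, subset of
#'   `c("synth", "project", "fbp", "twist", "train", "benchmark")`.
#' @param n_slices Number of phantom slices to synthesize.
#' @param P Total number of simulated projections per slice.
#' @param N_list Undersampling levels (retained projection counts).
#' @param phantom Named list of [phantom_config()] arguments.
#' @param filter_gt,filter_input Named lists of [filter_spec()] arguments for
#'   the ground-truth and undersampled reconstructions.
#' @param twist Named list of [twist_config()] arguments.
#' @param unet Named list of [unet_spec()] arguments.
#' @param train Named list of [train_config()] arguments (its `seed` is
#'   derived from the master seed).
#' @param train_N Projection counts to train CNN models for (default:
#'   `N_list`).
#' @param methods Methods to benchmark.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir = "optrecon-run", seed = 1L,
                       stages = c("synth", "project", "fbp"),
                       n_slices = 10L, P = 400L, N_list = c(64L, 40L, 20L),
                       phantom = list(), filter_gt = list(window = "hann",
                                                          frequency_scale = 0.4),
                       filter_input = list(window = "none", frequency_scale = 1),
                       twist = list(), unet = list(),
                       train = list(), train_N = NULL, methods = c("FBP", "CS"),
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stages <- match.arg(stages, c("synth", "project", "fbp", "twist", "train",
                                "benchmark"), several.ok = TRUE)
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 stages = stages, n_slices = as.integer(n_slices),
                 P = as.integer(P), N_list = as.integer(N_list),
                 phantom = phantom, filter_gt = filter_gt,
                 filter_input = filter_input, twist = twist, unet = unet,
                 train = train,
                 train_N = as.integer(train_N %||% N_list),
                 methods = methods, log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the reconstruction pipeline
#'
#' Executes the requested stages in order: `synth` (phantom volume),
#' `project` (full sinograms), `fbp` (ground-truth and undersampled FBP),
#' `twist` (compressed-sensing reconstructions), `train` (one CNN per
#' requested undersampling level) and `benchmark` (PSNR tables). Later stages
#' recompute what they need if an earlier stage was not requested. All
#' artifacts, with content checksums over the decoded arrays, are listed in
#' `manifest.yml`; deterministic stages rerun with the same configuration and
#' seed produce identical checksums.
#'
#' @param config A [run_config()].
#' @return The manifest (named list of artifacts), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$log_level == "info") message(...)
  out <- function(...) file.path(config$output_dir, ...)
  write_run_config(config, out("config.yml"))
  manifest <- list(config = list(path = out("config.yml")))
  flush_manifest <- function()
    yaml::write_yaml(manifest, out("manifest.yml"))
  on.exit(flush_manifest())
  seeds <- derive_seeds(config$seed, 4L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      flush_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  pconf <- do.call(phantom_config, config$phantom)
  f_gt <- do.call(filter_spec, config$filter_gt)
  f_in <- do.call(filter_spec, config$filter_input)
  tconf <- do.call(twist_config, config$twist)

  volume <- NULL; sinos <- NULL
  need_volume <- function() {
    if (is.null(volume))
      volume <<- generate_volume(pconf, config$n_slices, seeds[1])
    volume
  }
  need_sinos <- function() {
    if (is.null(sinos))
      sinos <<- lapply(need_volume(), radon_project,
                       angles_deg = full_rotation_angles(config$P))
    sinos
  }

  if ("synth" %in% config$stages) stage("synth", {
    say("synth: ", config$n_slices, " phantom slices")
    p <- out("phantom.tif")
    write_volume(need_volume(), p,
                 metadata = c(config$phantom, list(seed = seeds[1])))
    manifest$phantom <- list(path = p,
                              checksum = array_checksum(simplify2array(need_volume())))
  })
  if ("project" %in% config$stages) stage("project", {
    say("project: P = ", config$P)
    arr <- simplify2array(lapply(need_sinos(), function(s) s$data))
    p <- out("sinograms.rds")
    saveRDS(arr, p)
    yaml::write_yaml(list(P = config$P,
                          angles_deg = full_rotation_angles(config$P)),
                     paste0(p, ".yml"))
    manifest$sinograms <- list(path = p, checksum = array_checksum(arr))
  })
  if ("fbp" %in% config$stages) stage("fbp", {
    gt <- lapply(need_sinos(), fbp, spec = f_gt)
    p <- out("recon_fbp_full.tif")
    write_volume(gt, p, metadata = config$filter_gt)
    manifest$fbp_full <- list(path = p,
                               checksum = array_checksum(simplify2array(gt)))
    for (N in config$N_list) {
      scheme <- subsample_indices(config$P, N)
      rec <- lapply(need_sinos(), function(s) fbp(apply_scheme(s, scheme), f_in))
      p <- out(sprintf("recon_fbp_N%03d.tif", N))
      write_volume(rec, p, metadata = c(config$filter_input, list(N = N)))
      manifest[[sprintf("fbp_N%03d", N)]] <-
        list(path = p, checksum = array_checksum(simplify2array(rec)))
    }
  })
  if ("twist" %in% config$stages) stage("twist", {
    for (N in config$N_list) {
      say("twist: N = ", N)
      scheme <- subsample_indices(config$P, N)
      res <- lapply(need_sinos(), function(s)
        twist_reconstruct(apply_scheme(s, scheme), tconf))
      rec <- lapply(res, `[[`, "image")
      p <- out(sprintf("recon_cs_N%03d.tif", N))
      write_volume(rec, p, metadata = list(tau = tconf$tau, N = N))
      traces <- do.call(rbind, lapply(seq_along(res), function(i)
        data.frame(slice = i, iteration = seq_along(res[[i]]$objective_trace) - 1L,
                   objective = res[[i]]$objective_trace)))
      write.csv(traces, out(sprintf("twist_trace_N%03d.csv", N)),
                row.names = FALSE)
      manifest[[sprintf("cs_N%03d", N)]] <-
        list(path = p, checksum = array_checksum(simplify2array(rec)))
    }
  })
  models <- list()
  if ("train" %in% config$stages) stage("train", {
    uspec <- do.call(unet_spec, config$unet)
    for (N in config$train_N) {
      say("train: N = ", N)
      pair_seeds <- derive_seeds(seeds[2] + N, config$n_slices)
      pairs <- lapply(seq_along(need_volume()), function(i)
        make_training_pair(volume[[i]], config$P, N, f_gt, f_in,
                           seed = pair_seeds[i]))
      tc <- do.call(train_config,
                    c(config$train, list(seed = seeds[3] + N)))
      fit <- train_unet(pairs, uspec, tc, projections = N)
      p <- out(sprintf("model_N%03d.rds", N))
      save_model(fit, p)
      write.csv(fit$history, out(sprintf("history_N%03d.csv", N)),
                row.names = FALSE)
      models[[as.character(N)]] <- fit
      manifest[[sprintf("model_N%03d", N)]] <-
        list(path = p, best_epoch = fit$best_epoch)
    }
  })
  if ("benchmark" %in% config$stages) stage("benchmark", {
    say("benchmark: ", paste(config$methods, collapse = ", "))
    bench <- benchmark_methods(need_sinos(), config$P, config$N_list,
                               methods = config$methods, models = models,
                               filter_gt = f_gt, filter_input = f_in,
                               twist = tconf)
    write_benchmark_csv(bench, out("benchmark.csv"),
                        out("benchmark_per_slice.csv"))
    manifest$benchmark <- list(path = out("benchmark.csv"))
  })
  flush_manifest()
  invisible(manifest)
}
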