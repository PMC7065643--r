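#' Training protocol configuration
#'
#' @param batch_size Slices per gradient step (default 32).
#' @param crop Side length of the random training crops in pixels
#'   (default 128).
#' @param early_stop_patience Stop when the held-out error has not improved
#'   on the best epoch for this many consecutive epochs (default 2); the
#'   weights of the best epoch are kept.
#' @param split_fraction Fraction of slice blocks assigned to training
#'   (default 0.8).
#' @param split_block Contiguous slices per assignment block (default 10);
#'   blocks, not slices, are randomized so neighboring (correlated) slices do
#'   not straddle the train/test split.
#' @param max_epochs Safety cap on epochs (default 100).
#' @param augment Apply random horizontal/vertical flips to training crops
#'   (default TRUE). The random-start-angle augmentation acts at pair
#'   creation, see [make_training_pair()].
#' @param learning_rate Adam step size (default 1e-3, with the conventional
#'   default moment decays 0.9/0.999).
#' @param seed Master seed; initialization, the split, shuffling, crops and
#'   flips draw from independent streams derived from it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, crop = 128L,
                         early_stop_patience = 2L, split_fraction = 0.8,
                         split_block = 10L, max_epochs = 100L, augment = TRUE,
                         learning_rate = 1e-3, seed = 1L) {
  assert_scalar_num(batch_size, "batch_size", lower = 1)
  assert_scalar_num(crop, "crop", lower = 8)
  assert_scalar_num(early_stop_patience, "early_stop_patience", lower = 1)
  assert_scalar_num(split_fraction, "split_fraction", lower = 1e-9, upper = 1 - 1e-9)
  assert_scalar_num(split_block, "split_block", lower = 1)
  assert_scalar_num(max_epochs, "max_epochs", lower = 1)
  assert_scalar_num(learning_rate, "learning_rate", lower = 1e-12)
  structure(list(batch_size = as.integer(batch_size), crop = as.integer(crop),
                 early_stop_patience = as.integer(early_stop_patience),
                 split_fraction = split_fraction,
                 split_block = as.integer(split_block),
                 max_epochs = as.integer(max_epochs), augment = isTRUE(augment),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

#' Mean absolute (l1) reconstruction error
#'
#' @param estimate,target Numeric arrays of identical shape.
#' @return Mean over pixels of `|estimate - target|`.
#' @export
l1_loss <- function(estimate, target) {
  if (!identical(dim(estimate), dim(target)))
    stop("`estimate` and `target` must have identical shape", call. = FALSE)
  mean(abs(estimate - target))
}

#' Normalize a training pair by the input's statistics
#'
#' Both images receive the same affine map (subtract the input's mean, divide
#' by the input's standard deviation), so the returned input has mean zero
#' and unit variance while the target stays on the input's scale.
#'
#' @param input Undersampled FBP slice (the network input).
#' @param target Fully sampled ground-truth slice.
#' @return List with `input`, `target`, and `params` (`shift`, `scale`).
#' @export
normalize_pair <- function(input, target) {
  if (!identical(dim(input), dim(target)))
    stop("`input` and `target` must have identical shape", call. = FALSE)
  shift <- mean(input); scale <- stats::sd(input)
  if (!is.finite(scale) || scale == 0)
    stop(degenerate_slice_error("zero-variance input slice"))
  list(input = (input - shift) / scale, target = (target - shift) / scale,
       params = list(shift = shift, scale = scale))
}

#' Block-wise train/test split of slice indices
#'
#' Slices are grouped into contiguous blocks of `split_block` neighbors and
#' blocks (not slices) are randomly assigned to training or testing, so
#' correlated neighboring slices never straddle the split.
#'
#' @param n_slices Total number of slices (must be at least `split_block`).
#' @param config A [train_config()] (uses `split_block`, `split_fraction`,
#'   `seed`).
#' @return List with integer vectors `train` and `test`; disjoint, exhaustive.
#' @export
split_dataset <- function(n_slices, config) {
  stopifnot(inherits(config, "train_config"))
  if (!is.numeric(n_slices) || n_slices < config$split_block)
    stop("`n_slices` must be at least `split_block`", call. = FALSE)
  n_slices <- as.integer(n_slices)
  block_of <- ceiling(seq_len(n_slices) / config$split_block)
  n_blocks <- max(block_of)
  n_train <- round(config$split_fraction * n_blocks)
  n_train <- min(max(n_train, 1L), n_blocks - 1L)
  seeds <- derive_seeds(config$seed, 1L)
  train_blocks <- with_seed(seeds[1], sort(sample.int(n_blocks, n_train)))
  train <- which(block_of %in% train_blocks)
  list(train = train, test = setdiff(seq_len(n_slices), train))
}

#' Build one (input, ground truth) training pair from a phantom slice
#'
#' Projects the slice at `P` equally spaced angles over a full rotation,
#' relabels a random start angle (acquisition-phase augmentation), then
#' reconstructs the ground truth `I` by FBP of the full sinogram with
#' `filter_gt` and the input `I0` by FBP of the `N`-projection subsampled
#' sinogram with `filter_input`. Optional random vertical/horizontal flips
#' are applied identically to both images.
#'
#' @param slice Square nonnegative matrix (e.g. from [generate_slice()]).
#' @param P Total number of simulated projections.
#' @param N Number of retained projections (`N <= P`).
#' @param filter_gt Filter for the ground-truth reconstruction (default Hann
#'   window at frequency scale 0.4).
#' @param filter_input Filter for the undersampled input (default pure ramp).
#' @param seed Integer seed for start angle and flips.
#' @param flips Apply random flips (default TRUE).
#' @return List with `input` (`I0`), `target` (`I`), and `augmentation`
#'   (start-angle offset and flip flags).
#' @export
make_training_pair <- function(slice, P, N,
                               filter_gt = filter_spec("hann", 0.4),
                               filter_input = filter_spec("none", 1),
                               seed = 1L, flips = TRUE) {
  if (N > P) stop("N must not exceed P", call. = FALSE)
  sino <- radon_project(slice, full_rotation_angles(P))
  aug <- with_seed(seed, list(
    offset = sample.int(P, 1L) - 1L,
    flip_h = flips && runif(1) < 0.5,
    flip_v = flips && runif(1) < 0.5))
  sino <- shift_start_angle(sino, aug$offset)
  I <- fbp(sino, filter_gt)
  I0 <- fbp(apply_scheme(sino, subsample_indices(P, N)), filter_input)
  if (aug$flip_h) { I <- I[, rev(seq_len(ncol(I)))]; I0 <- I0[, rev(seq_len(ncol(I0)))] }
  if (aug$flip_v) { I <- I[rev(seq_len(nrow(I))), ]; I0 <- I0[rev(seq_len(nrow(I0))), ] }
  list(input = I0, target = I, augmentation = aug)
}

# Early-stopping bookkeeping: given the held-out error after each epoch,
# return the epoch training stops at and the best epoch whose weights are
# kept. Training stops once `patience` consecutive epochs have failed to
# improve on the best error so far.
#' Trace the early-stopping rule over a held-out error sequence
#'
#' @param errors Numeric vector of held-out errors, one per epoch.
#' @param patience Consecutive non-improving epochs tolerated.
#' @return List with `stop_epoch` (last epoch run, `length(errors)` if the
#'   rule never triggers) and `best_epoch` (weights kept).
#' @export
early_stopping_trace <- function(errors, patience = 2L) {
  best <- Inf; best_epoch <- 0L
  for (e in seq_along(errors)) {
    if (errors[e] < best) { best <- errors[e]; best_epoch <- e }
    if (e - best_epoch >= patience)
      return(list(stop_epoch = e, best_epoch = best_epoch))
  }
  list(stop_epoch = length(errors), best_epoch = best_epoch)
}

## ---- Adam optimizer over a nested parameter list ----

adam_init <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - beta1^opt$t; corr2 <- 1 - beta2^opt$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in names(p)) {
        if (is.null(g[[nm]])) next
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      return(out)
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    list(p = p - lr * (m / corr1) / (sqrt(v / corr2) + eps), m = m, v = v)
  }
  r <- upd(params, grads, opt$m, opt$v)
  list(params = r$p, opt = list(m = r$m, v = r$v, t = opt$t))
}

## ---- training loop ----

# Draw one random crop window shared by input and target (slices smaller
# than the crop are reflect-padded first).
crop_pair <- function(input, target, crop) {
  H <- nrow(input); W <- ncol(input)
  if (H < crop || W < crop) {
    input <- reflect_pad(input, max(H, crop), max(W, crop))$x
    target <- reflect_pad(target, max(H, crop), max(W, crop))$x
    H <- nrow(input); W <- ncol(input)
  }
  i <- if (H > crop) sample.int(H - crop + 1L, 1L) else 1L
  j <- if (W > crop) sample.int(W - crop + 1L, 1L) else 1L
  ri <- i + seq_len(crop) - 1L; rj <- j + seq_len(crop) - 1L
  list(input = input[ri, rj], target = target[ri, rj])
}

#' Train the U-net on (undersampled, ground-truth) slice pairs
#'
#' Minimizes the mean absolute error between network output and ground truth
#' with Adam over random crops of the training pairs (batch-wise, with
#' optional flip augmentation), evaluating the mean l1 error on the held-out
#' pairs after every epoch. Training stops when the held-out error has not
#' improved for `early_stop_patience` consecutive epochs (or at
#' `max_epochs`); the weights of the best held-out epoch are returned.
#' Each pair is normalized by its input's statistics (see [normalize_pair()]);
#' zero-variance inputs are skipped with a warning.
#'
#' @param pairs List of pairs as returned by [make_training_pair()].
#' @param spec A [unet_spec()].
#' @param config A [train_config()].
#' @param split Optional list with `train` and `test` index vectors (e.g.
#'   from [split_dataset()]); computed from `config` when omitted.
#' @param projections Number of projections the inputs were reconstructed
#'   from (recorded in the returned model).
#' @return An object of class `trained_unet`: `model` (best-epoch weights and
#'   normalization statistics), `history` (per-epoch train/test mean l1),
#'   `best_epoch`, `stop_epoch`, `split`, `train_config`, `projections`.
#' @export
train_unet <- function(pairs, spec, config, split = NULL, projections = NA_integer_) {
  stopifnot(inherits(spec, "unet_spec"), inherits(config, "train_config"))
  if (length(pairs) == 0L) stop("empty training set", call. = FALSE)
  if (is.null(split)) split <- split_dataset(length(pairs), config)
  seeds <- derive_seeds(config$seed, 3L)
  keep <- rep(TRUE, length(pairs))
  norm <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    norm[[i]] <- tryCatch(normalize_pair(pairs[[i]]$input, pairs[[i]]$target),
                          degenerate_slice = function(e) NULL)
    if (is.null(norm[[i]])) {
      warning(sprintf("skipping degenerate (zero-variance) slice %d", i))
      keep[i] <- FALSE
    }
  }
  train_ids <- intersect(split$train, which(keep))
  test_ids <- intersect(split$test, which(keep))
  if (!length(train_ids) || !length(test_ids))
    stop("train or test set empty after dropping degenerate slices", call. = FALSE)

  model <- build_unet(spec, seed = seeds[1])
  opt <- adam_init(model$params)
  mult <- 2L^spec$depth
  crop <- mult * ceiling(config$crop / mult)

  eval_heldout <- function(model) {
    errs <- vapply(test_ids, function(i) {
      p <- norm[[i]]
      H <- nrow(p$input); W <- ncol(p$input)
      Hp <- mult * ceiling(H / mult); Wp <- mult * ceiling(W / mult)
      pin <- reflect_pad(p$input, Hp, Wp)
      xb <- array(pin$x, dim = c(Hp, Wp, 1L, 1L))
      out <- unet_forward(model, xb, training = FALSE)$out
      est <- matrix(out[, , 1L, 1L], Hp, Wp)[pin$top + seq_len(H),
                                             pin$left + seq_len(W)]
      l1_loss(est, p$target)
    }, numeric(1))
    mean(errs)
  }

  history <- data.frame(epoch = integer(), train_l1 = numeric(),
                        test_l1 = numeric())
  best <- list(err = Inf, epoch = 0L, params = model$params,
               state = model$state)
  stop_epoch <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    epoch_losses <- with_seed(seeds[2] + epoch, {
      order_ids <- sample(train_ids)
      n_batches <- ceiling(length(order_ids) / config$batch_size)
      losses <- numeric(n_batches)
      for (bt in seq_len(n_batches)) {
        ids <- order_ids[((bt - 1L) * config$batch_size + 1L):
                           min(bt * config$batch_size, length(order_ids))]
        B <- length(ids)
        xb <- array(0, dim = c(crop, crop, 1L, B))
        yb <- array(0, dim = c(crop, crop, 1L, B))
        for (b in seq_len(B)) {
          p <- norm[[ids[b]]]
          cp <- crop_pair(p$input, p$target, crop)
          xt <- cp$input; tt <- cp$target
          if (config$augment) {
            if (runif(1) < 0.5) { xt <- xt[, rev(seq_len(crop))]; tt <- tt[, rev(seq_len(crop))] }
            if (runif(1) < 0.5) { xt <- xt[rev(seq_len(crop)), ]; tt <- tt[rev(seq_len(crop)), ] }
          }
          xb[, , 1L, b] <- xt; yb[, , 1L, b] <- tt
        }
        fw <- unet_forward(model, xb, training = TRUE)
        model$state <- fw$state
        resid <- fw$out - yb
        losses[bt] <- mean(abs(resid))
        if (!is.finite(losses[bt]))
          stop(structure(class = c("training_failure", "error", "condition"),
                         list(message = "non-finite training loss",
                              call = sys.call(-1), history = history)))
        dout <- sign(resid) / length(resid)
        grads <- unet_backward(model, fw$cache, dout)
        stepped <- adam_step(model$params, grads, opt, config$learning_rate)
        model$params <- stepped$params
        opt <- stepped$opt
      }
      losses
    })
    test_err <- eval_heldout(model)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_l1 = mean(epoch_losses),
                                         test_l1 = test_err))
    es <- early_stopping_trace(history$test_l1, config$early_stop_patience)
    if (test_err < best$err)
      best <- list(err = test_err, epoch = epoch, params = model$params,
                   state = model$state)
    if (es$stop_epoch == epoch && es$best_epoch < epoch &&
        epoch - es$best_epoch >= config$early_stop_patience) {
      stop_epoch <- epoch
      break
    }
    stop_epoch <- epoch
  }
  model$params <- best$params
  model$state <- best$state
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 stop_epoch = stop_epoch, split = split,
                 train_config = config, projections = projections),
            class = "trained_unet")
}

#' @export
print.trained_unet <- function(x, ...) {
  cat(sprintf("<trained_unet> %d epochs (best %d), held-out l1 %.5g, N = %s\n",
              x$stop_epoch, x$best_epoch,
              x$history$test_l1[x$best_epoch],
              x$projections))
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single file embedding the weights, the architecture
#' spec and the training configuration, so reconstruction needs no external
#' configuration.
#'
#' @param model A `trained_unet` (or `unet_model`).
#' @param path File path.
#' @return `load_model` returns the saved object.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
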