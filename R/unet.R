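#' U-net architecture specification
#'
#' A modified U-net for streak-artifact removal. The contracting path has
#' `depth` blocks of two zero-padded 3x3 convolutions (each followed by batch
#' normalization and a rectified-linear activation) and 2x2 max pooling, the
#' feature count doubling each block starting from `base_features`. The
#' expanding path upsamples by bilinear interpolation (x2), concatenates the
#' skip features from the matching contracting scale, and passes the
#' concatenation through two 3x3 convolutions that quarter the channel count,
#' so expanding-path widths are half those of a conventional U-net. The
#' pooled deepest features are upsampled directly (no extra convolutions at
#' the deepest scale). A linear 1x1 convolution maps to the single output
#' channel. The network is fully convolutional: any input whose sides are
#' multiples of `2^depth` is mapped to an equally sized output.
#'
#' @param depth Number of pooling levels (default 4).
#' @param base_features Channels of the first block (default 64). Must be a
#'   multiple of 4 so the quartering rule yields whole channel counts.
#' @return An object of class `unet_spec`.
#' @export
unet_spec <- function(depth = 4L, base_features = 64L) {
  assert_scalar_num(depth, "depth", lower = 1, upper = 8)
  assert_scalar_num(base_features, "base_features", lower = 4)
  if (base_features %% 4 != 0)
    stop("`base_features` must be a multiple of 4 (quartering rule)",
         call. = FALSE)
  structure(list(depth = as.integer(depth),
                 base_features = as.integer(base_features),
                 kernel = 3L, pool = 2L, upsample = "bilinear",
                 padding = "zero"),
            class = "unet_spec")
}

#' Channel bookkeeping of a U-net specification
#'
#' @param spec A [unet_spec()].
#' @return A list with `contracting` (output channels of each contracting
#'   block), `concat` (channel counts entering each expanding block, deepest
#'   first), and `expanding` (output channels of each expanding block).
#' @export
unet_channel_plan <- function(spec) {
  stopifnot(inherits(spec, "unet_spec"))
  d <- spec$depth
  enc <- as.integer(spec$base_features * 2^(0:(d - 1L)))
  up_in <- enc[d] # pooled bottom features, upsampled directly
  concat <- integer(d); dec <- integer(d)
  for (j in seq_len(d)) {
    skip <- enc[d + 1L - j]
    concat[j] <- as.integer(up_in + skip)
    dec[j] <- concat[j] %/% 4L
    up_in <- dec[j]
  }
  list(contracting = enc, concat = concat, expanding = dec)
}

kaiming_uniform <- function(k, cin, cout) {
  bound <- 1 / sqrt(k * k * cin)
  array(runif(k * k * cin * cout, -bound, bound), dim = c(k, k, cin, cout))
}

new_conv_bn <- function(k, cin, cout) {
  list(w = kaiming_uniform(k, cin, cout),
       gamma = rep(1, cout), beta = rep(0, cout))
}

#' Build an untrained U-net
#'
#' Initializes convolution weights (Kaiming-uniform) and batch-normalization
#' parameters for the architecture described by `spec`.
#'
#' @param spec A [unet_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `unet_model` holding parameters, running
#'   batch-normalization statistics, and the spec.
#' @export
build_unet <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  plan <- unet_channel_plan(spec)
  d <- spec$depth
  with_seed(seed, {
    params <- list()
    cin <- 1L
    for (i in seq_len(d)) {
      cout <- plan$contracting[i]
      params[[paste0("enc", i, "a")]] <- new_conv_bn(3L, cin, cout)
      params[[paste0("enc", i, "b")]] <- new_conv_bn(3L, cout, cout)
      cin <- cout
    }
    for (j in seq_len(d)) {
      cc <- plan$concat[j]; cout <- plan$expanding[j]
      params[[paste0("dec", j, "a")]] <- new_conv_bn(3L, cc, cout)
      params[[paste0("dec", j, "b")]] <- new_conv_bn(3L, cout, cout)
    }
    ch <- plan$expanding[d]
    fan <- 1 * 1 * ch
    params$head <- list(w = kaiming_uniform(1L, ch, 1L),
                        b = runif(1, -1 / sqrt(fan), 1 / sqrt(fan)))
    state <- list()
    for (nm in names(params)) {
      if (nm == "head") next
      cout <- length(params[[nm]]$gamma)
      state[[nm]] <- list(mean = rep(0, cout), var = rep(1, cout))
    }
    structure(list(spec = spec, params = params, state = state),
              class = "unet_model")
  })
}

#' @export
print.unet_model <- function(x, ...) {
  plan <- unet_channel_plan(x$spec)
  cat(sprintf("<unet_model> depth %d, base %d; contracting %s; expanding %s\n",
              x$spec$depth, x$spec$base_features,
              paste(plan$contracting, collapse = "/"),
              paste(plan$expanding, collapse = "/")))
  invisible(x)
}

n_parameters <- function(model) {
  sum(vapply(model$params, function(p) sum(lengths(lapply(p, as.numeric))),
             numeric(1)))
}

## ---- batch normalization (training statistics over H*W*N per channel) ----

bn_fwd <- function(x, gamma, beta, st, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  M <- matrix(x, nrow = HW)
  colc <- rep(seq_len(C), N)
  if (training) {
    mu_cn <- colMeans(M)
    mu <- rowMeans(matrix(mu_cn, C))
    ex2 <- rowMeans(matrix(colMeans(M^2), C))
    v <- pmax(ex2 - mu^2, 0)
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    st$var <- (1 - momentum) * st$var + momentum * v
  } else {
    mu <- st$mean; v <- st$var
  }
  invstd <- 1 / sqrt(v + eps)
  Mh <- sweep(M, 2, mu[colc])
  Mh <- sweep(Mh, 2, invstd[colc], "*")
  Y <- sweep(Mh, 2, gamma[colc], "*")
  Y <- sweep(Y, 2, beta[colc], "+")
  y <- array(Y, dim = d)
  cache <- if (training) list(xhat = Mh, invstd = invstd, colc = colc,
                              gamma = gamma, d = d) else NULL
  list(y = y, state = st, cache = cache)
}

bn_bwd <- function(dy, cache) {
  d <- cache$d; HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  Dy <- matrix(dy, nrow = HW)
  colc <- cache$colc
  xhat <- cache$xhat
  dgamma <- rowSums(matrix(colSums(Dy * xhat), C))
  dbeta <- rowSums(matrix(colSums(Dy), C))
  Dxhat <- sweep(Dy, 2, cache$gamma[colc], "*")
  n <- HW * N
  m1 <- rowSums(matrix(colSums(Dxhat), C)) / n       # E[dxhat]
  m2 <- rowSums(matrix(colSums(Dxhat * xhat), C)) / n # E[dxhat * xhat]
  Dx <- Dxhat - sweep(xhat, 2, m2[colc], "*")
  Dx <- sweep(Dx, 2, m1[colc])
  Dx <- sweep(Dx, 2, cache$invstd[colc], "*")
  list(dx = array(Dx, dim = d), dgamma = dgamma, dbeta = dbeta)
}

## ---- conv + BN + ReLU block ----

cbr_fwd <- function(x, p, st, training) {
  z <- cpp_conv2d_fwd(x, p$w, numeric(0))
  bn <- bn_fwd(z, p$gamma, p$beta, st, training)
  y <- bn$y
  mask <- y > 0
  y[!mask] <- 0
  list(y = y, state = bn$state,
       cache = if (training) list(x = x, bn = bn$cache, mask = mask) else NULL)
}

cbr_bwd <- function(dy, p, cache) {
  dy[!cache$mask] <- 0
  bb <- bn_bwd(dy, cache$bn)
  cv <- cpp_conv2d_bwd(cache$x, p$w, bb$dx, TRUE, FALSE)
  list(dx = cv$dx,
       grads = list(w = cv$dw, gamma = bb$dgamma, beta = bb$dbeta))
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

## ---- full network ----

unet_forward <- function(model, x, training = FALSE) {
  d <- model$spec$depth
  if (any(dim(x)[1:2] %% 2L^d != 0))
    stop(sprintf("input sides must be multiples of %d", 2L^d), call. = FALSE)
  p <- model$params; st <- model$state
  caches <- list(); skips <- list(); pools <- list()
  h <- x
  for (i in seq_len(d)) {
    a <- cbr_fwd(h, p[[paste0("enc", i, "a")]], st[[paste0("enc", i, "a")]], training)
    st[[paste0("enc", i, "a")]] <- a$state
    b <- cbr_fwd(a$y, p[[paste0("enc", i, "b")]], st[[paste0("enc", i, "b")]], training)
    st[[paste0("enc", i, "b")]] <- b$state
    skips[[i]] <- b$y
    pl <- cpp_maxpool_fwd(b$y)
    pools[[i]] <- list(idx = pl$idx, H = dim(b$y)[1], W = dim(b$y)[2])
    h <- pl$y
    caches[[paste0("enc", i)]] <- list(a = a$cache, b = b$cache)
  }
  for (j in seq_len(d)) {
    up <- cpp_upsample2_fwd(h)
    skip <- skips[[d + 1L - j]]
    cc <- concat_c(up, skip)
    a <- cbr_fwd(cc, p[[paste0("dec", j, "a")]], st[[paste0("dec", j, "a")]], training)
    st[[paste0("dec", j, "a")]] <- a$state
    b <- cbr_fwd(a$y, p[[paste0("dec", j, "b")]], st[[paste0("dec", j, "b")]], training)
    st[[paste0("dec", j, "b")]] <- b$state
    caches[[paste0("dec", j)]] <- list(a = a$cache, b = b$cache,
                                       up_ch = dim(up)[3])
    h <- b$y
  }
  out <- cpp_conv2d_fwd(h, p$head$w, p$head$b)
  cache <- if (training) list(caches = caches, pools = pools,
                              head_in = h) else NULL
  list(out = out, state = st, cache = cache)
}

unet_backward <- function(model, cache, dout) {
  d <- model$spec$depth
  p <- model$params
  grads <- list()
  hv <- cpp_conv2d_bwd(cache$head_in, p$head$w, dout, TRUE, TRUE)
  grads$head <- list(w = hv$dw, b = hv$db)
  dh <- hv$dx
  dskips <- vector("list", d)
  for (j in rev(seq_len(d))) {
    cj <- cache$caches[[paste0("dec", j)]]
    bb <- cbr_bwd(dh, p[[paste0("dec", j, "b")]], cj$b)
    grads[[paste0("dec", j, "b")]] <- bb$grads
    ba <- cbr_bwd(bb$dx, p[[paste0("dec", j, "a")]], cj$a)
    grads[[paste0("dec", j, "a")]] <- ba$grads
    dcc <- ba$dx
    uc <- cj$up_ch
    dup <- dcc[, , seq_len(uc), , drop = FALSE]
    dskips[[d + 1L - j]] <- dcc[, , uc + seq_len(dim(dcc)[3] - uc), , drop = FALSE]
    dh <- cpp_upsample2_bwd(dup)
  }
  for (i in rev(seq_len(d))) {
    pl <- cache$pools[[i]]
    dpost <- cpp_maxpool_bwd(dh, pl$idx, pl$H, pl$W) + dskips[[i]]
    ci <- cache$caches[[paste0("enc", i)]]
    bb <- cbr_bwd(dpost, p[[paste0("enc", i, "b")]], ci$b)
    grads[[paste0("enc", i, "b")]] <- bb$grads
    ba <- cbr_bwd(bb$dx, p[[paste0("enc", i, "a")]], ci$a)
    grads[[paste0("enc", i, "a")]] <- ba$grads
    dh <- ba$dx
  }
  grads
}

#' Apply a trained network to an undersampled FBP slice
#'
#' The slice is normalized by its own mean and standard deviation, padded
#' reflectively so both sides are multiples of `2^depth`, passed through the
#' network in inference mode, cropped back to its original size, and
#' de-normalized with the same affine parameters, so the output is in the
#' intensity units of the input.
#'
#' @param model A trained model from [train_unet()] (or a `unet_model`).
#' @param I0 Numeric matrix: the streak-corrupted undersampled FBP
#'   reconstruction.
#' @return Numeric matrix of the same size as `I0`.
#' @export
cnn_reconstruct <- function(model, I0) {
  if (inherits(model, "trained_unet")) model <- model$model
  stopifnot(inherits(model, "unet_model"))
  if (!is.matrix(I0) || !all(is.finite(I0)))
    stop("`I0` must be a finite numeric matrix", call. = FALSE)
  m <- mean(I0); s <- stats::sd(I0)
  if (!is.finite(s) || s == 0)
    stop(degenerate_slice_error("zero-variance input slice"))
  xn <- (I0 - m) / s
  mult <- 2L^model$spec$depth
  H <- nrow(xn); W <- ncol(xn)
  Hp <- mult * ceiling(H / mult); Wp <- mult * ceiling(W / mult)
  pad <- reflect_pad(xn, Hp, Wp)
  xb <- array(pad$x, dim = c(Hp, Wp, 1L, 1L))
  out <- unet_forward(model, xb, training = FALSE)$out
  est <- matrix(out[, , 1L, 1L], Hp, Wp)[pad$top + seq_len(H),
                                         pad$left + seq_len(W), drop = FALSE]
  est * s + m
}

degenerate_slice_error <- function(msg) {
  structure(class = c("degenerate_slice", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
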