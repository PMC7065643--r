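# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All user-facing randomness flows through explicit seeds.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed (keeps every consumer
# of randomness on an independent, reproducible stream).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# FFT sample frequencies in cycles/sample, R fft ordering: 0, 1/n, ...,
# floor(n/2)/n, then negative frequencies.
fft_freq <- function(n) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n == 1L) k <- 0
  k / n
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)

# Mirror (reflect, edge not repeated) padding of a matrix to a target size,
# content placed at the top-left-ish center.
reflect_pad <- function(x, H, W) {
  h <- nrow(x); w <- ncol(x)
  if (h > H || w > W) stop("target smaller than input", call. = FALSE)
  top <- (H - h) %/% 2L; left <- (W - w) %/% 2L
  ridx <- reflect_index(seq_len(H) - top, h)
  cidx <- reflect_index(seq_len(W) - left, w)
  list(x = x[ridx, cidx, drop = FALSE], top = top, left = left)
}

reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j < n, j, period - j) + 1L)
}

# md5 of the content of a numeric array (values + dimensions), independent of
# the file format it is stored in.
array_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  writeBin(as.integer(dim(x) %||% length(x)), con)
  writeBin(as.numeric(x), con)
  close(con)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
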