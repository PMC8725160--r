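# Internal numerical helpers shared across modules.

# Gauss-Legendre nodes and weights on [-1, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- beta
  J[cbind(i + 1L, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1L, ]^2)
}

# Rescale [-1,1] nodes/weights to [a,b].
gl_rescale <- function(gl, a, b) {
  list(x = (b - a) / 2 * gl$x + (a + b) / 2, w = (b - a) / 2 * gl$w)
}

# log I0(x), stable for large x. besselI's scaled form fails above ~1e5;
# beyond that the asymptotic expansion I0(x) ~ e^x / sqrt(2 pi x) (1 + 1/(8x))
# is accurate to better than 1e-10.
log_bessel_i0 <- function(x) {
  out <- numeric(length(x))
  big <- x > 5e4
  if (any(!big)) {
    xs <- x[!big]
    out[!big] <- log(besselI(xs, 0, expon.scaled = TRUE)) + xs
  }
  if (any(big)) {
    xb <- x[big]
    out[big] <- xb - 0.5 * log(2 * pi * xb) + log1p(1 / (8 * xb) + 9 / (128 * xb^2))
  }
  out
}

# log cosh(x), stable for large |x|.
log_cosh <- function(x) {
  ax <- abs(x)
  ax + log1p(exp(-2 * ax)) - log(2)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mrellg <- function(...) stop(..., call. = FALSE)
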