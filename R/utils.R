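# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  seed = NULL runs code unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Centered rolling mean with window of k samples (NA at the edges).
roll_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

# Centered rolling standard deviation (NA at the edges).
roll_sd <- function(x, k) {
  m1 <- roll_mean(x, k)
  m2 <- roll_mean(x^2, k)
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  sqrt(pmax(m2 - m1^2, 0) * k / (k - 1))
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}
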