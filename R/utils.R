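# Internal numeric helpers shared across modules.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) abort("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L]
  )
}

#' Derive a stream of child seeds from one integer seed
#'
#' All stochastic operations funnel their randomness through a single integer
#' seed; multi-stage procedures derive per-stage seeds with this helper so one
#' top-level seed reproduces an entire run.
#'
#' @param seed Integer scalar.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[0, 2^31 - 1)`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  # splitmix-style integer scramble, kept in double arithmetic below 2^31
  s <- as.double(seed) %% 2147483647
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% 2147483647
    out[i] <- s
  }
  as.integer(out %% 2147483647)
}

# Orthonormal basis of the plane orthogonal to a unit vector t.
orthobasis <- function(t) {
  ref <- if (abs(t[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(cross3(t, ref))
  w <- cross3(t, u)
  list(u = u, w = w)
}

`%||%` <- rlang::`%||%`
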