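#' Derive a child seed from a master seed and stream coordinates
#'
#' A splitmix-style integer mix (two rounds of a 31-bit linear
#' congruential step followed by an xor-shift) folding each coordinate
#' into the state, so per-sequence seeds are stable under reordering of
#' the generation loop and never collide for distinct coordinates in
#' practice.  The result is a nonnegative integer below 2^31 - 1,
#' suitable for [set.seed()].
#'
#' @param ... integers: the master seed followed by stream coordinates
#'   (e.g. class, subject, repetition).
#' @return A single integer seed.
#' @export
mix_seed <- function(...) {
  x <- 0
  for (v in as.numeric(c(...))) {
    x <- (x * 69069 + v + 12345) %% 2147483647
    xi <- as.integer(x)
    x <- as.numeric(bitwXor(xi, bitwShiftR(xi, 13))) %% 2147483647
    x <- (x * 40692 + 3791) %% 2147483647
  }
  as.integer(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded to `seed`, then
#' restores the caller's RNG state, so reproducible draws never disturb
#' the enclosing simulation.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# rotation matrix Rz(c) %*% Ry(b) %*% Rx(a) for angles th = c(a, b, c)
rot3 <- function(th) {
  ca <- cos(th[1L]); sa <- sin(th[1L])
  cb <- cos(th[2L]); sb <- sin(th[2L])
  cc <- cos(th[3L]); sc <- sin(th[3L])
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3L)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3L)
  Rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3L)
  Rz %*% Ry %*% Rx
}
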