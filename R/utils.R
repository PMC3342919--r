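#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# All generators route their randomness through this so that identical
# configurations give bit-identical outputs regardless of what the session
# has done with .Random.seed beforehand.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Index of the nearest seed point for each query point; ties go to the
# smaller index so assignment is deterministic on boundaries. Vectorized
# over points, looping only over seeds.
nearest_seed <- function(x, y, seed_x, seed_y) {
  best <- rep.int(1L, length(x))
  best_d2 <- (x - seed_x[1])^2 + (y - seed_y[1])^2
  for (j in seq_along(seed_x)[-1]) {
    d2 <- (x - seed_x[j])^2 + (y - seed_y[j])^2
    hit <- d2 < best_d2 # strict: earlier (smaller) index wins ties
    best[hit] <- j
    best_d2[hit] <- d2[hit]
  }
  best
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

KM2_TO_ACRES <- 247.105
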