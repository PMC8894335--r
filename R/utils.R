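#' @keywords internal
"_PACKAGE"

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that internally seeded
#' operations (phantom rendering, per-subject noise draws) do not disturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a parent seed and an index, staying within the
# 32-bit signed integer range R requires of set.seed().
derive_seed <- function(parent, index) {
  as.integer((as.double(parent) * 48271 + index * 16807) %% 2147483647)
}

# Truncated-normal draw by rejection; bounds are hard guarantees.
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
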