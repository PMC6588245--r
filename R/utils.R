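# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched, making every generator a pure function
# of its arguments.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# First-local-minimum rule used for both the pose-distance profile and the
# AMI lag profile: smallest index i with x[i-1] > x[i] <= x[i+1]. The left
# boundary qualifies when x[1] < x[2] (strict, so a flat start is skipped).
# Returns NA when the profile has no such point (e.g. strictly decreasing).
first_local_min <- function(x) {
  n <- length(x)
  if (n == 1L) return(1L)
  if (x[1] < x[2]) return(1L)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      if (x[i - 1L] > x[i] && x[i] <= x[i + 1L]) return(i)
    }
  }
  NA_integer_
}

moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  stats::filter(x, rep(1 / window, window), sides = 2) |>
    (\(v) { # shrink the kernel at the edges instead of dropping frames
      v <- as.numeric(v)
      half <- (window - 1L) %/% 2L
      n <- length(x)
      for (i in which(is.na(v))) {
        lo <- max(1L, i - half); hi <- min(n, i + half)
        v[i] <- mean(x[lo:hi])
      }
      v
    })()
}
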