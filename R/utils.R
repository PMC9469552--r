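# Internal numerical helpers shared across modules.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluate an expression under a temporary RNG state
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's \code{.Random.seed} afterwards, so library functions never
#' perturb user-level randomness.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Glorot (Xavier) uniform initialisation for a fan_in x fan_out weight matrix.
glorot <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

# Min-max scale a numeric vector to [0,1]; constant vectors map to 0.5.
minmaxScale <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= .Machine$double.eps * max(1, abs(r[2])))
    return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

popcount <- function(bits) sum(bits != 0)

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
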