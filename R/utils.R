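# Shared numeric helpers.

#' Logit (base 2) transform between beta and M scales
#'
#' `beta_logit2()` maps a methylation fraction to the M scale,
#' `beta_unlogit2()` inverts it. No clipping is applied here; see
#' [beta_to_m()] for the clipped transform used on data.
#'
#' @param beta,m Numeric vectors.
#' @return Numeric vector on the other scale.
#' @export
beta_logit2 <- function(beta) log2(beta / (1 - beta))

#' @rdname beta_logit2
#' @export
beta_unlogit2 <- function(m) 2^m / (1 + 2^m)

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state so
# generators are pure functions of (config, seed).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# One Dirichlet draw per row via gamma normalization.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

# Newton inversion of the trigamma function (used by the empirical-Bayes
# prior-df estimator). Monotone decreasing on (0, Inf).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}
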