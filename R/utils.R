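`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dirichlet random deviates
#'
#' One draw per row of `alpha` (or `n` draws from a single `alpha` vector),
#' via normalized independent gammas.
#'
#' @param n number of draws.
#' @param alpha positive concentration vector.
#' @return an `n` x `length(alpha)` matrix whose rows sum to 1.
#' @keywords internal
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Lognormal draws parameterized by arithmetic mean and coefficient of
# variation. cv = 0 degenerates to the mean exactly.
rlnorm_mean <- function(n, mean, cv) {
  stopifnot(all(mean > 0), cv >= 0)
  if (cv == 0) return(rep(mean, length.out = n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

stop_psq <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "paddysoilq_error")))
}
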