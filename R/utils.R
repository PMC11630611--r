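# Internal numerical and RNG helpers.

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded package operations never disturb the global
#' random stream. A `NULL` seed evaluates `expr` under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so state can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Multivariate normal log-density for a matrix of deviations (rows = points),
# one shared covariance. `dev` is n x d of (x - mu).
dmvnorm_log_dev <- function(dev, sigma) {
  d <- ncol(dev)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("covariance matrix is not positive definite", call. = FALSE)
  }
  logdet <- 2 * sum(log(diag(ch)))
  z <- backsolve(ch, t(dev), transpose = TRUE)  # d x n
  q <- colSums(z^2)
  -0.5 * (d * log(2 * pi) + logdet + q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
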