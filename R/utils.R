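#' @keywords internal
"_PACKAGE"

#' Logistic sigmoid
#'
#' @param x numeric vector.
#' @return `1 / (1 + exp(-x))`.
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

## Evaluate an expression under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.  All stochastic operations in the
## package route through this so that results are a pure function of their
## seed argument.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

## Derive a child seed from a parent seed and a stream label, kept within
## 32-bit integer range.
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

## log N(x; mu, Sigma) for a dense covariance, via Cholesky.
dmvnorm_log <- function(x, mu, Sigma) {
  x <- as.numeric(x); mu <- as.numeric(mu)
  L <- chol(Sigma)
  z <- backsolve(L, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + sum(z^2)) - sum(log(diag(L)))
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pdvoice <- function(...) stop(..., call. = FALSE)
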