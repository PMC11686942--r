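#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm rbinom rpois runif rlnorm rexp var sd cor coef
#' @importFrom stats lm pchisq pf pt qnorm quantile logLik model.matrix phyper
#' @importFrom stats optimize setNames complete.cases simulate as.formula
#' @importFrom utils head tail
NULL

# Euclidean distance matrix between two coordinate sets (meters, planar).
dist_xy <- function(x1, y1, x2 = x1, y2 = y1) {
  dx <- outer(x1, x2, "-")
  dy <- outer(y1, y2, "-")
  sqrt(dx^2 + dy^2)
}

# Cholesky factor with adaptive diagonal jitter (1e-10 * mean diag, x10 up to
# 1e-6 * mean diag). Errors with a diagnostic if the matrix stays indefinite.
chol_jitter <- function(S, what = "covariance matrix") {
  L <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(L)) return(L)
  scale <- mean(diag(S))
  jit <- 1e-10
  while (jit <= 1e-6) {
    L <- tryCatch(chol(S + diag(jit * scale, nrow(S))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- jit * 10
  }
  abort(sprintf("%s is not positive definite even after diagonal jitter up to %g * mean(diag)",
                what, 1e-6))
}

# One multivariate normal draw per column of Z given an upper-triangular
# Cholesky factor L (so cov = t(L) %*% L).
mvn_from_chol <- function(L, n_draws = 1) {
  z <- matrix(rnorm(ncol(L) * n_draws), ncol(L), n_draws)
  crossprod(L, z)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

check_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s", name,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
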