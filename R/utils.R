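## Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clip probabilities away from 0 and 1
#'
#' Probabilities exactly 0 or 1 break logit transforms; they are moved to
#' `eps` / `1 - eps` with a warning.
#'
#' @param p numeric vector of probabilities.
#' @param eps clipping margin (default `1e-6`).
#' @return clipped vector.
#' @keywords internal
clip_probability <- function(p, eps = 1e-6) {
  bad <- p <= 0 | p >= 1
  if (any(bad, na.rm = TRUE)) {
    warning(sprintf("%d probabilities at or outside (0,1) clipped to [%g, %g]",
                    sum(bad, na.rm = TRUE), eps, 1 - eps))
  }
  pmin(pmax(p, eps), 1 - eps)
}

## log(sum(exp(x))) by row, guarded against overflow
row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

## 2-D Gauss-Hermite grid (physicists' convention) for adaptive quadrature.
## Returns nodes z (Q x 2) and weights w with sum(w * pi^-1) = 1.
gh_grid_2d <- function(k = 9L) {
  gh <- pracma::gaussHermite(k)
  z <- as.matrix(expand.grid(z1 = gh$x, z2 = gh$x))
  w <- as.vector(outer(gh$w, gh$w))
  list(z = z, logw = log(w) - log(pi), n = nrow(z))
}

## Nearest positive semi-definite repair by eigenvalue clipping.
nearest_psd <- function(S, eps = 1e-10) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (all(e$values >= 0)) return(S)
  warning("covariance matrix not positive semi-definite; repaired by eigenvalue clipping")
  v <- pmax(e$values, eps)
  S2 <- e$vectors %*% (v * t(e$vectors))
  (S2 + t(S2)) / 2
}

## Multivariate normal draws (chol-based) with PSD repair.
draw_mvn <- function(n, mu, Sigma) {
  p <- length(mu)
  if (p == 1L) {
    return(matrix(stats::rnorm(n, mu, sqrt(max(Sigma[1L], 0))), ncol = 1L))
  }
  if (max(abs(Sigma)) == 0) {
    return(matrix(mu, n, p, byrow = TRUE))
  }
  Sigma <- nearest_psd(Sigma)
  L <- tryCatch(chol(Sigma), error = function(e) {
    chol(Sigma + diag(1e-10, p))
  })
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% L, 2L, mu, `+`)
}

## Mid-point between two assessment dates (calendar years).
midpoint_year <- function(year_previous, year_ascertained) {
  (year_previous + year_ascertained) / 2
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
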