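# ---------------------------------------------------------------------------
# Density approximation at a point: log-spline ML estimator on a bounded
# support, and the method-of-moments truncated-normal approximation
# ---------------------------------------------------------------------------

#' Log-spline density estimate on a bounded support
#'
#' Maximum-likelihood log-density on a cubic B-spline basis over `support`:
#' `log f(x) = B(x) %*% beta - log Z(beta)`, with the basis dimension chosen
#' by BIC over `df_grid`.  The normalizing constant is computed by Simpson
#' quadrature on a fine grid, so the returned density integrates to one over
#' the support up to quadrature error.
#'
#' @param samples Numeric draws; at least 500 inside the support.
#' @param support Length-2 numeric: the known bounds of the quantity.
#' @param df_grid Candidate basis dimensions.
#' @param n_grid Quadrature grid size (odd; Simpson weights).
#' @return A function `f(x)` returning the estimated density (0 outside the
#'   support), with the selected `df` in attribute `"df"`.
#' @export
logspline_density <- function(samples, support = c(-1, 1),
                              df_grid = c(5, 7, 9, 12), n_grid = 1001) {
  stopifnot(length(support) == 2, support[1] < support[2])
  x <- samples[samples >= support[1] & samples <= support[2] &
                 is.finite(samples)]
  n <- length(x)
  if (n < 500) {
    abort("need at least 500 samples within the support",
          class = "ordtree_value_error")
  }
  if (sd(x) == 0) {
    abort("degenerate input: all samples identical",
          class = "ordtree_value_error")
  }
  if (n_grid %% 2 == 0) n_grid <- n_grid + 1
  grid <- seq(support[1], support[2], length.out = n_grid)
  h <- grid[2] - grid[1]
  w <- rep(c(2, 4), length.out = n_grid); w[1] <- w[n_grid] <- 1
  w <- w * h / 3                               # Simpson weights

  fit_one <- function(df) {
    B <- splines::bs(x, df = df, degree = 3, intercept = FALSE,
                     Boundary.knots = support)
    Bg <- splines::bs(grid, df = df, degree = 3, intercept = FALSE,
                      Boundary.knots = support,
                      knots = attr(B, "knots"))
    s <- colSums(B)                            # sufficient statistics
    negll <- function(beta) {
      z <- Bg %*% beta
      m <- max(z)
      logZ <- m + log(sum(w * exp(z - m)))
      -(sum(s * beta) - n * logZ)
    }
    grad <- function(beta) {
      z <- drop(Bg %*% beta)
      m <- max(z)
      u <- w * exp(z - m)
      EB <- colSums(Bg * u) / sum(u)
      -(s - n * EB)
    }
    opt <- optim(rep(0, df), negll, grad, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    list(df = df, beta = opt$par, negll = opt$value,
         bic = 2 * opt$value + df * log(n), knots = attr(B, "knots"))
  }
  fits <- lapply(df_grid, fit_one)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]

  Bg <- splines::bs(grid, df = best$df, degree = 3, intercept = FALSE,
                    Boundary.knots = support, knots = best$knots)
  z <- drop(Bg %*% best$beta)
  m <- max(z)
  logZ <- m + log(sum(w * exp(z - m)))
  f <- function(xnew) {
    out <- numeric(length(xnew))
    inside <- xnew >= support[1] & xnew <= support[2]
    if (any(inside)) {
      Bn <- splines::bs(xnew[inside], df = best$df, degree = 3,
                        intercept = FALSE, Boundary.knots = support,
                        knots = best$knots)
      out[inside] <- exp(drop(Bn %*% best$beta) - logZ)
    }
    out
  }
  attr(f, "df") <- best$df
  attr(f, "support") <- support
  f
}

#' Bivariate log-spline density estimate on a bounded rectangle
#'
#' Tensor-product extension of [logspline_density()]: the log-density is a
#' linear combination of products of univariate cubic B-spline basis
#' functions, fitted by maximum likelihood with Simpson quadrature on a 2-D
#' grid for the normalizing constant.  Used for the joint point-null test of
#' two quantities behind the `joint` flag of [savage_dickey_bf()].
#'
#' @param samples A two-column matrix of draws; at least 500 inside the
#'   support rectangle.
#' @param support List of two length-2 numerics (per-dimension bounds).
#' @param df Basis dimension per margin.
#' @param n_grid Per-dimension quadrature grid size (odd).
#' @return A function `f(x, y)` returning the estimated joint density.
#' @export
logspline_density2d <- function(samples, support = list(c(-1, 1), c(-1, 1)),
                                df = 6, n_grid = 61) {
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == 2, length(support) == 2)
  inside <- samples[, 1] >= support[[1]][1] & samples[, 1] <= support[[1]][2] &
            samples[, 2] >= support[[2]][1] & samples[, 2] <= support[[2]][2]
  x <- samples[inside & rowSums(!is.finite(samples)) == 0, , drop = FALSE]
  n <- nrow(x)
  if (n < 500) {
    abort("need at least 500 samples within the support",
          class = "ordtree_value_error")
  }
  if (n_grid %% 2 == 0) n_grid <- n_grid + 1
  simpson_w <- function(g) {
    h <- g[2] - g[1]
    w <- rep(c(2, 4), length.out = length(g)); w[1] <- w[length(g)] <- 1
    w * h / 3
  }
  basis <- function(v, d) {
    splines::bs(v, df = df, degree = 3, intercept = FALSE,
                Boundary.knots = support[[d]],
                knots = attr(B_ref[[d]], "knots"))
  }
  B_ref <- list(
    splines::bs(x[, 1], df = df, degree = 3, intercept = FALSE,
                Boundary.knots = support[[1]]),
    splines::bs(x[, 2], df = df, degree = 3, intercept = FALSE,
                Boundary.knots = support[[2]])
  )
  # tensor-product design: row-wise Kronecker of the two margins
  tensor <- function(B1, B2) {
    out <- matrix(NA_real_, nrow(B1), df * df)
    k <- 0
    for (i in seq_len(df)) for (j in seq_len(df)) {
      k <- k + 1
      out[, k] <- B1[, i] * B2[, j]
    }
    out
  }
  s <- colSums(tensor(B_ref[[1]], B_ref[[2]]))
  g1 <- seq(support[[1]][1], support[[1]][2], length.out = n_grid)
  g2 <- seq(support[[2]][1], support[[2]][2], length.out = n_grid)
  gg <- expand.grid(g1 = g1, g2 = g2)
  Bg <- tensor(basis(gg$g1, 1), basis(gg$g2, 2))
  w <- simpson_w(g1)[match(gg$g1, g1)] * simpson_w(g2)[match(gg$g2, g2)]
  negll <- function(beta) {
    z <- drop(Bg %*% beta)
    m <- max(z)
    logZ <- m + log(sum(w * exp(z - m)))
    -(sum(s * beta) - n * logZ)
  }
  grad <- function(beta) {
    z <- drop(Bg %*% beta)
    m <- max(z)
    u <- w * exp(z - m)
    EB <- colSums(Bg * u) / sum(u)
    -(s - n * EB)
  }
  opt <- optim(rep(0, df * df), negll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  z <- drop(Bg %*% opt$par)
  m <- max(z)
  logZ <- m + log(sum(w * exp(z - m)))
  beta <- opt$par
  function(xnew, ynew) {
    inside <- xnew >= support[[1]][1] & xnew <= support[[1]][2] &
              ynew >= support[[2]][1] & ynew <= support[[2]][2]
    out <- numeric(length(xnew))
    if (any(inside)) {
      Bn <- tensor(basis(xnew[inside], 1), basis(ynew[inside], 2))
      out[inside] <- exp(drop(Bn %*% beta) - logZ)
    }
    out
  }
}

#' Truncated-normal density approximation at a point
#'
#' Fits a normal distribution to the samples by the method of moments,
#' truncates it to `bounds` (the inherent range of a difference of
#' probabilities is `[-1, 1]`), and evaluates the resulting density.
#'
#' @param samples Numeric draws (>= 2).
#' @param point Evaluation point.
#' @param bounds Length-2 truncation bounds.
#' @return The truncated-normal density at `point` (0 outside the bounds).
#' @export
truncnorm_density <- function(samples, point, bounds = c(-1, 1)) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  if (length(samples) < 2) {
    abort("need at least 2 samples", class = "ordtree_value_error")
  }
  m <- mean(samples)
  s <- sd(samples)
  if (s == 0) {
    abort("degenerate input: zero sample SD", class = "ordtree_value_error")
  }
  if (point < bounds[1] || point > bounds[2]) return(0)
  mass <- pnorm(bounds[2], m, s) - pnorm(bounds[1], m, s)
  dnorm(point, m, s) / mass
}
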