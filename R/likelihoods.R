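#' Expression distribution parametrization
#'
#' Per-cell, per-feature parameters of the decoder's output distribution.
#' Count-family means are strictly positive; the zero-inflation mixing
#' probability is kept on the logit scale and passed through a logistic
#' transform when evaluated.
#'
#' @param family `"gaussian"`, `"poisson"` or `"zinb"`.
#' @param mean n x M matrix of means (`mu`). Strictly positive for count
#'   families, any real for gaussian.
#' @param dispersion Per-feature vector (length M): inverse-dispersion
#'   `theta` for zinb, variance for gaussian. Ignored for poisson.
#' @param zero_inflation_logit n x M matrix of zero-inflation logits (zinb
#'   only).
#' @return An object of class `expression_distribution`.
#' @export
expression_distribution <- function(family = c("gaussian", "poisson", "zinb"),
                                    mean, dispersion = NULL,
                                    zero_inflation_logit = NULL) {
  family <- match.arg(family)
  mean <- as.matrix(mean)
  if (!all(is.finite(mean))) stop("distribution means must be finite")
  if (family %in% c("poisson", "zinb") && any(mean <= 0)) {
    stop("count-family means must be strictly positive")
  }
  if (family == "zinb") {
    if (is.null(dispersion)) stop("zinb requires a dispersion (theta) vector")
    if (is.null(zero_inflation_logit)) stop("zinb requires zero-inflation logits")
    zero_inflation_logit <- as.matrix(zero_inflation_logit)
    if (!identical(dim(zero_inflation_logit), dim(mean))) {
      stop("zero-inflation logits must match the mean matrix dimensions")
    }
    if (any(dispersion <= 0) || !all(is.finite(dispersion))) {
      stop("zinb dispersion must be positive and finite")
    }
  }
  if (family == "gaussian") {
    if (is.null(dispersion)) dispersion <- rep(1, ncol(mean))
    if (any(dispersion <= 0)) stop("gaussian variance must be positive")
  }
  structure(
    list(family = family, mean = mean, dispersion = dispersion,
         zero_inflation_logit = zero_inflation_logit),
    class = "expression_distribution"
  )
}

#' @export
print.expression_distribution <- function(x, ...) {
  cat("<expression_distribution> family = ", x$family, ", ",
      nrow(x$mean), " cells x ", ncol(x$mean), " features\n", sep = "")
  invisible(x)
}

#' Expected value of an expression distribution
#'
#' For zinb this is `(1 - pi) * mu`, accounting for the structural-zero
#' component; for gaussian and poisson it is `mu` itself.
#'
#' @param dist An [expression_distribution()].
#' @return An n x M matrix.
#' @export
expected_value <- function(dist) {
  if (dist$family == "zinb") {
    (1 - plogis(dist$zero_inflation_logit)) * dist$mean
  } else {
    dist$mean
  }
}

softplus <- function(x) {
  # log(1 + exp(x)), stable for large |x|
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Negative log-likelihood of observations under an expression distribution
#'
#' Exact negative log density (gaussian) or log pmf (poisson, zinb), summed
#' over features, returned per cell. The zinb pmf is the mixture
#' `pi * 1[x = 0] + (1 - pi) * NB(x; mu, theta)` with
#' `pi = plogis(zero_inflation_logit)` and the NB mean/inverse-dispersion
#' parametrization.
#'
#' @param x Observation matrix (n x M) or a single-cell vector of length M.
#'   Count families require non-negative, finite values.
#' @param dist An [expression_distribution()] with matching dimensions.
#' @param cells Optional integer or logical index restricting to a subset of
#'   rows of both `x` and `dist`.
#' @return Numeric vector of per-cell NLLs (a scalar for a single cell).
#' @export
nll <- function(x, dist, cells = NULL) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  mu <- dist$mean
  zi <- dist$zero_inflation_logit
  if (!is.null(cells)) {
    x <- x[cells, , drop = FALSE]
    mu <- mu[cells, , drop = FALSE]
    if (!is.null(zi)) zi <- zi[cells, , drop = FALSE]
  }
  if (!identical(dim(x), dim(mu))) {
    stop("observation matrix is ", nrow(x), " x ", ncol(x),
         " but the distribution is ", nrow(mu), " x ", ncol(mu))
  }
  if (!all(is.finite(x))) stop("observations must be finite")
  if (dist$family %in% c("poisson", "zinb") && any(x < 0)) {
    stop("count families require non-negative observations")
  }
  per_entry <- switch(
    dist$family,
    gaussian = {
      v <- rep(dist$dispersion, each = nrow(mu))
      0.5 * log(2 * pi * v) + (x - mu)^2 / (2 * v)
    },
    poisson = mu - x * log(mu) + lgamma(x + 1),
    zinb = {
      th <- rep(dist$dispersion, each = nrow(mu))
      log_nb <- lgamma(x + th) - lgamma(th) - lgamma(x + 1) +
        th * (log(th) - log(th + mu)) + x * (log(mu) - log(th + mu))
      sp <- softplus(zi)
      out <- sp - log_nb                      # x > 0 branch: -[log_nb - softplus]
      z0 <- x == 0
      if (any(z0)) {
        # log(pi + (1-pi) p0) = logaddexp(s, log p0) - softplus(s)
        lp0 <- (th * (log(th) - log(th + mu)))[z0]
        s0 <- zi[z0]
        m <- pmax(s0, lp0)
        out[z0] <- sp[z0] - (m + log(exp(s0 - m) + exp(lp0 - m)))
      }
      out
    }
  )
  drop(rowSums(per_entry))
}

# Per-entry gradients of the NLL with respect to mu, log(theta) and the
# zero-inflation logit; used by the trainer. Returns matrices matching x.
nll_grads <- function(x, mu, family, theta = NULL, zi = NULL, variance = NULL) {
  if (family == "poisson") {
    return(list(dmu = 1 - x / mu))
  }
  if (family == "gaussian") {
    v <- rep(variance, each = nrow(mu))
    return(list(dmu = (mu - x) / v,
                dlogvar = 0.5 - (x - mu)^2 / (2 * v)))
  }
  th <- rep(theta, each = nrow(mu))
  pi_ <- plogis(zi)
  dmu <- -(x / mu - (x + th) / (th + mu))
  dth <- -(digamma(x + th) - digamma(th) + log(th / (th + mu)) + (mu - x) / (th + mu))
  ds <- pi_
  z0 <- x == 0
  if (any(z0)) {
    lp0 <- (th * (log(th) - log(th + mu)))[z0]
    s0 <- zi[z0]
    m <- pmax(s0, lp0)
    ea <- exp(s0 - m); eb <- exp(lp0 - m)
    w <- ea / (ea + eb)        # pi mass share of P(0)
    v0 <- 1 - w                # NB-zero mass share
    th0 <- th[z0]; mu0 <- mu[z0]
    dmu[z0] <- v0 * th0 / (th0 + mu0)
    dth[z0] <- -v0 * (log(th0 / (th0 + mu0)) + mu0 / (th0 + mu0))
    ds[z0] <- pi_[z0] - w
  }
  list(dmu = dmu, dlogtheta = dth * th, ds = ds)
}

#' Draw observations from an expression distribution
#'
#' Samples one matrix of observations using the current RNG state. Used by
#' the synthetic-data generator and in self-consistency checks.
#'
#' @param dist An [expression_distribution()].
#' @return An n x M matrix on the family's support.
#' @export
sample_expression <- function(dist) {
  n <- nrow(dist$mean); m <- ncol(dist$mean)
  mu <- dist$mean
  switch(
    dist$family,
    gaussian = mu + matrix(rnorm(n * m, sd = rep(sqrt(dist$dispersion), each = n)), n, m),
    poisson = matrix(rpois(n * m, lambda = mu), n, m),
    zinb = {
      th <- rep(dist$dispersion, each = n)
      counts <- matrix(rnbinom(n * m, mu = mu, size = th), n, m)
      drop_mask <- matrix(runif(n * m) < plogis(dist$zero_inflation_logit), n, m)
      counts[drop_mask] <- 0
      counts
    }
  )
}
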