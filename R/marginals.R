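## Positive-support marginal distributions for the cohort simulator.
##
## Each feature/group marginal is fitted so that its mean and SD reproduce the
## configured summary exactly: a zero-truncated normal where that family can
## attain the target coefficient of variation (CV <= 0.85; the family's limit
## is CV -> 1), otherwise a moment-matched lognormal.  Both are continuous,
## strictly positive and monotone transforms of a standard normal, so a
## Gaussian copula drives them without disturbing rank correlations.

MARGINAL_CV_LIMIT <- 0.85

## mean and sd of a normal(mu, sigma) truncated below at zero
truncnorm_moments <- function(mu, sigma) {
  a <- -mu / sigma
  zc <- pnorm(mu / sigma)           # P(X > 0)
  lam <- exp(dnorm(a, log = TRUE) - pnorm(mu / sigma, log.p = TRUE))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  list(mean = m, sd = sqrt(max(v, 0)), zc = zc)
}

fit_marginal <- function(mean, sd) {
  stopifnot(is.finite(mean), is.finite(sd), mean > 0, sd > 0)
  cv <- sd / mean
  if (cv <= MARGINAL_CV_LIMIT) {
    obj <- function(par) {
      mo <- truncnorm_moments(par[1L], exp(par[2L]))
      (mo$mean / mean - 1)^2 + (mo$sd / sd - 1)^2
    }
    fit <- stats::optim(c(mean, log(sd)), obj,
                        control = list(maxit = 5000, reltol = 1e-15))
    mo <- truncnorm_moments(fit$par[1L], exp(fit$par[2L]))
    if (abs(mo$mean / mean - 1) < 1e-6 && abs(mo$sd / sd - 1) < 1e-6) {
      return(structure(list(family = "truncnorm",
                            mu = fit$par[1L], sigma = exp(fit$par[2L]),
                            mean = mean, sd = sd),
                       class = "phenomet_marginal"))
    }
  }
  s2 <- log1p(cv^2)
  structure(list(family = "lognormal",
                 mu = log(mean) - s2 / 2, sigma = sqrt(s2),
                 mean = mean, sd = sd),
            class = "phenomet_marginal")
}

marginal_density <- function(x, m) {
  switch(m$family,
    truncnorm = ifelse(x < 0, 0,
      dnorm(x, m$mu, m$sigma) / pnorm(m$mu / m$sigma)),
    lognormal = dlnorm(x, m$mu, m$sigma))
}

marginal_cdf <- function(x, m) {
  switch(m$family,
    truncnorm = {
      a <- pnorm(0, m$mu, m$sigma)
      pmin(pmax((pnorm(x, m$mu, m$sigma) - a) / (1 - a), 0), 1)
    },
    lognormal = plnorm(x, m$mu, m$sigma))
}

marginal_quantile <- function(u, m) {
  u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  switch(m$family,
    truncnorm = {
      a <- pnorm(0, m$mu, m$sigma)
      qnorm(a + u * (1 - a), m$mu, m$sigma)
    },
    lognormal = qlnorm(u, m$mu, m$sigma))
}

## Population Cliff's delta P(X > Y) - P(X < Y) for independent X ~ mx, Y ~ my
## (continuous marginals, so ties have probability zero):
## delta = 2 * E_x[F_y(X)] - 1, by numeric integration.
marginal_delta <- function(mx, my) {
  hi <- 1.5 * max(marginal_quantile(1 - 1e-9, mx), marginal_quantile(1 - 1e-9, my))
  val <- stats::integrate(function(x) marginal_density(x, mx) * marginal_cdf(x, my),
                          0, hi, rel.tol = 1e-9, subdivisions = 2000L)$value
  2 * val - 1
}

## Spearman correlation induced by a Gaussian copula with latent correlation r
latent_to_spearman <- function(r) (6 / pi) * asin(r / 2)
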