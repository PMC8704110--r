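# Truncated-distribution calibration.
#
# The generator's count distributions are specified by the *observed* moments
# of the population they emulate (mean/SD of a truncated variable), not by the
# latent location/scale of the parent normal or log-normal. These helpers
# solve the inverse problem once, at configuration time.

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and standard deviation of a normal distribution with
#' parent parameters `mu`, `sigma`, truncated to `[lo, hi]`.
#'
#' @param mu,sigma parent normal parameters.
#' @param lo,hi truncation bounds, `lo < hi`.
#' @return list with elements `mean` and `sd`.
#' @keywords internal
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a)
  db <- dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

#' Moments of a truncated log-normal distribution
#' @inheritParams truncnorm_moments
#' @return list with elements `mean` and `sd`.
#' @keywords internal
trunclnorm_moments <- function(mu, sigma, lo, hi) {
  la <- (log(lo) - mu) / sigma
  lb <- (log(hi) - mu) / sigma
  Z <- pnorm(lb) - pnorm(la)
  m1 <- exp(mu + sigma^2 / 2) * (pnorm(lb - sigma) - pnorm(la - sigma)) / Z
  m2 <- exp(2 * mu + 2 * sigma^2) *
    (pnorm(lb - 2 * sigma) - pnorm(la - 2 * sigma)) / Z
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Solve mu such that the truncated mean equals `target_mean`, at fixed sigma.
# The truncated mean is strictly increasing in mu and spans (lo, hi); a
# +/- 5 sigma bracket always encloses the root for interior targets while
# keeping the normalising constant representable.
solve_mu <- function(target_mean, sigma, lo, hi, moments_fun) {
  f <- function(mu) moments_fun(mu, sigma, lo, hi)$mean - target_mean
  uniroot(f, c(lo - 5 * sigma, hi + 5 * sigma), tol = 1e-9)$root
}

solve_mu_ln <- function(target_mean, sigma, lo, hi) {
  f <- function(mu) trunclnorm_moments(mu, sigma, lo, hi)$mean - target_mean
  uniroot(f, c(log(lo) - 5 * sigma, log(hi) + 5 * sigma), tol = 1e-9)$root
}

#' Calibrate a truncated normal to target moments
#'
#' Finds parent `(mu, sigma)` so that the `[lo, hi]`-truncated distribution
#' has mean `target_mean` exactly and standard deviation as close to
#' `target_sd` as the family allows. The mean is matched by a root solve at
#' every candidate sigma; sigma is then chosen to minimise the squared SD gap.
#' A truncated normal on a bounded interval has a supremum SD (the uniform
#' limit `(hi-lo)/sqrt(12)` at the midpoint mean, less for off-centre means),
#' so some printed SDs are only approachable; the achieved moments are
#' returned for inspection.
#'
#' @param target_mean,target_sd moments of the truncated variable.
#' @param lo,hi truncation bounds.
#' @return list: `mu`, `sigma`, `lo`, `hi`, `mean` and `sd` achieved.
#' @keywords internal
calibrate_truncnorm <- function(target_mean, target_sd, lo, hi) {
  stopifnot(lo < hi, target_mean > lo, target_mean < hi, target_sd > 0)
  obj <- function(ls) {
    s <- exp(ls)
    mu <- tryCatch(solve_mu(target_mean, s, lo, hi, truncnorm_moments),
                   error = function(e) NA_real_)
    if (!is.finite(mu)) return(1e6)
    (truncnorm_moments(mu, s, lo, hi)$sd - target_sd)^2
  }
  # sigma band kept finite: past a few target SDs the truncated shape
  # approaches a tilted uniform (diminishing SD gain) and the normal-CDF
  # differences underflow, so the search stays in the stable regime
  ls <- optimize(obj, log(c(target_sd / 5, target_sd * 4)), tol = 1e-7)$minimum
  sigma <- exp(ls)
  mu <- solve_mu(target_mean, sigma, lo, hi, truncnorm_moments)
  got <- truncnorm_moments(mu, sigma, lo, hi)
  list(mu = mu, sigma = sigma, lo = lo, hi = hi,
       mean = got$mean, sd = got$sd)
}

#' Calibrate a truncated log-normal to target moments
#' @inheritParams calibrate_truncnorm
#' @return list: `mu`, `sigma`, `lo`, `hi`, achieved `mean` and `sd`.
#' @keywords internal
calibrate_trunclnorm <- function(target_mean, target_sd, lo, hi) {
  stopifnot(lo > 0, lo < hi, target_mean > lo, target_mean < hi,
            target_sd > 0)
  obj <- function(ls) {
    s <- exp(ls)
    mu <- tryCatch(solve_mu_ln(target_mean, s, lo, hi),
                   error = function(e) NA_real_)
    if (!is.finite(mu)) return(1e6)
    (trunclnorm_moments(mu, s, lo, hi)$sd - target_sd)^2
  }
  ls <- optimize(obj, log(c(0.05, 3)), tol = 1e-7)$minimum
  sigma <- exp(ls)
  mu <- solve_mu_ln(target_mean, sigma, lo, hi)
  got <- trunclnorm_moments(mu, sigma, lo, hi)
  list(mu = mu, sigma = sigma, lo = lo, hi = hi,
       mean = got$mean, sd = got$sd)
}

# Inverse-CDF samplers: deterministic given the R RNG state, never outside
# the truncation bounds.
rtruncnorm_cal <- function(n, cal) {
  u <- runif(n, pnorm((cal$lo - cal$mu) / cal$sigma),
             pnorm((cal$hi - cal$mu) / cal$sigma))
  pmin(pmax(cal$mu + cal$sigma * qnorm(u), cal$lo), cal$hi)
}

rtrunclnorm_cal <- function(n, cal) {
  u <- runif(n, pnorm((log(cal$lo) - cal$mu) / cal$sigma),
             pnorm((log(cal$hi) - cal$mu) / cal$sigma))
  pmin(pmax(exp(cal$mu + cal$sigma * qnorm(u)), cal$lo), cal$hi)
}

# Beta draws parameterised by mean and nominal SD: the mean is exact under
# truncation-free support [0,1], which a truncated normal cannot offer.
rbeta_meansd <- function(n, mean, sd) {
  stopifnot(mean > 0, mean < 1)
  nu <- mean * (1 - mean) / sd^2 - 1
  if (nu <= 0) {
    stop("trait sd ", sd, " too large for mean ", mean,
         " (requires sd^2 < mean*(1-mean))", call. = FALSE)
  }
  rbeta(n, mean * nu, (1 - mean) * nu)
}
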