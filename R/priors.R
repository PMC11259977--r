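#' Fossil calibration with hard minimum and soft maximum
#'
#' The prior on a calibrated node age places probability mass `1 - p_tail`
#' (default 97.5%) uniformly between the hard minimum `t_min` and the soft
#' maximum `t_max` -- equal probability per unit time -- and mass `p_tail`
#' (default 2.5%) in an exponential tail above `t_max`. The tail rate is
#' chosen so the density is continuous at `t_max`:
#' `theta = (1 - p_tail) / (p_tail * (t_max - t_min))`. Mass below `t_min`
#' is exactly zero (hard bound).
#'
#' @param t_min Hard minimum age (100 Myr units).
#' @param t_max Soft maximum age (100 Myr units), `> t_min`.
#' @param p_tail Tail mass above the soft maximum.
#' @return An object of class `calibration`.
#' @export
calibration <- function(t_min, t_max, p_tail = 0.025) {
  if (!(t_min >= 0 && t_min < t_max))
    stop("calibration requires 0 <= t_min < t_max")
  if (!(p_tail > 0 && p_tail < 1)) stop("p_tail must be in (0, 1)")
  body_dens <- (1 - p_tail) / (t_max - t_min)
  structure(list(t_min = t_min, t_max = t_max, p_tail = p_tail,
                 body_dens = body_dens,
                 tail_rate = body_dens / p_tail),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: [%g, %g] (Ma %g-%g), %.1f%% body + %.1f%% tail\n",
              x$t_min, x$t_max, unit_to_ma(x$t_min), unit_to_ma(x$t_max),
              100 * (1 - x$p_tail), 100 * x$p_tail))
  invisible(x)
}

#' Calibration log density
#'
#' @param t Age(s), 100 Myr units.
#' @param cal A [calibration()].
#' @return Log density, vectorized over `t`; `-Inf` below the hard minimum.
#' @export
calibration_log_density <- function(t, cal) {
  stopifnot(inherits(cal, "calibration"))
  out <- rep(-Inf, length(t))
  body <- t >= cal$t_min & t <= cal$t_max
  out[body] <- log(cal$body_dens)
  up <- t > cal$t_max
  out[up] <- log(cal$body_dens) - cal$tail_rate * (t[up] - cal$t_max)
  out
}

#' Calibration cumulative distribution function
#'
#' @inheritParams calibration_log_density
#' @return Probabilities, vectorized over `t`.
#' @export
calibration_cdf <- function(t, cal) {
  stopifnot(inherits(cal, "calibration"))
  out <- numeric(length(t))
  body <- t >= cal$t_min & t <= cal$t_max
  out[body] <- cal$body_dens * (t[body] - cal$t_min)
  up <- t > cal$t_max
  out[up] <- (1 - cal$p_tail) +
    cal$p_tail * (1 - exp(-cal$tail_rate * (t[up] - cal$t_max)))
  out
}

#' Calibration quantile function
#'
#' @param p Probabilities.
#' @param cal A [calibration()].
#' @return Ages (100 Myr), vectorized over `p`.
#' @export
calibration_quantile <- function(p, cal) {
  stopifnot(inherits(cal, "calibration"), all(p >= 0 & p <= 1))
  out <- numeric(length(p))
  pb <- 1 - cal$p_tail
  body <- p <= pb
  out[body] <- cal$t_min + p[body] / cal$body_dens
  up <- !body
  out[up] <- cal$t_max - log1p(-(p[up] - pb) / cal$p_tail) / cal$tail_rate
  out
}

#' Draw ages from a calibration prior
#'
#' @param n Number of draws.
#' @param cal A [calibration()].
#' @return Numeric vector of ages (100 Myr).
#' @export
rcalibration <- function(n, cal) calibration_quantile(runif(n), cal)

#' Birth-death node-age prior
#'
#' Parameters of the birth-death process with incomplete species sampling
#' whose kernel density provides the prior on uncalibrated node ages,
#' conditional on the root age.
#'
#' @param lambda Per-lineage birth rate.
#' @param mu Per-lineage death rate.
#' @param rho Sampling fraction, in (0, 1].
#' @return An object of class `birth_death_prior`.
#' @export
birth_death_prior <- function(lambda = 1, mu = 1, rho = 0.1) {
  stopifnot(lambda > 0, mu > 0, rho > 0, rho <= 1)
  structure(list(lambda = lambda, mu = mu, rho = rho),
            class = "birth_death_prior")
}

# Kernel density g(t | t_root) of one uncalibrated node age under the
# birth-death-with-sampling construction. Equal-rate (lambda == mu) closed
# form used when |lambda - mu| < tol.
bd_kernel_density <- function(t, t_root, bd, tol = 1e-8) {
  la <- bd$lambda; mu <- bd$mu; rho <- bd$rho
  out <- numeric(length(t))
  ok <- t > 0 & t < t_root
  ti <- t[ok]
  if (abs(la - mu) < tol) {
    a <- rho * la
    out[ok] <- (1 + a * t_root) / (t_root * (1 + a * ti)^2)
  } else {
    P0 <- function(s) rho * (la - mu) /
      (rho * la + (la * (1 - rho) - mu) * exp((mu - la) * s))
    p1 <- function(s) P0(s)^2 * exp((mu - la) * s) / rho
    vt1 <- 1 - P0(t_root) * exp((mu - la) * t_root) / rho
    out[ok] <- la * p1(ti) / vt1
  }
  out
}

bd_kernel_cdf <- function(t, t_root, bd, tol = 1e-8) {
  la <- bd$lambda; mu <- bd$mu; rho <- bd$rho
  t <- pmin(pmax(t, 0), t_root)
  if (abs(la - mu) < tol) {
    a <- rho * la
    (1 + a * t_root) * t / (t_root * (1 + a * t))
  } else {
    # closed form: d/ds[-P0(s)e^{(mu-la)s}/(rho*la)] = p1(s), so
    # CDF(t) = (1 - P0(t)e^{(mu-la)t}/rho) / vt1
    P0 <- function(s) rho * (la - mu) /
      (rho * la + (la * (1 - rho) - mu) * exp((mu - la) * s))
    vt1 <- 1 - P0(t_root) * exp((mu - la) * t_root) / rho
    (1 - P0(t) * exp((mu - la) * t) / rho) / vt1
  }
}

#' Draw node ages from the birth-death kernel
#'
#' Inverse-CDF sampling of iid ages conditional on the root age.
#'
#' @param n Number of draws.
#' @param t_root Root age (100 Myr).
#' @param bd A [birth_death_prior()].
#' @return Numeric vector of ages in (0, t_root).
#' @export
rbd_kernel <- function(n, t_root, bd) {
  u <- runif(n)
  if (abs(bd$lambda - bd$mu) < 1e-8) {
    a <- bd$rho * bd$lambda
    u * t_root / (1 + a * t_root - a * u * t_root)
  } else {
    vapply(u, function(ui) {
      uniroot(function(s) bd_kernel_cdf(s, t_root, bd) - ui,
              lower = 0, upper = t_root, tol = 1e-10)$root
    }, numeric(1))
  }
}

#' Birth-death log prior for uncalibrated node ages
#'
#' Log of the product over uncalibrated internal nodes of the kernel density
#' conditional on the root age (Yang-Rannala construction with species
#' sampling).
#'
#' @param ages Ages of the uncalibrated internal nodes (100 Myr).
#' @param t_root Root age (100 Myr).
#' @param bd A [birth_death_prior()].
#' @return Log density; `-Inf` if any age falls outside `(0, t_root)`.
#' @export
birth_death_log_prior <- function(ages, t_root, bd) {
  stopifnot(inherits(bd, "birth_death_prior"))
  if (length(ages) == 0L) return(0)
  if (any(ages <= 0 | ages >= t_root)) return(-Inf)
  sum(log(bd_kernel_density(ages, t_root, bd)))
}

#' Gamma hyperpriors on locus rates and rate variance
#'
#' `rgene`-style gamma prior on the per-locus mean substitution rate (100-Myr
#' time units) and a gamma prior on the clock variance parameter sigma^2.
#'
#' @param alpha_r,beta_r Shape and rate of the locus mean-rate gamma prior.
#'   The default mean `alpha_r/beta_r = 0.05` substitutions/site/100 Myr is a
#'   typical vertebrate amino-acid rate.
#' @param alpha_s,beta_s Shape and rate of the sigma^2 gamma prior
#'   (defaults 1 and 10: exponential with mean 0.1).
#' @return An object of class `rate_hyperpriors`.
#' @export
rate_hyperpriors <- function(alpha_r = 2, beta_r = 40,
                             alpha_s = 1, beta_s = 10) {
  stopifnot(alpha_r > 0, beta_r > 0, alpha_s > 0, beta_s > 0)
  structure(list(alpha_r = alpha_r, beta_r = beta_r,
                 alpha_s = alpha_s, beta_s = beta_s),
            class = "rate_hyperpriors")
}

#' Hyperprior log density
#'
#' @param value Positive parameter value(s).
#' @param which `"locus_rate"` or `"sigma2"`.
#' @param hp A [rate_hyperpriors()].
#' @return Log gamma density; `-Inf` for non-positive values.
#' @export
hyperprior_log_density <- function(value, which = c("locus_rate", "sigma2"),
                                   hp = rate_hyperpriors()) {
  which <- match.arg(which)
  out <- rep(-Inf, length(value))
  ok <- value > 0
  out[ok] <- if (which == "locus_rate")
    dgamma(value[ok], hp$alpha_r, rate = hp$beta_r, log = TRUE)
  else
    dgamma(value[ok], hp$alpha_s, rate = hp$beta_s, log = TRUE)
  out
}
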