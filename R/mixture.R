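#' Fit a two-component normal mixture to site weights by EM
#'
#' Maximum-likelihood decomposition of a weight distribution (values on
#' \[0, 100\]) into two untruncated normal components. Initialization uses
#' the 25th/75th percentiles as component means with equal mixing weights
#' and the pooled standard deviation; EM stops when the log-likelihood gain
#' drops below `tol`. Components are ordered so `mu2 > mu1`; the mixing
#' weight `pi2` of the higher-mean component is the candidate
#' deaminase-attributable fraction. A component standard deviation falling
#' below `sigma_floor` triggers one restart from a perturbed
#' initialization; a second collapse flags the fit as not converged.
#'
#' @param weights Numeric vector of site weights.
#' @param seed Optional seed (used only for the perturbed restart).
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param sigma_floor Smallest admissible component standard deviation, in
#'   weight units.
#' @param n_min Minimum number of observations.
#' @return A `mixture_fit` object with elements `mu1`, `sigma1`, `pi1`,
#'   `mu2`, `sigma2`, `pi2`, `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `n`.
#' @export
fit_two_normal_mixture <- function(weights, seed = NULL, tol = 1e-6,
                                   max_iter = 1000, sigma_floor = 0.5,
                                   n_min = 100) {
  weights <- weights[is.finite(weights)]
  if (length(weights) < n_min) {
    abort(sprintf("need at least %d weights to fit a mixture", n_min))
  }
  run_em <- function(mu, sigma, lambda) {
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    collapsed <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- lambda[1] * dnorm(weights, mu[1], sigma[1])
      d2 <- lambda[2] * dnorm(weights, mu[2], sigma[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      r2 <- d2 / tot
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
      ll_old <- ll
      n2 <- sum(r2); n1 <- length(weights) - n2
      lambda <- c(n1, n2) / length(weights)
      mu <- c(sum((1 - r2) * weights) / n1, sum(r2 * weights) / n2)
      sigma <- sqrt(c(sum((1 - r2) * (weights - mu[1])^2) / n1,
                      sum(r2 * (weights - mu[2])^2) / n2))
      if (any(!is.finite(sigma)) || any(sigma < sigma_floor)) {
        collapsed <- TRUE
        break
      }
    }
    list(mu = mu, sigma = sigma, lambda = lambda, loglik = ll, trace = trace,
         n_iter = it, converged = converged, collapsed = collapsed)
  }
  q <- quantile(weights, c(0.25, 0.75), names = FALSE)
  s0 <- max(sd(weights), sigma_floor)
  fit <- run_em(q, c(s0, s0), c(0.5, 0.5))
  if (fit$collapsed) {
    jitter <- with_seed_(seed, stats::rnorm(2, 0, s0 / 4))
    fit <- run_em(q + jitter, c(s0, s0) * 1.5, c(0.5, 0.5))
    if (fit$collapsed) fit$converged <- FALSE
  }
  ord <- order(fit$mu)
  out <- list(
    mu1 = fit$mu[ord[1]], sigma1 = fit$sigma[ord[1]], pi1 = fit$lambda[ord[1]],
    mu2 = fit$mu[ord[2]], sigma2 = fit$sigma[ord[2]], pi2 = fit$lambda[ord[2]],
    loglik = fit$loglik, loglik_trace = fit$trace, n_iter = fit$n_iter,
    converged = fit$converged, n = length(weights)
  )
  class(out) <- "mixture_fit"
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit: n=%d, %s after %d iter>\n  low : mu=%.2f sd=%.2f pi=%.3f\n  high: mu=%.2f sd=%.2f pi=%.3f (candidate fraction)\n",
    x$n, if (x$converged) "converged" else "NOT converged", x$n_iter,
    x$mu1, x$sigma1, x$pi1, x$mu2, x$sigma2, x$pi2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mixture_fit <- function(x, ...) {
  tibble(component = c("low", "high"),
         mean = c(x$mu1, x$mu2), sd = c(x$sigma1, x$sigma2),
         weight = c(x$pi1, x$pi2))
}

#' @exportS3Method generics::glance
glance.mixture_fit <- function(x, ...) {
  tibble(loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
         n = x$n, fraction = x$pi2)
}

mixture_cdf <- function(fit, q) {
  fit$pi1 * pnorm(q, fit$mu1, fit$sigma1) +
    fit$pi2 * pnorm(q, fit$mu2, fit$sigma2)
}

#' Chi-squared goodness of fit of a mixture to binned weights
#'
#' Weights are binned into \[0,10), \[10,20), ..., \[90,100\]; expected
#' counts come from the fitted mixture CDF (tail mass folded into the
#' outermost bins). Adjacent bins are pooled until every expected count is
#' at least 5; degrees of freedom are bins - 1 - 5 (five free parameters),
#' floored at 1.
#'
#' @param fit A `mixture_fit`.
#' @param weights The data the fit was estimated from.
#' @param binwidth Bin width in weight units.
#' @return One-row tibble: `chi2`, `df`, `p`, `n_bins`.
#' @export
goodness_of_fit <- function(fit, weights, binwidth = 10) {
  stopifnot(inherits(fit, "mixture_fit"))
  breaks <- seq(0, 100, by = binwidth)
  obs <- as.numeric(table(cut(weights, breaks, right = FALSE,
                              include.lowest = FALSE)))
  # the closed top of the last bin
  obs[length(obs)] <- obs[length(obs)] + sum(weights == 100)
  inner <- breaks[-c(1, length(breaks))]
  cdf <- c(0, mixture_cdf(fit, inner), 1) # fold tails into end bins
  expct <- fit$n * diff(cdf)
  # pool adjacent bins left to right until every expected count >= 5
  pooled_o <- numeric(0); pooled_e <- numeric(0)
  acc_o <- 0; acc_e <- 0
  for (k in seq_along(expct)) {
    acc_o <- acc_o + obs[k]; acc_e <- acc_e + expct[k]
    if (acc_e >= 5) {
      pooled_o <- c(pooled_o, acc_o); pooled_e <- c(pooled_e, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0) { # fold any remainder into the last pooled bin
    if (length(pooled_e) == 0) abort("distribution too narrow")
    pooled_o[length(pooled_o)] <- pooled_o[length(pooled_o)] + acc_o
    pooled_e[length(pooled_e)] <- pooled_e[length(pooled_e)] + acc_e
  }
  if (length(pooled_e) < 3) abort("distribution too narrow")
  chi2 <- sum((pooled_o - pooled_e)^2 / pooled_e)
  df <- max(length(pooled_e) - 1 - 5, 1)
  tibble(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
         n_bins = length(pooled_e), n_obs = sum(pooled_o))
}

#' Estimate the deaminase-attributable mutation fraction
#'
#' Fits the two-normal mixture and returns the mixing weight of the
#' higher-mean component, gated by the chi-squared goodness-of-fit test:
#' the estimate is NA when the fit did not converge or when the observed
#' and expected binned distributions differ significantly (GOF p < 0.05).
#' A boundary-pileup warning is flagged when the last weight bin holds more
#' than twice the count of its neighbor — the failure mode in which mass
#' piled against the upper boundary distorts the normal components.
#'
#' @param weights Numeric site weights in \[0, 100\].
#' @param seed Optional seed for the EM restart path.
#' @param gof_alpha GOF gate level.
#' @param ... Passed to [fit_two_normal_mixture()].
#' @return Numeric fraction or NA, with attributes `fit` (the
#'   `mixture_fit`), `gof` (the GOF tibble) and `boundary_pileup` (logical).
#' @export
estimate_fraction <- function(weights, seed = NULL, gof_alpha = 0.05, ...) {
  fit <- fit_two_normal_mixture(weights, seed = seed, ...)
  gof <- tryCatch(goodness_of_fit(fit, weights), error = function(e) NULL)
  counts <- as.numeric(table(cut(weights, seq(0, 100, 10), right = FALSE)))
  counts[10] <- counts[10] + sum(weights == 100)
  pileup <- counts[10] > 2 * counts[9]
  if (pileup) warn("boundary pileup: last weight bin exceeds its neighbor >2x")
  frac <- if (!fit$converged || is.null(gof) || gof$p < gof_alpha) {
    NA_real_
  } else {
    fit$pi2
  }
  structure(frac, fit = fit, gof = gof, boundary_pileup = pileup)
}
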