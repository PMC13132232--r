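# Detection-probability prior: distance-bin averaging of double-observer
# detection estimates and Beta moment matching. Detection here is the
# unconditional probability that a group present in the strip is recorded,
# including groups missed by all observers.

#' Average detection over equal-width distance bins
#'
#' Survey design places groups uniformly in distance from the trackline, so
#' equal-width distance bins get equal weight. Each bin supplies a mean and a
#' symmetric 95% interval; the per-bin SE is approximated as the interval
#' range divided by `2 * 1.96`. The pooled mean is the unweighted mean of bin
#' means and the pooled variance is the unweighted mean of bin variances
#' (per-observation detection uncertainty, not the variance of the mean).
#'
#' @param bins data.frame with columns `mean`, `ci_low`, `ci_high`.
#' @return list with `mean` and `sd`.
#' @export
average_detection_bins <- function(bins) {
  stopifnot(nrow(bins) >= 1)
  if (any(bins$ci_high < bins$ci_low))
    stop("ci_high < ci_low in detection bins", call. = FALSE)
  if (any(bins$mean < 0 | bins$mean > 1))
    stop("bin means must lie in [0, 1]", call. = FALSE)
  se <- (bins$ci_high - bins$ci_low) / (2 * 1.96)
  list(mean = mean(bins$mean), sd = sqrt(mean(se^2)))
}

#' Moment-matched Beta prior
#'
#' Matches a Beta(alpha, beta) to a mean `m` and standard deviation `s` via
#' `nu = m (1 - m) / s^2 - 1`, `alpha = m nu`, `beta = (1 - m) nu`. Requires
#' `0 < m < 1` and `s^2 < m (1 - m)`.
#'
#' @param mean,sd prior moments of the detection rate.
#' @param source optional provenance note stored with the prior.
#' @return `beta_prior` object with `alpha`, `beta`, `mean`, `sd`.
#' @export
beta_from_moments <- function(mean, sd, source = NULL) {
  m <- mean; s <- sd
  if (!(m > 0 && m < 1)) stop("mean must lie in (0, 1)", call. = FALSE)
  if (!(s > 0)) stop("sd must be > 0", call. = FALSE)
  if (s^2 >= m * (1 - m))
    stop(sprintf("infeasible moments: s^2 = %.4g >= m(1-m) = %.4g",
                 s^2, m * (1 - m)), call. = FALSE)
  nu <- m * (1 - m) / s^2 - 1
  structure(list(alpha = m * nu, beta = (1 - m) * nu, mean = m, sd = s,
                 source = source),
            class = "beta_prior")
}

#' Beta prior from explicit shape parameters
#' @param alpha,beta shape parameters (> 0).
#' @param source optional provenance note.
#' @export
beta_prior <- function(alpha, beta, source = NULL) {
  stopifnot(alpha > 0, beta > 0)
  m <- alpha / (alpha + beta)
  v <- alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1))
  structure(list(alpha = alpha, beta = beta, mean = m, sd = sqrt(v),
                 source = source),
            class = "beta_prior")
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(sprintf("Beta(%.3f, %.3f) detection prior: mean %.3f, sd %.3f\n",
              x$alpha, x$beta, x$mean, x$sd))
  if (!is.null(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Quantiles of a detection prior
#' @param prior `beta_prior`; @param probs probabilities in (0, 1).
#' @export
prior_quantiles <- function(prior, probs = c(0.05, 0.5, 0.95)) {
  stopifnot(all(probs > 0 & probs < 1))
  stats::qbeta(probs, prior$alpha, prior$beta)
}
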