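# Negative-binomial penalized-spline GAM fitting.
#
# Inner loop: penalized iteratively reweighted least squares (Fisher
# scoring with step halving) for the coefficients at fixed smoothing
# parameters and dispersion. Outer loop: Laplace-approximate restricted
# marginal likelihood (REML) maximized over (log lambda, log theta) by
# Nelder-Mead. The response is NB2 with variance mu + mu^2/theta, log link,
# and log segment area as offset, so the linear predictor is log expected
# count per km^2.

nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

chol_solve <- function(H, b) {
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) R <- chol(H + diag(1e-8 * mean(diag(H)), nrow(H)))
  backsolve(R, forwardsolve(t(R), b))
}

#' Penalized IRLS for a negative-binomial GAM at fixed penalties
#'
#' Maximizes the penalized log-likelihood
#' `l(beta) - 0.5 * t(beta) %*% S %*% beta` for counts
#' `y ~ NB(mu = exp(X beta + offset), theta)` by Fisher-scoring IRLS with
#' step halving. This is the engine's inner loop, exported so that it can be
#' checked directly against brute-force maximization.
#'
#' @param X design matrix; @param y counts; @param offset log-area vector;
#' @param S total (already lambda-weighted) penalty matrix;
#' @param theta NB dispersion (> 0; variance `mu + mu^2/theta`).
#' @param beta optional warm start.
#' @param maxit,tol iteration cap and relative penalized-likelihood
#'   convergence tolerance.
#' @param polish extra Newton steps taken after convergence (quadratic
#'   contraction pushes the coefficients to near machine accuracy).
#' @return list: beta, eta, mu, w (working weights), H (penalized Fisher
#'   information), XtWX, loglik, penll, iter, converged.
#' @export
nb_pirls <- function(X, y, offset, S, theta, beta = NULL,
                     maxit = 200, tol = 1e-8, polish = 2L) {
  p <- ncol(X)
  if (is.null(beta)) {
    beta <- rep(0, p)
    beta[1] <- log(max(sum(y), 0.5) / sum(exp(offset)))
  }
  eta_of <- function(b) pmin(pmax(X %*% b + offset, -30), 30)
  pen_of <- function(b) 0.5 * sum(b * (S %*% b))
  eta <- eta_of(beta)
  penll <- nb_loglik(y, exp(eta), theta) - pen_of(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- pmax(exp(eta), 1e-10)
    w <- as.numeric(mu * theta / (mu + theta))
    z <- (eta - offset) + (y - mu) / mu
    Xw <- X * w
    XtWX <- crossprod(X, Xw)
    H <- XtWX + S
    beta_new <- as.numeric(chol_solve(H, crossprod(Xw, z)))
    # step halving to guarantee penalized-likelihood ascent
    step <- 1
    repeat {
      b_try <- beta + step * (beta_new - beta)
      eta_try <- eta_of(b_try)
      pl_try <- nb_loglik(y, exp(eta_try), theta) - pen_of(b_try)
      if (is.finite(pl_try) && pl_try >= penll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { b_try <- beta; eta_try <- eta; pl_try <- penll; break }
    }
    dl <- abs(pl_try - penll)
    beta <- b_try; eta <- eta_try
    penll <- pl_try
    if (dl < tol * (abs(penll) + 0.1)) {
      converged <- TRUE
      if (polish > 0L) { polish <- polish - 1L; next }  # quadratic cleanup
      break
    }
  }
  mu <- pmax(exp(eta), 1e-10)
  w <- as.numeric(mu * theta / (mu + theta))
  XtWX <- crossprod(X, X * w)
  list(beta = beta, eta = as.numeric(eta), mu = as.numeric(mu), w = w,
       H = XtWX + S, XtWX = XtWX,
       loglik = nb_loglik(y, mu, theta), penll = penll,
       iter = it, converged = converged)
}

# Laplace-approximate restricted marginal likelihood at rho =
# (log lambda_1..m, log theta). S_emb: list of p x p embedded penalties;
# rankS: rank of the summed penalty (fixed across lambda > 0).
make_laml <- function(X, y, offset, S_emb, rankS, pirls_tol = 1e-8) {
  p <- ncol(X)
  Mp <- p - rankS
  warm <- new.env(parent = emptyenv())
  warm$beta <- NULL
  m <- length(S_emb)
  function(rho) {
    if (any(abs(rho) > 18)) return(1e10)
    lam <- exp(rho[seq_len(m)])
    theta <- exp(rho[m + 1])
    Slam <- matrix(0, p, p)
    for (j in seq_len(m)) Slam <- Slam + lam[j] * S_emb[[j]]
    fit <- tryCatch(
      nb_pirls(X, y, offset, Slam, theta, beta = warm$beta, tol = pirls_tol),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$beta))) {
      warm$beta <- NULL
      return(1e10)
    }
    warm$beta <- fit$beta
    ldetH <- tryCatch(2 * sum(log(diag(chol(fit$H)))), error = function(e) NA)
    if (!is.finite(ldetH)) return(1e10)
    ldetS <- if (rankS > 0) {
      ev <- sort(eigen(Slam, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)[seq_len(rankS)]
      if (any(ev <= 0)) return(1e10)
      sum(log(ev))
    } else 0
    laml <- fit$penll + 0.5 * ldetS - 0.5 * ldetH + 0.5 * Mp * log(2 * pi)
    if (!is.finite(laml)) return(1e10)
    -laml
  }
}

#' Fit a negative-binomial spatio-temporal GAM
#'
#' @param spec model specification from [model_spec()] / [model_preset()].
#' @param data segment table (or data.frame) with columns `x_c`, `y_c`,
#'   `year`, `count`, `area`, plus `observer` / `survey_id` when the spec
#'   uses them.
#' @param control list: `outer_maxit` (Nelder-Mead iterations, default 500),
#'   `outer_reltol` (1e-6), `pirls_tol` (1e-8), `theta0` (starting
#'   dispersion, default moment-based).
#' @return `nbgam` object: coefficients `beta`, Bayesian covariance `V_b`,
#'   smoothing parameters `lambda`, dispersion `theta`, per-term and total
#'   effective degrees of freedom, log-likelihood and AIC (trace-edf based),
#'   term map, and the standardization/basis metadata needed for prediction.
#' @export
nb_gam <- function(spec, data, control = list()) {
  ctrl <- utils::modifyList(list(outer_maxit = 500, outer_reltol = 1e-6,
                                 pirls_tol = 1e-8, theta0 = NULL), control)
  data <- as.data.frame(data)
  need <- c("x_c", "y_c", "year", "count", "area")
  check_columns(data, need, "model data")
  y <- as.numeric(data$count)
  if (all(y == 0)) stop("all counts are zero: degenerate likelihood", call. = FALSE)
  if (any(data$area <= 0)) stop("segment areas must be > 0", call. = FALSE)
  offset <- log(data$area)
  des <- build_design(spec, data)
  X <- des$X
  p <- ncol(X)
  S_emb <- lapply(des$S, embed_S, p = p)
  m <- length(S_emb)
  rankS <- if (m > 0) {
    Ssum <- Reduce(`+`, S_emb)
    ev <- eigen(Ssum, symmetric = TRUE, only.values = TRUE)$values
    sum(ev > max(ev) * 1e-9)
  } else 0L
  theta0 <- ctrl$theta0
  if (is.null(theta0)) {
    mbar <- mean(y); v <- stats::var(y)
    theta0 <- if (is.finite(v) && v > mbar) mbar^2 / (v - mbar) else 1
    theta0 <- min(max(theta0, 0.1), 10)
  }
  fn <- make_laml(X, y, offset, S_emb, rankS, pirls_tol = ctrl$pirls_tol)
  if (m > 0) {
    par0 <- c(rep(0, m), log(theta0))
    opt <- stats::optim(par0, fn, method = "Nelder-Mead",
                        control = list(maxit = ctrl$outer_maxit,
                                       reltol = ctrl$outer_reltol))
    # restart from the optimum: a fresh simplex escapes premature collapse
    # along flat penalty directions (e.g. random effects shrinking away)
    opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                         control = list(maxit = ctrl$outer_maxit,
                                        reltol = ctrl$outer_reltol))
    if (opt2$value <= opt$value) opt <- opt2
  } else {
    opt <- stats::optim(log(theta0), fn, method = "Brent",
                        lower = -12, upper = 12)
    opt$par <- c(numeric(0), opt$par)
  }
  lam <- exp(opt$par[seq_len(m)])
  theta <- exp(opt$par[m + 1])
  Slam <- matrix(0, p, p)
  for (j in seq_len(m)) Slam <- Slam + lam[j] * S_emb[[j]]
  fit <- nb_pirls(X, y, offset, Slam, theta, tol = ctrl$pirls_tol)
  if (!fit$converged)
    stop("penalized IRLS failed to converge at the selected smoothing parameters",
         call. = FALSE)
  V_b <- chol_solve(fit$H, diag(p))
  V_b <- (V_b + t(V_b)) / 2
  edf_i <- rowSums(V_b * fit$XtWX)       # diag(V_b %*% XtWX), symmetric XtWX
  edf_term <- vapply(des$term_map, function(cols) sum(edf_i[cols]), numeric(1))
  names(lam) <- des$S_labels
  out <- list(beta = fit$beta, V_b = V_b, lambda = lam, theta = theta,
              edf = sum(edf_i), edf_term = edf_term, edf_i = edf_i,
              loglik = fit$loglik,
              aic = -2 * fit$loglik + 2 * sum(edf_i),
              term_map = des$term_map, spec = spec, info = des$info,
              Slam = Slam, X = X, y = y, offset = offset,
              fitted = fit$mu, w = fit$w,
              laml = -opt$value, outer_convergence = opt$convergence,
              n = length(y),
              basis = "tensor-product cubic B-splines, 2nd-order difference penalties")
  class(out) <- "nbgam"
  out
}

#' @export
print.nbgam <- function(x, ...) {
  labs <- vapply(x$spec$terms, `[[`, "", "label")
  cat("Negative-binomial GAM: Count ~", paste(labs, collapse = " + "), "\n")
  cat(sprintf("  n = %d, edf = %.2f, theta = %.3f, logLik = %.2f, AIC(edf) = %.2f\n",
              x$n, x$edf, x$theta, x$loglik, x$aic))
  cat("  per-term edf:\n")
  for (nm in names(x$edf_term))
    cat(sprintf("    %-14s %6.2f\n", nm, x$edf_term[[nm]]))
  cat("  basis:", x$basis, "\n")
  invisible(x)
}

#' @export
logLik.nbgam <- function(object, ...) {
  structure(object$loglik, df = object$edf, class = "logLik")
}

#' @export
coef.nbgam <- function(object, ...) object$beta

#' @export
vcov.nbgam <- function(object, ...) object$V_b

#' Predict from a fitted density GAM
#'
#' Builds the prediction design matrix with the fitted bases and
#' standardization, optionally zeroing the columns of excluded terms (e.g.
#' `exclude = "s(Year)"` for a year-averaged spatial surface). The offset is
#' never added: link-scale predictions are log density per km^2 and
#' `type = "response"` gives density per km^2.
#'
#' Years beyond the fitted factor levels are only allowed for a year random
#' effect when the model also carries a temporal smooth (the random effect
#' then sits at its prior mean 0); a pure random-effect year model refuses
#' extrapolation.
#'
#' @param object fitted `nbgam`; @param newdata data.frame with `x_c`,
#'   `y_c`, `year` and any factor columns the spec needs; @param type
#'   `"link"`, `"response"` or `"lpmatrix"`; @param exclude character vector
#'   of term labels to zero out.
#' @param ... unused.
#' @return vector of predictions, or the prediction matrix for
#'   `type = "lpmatrix"`.
#' @export
predict.nbgam <- function(object, newdata, type = c("link", "response", "lpmatrix"),
                          exclude = character(0), ...) {
  type <- match.arg(type)
  labs <- names(object$term_map)
  bad <- setdiff(exclude, labs)
  if (length(bad))
    stop("unknown term label(s) in exclude: ", paste(bad, collapse = ", "),
         call. = FALSE)
  types <- vapply(object$spec$terms, `[[`, "", "type")
  if ("observer_re" %in% types && !"s(Observer)" %in% exclude &&
      is.null(newdata$observer))
    stop("newdata needs an observer column (or exclude 's(Observer)')",
         call. = FALSE)
  nd <- as.data.frame(newdata)
  if (!"observer" %in% names(nd)) nd$observer <- NA_character_
  des <- build_design(object$spec, nd, info = object$info)
  if (des$new_year_levels && !"temporal" %in% types &&
      !"s(fYear)" %in% exclude)
    stop(paste("prediction years outside the fitted series need a temporal",
               "smooth; a year random effect alone cannot extrapolate"),
         call. = FALSE)
  Xp <- des$X
  for (lab in exclude) Xp[, object$term_map[[lab]]] <- 0
  if (type == "lpmatrix") return(Xp)
  eta <- as.numeric(Xp %*% object$beta)
  if (type == "response") exp(eta) else eta
}

#' Rank candidate models by AIC
#'
#' AIC uses the trace-based effective degrees of freedom
#' (`-2 logLik + 2 edf`, "edf-AIC"). Candidates that fail to converge are
#' reported and excluded, not fatal. Ties in AIC break toward the smaller
#' edf.
#'
#' @param specs named list of `nbgam_spec` objects.
#' @param data model data as in [nb_gam()].
#' @param control passed to [nb_gam()].
#' @return data.frame (model, edf, AIC, dAIC) sorted by AIC, with the fits
#'   in a `fits` attribute.
#' @export
select_models <- function(specs, data, control = list()) {
  stopifnot(length(specs) >= 1)
  if (is.null(names(specs))) names(specs) <- paste0("model", seq_along(specs))
  fits <- list()
  rows <- list()
  for (nm in names(specs)) {
    f <- tryCatch(nb_gam(specs[[nm]], data, control = control),
                  error = function(e) e)
    if (inherits(f, "error")) {
      message(sprintf("model %s failed: %s", nm, conditionMessage(f)))
      next
    }
    fits[[nm]] <- f
    rows[[nm]] <- data.frame(model = nm, edf = f$edf, AIC = f$aic)
  }
  if (!length(rows)) stop("no candidate model converged", call. = FALSE)
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC, tab$edf), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  structure(tab, fits = fits)
}

#' Randomized-quantile residual diagnostics
#'
#' Randomized quantile residuals for the fitted NB model (uniform draw
#' between the NB CDF at `y - 1` and at `y`, mapped through the standard
#' normal quantile function), plus the observed/expected zero fraction and
#' the Pearson dispersion ratio.
#'
#' @param fit fitted `nbgam`; @param seed RNG seed for the randomization.
#' @return list: residuals, zero_obs, zero_exp, zero_ratio,
#'   dispersion_ratio.
#' @export
quantile_residuals <- function(fit, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- fit$y; mu <- fit$fitted; th <- fit$theta
  lo <- stats::pnbinom(y - 1, size = th, mu = mu)
  hi <- stats::pnbinom(y, size = th, mu = mu)
  u <- stats::runif(length(y), lo, hi)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  r <- stats::qnorm(u)
  zero_exp <- mean(stats::dnbinom(0, size = th, mu = mu))
  zero_obs <- mean(y == 0)
  pearson <- sum((y - mu)^2 / (mu + mu^2 / th))
  list(residuals = r, zero_obs = zero_obs, zero_exp = zero_exp,
       zero_ratio = zero_obs / zero_exp,
       dispersion_ratio = pearson / (fit$n - fit$edf))
}
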