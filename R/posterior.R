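# Posterior simulation of population totals: prediction grids, coefficient
# sampling (direct MVN and Metropolis-Hastings on the Laplace posterior),
# grid totals, Beta detection correction, and geometric-mean growth-rate
# trends.

#' Build a prediction grid over a study area
#'
#' Axis-aligned square lattice of `cell_km` cells clipped to each stratum
#' polygon; boundary cells carry their clipped area (<= cell_km^2) and the
#' centroid of the clipped cell is the prediction point. The summed cell
#' area reproduces the study-area total to 0.1%.
#'
#' @param area `study_area`; @param cell_km cell edge in km (default 1);
#' @param years years the grid will be replicated over at prediction time.
#' @return `pred_grid`: list with `cells` (cell_id, stratum, x_c, y_c, area)
#'   and `years`.
#' @export
make_grid <- function(area, cell_km = 1, years) {
  stopifnot(cell_km > 0)
  cells <- list()
  for (s in names(area$polygons)) {
    v <- area$polygons[[s]]
    bb <- apply(v, 2, range)
    xs <- seq(floor(bb[1, 1] / cell_km) * cell_km, bb[2, 1], by = cell_km)
    ys <- seq(floor(bb[1, 2] / cell_km) * cell_km, bb[2, 2], by = cell_km)
    for (x0 in xs) for (y0 in ys) {
      cp <- clip_poly_rect(v, x0, x0 + cell_km, y0, y0 + cell_km)
      if (nrow(cp) < 3) next
      a <- poly_area(cp)
      if (a <= 1e-12) next
      ct <- poly_centroid(cp)
      cells[[length(cells) + 1]] <- data.frame(
        stratum = s, x_c = ct[1], y_c = ct[2], area = a)
    }
  }
  if (!length(cells)) stop("degenerate study area: no grid cells", call. = FALSE)
  cells <- do.call(rbind, cells)
  cells$cell_id <- seq_len(nrow(cells))
  tot <- sum(cells$area)
  if (abs(tot - area$total_area) > 1e-3 * area$total_area)
    stop(sprintf("grid area %.4f km^2 does not match study area %.4f km^2",
                 tot, area$total_area), call. = FALSE)
  structure(list(cells = cells, years = years, cell_km = cell_km),
            class = "pred_grid")
}

#' Draw GAM coefficients from the multivariate-normal posterior
#'
#' Direct simulation from `MVN(beta_hat, V_b)` via a symmetric eigen
#' factorization with negative eigenvalues clipped to zero.
#'
#' @param fit fitted `nbgam`; @param n_draws number of draws (default 500);
#' @param seed RNG seed.
#' @return `n_draws x p` matrix of coefficient draws.
#' @export
sample_coef_mvn <- function(fit, n_draws = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(fit$beta)
  eg <- eigen(fit$V_b, symmetric = TRUE)
  rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  Z <- matrix(stats::rnorm(n_draws * p), n_draws, p)
  sweep(Z %*% rt, 2, fit$beta, `+`)
}

#' Draw GAM coefficients by Metropolis-Hastings
#'
#' Samples the Laplace posterior proportional to
#' `exp(loglik(beta) - 0.5 t(beta) S beta)` by alternating a heavy-tailed
#' independence proposal (multivariate t centred at `beta_hat`, scaled
#' `V_b`) with random-walk steps (scaled `V_b`). Preferable to direct MVN
#' simulation for sparse surveys, where large zero regions make the
#' quadratic approximation poor in the tails.
#'
#' @param fit fitted `nbgam`; @param n_draws retained draws; @param burnin
#'   discarded initial draws; @param thin thinning interval; @param t_df
#'   degrees of freedom of the t proposal; @param t_scale,rw_scale proposal
#'   scales (multiples of the `V_b` factor); @param seed RNG seed.
#' @return draws matrix with acceptance rates in an `acceptance` attribute.
#' @export
sample_coef_mh <- function(fit, n_draws = 500, burnin = 500, thin = 1,
                           t_df = 40, t_scale = 1, rw_scale = 0.25,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(fit$beta)
  eg <- eigen(fit$V_b, symmetric = TRUE)
  rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  rti <- eg$vectors %*% ((1 / sqrt(pmax(eg$values, 1e-12))) * t(eg$vectors))
  X <- fit$X; y <- fit$y; off <- fit$offset; S <- fit$Slam; th <- fit$theta
  logpost <- function(b) {
    eta <- pmin(pmax(X %*% b + off, -30), 30)
    nb_loglik(y, exp(eta), th) - 0.5 * sum(b * (S %*% b))
  }
  # log density of the multivariate-t independence proposal (up to const)
  logq <- function(b) {
    u <- as.numeric(rti %*% (b - fit$beta)) / t_scale
    -0.5 * (t_df + p) * log1p(sum(u^2) / t_df)
  }
  b <- fit$beta
  lp <- logpost(b)
  total <- burnin + n_draws * thin
  out <- matrix(NA_real_, n_draws, p)
  acc <- c(t = 0, rw = 0); ntry <- c(t = 0, rw = 0)
  kept <- 0
  for (i in seq_len(total)) {
    if (i %% 2 == 1) {
      u <- stats::rnorm(p) / sqrt(stats::rchisq(1, t_df) / t_df)
      prop <- fit$beta + as.numeric(rt %*% u) * t_scale
      lr <- logpost(prop) - lp + logq(b) - logq(prop)
      ntry["t"] <- ntry["t"] + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        b <- prop; lp <- logpost(b); acc["t"] <- acc["t"] + 1
      }
    } else {
      prop <- b + as.numeric(rt %*% stats::rnorm(p)) * rw_scale
      lr <- logpost(prop) - lp
      ntry["rw"] <- ntry["rw"] + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        b <- prop; lp <- lr + lp; acc["rw"] <- acc["rw"] + 1
      }
    }
    if (i > burnin && (i - burnin) %% thin == 0) {
      kept <- kept + 1
      out[kept, ] <- b
    }
  }
  rate <- acc / pmax(ntry, 1)
  if (any(rate < 0.01))
    warning(sprintf("low MH acceptance (t: %.3f, rw: %.3f)", rate["t"], rate["rw"]))
  structure(out, acceptance = rate)
}

#' Expected population totals from coefficient draws
#'
#' For each coefficient draw `b_i` and year `j`, the expected total of
#' indicated pairs is `Y_ij = sum_k area_k * exp(x_jk' b_i)` over the grid
#' cells. These are expectations of the count model, so they are strictly
#' positive. Observer effects are excluded automatically (population-level
#' prediction); the survey factor, when present, is fixed at `survey` (the
#' baseline level by default, i.e. the survey for which detection was
#' estimated).
#'
#' @param fit fitted `nbgam`; @param draws coefficient draw matrix;
#' @param grid `pred_grid`; @param years years to total over (default the
#'   grid's); @param survey survey factor level for prediction; @param
#'   exclude extra term labels to exclude.
#' @return `posterior_totals` object: `index` (draws x years matrix of
#'   expected indicated pairs), `years`.
#' @export
posterior_totals <- function(fit, draws, grid, years = NULL, survey = NULL,
                             exclude = character(0)) {
  if (is.null(years)) years <- grid$years
  types <- vapply(fit$spec$terms, `[[`, "", "type")
  if ("observer_re" %in% types) exclude <- union(exclude, "s(Observer)")
  cells <- grid$cells
  nd <- cells[rep(seq_len(nrow(cells)), times = length(years)), ]
  nd$year <- rep(years, each = nrow(cells))
  if ("survey" %in% types) {
    lev <- fit$info$metas[[which(types == "survey")]]$levels
    nd$survey_id <- if (is.null(survey)) lev[1] else survey
  }
  Xp <- predict(fit, nd, type = "lpmatrix", exclude = exclude)
  eta <- tcrossprod(Xp, draws)               # (cells*years) x draws
  eta <- pmin(eta, 30)
  a <- cells$area
  Y <- matrix(NA_real_, nrow(draws), length(years))
  for (j in seq_along(years)) {
    rows <- (j - 1) * nrow(cells) + seq_len(nrow(cells))
    Y[, j] <- as.numeric(crossprod(exp(eta[rows, , drop = FALSE]), a))
  }
  colnames(Y) <- years
  structure(list(index = Y, years = years), class = "posterior_totals")
}

#' Apply a detection correction to index totals
#'
#' One detection draw `d_i` per posterior draw, held constant across years
#' within a draw, converts the indicated-pair index to indicated breeding
#' birds: `N_ij = 2 * Y_ij / d_i`.
#'
#' @param totals `posterior_totals`; @param prior `beta_prior` for the
#'   detection rate; @param d optional fixed detection rate (overrides the
#'   prior, e.g. `d = 1` for no correction); @param seed RNG seed.
#' @return the object with `corrected` (draws x years) and `d` added.
#' @export
detection_correct <- function(totals, prior = NULL, d = NULL, seed = NULL) {
  n <- nrow(totals$index)
  if (is.null(d)) {
    if (is.null(prior)) stop("supply a beta_prior or a fixed d", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    d <- stats::rbeta(n, prior$alpha, prior$beta)
  } else {
    d <- rep(d, length.out = n)
  }
  totals$corrected <- 2 * totals$index / d
  totals$d <- d
  totals
}

#' Posterior draws of the geometric-mean growth rate
#'
#' Per-draw log trend between year `j` and `j + t`:
#' `T_i = (log N_{i,j+t} - log N_{i,j}) / t`. A constant-within-draw
#' detection correction cancels exactly, so index and corrected totals give
#' identical trends draw by draw.
#'
#' @param totals `posterior_totals` (corrected totals used when present);
#' @param start_year year `j`; @param lag `t >= 1`.
#' @return list: `draws` (per-draw trend), `mean`, `median`, `q025`, `q975`.
#' @export
trend_draws <- function(totals, start_year, lag) {
  stopifnot(lag >= 1)
  M <- if (!is.null(totals$corrected)) totals$corrected else totals$index
  j0 <- match(start_year, totals$years)
  j1 <- match(start_year + lag, totals$years)
  if (is.na(j0) || is.na(j1))
    stop("both trend endpoint years must be in the prediction years", call. = FALSE)
  tr <- (log(M[, j1]) - log(M[, j0])) / lag
  list(draws = tr, mean = mean(tr), median = stats::median(tr),
       q025 = unname(stats::quantile(tr, 0.025)),
       q975 = unname(stats::quantile(tr, 0.975)))
}

#' Per-year posterior summary
#'
#' @param M draws x years matrix (or a `posterior_totals` object, in which
#'   case the corrected totals are summarized when present);
#' @param years optional year labels.
#' @return data.frame: year, mean, median, q025, q975 (type-7 quantiles).
#' @export
summarize_draws <- function(M, years = NULL) {
  if (inherits(M, "posterior_totals")) {
    years <- M$years
    M <- if (!is.null(M$corrected)) M$corrected else M$index
  }
  stopifnot(nrow(M) >= 2)
  if (is.null(years)) years <- colnames(M)
  if (is.null(years)) years <- seq_len(ncol(M))
  data.frame(year = as.numeric(years),
             mean = colMeans(M),
             median = apply(M, 2, stats::median),
             q025 = apply(M, 2, stats::quantile, probs = 0.025),
             q975 = apply(M, 2, stats::quantile, probs = 0.975),
             row.names = NULL)
}

#' Write a gridded density surface as CSV
#'
#' Cell-level density (per km^2) for a given year, for mapping.
#'
#' @param fit fitted `nbgam`; @param grid `pred_grid`; @param year year to
#'   predict; @param path CSV destination; @param exclude term labels to
#'   exclude (e.g. year terms for an average surface); @param survey survey
#'   level.
#' @return the cell data.frame, invisibly when written.
#' @export
density_surface <- function(fit, grid, year, path = NULL,
                            exclude = character(0), survey = NULL) {
  types <- vapply(fit$spec$terms, `[[`, "", "type")
  if ("observer_re" %in% types) exclude <- union(exclude, "s(Observer)")
  nd <- grid$cells
  nd$year <- year
  if ("survey" %in% types) {
    lev <- fit$info$metas[[which(types == "survey")]]$levels
    nd$survey_id <- if (is.null(survey)) lev[1] else survey
  }
  nd$density <- predict(fit, nd, type = "response", exclude = exclude)
  out <- nd[, c("cell_id", "stratum", "x_c", "y_c", "area", "density")]
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
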