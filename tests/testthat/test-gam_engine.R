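# Independent oracle: direct maximization of the penalized NB log-likelihood
# with analytic gradient, no IRLS involved.
brute_force_penalized <- function(X, y, offset, S, theta, start = NULL) {
  fn <- function(b) {
    mu <- exp(pmin(X %*% b + offset, 30))
    -(sum(dnbinom(y, size = theta, mu = mu, log = TRUE)) -
        0.5 * sum(b * (S %*% b)))
  }
  gr <- function(b) {
    mu <- as.numeric(exp(pmin(X %*% b + offset, 30)))
    -(as.numeric(crossprod(X, y - mu * (y + theta) / (mu + theta))) -
        as.numeric(S %*% b))
  }
  if (is.null(start)) start <- rep(0, ncol(X))
  o <- optim(start, fn, gr, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-15))
  o$par
}

test_that("penalized IRLS matches brute-force maximization on small instances", {
  set.seed(7)
  for (rep in 1:3) {
    n <- 60
    x <- runif(n)
    B <- splines::bs(x, df = 7)              # 7 cols + intercept = 8 coefs
    X <- cbind(1, B)
    offset <- log(runif(n, 0.5, 2))
    mu <- exp(0.3 + sin(2 * pi * x) + offset)
    y <- rnbinom(n, size = 1.7, mu = mu)
    D <- diff(diag(7), differences = 2)
    S <- matrix(0, 8, 8); S[2:8, 2:8] <- crossprod(D) * 3
    f <- nb_pirls(X, y, offset, S, theta = 1.7, tol = 1e-12)
    b_oracle <- brute_force_penalized(X, y, offset, S, theta = 1.7,
                                      start = f$beta * 0.9)
    expect_lt(max(abs(f$beta - b_oracle)), 1e-6)
  }
})

test_that("Poisson-limit intercept fit equals the closed-form offset MLE", {
  set.seed(2)
  n <- 400
  area <- runif(n, 0.5, 1.5)
  y <- rpois(n, 2 * area)
  f <- nb_pirls(matrix(1, n, 1), y, log(area), matrix(0, 1, 1),
                theta = 1e8, tol = 1e-12)
  expect_equal(f$beta, log(sum(y) / sum(area)), tolerance = 1e-6)
})

test_that("doubling all areas shifts only the intercept by -log 2", {
  d <- mk_model_data(600, function(d) rep(1.5, nrow(d)), theta = 2, seed = 3)
  f1 <- nb_gam(model_spec(), d)
  d2 <- d; d2$area <- d2$area * 2
  f2 <- nb_gam(model_spec(), d2)
  expect_equal(f2$beta[1] - f1$beta[1], -log(2), tolerance = 1e-6)
  expect_equal(f2$theta, f1$theta, tolerance = 1e-6)
})

test_that("intercept-only fit recovers the baseline and the NB dispersion", {
  d <- mk_model_data(2000, function(d) rep(exp(0.4), nrow(d)), theta = 2,
                     seed = 11)
  f <- nb_gam(model_spec(), d)
  expect_lt(abs(f$beta[1] - 0.4), 0.15)
  expect_gt(f$theta, 1.5)
  expect_lt(f$theta, 2.7)
})

test_that("V_b at zero penalty reduces to the classical GLM covariance", {
  skip_if_not_installed("MASS")
  set.seed(8)
  n <- 300
  x <- runif(n)
  a <- runif(n, 0.5, 2)
  y <- rnbinom(n, size = 2, mu = exp(0.5 + 0.8 * x) * a)
  X <- cbind(1, x)
  f <- nb_pirls(X, y, log(a), matrix(0, 2, 2), theta = 2, tol = 1e-12)
  V <- solve(f$H)
  g <- glm(y ~ x + offset(log(a)), family = MASS::negative.binomial(2))
  Vg <- vcov(g) / summary(g)$dispersion       # unit-dispersion covariance
  expect_equal(unname(V), unname(Vg), tolerance = 1e-4)
})

test_that("smooth terms obey their sum-to-zero constraints", {
  d <- mk_model_data(500, function(d) exp(0.2 * sin(d$year - 2004)),
                     theta = 2, seed = 5)
  f <- nb_gam(model_preset("M1", k_spatial = 4, k_temporal = 6), d)
  for (lab in c("s(X,Y)", "s(Year)")) {
    cols <- f$term_map[[lab]]
    expect_lt(max(abs(colMeans(f$X[, cols, drop = FALSE]))), 1e-8)
  }
})

test_that("an infinitely penalized 1-D smooth collapses to a straight line", {
  d <- mk_model_data(400, function(d) exp(0.1 * (d$year - 2004)), seed = 6)
  des <- stripgam:::build_design(model_spec(term_temporal(8)), d)
  Slam <- stripgam:::embed_S(des$S[[1]], ncol(des$X)) * 1e9
  f <- nb_pirls(des$X, d$count, log(d$area), Slam, theta = 2, tol = 1e-12)
  nd <- d[!duplicated(d$year), ][order(unique(d$year)), ]
  pd <- stripgam:::build_design(model_spec(term_temporal(8)), nd,
                                info = des$info)
  fterm <- as.numeric(pd$X[, -1, drop = FALSE] %*% f$beta[-1])
  # second differences of a straight line vanish (equally spaced years)
  expect_lt(max(abs(diff(fterm, differences = 2))), 1e-4)
})

test_that("a log-linear trend shrinks the year smooth to ~1 edf", {
  set.seed(9)
  d <- expand.grid(rep = 1:100, year = 1999:2014)
  d$x_c <- runif(nrow(d), 300, 320); d$y_c <- runif(nrow(d), 2000, 2014)
  d$area <- 1
  d$count <- rnbinom(nrow(d), size = 3, mu = exp(-1 + 0.08 * (d$year - 2004)))
  f <- nb_gam(model_preset("M1", k_spatial = 4, k_temporal = 8), d)
  expect_lte(f$edf_term[["s(Year)"]], 1.5)
})

test_that("year random effect builds one ridge column per level", {
  d <- mk_model_data(300, function(d) rep(1, nrow(d)), seed = 10,
                     years = 2000:2015)
  des <- stripgam:::build_design(model_spec(term_year_re()), d)
  cols <- des$term_map[["s(fYear)"]]
  expect_length(cols, 16)
  expect_equal(des$S[[1]]$S, diag(16))
})

test_that("model ranking prefers the generating structure and reports dAIC", {
  cfg <- rect_cfg(w = 16, h = 12, spacing = 1.2, years = 2000:2015,
                  base_density = 1.2, amp = 1, detection = 0.5)
  sim <- simulate_survey(cfg, seed = 21, compute_truth = FALSE)
  obs <- indicated_units(apply_inclusion_rules(sim$observations))
  seg <- assign_counts(segment_transects(sim$transects, 1, 0.4), obs)
  tab <- select_models(list(M0 = model_preset("M0"),
                            M1 = model_preset("M1")), seg)
  expect_equal(tab$model[1], "M1")     # cyclic data: year structure wins
  expect_gt(tab$dAIC[2], 5)
  expect_equal(tab$dAIC[1], 0)
  one <- select_models(list(M0 = model_preset("M0")), seg)
  expect_equal(one$dAIC, 0)
})

test_that("an absent observer effect shrinks away and leaves AIC unchanged", {
  cfg <- rect_cfg(w = 16, h = 12, spacing = 1.2, years = 2000:2009,
                  base_density = 1, amp = 1, detection = 0.5)
  sim <- simulate_survey(cfg, seed = 31, compute_truth = FALSE)
  obs <- indicated_units(apply_inclusion_rules(sim$observations))
  seg <- assign_counts(segment_transects(sim$transects, 1, 0.4), obs)
  set.seed(1)
  seg$observer <- sample(c("A", "B"), nrow(seg), replace = TRUE)
  f4 <- nb_gam(model_preset("M4", k_spatial = 4), seg)
  f4o <- nb_gam(model_preset("M4", k_spatial = 4, observer = TRUE), seg)
  expect_lt(f4o$edf_term[["s(Observer)"]], 0.15)
  # the vanished term leaves the ranking criterion essentially untouched
  expect_lt(abs(f4$aic - f4o$aic), 0.5)
})

test_that("prediction is linear in terms and honors exclusions", {
  d <- mk_model_data(500, function(d) exp(0.2 * sin(d$year - 2004)), seed = 12)
  f <- nb_gam(model_preset("M1", k_spatial = 4, k_temporal = 6), d)
  nd <- d[1:20, ]
  full <- predict(f, nd, type = "link")
  parts <- predict(f, nd, exclude = c("s(X,Y)", "s(Year)")) +
    (predict(f, nd, exclude = "s(Year)") - f$beta[1]) +
    (predict(f, nd, exclude = "s(X,Y)") - f$beta[1])
  expect_equal(full, parts, tolerance = 1e-10)
  # excluding everything but the intercept gives a flat density surface
  flat <- predict(f, nd, type = "response",
                  exclude = c("s(X,Y)", "s(Year)"))
  expect_equal(flat, rep(exp(f$beta[1]), 20), tolerance = 1e-12)
  expect_error(predict(f, nd, exclude = "s(Nope)"), "unknown term")
})

test_that("year random effects refuse extrapolation without a temporal smooth", {
  d <- mk_model_data(400, function(d) rep(1, nrow(d)), seed = 13,
                     years = 2000:2009)
  f4 <- nb_gam(model_preset("M4", k_spatial = 4), d)
  nd <- d[1:4, ]; nd$year <- 2020
  expect_error(predict(f4, nd), "extrapolate")
  f3 <- nb_gam(model_preset("M3", k_spatial = 4, k_temporal = 6), d)
  expect_silent(predict(f3, nd))
})

test_that("quantile residuals are calibrated for a correctly specified model", {
  d <- mk_model_data(1200, function(d) rep(1.2, nrow(d)), theta = 1.5,
                     seed = 14)
  f <- nb_gam(model_spec(), d)
  qr <- quantile_residuals(f, seed = 1)
  expect_gt(ks.test(pnorm(qr$residuals), "punif")$p.value, 0.01)
  expect_gt(qr$dispersion_ratio, 0.8)
  expect_lt(qr$dispersion_ratio, 1.2)
  expect_lt(abs(qr$zero_ratio - 1), 0.15)
})

test_that("injected extra zeros raise the zero-inflation metric", {
  d <- mk_model_data(1200, function(d) rep(1.2, nrow(d)), theta = 5, seed = 15)
  set.seed(16)
  d$count[runif(nrow(d)) < 0.3] <- 0
  f <- nb_gam(model_spec(), d)
  qr <- quantile_residuals(f, seed = 2)
  expect_gt(qr$zero_ratio, 1)
})

test_that("the engine agrees with an independent GAM implementation", {
  skip_if_not_installed("mgcv")
  cfg <- sim_preset("triangle_like")
  sim <- simulate_survey(cfg, seed = 42, compute_truth = FALSE)
  obs <- indicated_units(apply_inclusion_rules(sim$observations))
  seg <- as.data.frame(assign_counts(segment_transects(sim$transects, 1, 0.4),
                                     obs))
  fit <- nb_gam(model_preset("M1"), seg)
  g <- mgcv::gam(count ~ s(x_c, y_c, k = 30) + s(year, k = 15) +
                   offset(log(area)),
                 family = mgcv::nb(), data = seg, method = "REML")
  expect_equal(fit$theta, g$family$getTheta(TRUE), tolerance = 0.1)
  nd <- data.frame(x_c = mean(seg$x_c), y_c = mean(seg$y_c),
                   year = 1999:2023, area = 1)
  p1 <- predict(fit, nd, type = "link")
  p2 <- as.numeric(predict(g, nd, type = "link"))
  expect_gt(cor(p1, p2), 0.98)
  expect_lt(max(abs(p1 - p2)), 0.5)
})
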