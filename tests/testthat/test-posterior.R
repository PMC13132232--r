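square_area <- function(side) {
  study_area(list(all = rbind(c(OX, OY), c(OX + side, OY),
                              c(OX + side, OY + side), c(OX, OY + side))))
}

# an intercept-only fit whose posterior is degenerate at beta0
flat_fit <- function(beta0 = 0) {
  d <- mk_model_data(100, function(d) rep(1, nrow(d)), seed = 20)
  f <- nb_gam(model_spec(), d)
  f$beta[] <- beta0
  f$V_b[] <- 0
  f
}

test_that("square and triangular study areas grid to the right total area", {
  g <- make_grid(square_area(10), 1, years = 2000)
  expect_equal(nrow(g$cells), 100)
  expect_equal(sum(g$cells$area), 100, tolerance = 1e-9)
  tri <- study_area(list(all = rbind(c(OX, OY), c(OX + 2, OY),
                                     c(OX, OY + 2))))
  gt <- make_grid(tri, 1, years = 2000:2002)
  expect_equal(sum(gt$cells$area), 2, tolerance = 1e-3)
  expect_true(any(gt$cells$area < 1))            # clipped boundary cells
  expect_true(all(gt$cells$area <= 1 + 1e-9))
  expect_length(gt$years, 3)
})

test_that("MVN coefficient draws reproduce the posterior moments", {
  d <- mk_model_data(500, function(d) rep(1, nrow(d)), seed = 21)
  f <- nb_gam(model_spec(), d)
  B <- sample_coef_mvn(f, 1e4, seed = 1)
  se <- sqrt(f$V_b[1, 1])
  expect_lt(abs(mean(B) - f$beta[1]), 3 * se / sqrt(1e4))
  expect_equal(var(as.numeric(B)), f$V_b[1, 1], tolerance = 0.05)
  # degenerate covariance: all draws equal the mode
  B0 <- sample_coef_mvn(flat_fit(0.7), 50, seed = 2)
  expect_true(all(B0 == 0.7))
})

test_that("MH sampling matches the MVN posterior on a well-behaved fit", {
  d <- mk_model_data(800, function(d) rep(1.5, nrow(d)), seed = 22)
  f <- nb_gam(model_spec(), d)
  mh <- sample_coef_mh(f, n_draws = 2000, burnin = 500, seed = 3)
  expect_gt(min(attr(mh, "acceptance")), 0.01)
  expect_lt(abs(mean(mh) - f$beta[1]), 4 * sqrt(f$V_b[1, 1] / 200))
  expect_gt(sd(mh) / sqrt(f$V_b[1, 1]), 0.75)
  expect_lt(sd(mh) / sqrt(f$V_b[1, 1]), 1.3)
  # thinning leaves the stationary distribution alone; seeding is exact
  mh5 <- sample_coef_mh(f, n_draws = 400, burnin = 500, thin = 5, seed = 4)
  expect_lt(abs(mean(mh5) - mean(mh)), 5 * sd(mh) / sqrt(200))
  expect_identical(sample_coef_mh(f, 100, burnin = 100, seed = 9),
                   sample_coef_mh(f, 100, burnin = 100, seed = 9))
})

test_that("a flat unit surface integrates to the study-area total", {
  f <- flat_fit(0)
  g <- make_grid(square_area(10), 1, years = 2001:2003)
  B <- sample_coef_mvn(f, 10, seed = 5)
  tot <- posterior_totals(f, B, g)
  expect_equal(dim(tot$index), c(10, 3))
  expect_true(all(abs(tot$index - 100) < 1e-9))
})

test_that("totals are stable under grid refinement", {
  run <- run_pipeline_triangle(seed = 77, model = "M1", n_draws = 25)
  g2 <- make_grid(run$sim$area, 0.5, years = 2010)
  t1 <- posterior_totals(run$fit, sample_coef_mvn(run$fit, 25, seed = 1),
                         run$grid, years = 2010)
  t2 <- posterior_totals(run$fit, sample_coef_mvn(run$fit, 25, seed = 1),
                         g2, years = 2010)
  expect_equal(t1$index[, 1], t2$index[, 1], tolerance = 0.005)
})

test_that("detection correction scales draws exactly and skews the posterior", {
  f <- flat_fit(0)
  g <- make_grid(square_area(10), 1, years = 2000)
  tot <- posterior_totals(f, sample_coef_mvn(f, 400, seed = 6), g)
  fixed <- detection_correct(tot, d = 0.5)
  expect_true(all(fixed$corrected == 2 * fixed$index / 0.5))
  expect_equal(unique(as.numeric(fixed$corrected)), 400)  # 2*100/0.5
  one <- detection_correct(tot, d = 1)
  expect_equal(one$corrected, 2 * one$index)
  pr <- beta_from_moments(0.307, 0.092)
  drawn <- detection_correct(tot, pr, seed = 7)
  expect_gt(mean(drawn$corrected), median(drawn$corrected))  # right skew
})

test_that("trend identities hold exactly", {
  Y <- matrix(rep(c(100, 150, 200), each = 4), nrow = 4)
  tot <- structure(list(index = Y, years = 2000 + c(0, 5, 10)),
                   class = "posterior_totals")
  tr <- trend_draws(tot, 2000, 10)
  expect_equal(tr$mean, log(2) / 10, tolerance = 1e-12)
  # antisymmetry under endpoint reversal
  rev_tot <- structure(list(index = Y[, 3:1], years = 2000 + c(0, 5, 10)),
                       class = "posterior_totals")
  expect_equal(trend_draws(rev_tot, 2000, 10)$draws, -tr$draws)
  expect_error(trend_draws(tot, 1990, 10), "endpoint")
})

test_that("constant-detection correction cancels in trends draw by draw", {
  set.seed(8)
  Y <- matrix(exp(rnorm(40, 5, 0.3)), nrow = 10)
  tot <- structure(list(index = Y, years = 2001:2004),
                   class = "posterior_totals")
  t_index <- trend_draws(tot, 2001, 3)
  corr <- detection_correct(tot, beta_from_moments(0.307, 0.092), seed = 9)
  t_corr <- trend_draws(corr, 2001, 3)
  expect_equal(t_corr$draws, t_index$draws, tolerance = 1e-12)
})

test_that("draw summaries use type-7 quantiles", {
  M <- matrix(1:100, ncol = 1)
  s <- summarize_draws(M, years = 1999)
  expect_equal(s$median, 50.5)
  expect_equal(s$q025, 3.475)
  expect_equal(s$mean, 50.5)
  const <- summarize_draws(matrix(5, 10, 1), years = 2000)
  expect_equal(unlist(const[, c("mean", "median", "q025", "q975")]),
               c(mean = 5, median = 5, q025 = 5, q975 = 5))
  set.seed(10)
  ln <- summarize_draws(matrix(rlnorm(2000, 0, 1), ncol = 1), years = 2001)
  expect_gt(ln$mean, ln$median)
})
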