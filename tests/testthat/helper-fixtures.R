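# Shared fixtures: all synthetic, built in code. Coordinates are offset into
# a realistic projected range (km) so the lon/lat heuristic never misfires.
OX <- 300
OY <- 2000

# straight transect rows in long vertex format
mk_transect <- function(id, x0, y0, x1, y1, year = 2010, survey = "s1",
                        stratum = "all", width = 0.4) {
  data.frame(transect_id = id, survey_id = survey, year = year,
             stratum = stratum, design_width = width, vertex = 1:2,
             x = c(x0, x1) + OX, y = c(y0, y1) + OY)
}

mk_obs <- function(x, y, unit = "pair", on_transect = TRUE, year = 2010,
                   survey = "s1", group_size = NA_real_) {
  data.frame(survey_id = survey, year = year, x = x + OX, y = y + OY,
             unit = unit, on_transect = on_transect, group_size = group_size,
             observer = NA_character_, side = NA_character_)
}

# small rectangular survey configuration for fast replicate loops
rect_cfg <- function(w = 10, h = 8, spacing = 2, years = 2010,
                     base_density = 1, gradient = 2, amp = 0, theta = 2,
                     detection = 1, strip_width = 0.4, segment_km = 1, ...) {
  poly <- rbind(c(0, 0), c(w, 0), c(w, h), c(0, h))
  sim_config(region = poly,
             strata = list(all = list(polygon = poly, spacing = spacing)),
             years = years, base_density = base_density, gradient = gradient,
             amp = amp, theta = theta, detection = detection,
             strip_width = strip_width, segment_km = segment_km,
             female_rate = 0, off_rate = 0, ...)
}

# segment-style model data without the simulator (for direct GAM tests)
mk_model_data <- function(n, mu_fun, theta = 2, seed = 1,
                          years = 2000:2009) {
  set.seed(seed)
  d <- data.frame(x_c = runif(n, OX, OX + 20), y_c = runif(n, OY, OY + 14),
                  year = sample(years, n, replace = TRUE),
                  area = runif(n, 0.5, 2))
  mu <- mu_fun(d) * d$area
  d$count <- rnbinom(n, size = theta, mu = mu)
  d
}

run_pipeline_triangle <- function(seed, model = "M2", n_draws = 500) {
  cfg <- sim_preset("triangle_like")
  sim <- simulate_survey(cfg, seed = seed)
  obs <- indicated_units(apply_inclusion_rules(sim$observations))
  seg <- assign_counts(segment_transects(sim$transects, cfg$segment_km,
                                         cfg$strip_width), obs)
  fit <- nb_gam(model_preset(model), seg)
  grid <- make_grid(sim$area, 1, years = cfg$all_years)
  draws <- sample_coef_mvn(fit, n_draws, seed = seed + 1)
  tot <- posterior_totals(fit, draws, grid)
  tot <- detection_correct(tot, beta_from_moments(0.307, 0.092),
                           seed = seed + 2)
  list(cfg = cfg, sim = sim, seg = seg, fit = fit, grid = grid, totals = tot)
}
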