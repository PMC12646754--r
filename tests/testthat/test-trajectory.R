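test_that("a noiseless cover trajectory is recovered everywhere", {
  tab <- make_noiseless()
  fit <- fit_trajectory(tab, "cover", k = 20)
  grid <- 10:440
  curve <- predict_curve(fit, grid)
  truthv <- truth_value(default_truth, "cover", grid)
  expect_lt(max(abs(curve$fitted - truthv)), 0.5)
})

test_that("pure-noise responses yield a near-zero adjusted R2", {
  tab <- simulate_plot_table(default_truth,
                             generator_config(n_plots = 1000, seed = 20))
  set.seed(99)
  tab$h_max_m <- rnorm(1000)
  fit <- suppressWarnings(fit_trajectory(tab, "h_max"))
  expect_lt(abs(adjusted_r2(fit)), 0.05)
})

test_that("an exactly linear response is reproduced by the splines", {
  tab <- small_table(seed = 4, n = 120)
  tab$h_max_m <- 2 + 0.05 * tab$stand_age_yr
  fit <- suppressWarnings(fit_trajectory(tab, "h_max"))
  expect_lt(fit$sse, 1e-6 * fit$sst)
  # evaluation at the training ages reproduces the observations
  curve <- predict_curve(fit, sort(tab$stand_age_yr))
  expect_equal(curve$fitted, 2 + 0.05 * curve$age, tolerance = 1e-6)
  # no rainfall dependence in the data: reference rainfall is irrelevant
  c1 <- predict_curve(fit, c(50, 200, 400), reference_rainfall = 260)
  c2 <- predict_curve(fit, c(50, 200, 400), reference_rainfall = 302)
  expect_lt(max(abs(c1$fitted - c2$fitted)), 1e-8)
})

test_that("log-response fits back-transform to the original scale", {
  tab <- small_table(seed = 6, n = 200)
  tab$tree_density_ha <- exp(2 + 0.003 * tab$stand_age_yr)
  # REML on an exactly-representable response can stop on a step failure
  # warning while still returning the exact fit; the check below is on values
  fit <- suppressWarnings(fit_trajectory(tab, "tree_density"))
  expect_true(fit$log_response)
  grid <- seq(20, 430, by = 10)
  curve <- predict_curve(fit, grid)
  expect_equal(curve$fitted, exp(2 + 0.003 * grid), tolerance = 1e-4)
  tab$tree_density_ha[1] <- 0
  expect_error(fit_trajectory(tab, "tree_density"),
               class = "firecanopy_bad_argument")
})

test_that("rate_of_change differentiates fitted curves in decadal units", {
  lin <- tibble::tibble(age = seq(0, 100, 1), fitted = 0.09 * seq(0, 100, 1))
  expect_equal(rate_of_change(lin)$rate_per_decade, rep(0.9, 101),
               tolerance = 1e-12)
  const <- tibble::tibble(age = seq(0, 100, 1), fitted = rep(3, 101))
  expect_true(all(rate_of_change(const)$rate_per_decade == 0))
  quad <- tibble::tibble(age = seq(0, 20, 1), fitted = seq(0, 20, 1)^2)
  r <- rate_of_change(quad)
  expect_equal(r$rate_per_decade[r$age == 10], 200, tolerance = 1e-9)
  coarse <- tibble::tibble(age = seq(0, 100, 10), fitted = runif(11))
  expect_error(rate_of_change(coarse), class = "firecanopy_bad_argument")
})

test_that("cumulating the rate reconstructs the curve", {
  tab <- small_table(seed = 12, n = 250)
  fit <- fit_trajectory(tab, "cover")
  curve <- predict_curve(fit)
  r <- rate_of_change(curve)
  dt <- diff(curve$age)
  mid_rate <- (r$rate_per_decade[-1] + r$rate_per_decade[-nrow(r)]) / 2
  rebuilt <- curve$fitted[1] + c(0, cumsum(mid_rate / 10 * dt))
  expect_lt(max(abs(rebuilt - curve$fitted)),
            0.01 * diff(range(curve$fitted)))
})

test_that("find_extremum locates and refines peaks", {
  grid <- seq(1, 450, 1)
  truth_curve <- tibble::tibble(age = grid,
                                fitted = truth_value(default_truth, "cover", grid))
  pk <- find_extremum(truth_curve, "maximum")
  expect_equal(pk$peak_age, 120, tolerance = 1)
  expect_equal(pk$peak_value, 48, tolerance = 0.1)
  expect_false(pk$boundary)
  # mean decadal decline from the peak to the end of the chronosequence
  expect_equal(pk$mean_rate_after, (20 - 48) / ((450 - 120) / 10),
               tolerance = 0.01)

  parab <- tibble::tibble(age = seq(80, 120, 2),
                          fitted = -(seq(80, 120, 2) - 100)^2)
  expect_equal(find_extremum(parab, "maximum")$peak_age, 100,
               tolerance = 1e-9)

  mono <- tibble::tibble(age = grid,
                         fitted = truth_value(default_truth, "h_max", grid))
  pk2 <- find_extremum(mono, "maximum")
  expect_true(pk2$boundary)
  expect_equal(pk2$peak_age, 450)
  expect_error(find_extremum(tibble::tibble(age = 1:10, fitted = rep(1, 10))),
               class = "firecanopy_bad_argument")
})

test_that("rainfall contrasts have the configured sign and vanish without effect", {
  tab <- simulate_plot_table(default_truth, generator_config(seed = 31))
  fit_hcv <- fit_trajectory(tab, "h_cv")
  ct <- rainfall_contrast(fit_hcv, kind = "minimum")
  expect_lt(mean(ct$series$difference), 0)

  tr0 <- trajectory_truth(rainfall_effects = c(
    h_max = 0, cover = 0, h_cv = 0, rumple_norm = 0, basal_area = 0,
    tree_density = 0
  ))
  tab0 <- simulate_plot_table(tr0, generator_config(
    seed = 31, noise_sd = list(h_max = 0, cover = 0, h_cv = 0,
                               rumple_norm = 0, basal_area = 0,
                               log10_density = 0)
  ))
  fit0 <- fit_trajectory(tab0, "cover", k = 15)
  ct0 <- rainfall_contrast(fit0)
  expect_lt(max(abs(ct0$series$difference)), 0.3)
  expect_error(rainfall_contrast(fit0, r_lo = 100),
               class = "firecanopy_bad_argument")
})

test_that("adjusted R2 matches an independent spreadsheet-style computation", {
  tab <- small_table(seed = 17, n = 80)
  fit <- fit_trajectory(tab, "basal_area")
  # recompute every ingredient from the raw model outputs
  y <- tab$basal_area_m2ha
  yhat <- as.numeric(predict(fit$model))
  n <- length(y)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  edf <- sum(fit$model$edf)
  expect_equal(adjusted_r2(fit), 1 - (1 - r2) * (n - 1) / (n - edf - 1),
               tolerance = 1e-10)
  # a perfect noiseless fit approaches 1
  tabn <- make_noiseless(n = 200, seed = 3)
  expect_gt(adjusted_r2(fit_trajectory(tabn, "h_max")), 0.999)
})

test_that("the smoother converges to the truth as noise shrinks", {
  sup_err <- vapply(c(1, 0.5, 0), function(scale) {
    ns <- lapply(list(h_max = 1.2, cover = 7, h_cv = 0.07, rumple_norm = 0.04,
                      basal_area = 2.5, log10_density = 0.15),
                 function(v) v * scale)
    tab <- simulate_plot_table(default_truth,
                               generator_config(n_plots = 500, seed = 2,
                                                noise_sd = ns))
    fit <- fit_trajectory(tab, "cover", k = 20)
    grid <- 10:440
    max(abs(predict_curve(fit, grid)$fitted -
              truth_value(default_truth, "cover", grid)))
  }, 0)
  expect_true(all(diff(sup_err) < 0))
})

test_that("fit preconditions are enforced", {
  tab <- small_table(seed = 1, n = 40)
  expect_error(fit_trajectory(tab[1:10, ], "cover"),
               class = "firecanopy_bad_argument")
  expect_error(fit_trajectory(tab, "not_a_metric"),
               class = "firecanopy_bad_argument")
  tab2 <- tab
  tab2$rainfall_mm_yr <- 290
  expect_error(fit_trajectory(tab2, "cover"),
               class = "firecanopy_bad_argument")
  tab3 <- tab
  tab3$cover_5m_pct[5] <- NA
  expect_error(fit_trajectory(tab3, "cover"),
               class = "firecanopy_bad_argument")
  fit <- fit_trajectory(tab, "cover")
  expect_error(predict_curve(fit, seq(0, 500, 1)),
               class = "firecanopy_extrapolation")
  expect_silent(predict_curve(fit, seq(0, 500, 1), allow_extrapolation = TRUE))
})

test_that("tidy and glance summarize recovery fits broom-style", {
  tab <- small_table(seed = 13, n = 100)
  fit <- fit_trajectory(tab, "cover")
  td <- tidy(fit)
  expect_equal(td$term, c("s(age)", "s(rain)", "s(area)"))
  expect_true(all(td$edf >= 0))
  gl <- glance(fit)
  expect_equal(gl$n, 100)
  expect_equal(gl$r2_adjusted, adjusted_r2(fit))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
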