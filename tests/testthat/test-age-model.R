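test_that("the inverse-model suite enumerates 4 + 6 + 1 specs", {
  suite <- model_suite()
  expect_length(suite, 11)
  sizes <- vapply(suite, function(s) length(s$metrics), 0L)
  expect_equal(sum(sizes == 1), 4)
  expect_equal(sum(sizes == 2), 6)
  expect_equal(sum(sizes == 4), 1)
  combos <- vapply(suite, function(s) paste(sort(s$metrics), collapse = "+"), "")
  expect_equal(anyDuplicated(combos), 0L)
  expect_error(age_model_spec(character(0)), class = "firecanopy_bad_argument")
  expect_error(age_model_spec("mean_height"), class = "firecanopy_bad_argument")
})

test_that("stratified splits cover the age range and follow the ceiling rule", {
  tab <- simulate_plot_table(default_truth, generator_config(seed = 23))
  sp <- stratified_split(tab, seed = 1)
  expect_length(sp$breaks, 12)
  expect_setequal(c(sp$train, sp$validation), seq_len(250))
  expect_length(intersect(sp$train, sp$validation), 0)
  # 250 roughly uniform ages over 11 classes: ceil(0.1 * n_c) per class
  expect_gte(length(sp$validation), 25)
  expect_lte(length(sp$validation), 36)
  # every non-empty class contributes at least one validation plot
  cls <- findInterval(tab$stand_age_yr, sp$breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  vcls <- unique(cls[sp$validation])
  occupied <- names(which(table(cls) >= 2))
  expect_true(all(as.integer(occupied) %in% vcls))
  # reproducibility
  expect_identical(stratified_split(tab, seed = 1), sp)
  expect_false(identical(stratified_split(tab, seed = 2)$validation,
                         sp$validation))
  expect_error(stratified_split(tab, n_classes = 1),
               class = "firecanopy_bad_argument")
})

test_that("singleton age classes stay in training", {
  tab <- small_table(seed = 3, n = 40)
  # push one plot far beyond the rest: it becomes a one-member top class
  tab$stand_age_yr <- c(runif(39, 1, 40), 450)
  sp <- stratified_split(tab, n_classes = 11, seed = 5)
  expect_false(40 %in% sp$validation)
  expect_true(40 %in% sp$train)
})

test_that("an oracle predictor gives RMSE 0 and R2 1", {
  tab <- small_table(seed = 21, n = 60)
  vr <- repeated_validation(tab, age_model_spec("h_max"), n_repetitions = 5,
                            seed = 3,
                            predict_fn = function(train, valid) valid$stand_age_yr)
  expect_equal(vr$rmse_mean, 0)
  expect_equal(vr$r2_mean, 1)
  expect_true(all(abs(vr$class_bias$mean_error) < 1e-12))
})

test_that("a train-mean predictor scores R2 near zero and RMSE near the age sd", {
  tab <- simulate_plot_table(default_truth, generator_config(seed = 29))
  vr <- repeated_validation(
    tab, age_model_spec("h_max"), n_repetitions = 50, seed = 7,
    predict_fn = function(train, valid) {
      rep(mean(train$stand_age_yr), nrow(valid))
    }
  )
  expect_lt(abs(vr$r2_mean), 0.1)
  expect_lt(abs(vr$rmse_mean - sd(tab$stand_age_yr)) / sd(tab$stand_age_yr),
            0.15)
})

test_that("repetition seeds form a stable stream", {
  tab <- small_table(seed = 25, n = 60)
  pfn <- function(train, valid) rep(mean(train$stand_age_yr), nrow(valid))
  v1 <- repeated_validation(tab, age_model_spec("cover"), n_repetitions = 1,
                            seed = 11, predict_fn = pfn)
  v5 <- repeated_validation(tab, age_model_spec("cover"), n_repetitions = 5,
                            seed = 11, predict_fn = pfn)
  expect_equal(v1$metrics, v5$metrics[1, ])
  expect_equal(v1$predictions,
               dplyr::filter(v5$predictions, repetition == 1))
})

test_that("inverse fits predict age and clamp to the training range", {
  tab <- make_noiseless(n = 300, seed = 9)
  fit <- fit_age_model(tab, age_model_spec(c("h_max", "cover", "h_cv",
                                             "rumple_norm")))
  p <- predict(fit, tab)
  expect_true(all(p >= fit$age_range[1] & p <= fit$age_range[2]))
  # noiseless structure determines age well once all four metrics are used
  expect_lt(sqrt(mean((p - tab$stand_age_yr)^2)), 10)
  expect_error(fit_age_model(tab, age_model_spec("h_max"), k = 1),
               class = "firecanopy_bad_argument")
  expect_error(fit_age_model(dplyr::select(tab, -h_max_m),
                             age_model_spec("h_max")),
               class = "firecanopy_bad_argument")
})

test_that("bias_by_age_class exposes systematic prediction bias", {
  obs <- seq(1, 450, length.out = 200)
  unbiased <- tibble::tibble(observed = obs, predicted = obs)
  b <- bias_by_age_class(unbiased)
  expect_true(all(b$mean_error == 0))
  expect_equal(sum(b$n), 200)

  capped <- tibble::tibble(observed = obs, predicted = pmin(obs, 300))
  b2 <- bias_by_age_class(capped, n_classes = 11)
  oldest <- b2[b2$class == max(b2$class), ]
  expect_lt(oldest$mean_error, -50)
  youngest <- b2[b2$class == 1, ]
  expect_equal(youngest$mean_error, 0)

  single <- tibble::tibble(observed = rep(100, 5), predicted = rep(90, 5))
  expect_equal(nrow(bias_by_age_class(single)), 1)
})

test_that("semivariogram matches hand computation and is flat under iid noise", {
  # two points, residuals 1 and 3, one bin: gamma = (1/2) * (3-1)^2 = 2
  g <- semivariogram(c(1, 3), c(0, 1), c(0, 0), breaks = c(0, 2))
  expect_equal(g$gamma, 2)
  expect_equal(g$n_pairs, 1)

  g0 <- semivariogram(rep(5, 20), runif(20), runif(20), breaks = c(0, 1, 2))
  expect_true(all(g0$gamma[g0$n_pairs > 0] == 0))

  # iid residuals: every bin's semivariance sits at the residual variance,
  # within 3 Monte-Carlo standard errors estimated from replicate draws
  set.seed(42)
  x <- runif(250, 0, 600)
  y <- runif(250, 0, 600)
  reps <- replicate(30, {
    r <- rnorm(250)
    semivariogram(r, x, y, n_bins = 8)$gamma
  })
  m <- rowMeans(reps)
  se <- apply(reps, 1, sd)
  expect_true(all(abs(m - 1) < 3 * pmax(se, 1e-6)))

  expect_error(semivariogram(1, 1, 1), class = "firecanopy_bad_argument")
})

test_that("validation tidiers and plots summarize the result", {
  tab <- small_table(seed = 33, n = 80)
  vr <- repeated_validation(tab, age_model_spec("h_max"), n_repetitions = 3,
                            seed = 2)
  expect_s3_class(tidy(vr), "tbl_df")
  gl <- glance(vr)
  expect_equal(gl$n_repetitions, 3)
  expect_true(gl$rmse_mean > 0)
  expect_s3_class(autoplot(vr), "ggplot")
})
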