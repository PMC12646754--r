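#' @importFrom mgcv gam s
NULL

# canonical metric name -> plot-table column
metric_columns <- c(
  h_max = "h_max_m", cover = "cover_5m_pct", h_cv = "h_cv",
  rumple_norm = "rumple_norm", basal_area = "basal_area_m2ha",
  tree_density = "tree_density_ha"
)

resolve_response <- function(response) {
  if (response %in% names(metric_columns)) {
    c(metric = response, column = unname(metric_columns[response]))
  } else if (response %in% metric_columns) {
    c(metric = names(metric_columns)[metric_columns == response],
      column = response)
  } else {
    fc_abort(sprintf(
      "unknown response '%s'; use one of %s (or the matching column name)",
      response, paste(names(metric_columns), collapse = ", ")
    ), "firecanopy_bad_argument")
  }
}

#' Fit an additive smooth recovery trajectory
#'
#' Fits the chronosequence model `metric ~ f1(stand age) + f2(rainfall) +
#' f3(plot area)` as a generalized additive model: each predictor gets a
#' penalized cubic B-spline smooth (P-spline basis with a second-difference
#' penalty, default basis dimension 10) and the smoothing parameters are
#' selected by restricted maximum likelihood (or GCV on request). No
#' age-rainfall interaction is included: in a real chronosequence the two
#' are partly confounded and an interaction cannot be estimated robustly.
#' Tree density is fitted on the log scale by default to tame its skew;
#' predictions are back-transformed with the plain exponential.
#'
#' @param data A plot table (see [simulate_plot_table()] /
#'   [read_plot_table()]) with at least 30 complete rows.
#' @param response A metric name (`"cover"`, `"h_max"`, `"h_cv"`,
#'   `"rumple_norm"`, `"basal_area"`, `"tree_density"`) or the matching
#'   column name.
#' @param log_response Fit on the log scale? Default: only for tree density.
#' @param k Basis dimension per smooth. 10 suffices for noisy field-scale
#'   data; raise it (15-20) when chasing sub-percent accuracy on noiseless
#'   curves.
#' @param method Smoothness selection: `"REML"` (default) or `"GCV.Cp"`.
#' @return A `recovery_gam` object; see [predict_curve()],
#'   [rainfall_contrast()], [adjusted_r2()], and the [generics::tidy()] /
#'   [generics::glance()] methods.
#' @examples
#' plots <- simulate_plot_table(trajectory_truth(), generator_config(seed = 1))
#' fit <- fit_trajectory(plots, "cover")
#' glance(fit)
#' @export
fit_trajectory <- function(data, response, log_response = NULL, k = 10,
                           method = c("REML", "GCV.Cp")) {
  method <- match.arg(method)
  info <- resolve_response(response)
  validate_plot_table(data)
  check_number(k, "k", lower = 3)
  if (!info[["column"]] %in% names(data)) {
    fc_abort(sprintf("column '%s' not found in the plot table", info[["column"]]),
             "firecanopy_bad_argument")
  }
  if (is.null(log_response)) log_response <- info[["metric"]] == "tree_density"
  df <- tibble::tibble(
    .y = data[[info[["column"]]]],
    .age = data$stand_age_yr,
    .rain = data$rainfall_mm_yr,
    .area = data$plot_area_ha
  )
  if (anyNA(df)) {
    fc_abort("response and predictors must not contain missing values",
             "firecanopy_bad_argument")
  }
  if (nrow(df) < 30) {
    fc_abort("need at least 30 plots to fit a trajectory", "firecanopy_bad_argument")
  }
  for (col in c(".age", ".rain", ".area")) {
    if (length(unique(df[[col]])) < 2) {
      fc_abort(sprintf("predictor '%s' does not vary", sub("^\\.", "", col)),
               "firecanopy_bad_argument")
    }
  }
  if (log_response) {
    if (any(df$.y <= 0)) {
      fc_abort("log-transformed response requires strictly positive values",
               "firecanopy_bad_argument")
    }
    df$.y <- log(df$.y)
  }
  fml <- .y ~ s(.age, bs = "ps", k = k, m = c(2, 2)) +
    s(.rain, bs = "ps", k = k, m = c(2, 2)) +
    s(.area, bs = "ps", k = k, m = c(2, 2))
  model <- gam(fml, data = df, method = method)
  edf <- sum(model$edf)
  sse <- sum(model$residuals^2)
  sst <- sum((df$.y - mean(df$.y))^2)
  n <- nrow(df)
  structure(
    list(
      model = model,
      response = info[["metric"]],
      response_column = info[["column"]],
      log_response = log_response,
      k = k, method = method, n = n, edf = edf,
      sse = sse, sst = sst,
      age_range = range(df$.age),
      rainfall_range = range(df$.rain),
      area_range = range(df$.area),
      data = data
    ),
    class = "recovery_gam"
  )
}

#' @export
print.recovery_gam <- function(x, ...) {
  cat(sprintf("<recovery_gam> %s%s ~ s(age) + s(rainfall) + s(area)\n",
              if (x$log_response) "log " else "", x$response))
  cat(sprintf("  n = %d, edf = %.2f, adjusted R2 = %.3f (%s)\n",
              x$n, x$edf, adjusted_r2(x), x$method))
  invisible(x)
}

#' Adjusted R-squared of an additive fit
#'
#' Explained variance adjusted for model complexity:
#' `1 - (1 - R2) * (n - 1) / (n - edf - 1)` with `R2 = 1 - SSE/SST` and
#' `edf` the summed effective degrees of freedom of the smooths (the
#' intercept is the extra `- 1`). Computed on the model scale (log scale for
#' log-transformed responses).
#'
#' @param fit A [fit_trajectory()] or [fit_age_model()] object.
#' @return A single number, at most 1.
#' @export
adjusted_r2 <- function(fit) {
  stopifnot(inherits(fit, c("recovery_gam", "age_gam")))
  if (fit$n <= fit$edf + 1) {
    fc_abort("adjusted R2 undefined: n <= edf + 1", "firecanopy_bad_argument")
  }
  r2 <- 1 - fit$sse / fit$sst
  1 - (1 - r2) * (fit$n - 1) / (fit$n - fit$edf - 1)
}

#' Evaluate a fitted recovery trajectory along a stand-age grid
#'
#' Evaluates the additive predictor over an age grid with rainfall and plot
#' area held at reference values, back-transforming when the response was
#' fitted on the log scale. By default evaluation is restricted to the
#' fitted age range; splines extrapolate poorly, so going beyond it must be
#' requested explicitly.
#'
#' @param fit A [fit_trajectory()] object.
#' @param age_grid Strictly increasing ages (yr); default a 1-yr grid over
#'   the fitted range.
#' @param reference_rainfall,reference_area Covariate values the curve is
#'   conditioned on (mm/yr, ha).
#' @param allow_extrapolation Permit ages outside the fitted range?
#' @return A `trajectory_curve` tibble with columns `age` and `fitted`, and
#'   the reference values as attributes.
#' @export
predict_curve <- function(fit, age_grid = NULL, reference_rainfall = 290,
                          reference_area = 4.4, allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "recovery_gam"))
  if (is.null(age_grid)) {
    age_grid <- seq(ceiling(fit$age_range[1]), floor(fit$age_range[2]), by = 1)
  }
  if (any(diff(age_grid) <= 0)) {
    fc_abort("age_grid must be strictly increasing", "firecanopy_bad_argument")
  }
  if (!allow_extrapolation &&
      (min(age_grid) < fit$age_range[1] - 1e-9 ||
       max(age_grid) > fit$age_range[2] + 1e-9)) {
    fc_abort(sprintf(
      "age_grid extends beyond the fitted range [%.1f, %.1f]; set allow_extrapolation = TRUE to override",
      fit$age_range[1], fit$age_range[2]
    ), "firecanopy_extrapolation")
  }
  nd <- data.frame(.age = age_grid, .rain = reference_rainfall,
                   .area = reference_area)
  yhat <- as.numeric(predict(fit$model, newdata = nd))
  if (fit$log_response) yhat <- exp(yhat)
  structure(
    tibble::tibble(age = age_grid, fitted = yhat),
    response = fit$response,
    log_response = fit$log_response,
    reference_rainfall = reference_rainfall,
    reference_area = reference_area,
    class = c("trajectory_curve", "tbl_df", "tbl", "data.frame")
  )
}

#' Decadal rate of change along a fitted curve
#'
#' Differentiates a [predict_curve()] result by central finite differences
#' (one-sided at the grid ends) and scales to per-decade units. The grid
#' must be fine enough (spacing <= 5 yr) for the differences to track the
#' smooth's derivative.
#'
#' @param curve A `trajectory_curve`.
#' @return A tibble with columns `age` and `rate_per_decade`.
#' @export
rate_of_change <- function(curve) {
  stopifnot(inherits(curve, "trajectory_curve") ||
              all(c("age", "fitted") %in% names(curve)))
  t <- curve$age
  y <- curve$fitted
  n <- length(t)
  if (n < 3) fc_abort("need at least 3 grid points", "firecanopy_bad_argument")
  if (max(diff(t)) > 5) {
    fc_abort("age grid too coarse for derivatives: spacing must be <= 5 yr",
             "firecanopy_bad_argument")
  }
  dy <- numeric(n)
  dy[1] <- (y[2] - y[1]) / (t[2] - t[1])
  dy[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  dy[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  tibble::tibble(age = t, rate_per_decade = 10 * dy)
}

#' Locate a trajectory's peak or trough
#'
#' Finds the maximum or minimum of a fitted curve on its grid, refines the
#' location by fitting a quadratic through the extremal point and its two
#' neighbours (exact for locally parabolic curves), and summarizes the mean
#' decadal rates on either side: `(peak value - start value)` per decade
#' elapsed before the extremum, and `(end value - peak value)` per decade
#' after it. An extremum sitting on the grid boundary is reported with
#' `boundary = TRUE` rather than refined.
#'
#' @param curve A `trajectory_curve`.
#' @param kind `"maximum"` or `"minimum"`.
#' @return A one-row tibble: `peak_age`, `peak_value`, `kind`, `boundary`,
#'   `mean_rate_before`, `mean_rate_after` (response units per decade).
#' @export
find_extremum <- function(curve, kind = c("maximum", "minimum")) {
  kind <- match.arg(kind)
  t <- curve$age
  y <- curve$fitted
  if (length(unique(y)) < 2) {
    fc_abort("curve is constant: no extremum", "firecanopy_bad_argument")
  }
  i <- if (kind == "maximum") which.max(y) else which.min(y)
  boundary <- i == 1L || i == length(y)
  if (!boundary) {
    # quadratic through (t[i-1], t[i], t[i+1]); vertex in closed form
    co <- stats::coef(stats::lm(yy ~ tt + I(tt^2),
                                data = data.frame(tt = t[(i - 1):(i + 1)],
                                                  yy = y[(i - 1):(i + 1)])))
    if (is.finite(co[3]) && abs(co[3]) > 1e-12) {
      t_star <- -co[2] / (2 * co[3])
      if (t_star >= t[i - 1] && t_star <= t[i + 1]) {
        peak_age <- unname(t_star)
        peak_value <- unname(co[1] + co[2] * t_star + co[3] * t_star^2)
      } else {
        peak_age <- t[i]; peak_value <- y[i]
      }
    } else {
      peak_age <- t[i]; peak_value <- y[i]
    }
  } else {
    peak_age <- t[i]; peak_value <- y[i]
  }
  dec_before <- (peak_age - t[1]) / 10
  dec_after <- (t[length(t)] - peak_age) / 10
  tibble::tibble(
    peak_age = peak_age,
    peak_value = peak_value,
    kind = kind,
    boundary = boundary,
    mean_rate_before = if (dec_before > 0) (peak_value - y[1]) / dec_before else NA_real_,
    mean_rate_after = if (dec_after > 0) (y[length(y)] - peak_value) / dec_after else NA_real_
  )
}

#' Rainfall contrast of a fitted trajectory
#'
#' Difference between the fitted curves at a high and a low reference
#' rainfall (defaults 302 and 260 mm/yr, the 95th and 5th percentiles of a
#' 250-330 mm/yr gradient), age by age, plus the difference evaluated at
#' the high-rainfall curve's extremum. Both rainfall values must lie inside
#' the fitted rainfall range.
#'
#' @param fit A [fit_trajectory()] object.
#' @param age_grid Ages (yr) to evaluate on; default the fitted range at
#'   1-yr steps.
#' @param r_lo,r_hi Low and high reference rainfall (mm/yr).
#' @param reference_area Plot area (ha) held fixed.
#' @param kind Extremum kind used for the peak difference.
#' @param allow_extrapolation Passed to [predict_curve()].
#' @return A list of class `rainfall_contrast`: `series` (tibble `age`,
#'   `difference`), `peak_age`, `peak_difference`, `r_lo`, `r_hi`.
#' @export
rainfall_contrast <- function(fit, age_grid = NULL, r_lo = 260, r_hi = 302,
                              reference_area = 4.4,
                              kind = c("maximum", "minimum"),
                              allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "recovery_gam"))
  kind <- match.arg(kind)
  for (r in c(r_lo, r_hi)) {
    if (r < fit$rainfall_range[1] - 1e-9 || r > fit$rainfall_range[2] + 1e-9) {
      fc_abort(sprintf("rainfall %g mm/yr is outside the fitted range [%.1f, %.1f]",
                       r, fit$rainfall_range[1], fit$rainfall_range[2]),
               "firecanopy_bad_argument")
    }
  }
  hi <- predict_curve(fit, age_grid, reference_rainfall = r_hi,
                      reference_area = reference_area,
                      allow_extrapolation = allow_extrapolation)
  lo <- predict_curve(fit, age_grid, reference_rainfall = r_lo,
                      reference_area = reference_area,
                      allow_extrapolation = allow_extrapolation)
  series <- tibble::tibble(age = hi$age, difference = hi$fitted - lo$fitted)
  pk <- find_extremum(hi, kind)
  at_peak <- function(r) {
    nd <- data.frame(.age = pk$peak_age, .rain = r, .area = reference_area)
    v <- as.numeric(predict(fit$model, newdata = nd))
    if (fit$log_response) exp(v) else v
  }
  structure(
    list(series = series, peak_age = pk$peak_age,
         peak_difference = at_peak(r_hi) - at_peak(r_lo),
         r_lo = r_lo, r_hi = r_hi, response = fit$response),
    class = "rainfall_contrast"
  )
}

#' @export
print.rainfall_contrast <- function(x, ...) {
  cat(sprintf("<rainfall_contrast> %s, %g vs %g mm/yr\n",
              x$response, x$r_hi, x$r_lo))
  cat(sprintf("  mean difference: %.3f; at the peak (age %.0f): %.3f\n",
              mean(x$series$difference), x$peak_age, x$peak_difference))
  invisible(x)
}

#' @rdname fit_trajectory
#' @param x A `recovery_gam` object.
#' @param ... Unused.
#' @export
tidy.recovery_gam <- function(x, ...) {
  s <- summary(x$model)$s.table
  tibble::tibble(
    term = sub("^s\\(\\.(.*)\\)$", "s(\\1)", rownames(s)),
    edf = s[, "edf"],
    ref_df = s[, "Ref.df"],
    statistic = s[, "F"],
    p_value = s[, "p-value"]
  )
}

#' @rdname fit_trajectory
#' @export
glance.recovery_gam <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    n = x$n,
    edf = x$edf,
    r2_adjusted = adjusted_r2(x),
    log_response = x$log_response,
    method = x$method
  )
}

#' Plot a fitted recovery trajectory
#'
#' Observed metric values against stand age with the fitted curve (at
#' reference rainfall and plot area) superimposed.
#'
#' @param object A [fit_trajectory()] object.
#' @param reference_rainfall,reference_area Reference covariates for the
#'   curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_gam <- function(object, reference_rainfall = 290,
                                  reference_area = 4.4, ...) {
  curve <- predict_curve(object, reference_rainfall = reference_rainfall,
                         reference_area = reference_area)
  obs <- tibble::tibble(age = object$data$stand_age_yr,
                        value = object$data[[object$response_column]])
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.35, size = 1) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(y = .data$fitted), linewidth = 1,
                       colour = "#2c7f3f") +
    ggplot2::labs(x = "Stand age (yr)", y = object$response,
                  title = sprintf("%s recovery trajectory", object$response)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.recovery_gam
#' @export
autoplot.trajectory_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$fitted)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "Stand age (yr)", y = attr(object, "response")) +
    ggplot2::theme_minimal()
}
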