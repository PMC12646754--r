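#' Specify an inverse (structure-to-age) model
#'
#' Declares which canopy structural metrics an inverse model uses to predict
#' stand age. Rainfall and plot area are always included as covariates; the
#' metric subset is drawn from the four CHM metrics.
#'
#' @param metrics Character vector, a non-empty subset of `"h_max"`,
#'   `"cover"`, `"h_cv"`, `"rumple_norm"`.
#' @return An `age_model_spec`.
#' @seealso [model_suite()], [fit_age_model()]
#' @export
age_model_spec <- function(metrics) {
  allowed <- c("h_max", "cover", "h_cv", "rumple_norm")
  if (length(metrics) < 1) {
    fc_abort("an age model needs at least one structural metric",
             "firecanopy_bad_argument")
  }
  if (!all(metrics %in% allowed)) {
    fc_abort(sprintf("metrics must be drawn from {%s}",
                     paste(allowed, collapse = ", ")),
             "firecanopy_bad_argument")
  }
  structure(list(metrics = unique(metrics)), class = "age_model_spec")
}

#' @export
print.age_model_spec <- function(x, ...) {
  cat("<age_model_spec>", paste(x$metrics, collapse = " + "),
      "(+ rainfall + plot area)\n")
  invisible(x)
}

#' Enumerate the inverse-model suite
#'
#' The standard suite of increasingly complex inverse models: each single
#' structural metric (4), every two-way combination (6), and all four
#' together (1) — 11 models, each with rainfall and plot area as additional
#' covariates.
#'
#' @return A named list of 11 [age_model_spec()] objects.
#' @export
model_suite <- function() {
  metrics <- c("h_max", "cover", "h_cv", "rumple_norm")
  singles <- lapply(metrics, age_model_spec)
  names(singles) <- metrics
  pairs <- utils::combn(metrics, 2, simplify = FALSE)
  pair_specs <- lapply(pairs, age_model_spec)
  names(pair_specs) <- vapply(pairs, paste, "", collapse = "+")
  c(singles, pair_specs, list(full = age_model_spec(metrics)))
}

#' Stratified train/validation split over age classes
#'
#' Divides the observed stand-age range into `n_classes` equal-length
#' classes and reserves, within each class, a `holdout_fraction` share of
#' the plots (rounded up, so every class of two or more plots contributes
#' at least one validation plot; singleton classes stay in training). The
#' validation subset therefore spans the full age range rather than
#' clustering where plots are dense.
#'
#' @param data A plot table with `stand_age_yr`.
#' @param n_classes Number of equal-length age classes (>= 2).
#' @param holdout_fraction Share of each class reserved for validation.
#' @param seed Integer seed; the split is reproducible from it.
#' @return A list: integer row indices `train` and `validation`
#'   (disjoint, exhaustive), the class `breaks`, and the `seed`.
#' @export
stratified_split <- function(data, n_classes = 11, holdout_fraction = 0.1,
                             seed = 1L) {
  validate_plot_table(data)
  check_number(n_classes, "n_classes", lower = 2)
  check_number(holdout_fraction, "holdout_fraction", lower = 0, upper = 1)
  age <- data$stand_age_yr
  breaks <- seq(min(age), max(age), length.out = n_classes + 1)
  cls <- findInterval(age, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  validation <- integer(0)
  with_local_seed(seed, {
    for (cl in sort(unique(cls))) {
      idx <- which(cls == cl)
      n <- length(idx)
      if (n < 2) next
      n_hold <- min(ceiling(holdout_fraction * n), n - 1)
      validation <- c(validation, sample(idx, n_hold))
    }
  })
  validation <- sort(validation)
  list(train = setdiff(seq_along(age), validation), validation = validation,
       breaks = breaks, seed = as.integer(seed))
}

#' Fit an inverse model of stand age
#'
#' Fits stand age as an additive smooth function of the spec's structural
#' metrics plus rainfall and plot area (penalized B-spline smooths, REML),
#' mirroring the forward trajectory models with the roles of age and
#' structure swapped. Predictions from the returned object are clamped to
#' the training age range: splines extrapolate wildly outside the observed
#' structure-age envelope and a stand age below the youngest or above the
#' oldest training plot is not interpretable anyway.
#'
#' @param data Training plot table (complete metric columns).
#' @param spec An [age_model_spec()].
#' @param k Basis dimension per smooth.
#' @param method Smoothness selection, as in [fit_trajectory()].
#' @return An `age_gam` object with a [predict][predict.age_gam] method.
#' @export
fit_age_model <- function(data, spec, k = 10, method = c("REML", "GCV.Cp")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "age_model_spec"))
  validate_plot_table(data)
  check_number(k, "k", lower = 3)
  cols <- unname(metric_columns[spec$metrics])
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    fc_abort(sprintf("plot table lacks metric column(s): %s",
                     paste(missing, collapse = ", ")), "firecanopy_bad_argument")
  }
  df <- data[, c("stand_age_yr", "rainfall_mm_yr", "plot_area_ha", cols)]
  if (anyNA(df)) {
    fc_abort("age-model training data must be complete", "firecanopy_bad_argument")
  }
  if (nrow(df) < 30) {
    fc_abort("need at least 30 training plots", "firecanopy_bad_argument")
  }
  terms <- vapply(c(cols, "rainfall_mm_yr", "plot_area_ha"), function(v) {
    sprintf("s(%s, bs = 'ps', k = %d, m = c(2, 2))", v, as.integer(k))
  }, "")
  fml <- stats::as.formula(paste("stand_age_yr ~", paste(terms, collapse = " + ")))
  model <- gam(fml, data = df, method = method)
  structure(
    list(
      model = model, spec = spec, k = k, method = method,
      n = nrow(df), edf = sum(model$edf),
      sse = sum(model$residuals^2),
      sst = sum((df$stand_age_yr - mean(df$stand_age_yr))^2),
      age_range = range(df$stand_age_yr)
    ),
    class = "age_gam"
  )
}

#' Predict stand age from canopy structure
#'
#' @param object An [fit_age_model()] result.
#' @param newdata Plot table rows with the spec's metric columns.
#' @param clamp Clamp predictions to the training age range (default)?
#' @param ... Unused.
#' @return Numeric predicted stand ages (yr).
#' @export
predict.age_gam <- function(object, newdata, clamp = TRUE, ...) {
  p <- as.numeric(predict(object$model, newdata = newdata))
  if (clamp) p <- pmin(pmax(p, object$age_range[1]), object$age_range[2])
  p
}

#' @export
print.age_gam <- function(x, ...) {
  cat(sprintf("<age_gam> stand age ~ %s (+ rainfall + area); n = %d, adj R2 = %.3f\n",
              paste(x$spec$metrics, collapse = " + "), x$n, adjusted_r2(x)))
  invisible(x)
}

#' Stratified repeated hold-out validation of an inverse model
#'
#' The validation routine for structure-to-age prediction: repeatedly
#' (default 500 times) split the plots with [stratified_split()], fit the
#' inverse model on the training share, predict the held-out plots, and
#' accumulate RMSE (years) and R-squared (`1 - SSE/SST` about the
#' validation-set mean; negative values are possible and reported). The
#' held-out predictions of all repetitions are pooled to diagnose per-age-
#' class bias. Single-repetition fit failures are skipped and counted;
#' more than 10% failures aborts.
#'
#' @param data A plot table with the spec's metric columns.
#' @param spec An [age_model_spec()].
#' @param n_repetitions Number of split-fit-predict repetitions.
#' @param n_classes,holdout_fraction Passed to [stratified_split()].
#' @param seed Integer seed; repetition `i` uses `seed + i - 1`, so a run
#'   with more repetitions extends (not reshuffles) a shorter one.
#' @param k,method Passed to [fit_age_model()].
#' @param predict_fn Optional override for testing: a
#'   `function(train, validation)` returning predicted ages for the
#'   validation rows, used instead of fitting a GAM.
#' @return A `validation_result`: per-repetition `metrics` tibble
#'   (`repetition`, `rmse`, `r2`), pooled `predictions` tibble, per-class
#'   bias table (`class_bias`), summary means/sds, the class `breaks`,
#'   `n_failed` and the `seed`.
#' @examples
#' \donttest{
#' plots <- simulate_plot_table(trajectory_truth(), generator_config(seed = 1))
#' vr <- repeated_validation(plots, age_model_spec("h_max"), n_repetitions = 20)
#' glance(vr)
#' }
#' @export
repeated_validation <- function(data, spec, n_repetitions = 500,
                                n_classes = 11, holdout_fraction = 0.1,
                                seed = 1L, k = 10,
                                method = c("REML", "GCV.Cp"),
                                predict_fn = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "age_model_spec"))
  validate_plot_table(data)
  check_number(n_repetitions, "n_repetitions", lower = 1)
  reps <- vector("list", n_repetitions)
  pooled <- vector("list", n_repetitions)
  n_failed <- 0
  breaks <- NULL
  for (i in seq_len(n_repetitions)) {
    sp <- stratified_split(data, n_classes, holdout_fraction,
                           seed = seed + i - 1)
    if (is.null(breaks)) breaks <- sp$breaks
    train <- data[sp$train, ]
    valid <- data[sp$validation, ]
    pred <- tryCatch({
      if (is.null(predict_fn)) {
        fit <- fit_age_model(train, spec, k = k, method = method)
        predict(fit, valid)
      } else {
        predict_fn(train, valid)
      }
    }, error = function(e) e)
    if (inherits(pred, "error")) {
      n_failed <- n_failed + 1
      next
    }
    obs <- valid$stand_age_yr
    sse <- sum((pred - obs)^2)
    sst <- sum((obs - mean(obs))^2)
    reps[[i]] <- tibble::tibble(
      repetition = i,
      rmse = sqrt(mean((pred - obs)^2)),
      r2 = if (sst > 0) 1 - sse / sst else NA_real_
    )
    pooled[[i]] <- tibble::tibble(
      repetition = i, plot_id = valid$plot_id,
      observed = obs, predicted = pred
    )
  }
  if (n_failed > 0.1 * n_repetitions) {
    fc_abort(sprintf("%d of %d validation repetitions failed", n_failed,
                     n_repetitions), "firecanopy_validation_failure")
  }
  metrics <- dplyr::bind_rows(reps)
  predictions <- dplyr::bind_rows(pooled)
  structure(
    list(
      spec = spec,
      metrics = metrics,
      predictions = predictions,
      class_bias = bias_by_age_class(predictions, breaks = breaks),
      rmse_mean = mean(metrics$rmse), rmse_sd = sd(metrics$rmse),
      r2_mean = mean(metrics$r2, na.rm = TRUE),
      r2_sd = sd(metrics$r2, na.rm = TRUE),
      n_repetitions = as.integer(n_repetitions), n_failed = n_failed,
      n_classes = n_classes, holdout_fraction = holdout_fraction,
      breaks = breaks, seed = as.integer(seed)
    ),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> age ~ %s; %d repetitions (%d failed)\n",
              paste(x$spec$metrics, collapse = " + "),
              x$n_repetitions, x$n_failed))
  cat(sprintf("  RMSE %.1f +/- %.1f yr, R2 %.3f +/- %.3f\n",
              x$rmse_mean, x$rmse_sd, x$r2_mean, x$r2_sd))
  invisible(x)
}

#' Prediction bias by stand-age class
#'
#' Summarizes prediction errors (predicted minus observed age) within age
#' classes: mean, median and interquartile range per class. Classes default
#' to equal-length intervals over the observed range, or can be supplied as
#' the break sequence of a [stratified_split()] so the diagnosis matches
#' the validation stratification.
#'
#' @param predictions Tibble with columns `observed` and `predicted` (yr).
#' @param breaks Optional class break sequence; otherwise derived from
#'   `n_classes`.
#' @param n_classes Number of equal-length classes when `breaks` is NULL.
#' @return A tibble with one row per non-empty class: `class`, `age_lo`,
#'   `age_hi`, `age_mid`, `n`, `mean_error`, `median_error`, `q25`, `q75`.
#' @export
bias_by_age_class <- function(predictions, breaks = NULL, n_classes = 11) {
  stopifnot(all(c("observed", "predicted") %in% names(predictions)))
  if (nrow(predictions) < 1) {
    fc_abort("need at least one prediction", "firecanopy_bad_argument")
  }
  if (is.null(breaks)) {
    breaks <- seq(min(predictions$observed), max(predictions$observed),
                  length.out = n_classes + 1)
  }
  cls <- findInterval(predictions$observed, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  predictions |>
    dplyr::mutate(class = cls, error = .data$predicted - .data$observed) |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_error = mean(.data$error),
      median_error = median(.data$error),
      q25 = unname(quantile(.data$error, 0.25)),
      q75 = unname(quantile(.data$error, 0.75)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      age_lo = breaks[.data$class],
      age_hi = breaks[.data$class + 1],
      age_mid = (.data$age_lo + .data$age_hi) / 2
    ) |>
    dplyr::select("class", "age_lo", "age_hi", "age_mid", "n",
                  "mean_error", "median_error", "q25", "q75")
}

#' Empirical semivariogram of model residuals
#'
#' Residual spatial-autocorrelation diagnostic: the binned semivariance
#' `gamma(h) = sum (r_i - r_j)^2 / (2 N(h))` over all point pairs whose
#' separation falls in each distance bin. Under spatial independence the
#' semivariogram is flat at the residual variance.
#'
#' @param residuals Numeric residuals, one per plot.
#' @param x,y Plot coordinates (same units define the bins, e.g. km).
#' @param breaks Distance-bin break sequence; default 10 equal bins up to
#'   half the maximum pairwise separation.
#' @param n_bins Number of bins when `breaks` is NULL.
#' @return A tibble with one row per bin: `dist_lo`, `dist_hi`, `dist_mid`,
#'   `n_pairs`, `gamma` (`NA` for empty bins).
#' @export
semivariogram <- function(residuals, x, y, breaks = NULL, n_bins = 10) {
  if (length(residuals) < 2 || length(x) != length(residuals) ||
      length(y) != length(residuals)) {
    fc_abort("need >= 2 residuals with matching coordinates",
             "firecanopy_bad_argument")
  }
  d <- as.numeric(dist(cbind(x, y)))
  if (is.null(breaks)) {
    breaks <- seq(0, max(d) / 2, length.out = n_bins + 1)
  }
  dr <- as.numeric(dist(cbind(residuals, 0))) # |r_i - r_j|
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  keep <- bin >= 1 & bin <= (length(breaks) - 1)
  purrr::map_dfr(seq_len(length(breaks) - 1), function(b) {
    sel <- keep & bin == b
    n <- sum(sel)
    tibble::tibble(
      dist_lo = breaks[b], dist_hi = breaks[b + 1],
      dist_mid = (breaks[b] + breaks[b + 1]) / 2,
      n_pairs = n,
      gamma = if (n > 0) sum(dr[sel]^2) / (2 * n) else NA_real_
    )
  })
}

#' @rdname repeated_validation
#' @param x A `validation_result`.
#' @param ... Unused.
#' @export
tidy.validation_result <- function(x, ...) x$class_bias

#' @rdname repeated_validation
#' @export
glance.validation_result <- function(x, ...) {
  tibble::tibble(
    model = paste(x$spec$metrics, collapse = "+"),
    n_repetitions = x$n_repetitions,
    n_failed = x$n_failed,
    rmse_mean = x$rmse_mean, rmse_sd = x$rmse_sd,
    r2_mean = x$r2_mean, r2_sd = x$r2_sd
  )
}

#' Plot per-age-class prediction errors
#'
#' Boxplots of pooled hold-out prediction errors (predicted minus observed
#' stand age) by age class.
#'
#' @param object A [repeated_validation()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.validation_result <- function(object, ...) {
  breaks <- object$breaks
  df <- object$predictions |>
    dplyr::mutate(
      class = findInterval(.data$observed, breaks, rightmost.closed = TRUE,
                           all.inside = TRUE),
      error = .data$predicted - .data$observed,
      class_label = sprintf("%.0f-%.0f", breaks[.data$class],
                            breaks[.data$class + 1])
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$class_label, .data$class), y = .data$error
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "#cfe6d4") +
    ggplot2::labs(x = "Stand-age class (yr)",
                  y = "Prediction error (predicted - observed, yr)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
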