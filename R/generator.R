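#' Configuration for the synthetic chronosequence generator
#'
#' Bundles and validates the sampling settings for [simulate_plot_table()].
#' Defaults emulate the study design the package targets: 250 plots spanning
#' stand ages 1-450 yr and a 250-330 mm/yr rainfall gradient, with plot areas
#' lognormal around 4.4 +/- 2.0 ha, scattered over a 600 x 600 km region.
#' Ages and rainfall are independent by default; set
#' `age_rainfall_correlation = -0.57` to reproduce the confounding present in
#' real chronosequence networks (a Gaussian-copula rank correlation).
#'
#' @param n_plots Number of plots (>= 10).
#' @param age_range,rainfall_range Length-2 sampling ranges (yr, mm/yr).
#' @param age_rainfall_correlation Copula correlation between age and rainfall,
#'   in \[-1, 0\].
#' @param plot_area_mean,plot_area_sd Mean and sd (ha) of the lognormal plot
#'   area distribution.
#' @param extent_km Side (km) of the square region plot coordinates are drawn
#'   from.
#' @param noise_sd Named list of observation-noise standard deviations:
#'   `h_max` (m), `cover` (percentage points), `h_cv`, `rumple_norm` (1/m),
#'   `basal_area` (m2/ha) on the natural scale, and `log10_density`
#'   (decades of trees/ha, applied on the log10 scale).
#' @param seed Integer seed; every random draw in the generator descends
#'   from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_plots = 250,
                             age_range = c(1, 450),
                             rainfall_range = c(250, 330),
                             age_rainfall_correlation = 0,
                             plot_area_mean = 4.4,
                             plot_area_sd = 2.0,
                             extent_km = 600,
                             noise_sd = list(
                               h_max = 1.2, cover = 7, h_cv = 0.07,
                               rumple_norm = 0.04, basal_area = 2.5,
                               log10_density = 0.15
                             ),
                             seed = 1L) {
  check_number(n_plots, "n_plots", lower = 10)
  check_number(age_rainfall_correlation, "age_rainfall_correlation",
               lower = -1, upper = 0)
  check_number(plot_area_mean, "plot_area_mean", lower = 0.01)
  check_number(plot_area_sd, "plot_area_sd", lower = 0)
  check_number(extent_km, "extent_km", lower = 1)
  if (length(age_range) != 2 || diff(age_range) <= 0 ||
      length(rainfall_range) != 2 || diff(rainfall_range) <= 0) {
    fc_abort("age_range and rainfall_range must be non-degenerate increasing intervals",
             "firecanopy_bad_argument")
  }
  defaults <- list(h_max = 1.2, cover = 7, h_cv = 0.07, rumple_norm = 0.04,
                   basal_area = 2.5, log10_density = 0.15)
  noise_sd <- utils::modifyList(defaults, as.list(noise_sd))
  if (any(unlist(noise_sd) < 0)) {
    fc_abort("noise standard deviations must be >= 0", "firecanopy_bad_argument")
  }
  structure(
    list(
      n_plots = as.integer(n_plots), age_range = age_range,
      rainfall_range = rainfall_range,
      age_rainfall_correlation = age_rainfall_correlation,
      plot_area_mean = plot_area_mean, plot_area_sd = plot_area_sd,
      extent_km = extent_km, noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# lognormal parameters from a target mean and sd on the natural scale
lognormal_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate a plot-level chronosequence table (Tier A)
#'
#' Draws a synthetic network of chronosequence plots: stand ages and rainfall
#' (uniform on their ranges, optionally negatively correlated through a
#' Gaussian copula), lognormal plot areas, uniform plot coordinates, and the
#' six structural/field metrics as truth-curve values plus Gaussian
#' observation noise. Noise is clamped to each metric's valid range (cover to
#' \[0, 100\], heights, H_cv, rumple and basal area to be non-negative);
#' tree-density noise is applied on the log10 scale so the density
#' distribution stays skewed and positive. The result is fully reproducible
#' from `config$seed`.
#'
#' @param truth A [trajectory_truth()] object.
#' @param config A [generator_config()].
#' @return A tibble with one row per plot and the standard plot-table columns
#'   (`plot_id`, `stand_age_yr`, `rainfall_mm_yr`, `plot_area_ha`, `x_km`,
#'   `y_km`, `h_max_m`, `cover_5m_pct`, `h_cv`, `rumple_norm`,
#'   `basal_area_m2ha`, `tree_density_ha`).
#' @examples
#' tr <- trajectory_truth()
#' plots <- simulate_plot_table(tr, generator_config(seed = 42))
#' dplyr::glimpse(plots)
#' @export
simulate_plot_table <- function(truth, config = generator_config()) {
  stopifnot(inherits(truth, "trajectory_truth"),
            inherits(config, "generator_config"))
  n <- config$n_plots
  with_local_seed(config$seed, {
    rho <- config$age_rainfall_correlation
    if (rho != 0) {
      # Gaussian copula; Pearson correlation of the normals chosen so the
      # uniforms' correlation matches the configured value
      rho_z <- 2 * sin(pi * rho / 6)
      z1 <- rnorm(n)
      z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * rnorm(n)
      u_age <- pnorm(z1)
      u_rain <- pnorm(z2)
    } else {
      u_age <- runif(n)
      u_rain <- runif(n)
    }
    age <- config$age_range[1] + u_age * diff(config$age_range)
    rain <- config$rainfall_range[1] + u_rain * diff(config$rainfall_range)
    lp <- lognormal_params(config$plot_area_mean, config$plot_area_sd)
    area <- rlnorm(n, lp$meanlog, lp$sdlog)
    x <- runif(n, 0, config$extent_km)
    y <- runif(n, 0, config$extent_km)

    ns <- config$noise_sd
    tv <- function(m) truth_value(truth, m, age, rain, area)
    h_max <- pmax(tv("h_max") + rnorm(n, 0, ns$h_max), 0)
    cover <- pmin(pmax(tv("cover") + rnorm(n, 0, ns$cover), 0), 100)
    h_cv <- pmax(tv("h_cv") + rnorm(n, 0, ns$h_cv), 0)
    rumple <- pmax(tv("rumple_norm") + rnorm(n, 0, ns$rumple_norm), 0)
    basal <- pmax(tv("basal_area") + rnorm(n, 0, ns$basal_area), 0)
    dens <- 10^(log10(tv("tree_density")) + rnorm(n, 0, ns$log10_density))

    tibble::tibble(
      plot_id = sprintf("plot_%03d", seq_len(n)),
      stand_age_yr = age,
      rainfall_mm_yr = rain,
      plot_area_ha = area,
      x_km = x,
      y_km = y,
      h_max_m = h_max,
      cover_5m_pct = cover,
      h_cv = h_cv,
      rumple_norm = rumple,
      basal_area_m2ha = basal,
      tree_density_ha = dens
    )
  })
}
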