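#' Parametric "truth" trajectories for the synthetic chronosequence
#'
#' Constructs the set of ground-truth recovery curves that the synthetic
#' generator draws from: canopy cover, maximum canopy height, height
#' heterogeneity (H_cv), normalized rumple, basal area and tree density, each
#' as a smooth function of stand age, plus linear-in-rainfall effects and
#' log-plot-size effects. The curve families are fixed (a gamma-type hump for
#' cover, monomolecular rise for H_max, exponential decay for density, a
#' lognormal hump for basal area and rumple, and a two-component decay-plus-
#' power curve for H_cv) but each is anchored to interpretable features —
#' peak value and age, end-of-chronosequence value, minimum age — and the
#' remaining shape parameter is solved at construction, so the anchors hold
#' exactly whatever the family.
#'
#' Default anchors describe a semi-arid obligate-seeder eucalypt woodland
#' chronosequence: cover at 5 m peaking at 48% around 120 yr post-fire and
#' declining to 20% by 450 yr; top height rising to a 15.5 m asymptote
#' (e-folding time 65 yr); tree density collapsing from ~6000 to ~20
#' trees/ha; basal area peaking at 15 m2/ha near 160 yr and back to
#' 10 m2/ha by 420 yr; H_cv high in young stands (standing dead trees),
#' minimal at 75 yr, rising again in old growth; rumple peaking near 60 yr.
#' Rainfall effects are expressed as the contrast over the 260 to 302 mm/yr
#' interval (the 5th and 95th percentiles of the rainfall gradient): +1.2 m
#' for H_max and +7 percentage points for cover (additive), -10% for H_cv
#' and +5% for rumple (relative), nothing for the field metrics. Plot size
#' enters as coefficient * ln(area / 4.4 ha).
#'
#' @param cover_peak,cover_peak_age Peak canopy cover (%) and its age (yr).
#' @param cover_end_age,cover_end Anchor age (yr) and cover (%) at the old end;
#'   must be below `cover_peak`.
#' @param hmax_asymptote,hmax_tau Asymptotic top height (m) and e-folding time
#'   (yr) of the monomolecular rise.
#' @param density_floor,density_initial,density_tau Old-growth floor, age-0
#'   intercept (trees/ha) and decay time (yr) of tree density.
#' @param basal_peak,basal_peak_age Peak basal area (m2/ha) and its age (yr).
#' @param basal_anchor_age,basal_anchor Anchor age and basal area on the
#'   declining limb; must be below `basal_peak`.
#' @param hcv_base,hcv_young_amp,hcv_old_amp,hcv_old_gamma H_cv curve
#'   components: baseline, young-stand (snag-driven) amplitude, old-growth
#'   amplitude and its power.
#' @param hcv_min_age Age (yr) at which H_cv attains its minimum; the young
#'   decay time is solved from it.
#' @param rumple_base,rumple_amp,rumple_peak_age,rumple_sigma Normalized
#'   rumple (1/m) baseline, hump amplitude, peak age and lognormal width.
#' @param rainfall_effects Named numeric vector of per-metric contrasts over
#'   `rainfall_contrast_interval`: additive for `h_max` (m), `cover`
#'   (percentage points) and `basal_area`; relative for `h_cv`,
#'   `rumple_norm` and `tree_density`.
#' @param plot_size_effects Named numeric vector of per-metric coefficients on
#'   `ln(area / area_reference)` (additive for `h_max`, `cover`,
#'   `basal_area`; relative for the rest, like `rainfall_effects`).
#' @param rainfall_reference Rainfall (mm/yr) at which the base curves apply.
#' @param rainfall_contrast_interval Length-2 interval (mm/yr) over which the
#'   rainfall contrasts are defined.
#' @param area_reference Reference plot area (ha).
#' @param age_range Ages (yr) over which the curves are considered valid.
#'
#' @return An object of class `trajectory_truth`: a list with the solved
#'   shape parameters (`cover_shape`, `basal_sigma`, `hcv_tau`), the base
#'   curve functions (`curves$<metric>`), and the effect settings. Evaluate
#'   with [truth_value()].
#' @seealso [truth_value()], [simulate_plot_table()]
#' @examples
#' tr <- trajectory_truth()
#' truth_value(tr, "cover", c(120, 450))
#' @export
trajectory_truth <- function(cover_peak = 48, cover_peak_age = 120,
                             cover_end_age = 450, cover_end = 20,
                             hmax_asymptote = 15.5, hmax_tau = 65,
                             density_floor = 20, density_initial = 6000,
                             density_tau = 45,
                             basal_peak = 15, basal_peak_age = 160,
                             basal_anchor_age = 420, basal_anchor = 10,
                             hcv_base = 0.25, hcv_young_amp = 0.45,
                             hcv_old_amp = 0.35, hcv_old_gamma = 1.5,
                             hcv_min_age = 75,
                             rumple_base = 0.10, rumple_amp = 0.25,
                             rumple_peak_age = 60, rumple_sigma = 1.0,
                             rainfall_effects = c(
                               h_max = 1.2, cover = 7, h_cv = -0.10,
                               rumple_norm = 0.05, basal_area = 0,
                               tree_density = 0
                             ),
                             plot_size_effects = c(
                               h_max = 0.8, cover = 0, h_cv = 0.02,
                               rumple_norm = 0.01, basal_area = 0,
                               tree_density = 0
                             ),
                             rainfall_reference = 290,
                             rainfall_contrast_interval = c(260, 302),
                             area_reference = 4.4,
                             age_range = c(1, 450)) {
  check_number(cover_peak, "cover_peak", lower = 0)
  check_number(cover_peak_age, "cover_peak_age", lower = 0)
  check_number(cover_end, "cover_end", lower = 0)
  check_number(hcv_min_age, "hcv_min_age", lower = 1)
  if (cover_end >= cover_peak) {
    fc_abort("cover end anchor must lie below the peak (hump-shaped curve)",
             "firecanopy_unsolvable_anchor")
  }
  if (basal_anchor >= basal_peak) {
    fc_abort("basal-area anchor must lie below the peak (hump-shaped curve)",
             "firecanopy_unsolvable_anchor")
  }
  if (cover_end_age <= cover_peak_age || basal_anchor_age <= basal_peak_age) {
    fc_abort("end anchors must lie beyond the peak age",
             "firecanopy_unsolvable_anchor")
  }

  # cover: C(t) = peak * (t/tp)^a * exp(a * (1 - t/tp)); a from the end anchor
  ratio <- cover_end_age / cover_peak_age
  cover_shape <- log(cover_end / cover_peak) / (log(ratio) + 1 - ratio)
  if (!is.finite(cover_shape) || cover_shape <= 0) {
    fc_abort("cover anchors give a non-positive shape exponent",
             "firecanopy_unsolvable_anchor")
  }

  # basal area: lognormal hump; width from the declining-limb anchor
  basal_sigma <- abs(log(basal_anchor_age / basal_peak_age)) /
    sqrt(2 * log(basal_peak / basal_anchor))

  # H_cv: base + A_y * exp(-t/tau) + A_o * (t/450)^gamma, tau solved so the
  # derivative vanishes at hcv_min_age; the exp term decays and the power term
  # grows, so that stationary point is the minimum
  t_old <- 450
  dmin <- function(tau) {
    hcv_young_amp * exp(-hcv_min_age / tau) / tau -
      hcv_old_amp * hcv_old_gamma / t_old * (hcv_min_age / t_old)^(hcv_old_gamma - 1)
  }
  lo <- 1e-3
  hi <- hcv_min_age
  if (dmin(hi) <= 0) {
    fc_abort("H_cv minimum-age anchor is unsolvable for these amplitudes",
             "firecanopy_unsolvable_anchor")
  }
  hcv_tau <- uniroot(dmin, c(lo, hi), tol = 1e-10)$root

  curves <- list(
    cover = function(t) {
      cover_peak * (t / cover_peak_age)^cover_shape *
        exp(cover_shape * (1 - t / cover_peak_age))
    },
    h_max = function(t) hmax_asymptote * (1 - exp(-t / hmax_tau)),
    tree_density = function(t) {
      density_floor + (density_initial - density_floor) * exp(-t / density_tau)
    },
    basal_area = function(t) {
      basal_peak * exp(-(log(t / basal_peak_age))^2 / (2 * basal_sigma^2))
    },
    h_cv = function(t) {
      hcv_base + hcv_young_amp * exp(-t / hcv_tau) +
        hcv_old_amp * (t / t_old)^hcv_old_gamma
    },
    rumple_norm = function(t) {
      rumple_base + rumple_amp *
        exp(-(log(t / rumple_peak_age))^2 / (2 * rumple_sigma^2))
    }
  )

  structure(
    list(
      curves = curves,
      cover_shape = cover_shape,
      basal_sigma = basal_sigma,
      hcv_tau = hcv_tau,
      rainfall_effects = rainfall_effects,
      plot_size_effects = plot_size_effects,
      rainfall_reference = rainfall_reference,
      rainfall_contrast_interval = rainfall_contrast_interval,
      area_reference = area_reference,
      age_range = age_range,
      hmax_asymptote = hmax_asymptote
    ),
    class = "trajectory_truth"
  )
}

#' Metrics with truth curves
#'
#' Canonical metric names used across the package, in the column order of the
#' plot table.
#' @return Character vector of the six metric names.
#' @export
truth_metrics <- function() {
  c("h_max", "cover", "h_cv", "rumple_norm", "basal_area", "tree_density")
}

# metrics whose rainfall / plot-size effects are relative (multiplicative)
.relative_effect_metrics <- c("h_cv", "rumple_norm", "tree_density")

#' Evaluate a truth trajectory
#'
#' Evaluates one metric's ground-truth value at given stand ages, rainfall and
#' plot area, combining the base age curve with the rainfall and plot-size
#' effects and clamping to the metric's valid range (cover to \[0, 100\],
#' everything else to be non-negative).
#'
#' @param truth A [trajectory_truth()] object.
#' @param metric One of `truth_metrics()`.
#' @param age Stand ages (yr); vectorized.
#' @param rainfall Mean annual rainfall (mm/yr); defaults to the truth's
#'   reference rainfall (no rainfall effect).
#' @param area Plot area (ha); defaults to the reference area (no size effect).
#' @return Numeric vector of truth values, same length as `age`.
#' @export
truth_value <- function(truth, metric, age,
                        rainfall = truth$rainfall_reference,
                        area = truth$area_reference) {
  stopifnot(inherits(truth, "trajectory_truth"))
  metric <- match.arg(metric, truth_metrics())
  base <- truth$curves[[metric]](age)
  span <- diff(truth$rainfall_contrast_interval)
  r_eff <- truth$rainfall_effects[[metric]]
  a_eff <- truth$plot_size_effects[[metric]]
  dr <- (rainfall - truth$rainfall_reference) / span
  la <- log(area / truth$area_reference)
  if (metric %in% .relative_effect_metrics) {
    out <- base * (1 + r_eff * dr) * (1 + a_eff * la)
  } else {
    out <- base + r_eff * dr + a_eff * la
  }
  out <- pmax(out, 0)
  if (metric == "cover") out <- pmin(out, 100)
  out
}

#' @export
print.trajectory_truth <- function(x, ...) {
  cat("<trajectory_truth>\n")
  cat(sprintf("  cover shape exponent: %.4f\n", x$cover_shape))
  cat(sprintf("  basal-area sigma:     %.4f\n", x$basal_sigma))
  cat(sprintf("  H_cv young tau:       %.2f yr\n", x$hcv_tau))
  cat(sprintf("  reference rainfall:   %g mm/yr, reference area: %g ha\n",
              x$rainfall_reference, x$area_reference))
  invisible(x)
}
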