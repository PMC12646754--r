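#' Poisson intensity that achieves a target Boolean-model cover
#'
#' Under a Boolean model (crown disks of mean area `mean_crown_area` centred
#' on a homogeneous Poisson process of intensity `lambda`), the expected
#' covered fraction is `1 - exp(-lambda * mean_crown_area)`. This inverts
#' that relation: the intensity whose expected cover equals `target_cover`.
#'
#' @param target_cover Covered fraction in \[0, 1).
#' @param mean_crown_area Mean crown disk area (m2), > 0.
#' @return Intensity (trees per m2).
#' @examples
#' boolean_density_for_cover(0.48, 20) * 1e4 # trees per ha
#' @export
boolean_density_for_cover <- function(target_cover, mean_crown_area) {
  check_number(mean_crown_area, "mean_crown_area", lower = 1e-9)
  if (!is_number(target_cover) || target_cover < 0 || target_cover >= 1) {
    fc_abort("target_cover must be in [0, 1): full cover is unreachable under a Boolean model",
             "firecanopy_bad_argument")
  }
  -log(1 - target_cover) / mean_crown_area
}

# moments of a normal truncated below at `a`
truncnorm_moments <- function(mu, sigma, a) {
  alpha <- (a - mu) / sigma
  lambda <- stats::dnorm(alpha) / (1 - stats::pnorm(alpha))
  m1 <- mu + sigma * lambda
  v <- sigma^2 * (1 - lambda * (lambda - alpha))
  list(mean = m1, var = max(v, 0), m2 = max(v, 0) + m1^2)
}

# sample a normal truncated below at `a` by the inverse-CDF method
rtruncnorm_lower <- function(n, mu, sigma, a) {
  p0 <- stats::pnorm(a, mu, sigma)
  u <- runif(n, p0, 1)
  stats::qnorm(pmin(u, 1 - 1e-12), mu, sigma)
}

#' Simulate an explicit tree-level stand scene (Tier B)
#'
#' Builds a synthetic stand for one plot: live canopy trees placed by a
#' homogeneous Poisson process whose intensity is calibrated (via
#' [boolean_density_for_cover()]) so that the expected crown cover above the
#' height threshold matches the truth cover curve at that age, plus an
#' exponentially-decaying population of snags (standing dead trees) drawn
#' from the pre-fire height distribution as near-zero-crown spikes. In young
#' stands whose truth top height is still below the cover threshold the live
#' cohort is instead a dense layer of sub-threshold saplings placed from the
#' tree-density curve, so very young scenes carry no live element above the
#' threshold and their rasters have (snags aside) zero cover.
#'
#' @param age Stand age (yr), within the truth's age range.
#' @param rainfall Mean annual rainfall (mm/yr).
#' @param area Plot area (ha); scenes are square.
#' @param truth A [trajectory_truth()] object.
#' @param seed Integer seed.
#' @param cover_threshold Height threshold (m) defining canopy cover.
#' @param height_sd Sd (m) of live canopy tree heights around the truth top
#'   height.
#' @param crown_ratio Crown radius as a fraction of tree height.
#' @param snags Include the snag layer?
#' @param snag_initial_density Snag density (per ha) immediately after fire.
#' @param snag_half_life Snag-fall half-life (yr).
#' @param snag_crown_radius Snag spike radius (m), <= 0.5.
#' @return A `stand_scene`: list with a `trees` tibble (`x`, `y`, `height`,
#'   `crown_radius`, `crown_form`, `is_snag`), the square `extent` (m), and
#'   the scene's `age`, `rainfall` and `cover_threshold`.
#' @seealso [rasterize_scene()]
#' @export
simulate_stand_scene <- function(age, rainfall = NULL, area = 1, truth = trajectory_truth(),
                                 seed = 1L, cover_threshold = 5,
                                 height_sd = 1, crown_ratio = 0.18,
                                 snags = TRUE, snag_initial_density = 200,
                                 snag_half_life = 20, snag_crown_radius = 0.3) {
  stopifnot(inherits(truth, "trajectory_truth"))
  check_number(age, "age", lower = truth$age_range[1], upper = truth$age_range[2])
  check_number(area, "area", lower = 1e-4)
  if (snag_crown_radius > 0.5) {
    fc_abort("snags are near-zero-crown spikes: snag_crown_radius must be <= 0.5 m",
             "firecanopy_bad_argument")
  }
  if (is.null(rainfall)) rainfall <- truth$rainfall_reference
  side <- sqrt(area * 1e4)
  h_top <- truth_value(truth, "h_max", age, rainfall)

  with_local_seed(seed, {
    trees <- list()
    if (h_top > cover_threshold + 0.5) {
      # canopy cohort: Boolean calibration against the truth cover
      target <- truth_value(truth, "cover", age, rainfall) / 100
      mom <- truncnorm_moments(h_top, height_sd, cover_threshold)
      mean_crown_area <- pi * crown_ratio^2 * mom$m2
      lambda <- boolean_density_for_cover(min(target, 0.98), mean_crown_area)
      n <- rpois(1, lambda * side^2)
      if (n > 0) {
        h <- rtruncnorm_lower(n, h_top, height_sd, cover_threshold)
        trees$canopy <- tibble::tibble(
          x = runif(n, 0, side), y = runif(n, 0, side), height = h,
          crown_radius = crown_ratio * h,
          crown_form = "spherical-cap", is_snag = FALSE
        )
      }
    } else {
      # sapling cohort: sub-threshold regrowth, density from the truth curve
      dens <- truth_value(truth, "tree_density", age, rainfall) / 1e4
      n <- rpois(1, dens * side^2)
      if (n > 0) {
        h <- pmin(rtruncnorm_lower(n, h_top, 0.15 * h_top + 0.05, 0.05),
                  cover_threshold - 0.01)
        trees$saplings <- tibble::tibble(
          x = runif(n, 0, side), y = runif(n, 0, side), height = h,
          crown_radius = crown_ratio * h,
          crown_form = "cone", is_snag = FALSE
        )
      }
    }
    if (snags) {
      sd_dens <- snag_initial_density * 2^(-age / snag_half_life) / 1e4
      n <- rpois(1, sd_dens * side^2)
      if (n > 0) {
        # pre-fire height distribution: mature-stand top heights
        h_mature <- truth_value(truth, "h_max", truth$age_range[2], rainfall)
        h <- rtruncnorm_lower(n, h_mature, 2, cover_threshold)
        trees$snags <- tibble::tibble(
          x = runif(n, 0, side), y = runif(n, 0, side), height = h,
          crown_radius = snag_crown_radius,
          crown_form = "cone", is_snag = TRUE
        )
      }
    }
    trees <- if (length(trees)) dplyr::bind_rows(trees) else tibble::tibble(
      x = numeric(), y = numeric(), height = numeric(),
      crown_radius = numeric(), crown_form = character(), is_snag = logical()
    )
    structure(
      list(trees = trees, extent = c(side, side), age = age,
           rainfall = rainfall, cover_threshold = cover_threshold),
      class = "stand_scene"
    )
  })
}

#' @export
print.stand_scene <- function(x, ...) {
  cat(sprintf("<stand_scene> age %g yr, %.0f x %.0f m, %d trees (%d snags)\n",
              x$age, x$extent[1], x$extent[2], nrow(x$trees), sum(x$trees$is_snag)))
  invisible(x)
}

#' Rasterize a stand scene into a canopy height model
#'
#' Converts an explicit tree list into a CHM by max-compositing crown
#' surfaces over pixel centres: each pixel takes the maximum height of any
#' crown surface covering its centre, and 0 (bare ground) otherwise. Cone
#' crowns fall linearly from the apex to zero at the crown edge; spherical-cap
#' crowns follow the upper hemisphere of radius equal to the crown radius,
#' centred that distance below the apex. Deterministic given the scene.
#'
#' @param scene A [simulate_stand_scene()] result.
#' @param resolution Pixel size (m), > 0.
#' @return A [chm()] raster with origin (0, 0).
#' @export
rasterize_scene <- function(scene, resolution = 1) {
  stopifnot(inherits(scene, "stand_scene"))
  check_number(resolution, "resolution", lower = 1e-6)
  nx <- max(1L, floor(scene$extent[1] / resolution))
  ny <- max(1L, floor(scene$extent[2] / resolution))
  z <- matrix(0, nrow = ny, ncol = nx)
  xs <- (seq_len(nx) - 0.5) * resolution
  ys <- (seq_len(ny) - 0.5) * resolution # row index from the south here
  tr <- scene$trees
  for (i in seq_len(nrow(tr))) {
    r <- tr$crown_radius[i]
    if (r <= 0) next
    h <- tr$height[i]
    cx <- tr$x[i]; cy <- tr$y[i]
    jx <- which(abs(xs - cx) < r)
    jy <- which(abs(ys - cy) < r)
    if (!length(jx) || !length(jy)) next
    d <- sqrt(outer((ys[jy] - cy)^2, (xs[jx] - cx)^2, `+`))
    if (tr$crown_form[i] == "cone") {
      zi <- h * (1 - d / r)
    } else {
      zi <- (h - r) + sqrt(pmax(r^2 - d^2, 0))
    }
    zi[d >= r] <- 0
    z[jy, jx] <- pmax(z[jy, jx], zi)
  }
  # matrix convention: row 1 = northernmost row
  chm(z[rev(seq_len(ny)), , drop = FALSE], resolution = resolution,
      origin = c(0, 0))
}
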