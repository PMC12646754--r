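valid_heights <- function(x) {
  v <- x$heights[!is.na(x$heights)]
  if (!length(v)) {
    fc_abort("raster has no valid (non-nodata) pixels", "firecanopy_empty_raster")
  }
  v
}

#' Maximum canopy height (upper height percentile)
#'
#' The plot-level maximum canopy height H_max, computed as an upper
#' percentile (default the 98th) of all valid CHM pixel heights, ground
#' zeros included. Quantiles use the linear-interpolation convention
#' (`stats::quantile()` type 7). Using a high percentile rather than the
#' literal maximum makes the metric robust to isolated spikes such as
#' standing dead trees.
#'
#' @param x A [chm()] object.
#' @param q Quantile in \[0, 1\]; `q = 1` gives the exact maximum.
#' @return Height in m.
#' @export
chm_h_max <- function(x, q = 0.98) {
  stopifnot(inherits(x, "chm"))
  check_number(q, "q", lower = 0, upper = 1)
  unname(quantile(valid_heights(x), probs = q, type = 7))
}

#' Canopy cover above a height threshold
#'
#' Percentage of valid CHM pixels whose height strictly exceeds the
#' threshold (default 5 m, a height chosen so that standing dead stems and
#' low regrowth do not count as canopy).
#'
#' @param x A [chm()] object.
#' @param threshold Height threshold in m, >= 0.
#' @return Cover in percent (0-100).
#' @export
chm_cover <- function(x, threshold = 5) {
  stopifnot(inherits(x, "chm"))
  if (!is_number(threshold) || threshold < 0) {
    fc_abort("threshold must be a single non-negative height (m)",
             "firecanopy_bad_argument")
  }
  v <- valid_heights(x)
  100 * sum(v > threshold) / length(v)
}

#' Coefficient of variation of canopy height
#'
#' Height heterogeneity H_cv: the sample standard deviation of canopy
#' heights divided by their mean, computed over the pixels strictly above
#' the cover threshold. Restricting to canopy pixels keeps the coefficient
#' in a bounded, interpretable range; including the ground zeros of an open
#' woodland would let it blow up as cover goes to zero. With fewer than two
#' qualifying pixels the metric is undefined: a classed warning
#' (`firecanopy_undefined_metric`) is emitted and `NA` returned.
#'
#' @inheritParams chm_cover
#' @return Dimensionless CV, or `NA` if undefined.
#' @export
chm_h_cv <- function(x, threshold = 5) {
  stopifnot(inherits(x, "chm"))
  v <- valid_heights(x)
  v <- v[v > threshold]
  if (length(v) < 2) {
    return(fc_undefined(sprintf(
      "H_cv undefined: %d pixel(s) above %g m (need >= 2)", length(v), threshold
    )))
  }
  sd(v) / mean(v)
}

# triangulated 3D surface area of the pixel-centre grid; fixed diagonal from
# the lower-left to the upper-right corner of every cell
chm_surface_area <- function(x) {
  z <- x$heights
  d <- dim(z)
  if (d[1] < 2 || d[2] < 2) {
    fc_abort("rumple needs a raster of at least 2 x 2 pixels",
             "firecanopy_bad_argument")
  }
  r <- x$resolution
  ul <- z[-d[1], -d[2], drop = FALSE]
  ur <- z[-d[1], -1, drop = FALSE]
  ll <- z[-1, -d[2], drop = FALSE]
  lr <- z[-1, -1, drop = FALSE]
  # triangle (LL, LR, UR): cross product gives (-r*dB, r*(dB-dC), r^2)
  dB <- lr - ll
  dC <- ur - ll
  a1 <- 0.5 * r * sqrt(dB^2 + (dB - dC)^2 + r^2)
  # triangle (LL, UR, UL)
  dB2 <- ur - ll
  dC2 <- ul - ll
  a2 <- 0.5 * r * sqrt((dC2 - dB2)^2 + dC2^2 + r^2)
  ok <- !(is.na(ul) | is.na(ur) | is.na(ll) | is.na(lr))
  if (!any(ok)) {
    fc_abort("no cell of the raster has four valid corners",
             "firecanopy_empty_raster")
  }
  list(surface = sum(a1[ok]) + sum(a2[ok]),
       ground = sum(ok) * r^2)
}

#' Normalized rumple index
#'
#' Canopy rugosity: the 3D surface area of the canopy height field divided
#' by its ground-projected area (the classical rumple index), further
#' divided by the maximum canopy height so that tall and short canopies are
#' comparable. The surface is triangulated over the pixel-centre grid, each
#' cell split into two 3D triangles along a fixed lower-left to upper-right
#' diagonal; the ground area is the summed area of the cells with four
#' valid corners (`(ncols-1) * (nrows-1) * resolution^2` for a complete
#' raster). A flat raster at height h therefore gives exactly `1 / h`.
#'
#' @inheritParams chm_h_max
#' @param q Quantile used for the H_max normalization.
#' @return Normalized rumple in 1/m.
#' @export
chm_rumple_norm <- function(x, q = 0.98) {
  stopifnot(inherits(x, "chm"))
  hm <- chm_h_max(x, q)
  if (hm <= 0) {
    fc_abort("rumple normalization undefined: H_max is 0",
             "firecanopy_zero_hmax")
  }
  sa <- chm_surface_area(x)
  (sa$surface / sa$ground) / hm
}

#' Compute all structural metrics for one CHM
#'
#' Evaluates the four canopy 3D structural metrics (H_max, cover above the
#' threshold, H_cv, normalized rumple) plus the mean height on one raster,
#' consistently with the individual metric functions. An undefined H_cv
#' (fewer than two canopy pixels) or an undefined rumple (H_max of 0) is
#' captured as `NA` rather than an error, so that degenerate rasters — for
#' example freshly burned plots with no canopy — still yield a metrics row.
#'
#' @inheritParams chm_h_max
#' @param threshold Cover / canopy height threshold (m).
#' @return A one-row tibble with columns `h_max_m`, `cover_5m_pct`, `h_cv`,
#'   `rumple_norm`, `mean_height_m`, `threshold_m`, `quantile`,
#'   `n_valid_pixels`.
#' @examples
#' flat <- chm(matrix(10, 8, 8))
#' chm_metrics(flat)
#' @export
chm_metrics <- function(x, threshold = 5, q = 0.98) {
  stopifnot(inherits(x, "chm"))
  v <- valid_heights(x)
  hm <- chm_h_max(x, q)
  rumple <- if (hm > 0 && all(dim(x$heights) >= 2)) chm_rumple_norm(x, q) else NA_real_
  tibble::tibble(
    h_max_m = hm,
    cover_5m_pct = chm_cover(x, threshold),
    h_cv = suppressWarnings(chm_h_cv(x, threshold)),
    rumple_norm = rumple,
    mean_height_m = mean(v),
    threshold_m = threshold,
    quantile = q,
    n_valid_pixels = length(v)
  )
}

#' Attach CHM-derived metrics to a plot table
#'
#' Computes [chm_metrics()] for each plot's raster and joins the metric
#' columns onto the plot table. Rasters are supplied either as a named list
#' of [chm()] objects or as a directory containing one `<plot_id>.tif` /
#' `<plot_id>.asc` file per plot.
#'
#' @param plots A plot table (see [read_plot_table()]).
#' @param rasters Named list of [chm()] objects, or a directory path.
#' @param threshold,q Metric settings, as in [chm_metrics()].
#' @return The plot table with the metric columns replaced/added.
#' @export
compute_plot_metrics <- function(plots, rasters, threshold = 5, q = 0.98) {
  validate_plot_table(plots)
  get_chm <- function(id) {
    if (is.character(rasters)) {
      if (!dir.exists(rasters)) {
        fc_abort(sprintf("raster directory '%s' does not exist", rasters),
                 "firecanopy_io_error")
      }
      hits <- list.files(rasters, pattern = paste0("^", id, "\\.(tif|tiff|asc|txt)$"),
                         full.names = TRUE)
      if (!length(hits)) {
        fc_abort(sprintf("no raster found for plot '%s' in '%s'", id, rasters),
                 "firecanopy_io_error")
      }
      read_chm(hits[1])
    } else {
      if (is.null(rasters[[id]])) {
        fc_abort(sprintf("no raster supplied for plot '%s'", id),
                 "firecanopy_io_error")
      }
      rasters[[id]]
    }
  }
  met <- purrr::map_dfr(plots$plot_id, function(id) {
    dplyr::mutate(chm_metrics(get_chm(id), threshold = threshold, q = q),
                  plot_id = id)
  })
  plots |>
    dplyr::select(-dplyr::any_of(setdiff(names(met), "plot_id"))) |>
    dplyr::left_join(met, by = "plot_id")
}
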