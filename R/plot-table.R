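plot_table_required <- c("plot_id", "stand_age_yr", "rainfall_mm_yr", "plot_area_ha")

plot_table_numeric <- c(
  "stand_age_yr", "rainfall_mm_yr", "plot_area_ha", "x_km", "y_km",
  "h_max_m", "cover_5m_pct", "h_cv", "rumple_norm", "basal_area_m2ha",
  "tree_density_ha"
)

validate_plot_table <- function(tbl, path = "<table>") {
  missing <- setdiff(plot_table_required, names(tbl))
  if (length(missing)) {
    fc_abort(sprintf("%s is missing required column(s): %s", path,
                     paste(missing, collapse = ", ")), "firecanopy_io_error")
  }
  for (col in intersect(plot_table_numeric, names(tbl))) {
    v <- tbl[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) & !is.na(v))
      fc_abort(sprintf("%s: column '%s' is not numeric (first bad row: %d)",
                       path, col, if (length(bad)) bad[1] else 1L),
               "firecanopy_io_error")
    }
  }
  for (col in c("stand_age_yr", "rainfall_mm_yr", "plot_area_ha")) {
    bad <- which(!is.na(tbl[[col]]) & tbl[[col]] <= 0)
    if (length(bad)) {
      fc_abort(sprintf("%s: column '%s' must be > 0 (row %d has %g)",
                       path, col, bad[1], tbl[[col]][bad[1]]),
               "firecanopy_io_error")
    }
  }
  invisible(tbl)
}

#' Read or write a plot metadata/metrics table
#'
#' The plot table is a CSV with one row per chronosequence plot. Required
#' columns: `plot_id`, `stand_age_yr`, `rainfall_mm_yr`, `plot_area_ha`.
#' Recognized optional columns: `x_km`, `y_km`, `platform`, `h_max_m`,
#' `cover_5m_pct`, `h_cv`, `rumple_norm`, `basal_area_m2ha`,
#' `tree_density_ha`. Unknown columns are preserved, and the pair of
#' functions round-trips losslessly.
#'
#' @param path CSV path.
#' @return `read_plot_table()` returns a validated tibble.
#' @export
read_plot_table <- function(path) {
  if (!file.exists(path)) {
    fc_abort(sprintf("file '%s' does not exist", path), "firecanopy_io_error")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_plot_table(tbl, path)
}

#' @param table A plot-table tibble/data frame.
#' @rdname read_plot_table
#' @return `write_plot_table()` returns `path` invisibly.
#' @export
write_plot_table <- function(table, path) {
  validate_plot_table(table)
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}
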