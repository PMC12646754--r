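#' Canopy height model raster
#'
#' A minimal in-memory container for a canopy height model: a numeric matrix
#' of heights (m) with row 1 the northernmost row, a square pixel size, the
#' map coordinates of the lower-left (south-west) corner, and `NA` for
#' nodata. Heights in `[-0.01, 0)` (sub-centimetre ground noise) are clamped
#' to 0; anything more negative is rejected.
#'
#' @param heights Numeric matrix of canopy heights (m); `NA` marks nodata.
#' @param resolution Pixel size (m), > 0.
#' @param origin Length-2 map coordinates of the lower-left corner.
#' @param crs Optional CRS tag (free-form string, carried along only).
#' @return An object of class `chm`.
#' @export
chm <- function(heights, resolution = 1, origin = c(0, 0), crs = NULL) {
  if (!is.matrix(heights) || !is.numeric(heights) || !length(heights)) {
    fc_abort("heights must be a non-empty numeric matrix", "firecanopy_bad_raster")
  }
  check_number(resolution, "resolution", lower = 1e-9)
  if (length(origin) != 2 || !all(is.finite(origin))) {
    fc_abort("origin must be two finite map coordinates", "firecanopy_bad_raster")
  }
  storage.mode(heights) <- "double"
  v <- heights[!is.na(heights)]
  if (any(!is.finite(v))) {
    fc_abort("heights must be finite or NA", "firecanopy_bad_raster")
  }
  if (any(v < -0.01)) {
    fc_abort("negative canopy heights below -0.01 m are not a valid CHM",
             "firecanopy_bad_raster")
  }
  heights[!is.na(heights) & heights < 0] <- 0
  structure(
    list(heights = heights, resolution = resolution,
         origin = as.numeric(origin), crs = crs),
    class = "chm"
  )
}

#' @export
dim.chm <- function(x) dim(x$heights)

#' @export
print.chm <- function(x, ...) {
  d <- dim(x$heights)
  v <- x$heights[!is.na(x$heights)]
  cat(sprintf("<chm> %d x %d pixels @ %g m, origin (%g, %g)\n",
              d[1], d[2], x$resolution, x$origin[1], x$origin[2]))
  cat(sprintf("  heights: %.2f-%.2f m, %d nodata pixels\n",
              min(v), max(v), sum(is.na(x$heights))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# ESRI ASCII grid

read_asc <- function(path) {
  lines <- readLines(path, n = 7)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[a-zA-Z_]", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1
    } else {
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    fc_abort(sprintf("'%s' is not an ESRI ASCII grid (missing %s)", path,
                     paste(setdiff(need, names(hdr)), collapse = ", ")),
             "firecanopy_io_error")
  }
  if (!any(c("xllcorner", "xllcenter") %in% names(hdr)) ||
      !any(c("yllcorner", "yllcenter") %in% names(hdr))) {
    fc_abort(sprintf("'%s' has no georeferencing (xll/yll missing)", path),
             "firecanopy_io_error")
  }
  res <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - res / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - res / 2
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr) {
    fc_abort(sprintf("'%s': expected %d values, found %d", path, nc * nr,
                     length(vals)), "firecanopy_io_error")
  }
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  chm(m, resolution = res, origin = c(xll, yll))
}

write_asc <- function(x, path, nodata = -9999) {
  d <- dim(x$heights)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", x$origin[1]),
    sprintf("yllcorner %.10g", x$origin[2]),
    sprintf("cellsize %.10g", x$resolution),
    sprintf("NODATA_value %g", nodata)
  )
  m <- x$heights
  m[is.na(m)] <- nodata
  rows <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 9,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GeoTIFF (single band, float32). The `tiff` package reads pixel data but not
# the georeferencing tags, so the tag directory is parsed here directly.

tiff_type_info <- function(type) {
  # bytes per element and readBin spec for the TIFF field types used here
  switch(as.character(type),
    "1" = list(size = 1, what = "integer", bsize = 1, signed = FALSE),
    "2" = list(size = 1, what = "character"),
    "3" = list(size = 2, what = "integer", bsize = 2, signed = FALSE),
    "4" = list(size = 4, what = "integer", bsize = 4, signed = TRUE),
    "12" = list(size = 8, what = "double", bsize = 8),
    NULL
  )
}

read_tiff_tags <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(as.integer(magic), c(0x49L, 0x49L))) "little"
            else if (identical(as.integer(magic), c(0x4dL, 0x4dL))) "big"
            else fc_abort(sprintf("'%s' is not a TIFF file", path),
                          "firecanopy_io_error")
  fortytwo <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  if (fortytwo != 42) {
    fc_abort(sprintf("'%s' is not a TIFF file", path), "firecanopy_io_error")
  }
  ifd_off <- readBin(con, "integer", 1, 4, endian = endian)
  seek(con, ifd_off)
  n_tags <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  tags <- list()
  entries <- lapply(seq_len(n_tags), function(i) {
    id <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", 1, 4, endian = endian)
    raw_val <- readBin(con, "raw", 4)
    list(id = id, type = type, count = count, raw = raw_val)
  })
  for (e in entries) {
    info <- tiff_type_info(e$type)
    if (is.null(info)) next
    total <- info$size * e$count
    if (total <= 4) {
      data_raw <- e$raw[seq_len(total)]
    } else {
      off <- readBin(e$raw, "integer", 1, 4, endian = endian)
      seek(con, off)
      data_raw <- readBin(con, "raw", total)
    }
    val <- if (e$type == 2) {
      rawToChar(data_raw[data_raw != as.raw(0)])
    } else {
      readBin(data_raw, info$what, e$count, info$bsize,
              signed = if (is.null(info$signed)) TRUE else info$signed,
              endian = endian)
    }
    tags[[as.character(e$id)]] <- val
  }
  tags
}

read_geotiff <- function(path) {
  tags <- read_tiff_tags(path)
  scale <- tags[["33550"]]
  if (is.null(scale)) {
    fc_abort(sprintf("'%s' has no georeferencing (ModelPixelScale tag missing)",
                     path), "firecanopy_io_error")
  }
  if (abs(scale[1] - scale[2]) > 1e-9 * max(scale[1:2])) {
    fc_abort(sprintf("'%s' has non-square pixels (%g x %g m)", path,
                     scale[1], scale[2]), "firecanopy_io_error")
  }
  res <- scale[1]
  tie <- tags[["33922"]]
  if (is.null(tie) || length(tie) < 6 || any(tie[1:2] != 0)) {
    fc_abort(sprintf("'%s' has no usable ModelTiepoint georeferencing", path),
             "firecanopy_io_error")
  }
  # as.is keeps integer samples unnormalized; float images reject it and are
  # already read at native scale
  m <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                error = function(e) tiff::readTIFF(path))
  if (length(dim(m)) == 3) {
    if (dim(m)[3] != 1) {
      fc_abort(sprintf("'%s' is not a single-band raster", path),
               "firecanopy_io_error")
    }
    m <- m[, , 1]
  }
  nodata <- tags[["42113"]]
  if (!is.null(nodata)) {
    nd <- suppressWarnings(as.numeric(nodata))
    if (is.finite(nd)) m[abs(m - nd) < 1e-6 * max(1, abs(nd))] <- NA_real_
  }
  # tiepoint maps raster (0, 0) = top-left corner to map (X, Y)
  xll <- tie[4]
  yll <- tie[5] - nrow(m) * res
  chm(m, resolution = res, origin = c(xll, yll))
}

write_geotiff <- function(x, path, nodata = -9999) {
  d <- dim(x$heights)
  nr <- d[1]; nc <- d[2]
  m <- x$heights
  m[is.na(m)] <- nodata
  vals <- as.numeric(t(m)) # row-major, top row first
  nodata_str <- c(charToRaw(format(nodata, scientific = FALSE)), as.raw(0))
  if (length(nodata_str) %% 2 == 1) nodata_str <- c(nodata_str, as.raw(0))

  n_tags <- 13L
  ifd_start <- 8L
  ifd_size <- 2L + n_tags * 12L + 4L
  off_scale <- ifd_start + ifd_size
  off_tie <- off_scale + 24L
  off_nodata <- off_tie + 48L
  off_data <- off_nodata + length(nodata_str)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, 2, endian = "little")
  writeBin(ifd_start, con, 4, endian = "little")

  wtag <- function(id, type, count, value, inline_short = FALSE) {
    writeBin(as.integer(id), con, 2, endian = "little")
    writeBin(as.integer(type), con, 2, endian = "little")
    writeBin(as.integer(count), con, 4, endian = "little")
    if (inline_short) {
      writeBin(as.integer(value), con, 2, endian = "little")
      writeBin(0L, con, 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, 4, endian = "little")
    }
  }
  writeBin(n_tags, con, 2, endian = "little")
  wtag(256, 4, 1, nc)                          # ImageWidth
  wtag(257, 4, 1, nr)                          # ImageLength
  wtag(258, 3, 1, 32, inline_short = TRUE)     # BitsPerSample
  wtag(259, 3, 1, 1, inline_short = TRUE)      # Compression: none
  wtag(262, 3, 1, 1, inline_short = TRUE)      # Photometric: BlackIsZero
  wtag(273, 4, 1, off_data)                    # StripOffsets
  wtag(277, 3, 1, 1, inline_short = TRUE)      # SamplesPerPixel
  wtag(278, 4, 1, nr)                          # RowsPerStrip
  wtag(279, 4, 1, 4L * nr * nc)                # StripByteCounts
  wtag(339, 3, 1, 3, inline_short = TRUE)      # SampleFormat: IEEE float
  wtag(33550, 12, 3, off_scale)                # ModelPixelScale
  wtag(33922, 12, 6, off_tie)                  # ModelTiepoint
  wtag(42113, 2, length(nodata_str), off_nodata) # GDAL_NODATA
  writeBin(0L, con, 4, endian = "little")      # next IFD

  writeBin(c(x$resolution, x$resolution, 0), con, 8, endian = "little")
  y_top <- x$origin[2] + nr * x$resolution
  writeBin(c(0, 0, 0, x$origin[1], y_top, 0), con, 8, endian = "little")
  writeBin(nodata_str, con)
  writeBin(vals, con, 4, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Read a canopy height model raster
#'
#' Reads a CHM from a GeoTIFF (`.tif`/`.tiff`) or ESRI ASCII grid
#' (`.asc`/`.txt`), honouring the nodata value and taking the pixel size from
#' the file's georeferencing. Files without georeferencing, with non-square
#' pixels, or with heights below -0.01 m are rejected; heights in
#' `[-0.01, 0)` are clamped to 0.
#'
#' @param path Path to the raster file.
#' @return A [chm()] object.
#' @seealso [write_chm()], [crop_chm()]
#' @export
read_chm <- function(path) {
  if (!file.exists(path)) {
    fc_abort(sprintf("file '%s' does not exist", path), "firecanopy_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = read_geotiff(path),
    asc = , txt = read_asc(path),
    fc_abort(sprintf("unsupported raster format '.%s' (use GeoTIFF or ESRI ASCII grid)",
                     ext), "firecanopy_io_error")
  )
}

#' Write a canopy height model raster
#'
#' Writes a [chm()] to GeoTIFF (single band, 32-bit float, uncompressed, with
#' ModelPixelScale/ModelTiepoint georeferencing and a GDAL-style nodata tag)
#' or ESRI ASCII grid, chosen from the file extension. Round-trips with
#' [read_chm()].
#'
#' @param x A [chm()] object.
#' @param path Destination path ending in `.tif`, `.tiff`, `.asc` or `.txt`.
#' @param nodata Value written for `NA` pixels.
#' @return `path`, invisibly.
#' @export
write_chm <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "chm"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = write_geotiff(x, path, nodata),
    asc = , txt = write_asc(x, path, nodata),
    fc_abort(sprintf("unsupported raster format '.%s'", ext),
             "firecanopy_io_error")
  )
}

#' Crop a canopy height model to a bounding box
#'
#' Keeps the pixels whose centres fall inside the bounding box, using
#' half-open intervals (minimum edge inclusive, maximum edge exclusive), and
#' updates the georeferencing. Cropping to the same box twice is idempotent.
#'
#' @param x A [chm()] object.
#' @param bbox Numeric `c(xmin, xmax, ymin, ymax)` in map coordinates (named
#'   elements in any order are also accepted).
#' @return The cropped [chm()].
#' @export
crop_chm <- function(x, bbox) {
  stopifnot(inherits(x, "chm"))
  if (!is.null(names(bbox)) && all(c("xmin", "xmax", "ymin", "ymax") %in% names(bbox))) {
    bbox <- bbox[c("xmin", "xmax", "ymin", "ymax")]
  }
  if (length(bbox) != 4 || !all(is.finite(bbox)) ||
      bbox[1] >= bbox[2] || bbox[3] >= bbox[4]) {
    fc_abort("bbox must be finite c(xmin, xmax, ymin, ymax) with min < max",
             "firecanopy_bad_argument")
  }
  d <- dim(x$heights)
  res <- x$resolution
  xc <- x$origin[1] + (seq_len(d[2]) - 0.5) * res
  yc <- x$origin[2] + (d[1] - seq_len(d[1]) + 0.5) * res # per matrix row
  keep_col <- which(xc >= bbox[1] & xc < bbox[2])
  keep_row <- which(yc >= bbox[3] & yc < bbox[4])
  if (!length(keep_col) || !length(keep_row)) {
    fc_abort("bbox does not contain any pixel centre of this raster",
             "firecanopy_empty_crop")
  }
  new_origin <- c(
    x$origin[1] + (min(keep_col) - 1) * res,
    x$origin[2] + (d[1] - max(keep_row)) * res
  )
  chm(x$heights[keep_row, keep_col, drop = FALSE], resolution = res,
      origin = new_origin, crs = x$crs)
}
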