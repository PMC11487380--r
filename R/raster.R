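#' Categorical raster on a regular square-celled grid
#'
#' The common currency of the pipeline: an integer class grid with a
#' nodata code, a cell size in metres (square cells only), the (x, y)
#' coordinate of the upper-left corner, and an opaque CRS tag. Rows run
#' north to south (row index increases southward), columns west to east;
#' this matches the usual on-disk raster layout.
#'
#' @param grid integer matrix of class codes (rows = north to south).
#' @param scheme a [class_scheme()] the non-nodata codes must belong to.
#' @param cell_size_m positive cell edge length in metres.
#' @param nodata integer nodata code (default -9999).
#' @param origin numeric length-2, (x, y) of the upper-left corner.
#' @param crs_tag opaque character string; rasters only interoperate when
#'   their tags are equal.
#' @return An object of class `categorical_raster`.
#' @export
categorical_raster <- function(grid, scheme, cell_size_m,
                               nodata = -9999L,
                               origin = c(0, nrow(grid) * cell_size_m),
                               crs_tag = "") {
  if (!is.matrix(grid) || nrow(grid) < 1L || ncol(grid) < 1L) {
    stop("'grid' must be a matrix with at least one cell")
  }
  if (!inherits(scheme, "class_scheme")) stop("'scheme' must be a class_scheme")
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1L ||
      !is.finite(cell_size_m) || cell_size_m <= 0) {
    stop("'cell_size_m' must be a single positive number (square cells)")
  }
  storage.mode(grid) <- "integer"
  nodata <- as.integer(nodata)
  bad <- setdiff(unique(grid[grid != nodata]), scheme$codes)
  if (length(bad) > 0L) {
    cnt <- vapply(bad, function(b) sum(grid == b), integer(1))
    stop("grid contains codes outside the class scheme: ",
         paste0(bad, " (", cnt, " cells)", collapse = ", "))
  }
  structure(
    list(grid = grid, scheme = scheme, cell_size_m = as.numeric(cell_size_m),
         nodata = nodata, origin = as.numeric(origin),
         crs_tag = as.character(crs_tag)),
    class = "categorical_raster"
  )
}

#' @export
print.categorical_raster <- function(x, ...) {
  cat("categorical_raster: ", nrow(x$grid), " x ", ncol(x$grid),
      " cells, cell size ", x$cell_size_m, " m\n", sep = "")
  cat("  classes:", paste(x$scheme$codes, collapse = " "),
      " nodata:", x$nodata, "\n")
  cat("  valid cells:", sum(x$grid != x$nodata), "\n")
  invisible(x)
}

#' Test whether two rasters are aligned
#'
#' Aligned means: same grid shape, same cell size, same upper-left
#' origin (to 1e-6 m) and same CRS tag. All multi-raster operations
#' require alignment.
#'
#' @param a,b `categorical_raster` objects.
#' @return `TRUE` or `FALSE`.
#' @export
is_aligned <- function(a, b) {
  identical(dim(a$grid), dim(b$grid)) &&
    isTRUE(all.equal(a$cell_size_m, b$cell_size_m, tolerance = 1e-9)) &&
    all(abs(a$origin - b$origin) < 1e-6) &&
    identical(a$crs_tag, b$crs_tag)
}

stop_if_misaligned <- function(a, b, what = "operation") {
  if (!is_aligned(a, b)) {
    stop(what, " requires aligned rasters (same shape, cell size, origin, CRS)")
  }
  invisible(TRUE)
}

#' Read an ESRI ASCII grid as a categorical raster
#'
#' Parses the six-line ESRI ASCII header (NCOLS, NROWS, XLLCORNER,
#' YLLCORNER, CELLSIZE, NODATA_VALUE; case-insensitive) followed by the
#' cell values, row-major from the north. Values must be integers; codes
#' outside the scheme (and not nodata) raise an error naming each
#' offending code and its cell count.
#'
#' @param path path to a `.asc` file.
#' @param scheme [class_scheme()] the codes must belong to.
#' @param crs_tag CRS tag to attach (ASC files carry none).
#' @return A `categorical_raster`.
#' @export
read_asc <- function(path, scheme, crs_tag = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("not an ESRI ASCII grid (missing header keys): ", path)
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("expected ", nr * nc, " cell values, found ", length(vals))
  }
  if (any(vals != round(vals))) stop("non-integer cell values in ", path)
  grid <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  categorical_raster(grid, scheme, hdr$cellsize, as.integer(nodata),
                     origin = origin, crs_tag = crs_tag)
}

#' Write a categorical raster as an ESRI ASCII grid
#'
#' @param r a `categorical_raster`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path) {
  nr <- nrow(r$grid); nc <- ncol(r$grid)
  hdr <- c(
    paste("NCOLS", nc),
    paste("NROWS", nr),
    paste("XLLCORNER", format(r$origin[1], scientific = FALSE)),
    paste("YLLCORNER",
          format(r$origin[2] - nr * r$cell_size_m, scientific = FALSE)),
    paste("CELLSIZE", format(r$cell_size_m, scientific = FALSE)),
    paste("NODATA_VALUE", r$nodata)
  )
  body <- apply(r$grid, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Clip a raster to a 0/1 mask
#'
#' Cells where the mask is 0 become nodata; cells where it is 1 are kept
#' unchanged. The operation is idempotent. This is the raster analogue of
#' restricting an area of interest within a larger map.
#'
#' @param r a `categorical_raster`.
#' @param mask an aligned `categorical_raster` whose non-nodata values
#'   are 0 or 1 (mask nodata is treated as 0).
#' @return The clipped `categorical_raster`.
#' @export
clip_to_mask <- function(r, mask) {
  stop_if_misaligned(r, mask, "clip_to_mask")
  mv <- mask$grid
  keep <- mv == 1L
  if (!all(mv %in% c(0L, 1L, mask$nodata))) {
    stop("mask must contain only 0/1 (or nodata) values")
  }
  out <- r$grid
  out[!keep] <- r$nodata
  r$grid <- out
  r
}

#' Per-class counts of non-nodata cells
#'
#' @param r a `categorical_raster`.
#' @return Integer vector of length J, in scheme order.
#' @export
class_counts <- function(r) {
  idx <- scheme_index(r$scheme, r$grid[r$grid != r$nodata])
  tabulate(idx, nbins = r$scheme$J)
}

#' Per-class area table of a raster
#'
#' Counts non-nodata cells per class and converts them to areas
#' (`cell count * cell_size_m^2 / 1e6` km2) and fractions of the valid
#' total. Classes absent from the raster report zero.
#'
#' @param r a `categorical_raster`.
#' @param year label attached to the table (default `NA`).
#' @return An `area_table`: data frame with columns `class_code`,
#'   `class_name`, `area_km2`, `fraction` and a `year` attribute.
#' @export
area_table <- function(r, year = NA) {
  n <- class_counts(r)
  if (sum(n) == 0L) stop("raster is entirely nodata; no area denominator")
  area_km2 <- n * r$cell_size_m^2 / 1e6
  area_table_from_km2(area_km2, r$scheme, year = year)
}

#' Build an area table directly from per-class areas
#'
#' Used when class areas come from a published table rather than a
#' raster; fractions are recomputed from the areas.
#'
#' @param area_km2 numeric vector of areas in km2, in scheme order.
#' @param scheme the [class_scheme()].
#' @param year label for the table.
#' @return An `area_table` data frame.
#' @export
area_table_from_km2 <- function(area_km2, scheme, year = NA) {
  if (length(area_km2) != scheme$J) {
    stop("'area_km2' must have one entry per scheme class")
  }
  if (any(area_km2 < 0)) stop("areas must be non-negative")
  tot <- sum(area_km2)
  frac <- if (tot > 0) area_km2 / tot else rep(0, scheme$J)
  out <- data.frame(
    class_code = scheme$codes,
    class_name = scheme$names,
    area_km2 = as.numeric(area_km2),
    fraction = frac,
    stringsAsFactors = FALSE
  )
  attr(out, "year") <- year
  class(out) <- c("area_table", "data.frame")
  out
}

#' Mean same-class neighbour fraction
#'
#' For each valid cell, the fraction of its valid 3x3 neighbours (centre
#' excluded, edges truncated) sharing its class, averaged over cells.
#' A measure of spatial autocorrelation of the categorical field: higher
#' values mean more clustered maps.
#'
#' @param r a `categorical_raster`.
#' @return A single number in \[0, 1\].
#' @export
same_class_neighbor_fraction <- function(r) {
  valid <- (r$grid != r$nodata) * 1
  nb_valid <- box_sum(valid, 3L) - valid
  num <- 0; den <- 0
  for (k in seq_len(r$scheme$J)) {
    ind <- (r$grid == r$scheme$codes[k] & valid == 1) * 1
    nb_same <- box_sum(ind, 3L) - ind
    sel <- ind == 1 & nb_valid > 0
    num <- num + sum(nb_same[sel] / nb_valid[sel])
    den <- den + sum(sel)
  }
  if (den == 0) return(NA_real_)
  num / den
}

# sum of a k x k (k odd) moving window, edge-truncated, via running sums
box_sum <- function(m, k) {
  h <- (k - 1L) %/% 2L
  col_run <- function(m, h) {
    nr <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    lo <- pmax(0L, seq_len(nr) - h - 1L)
    hi <- pmin(nr, seq_len(nr) + h)
    cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  }
  t(col_run(t(col_run(m, h)), h))
}
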