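#' Per-cell carbon storage map
#'
#' Each cell stores `A * (CAG + CBG + CSOIL + CDOM)` Mg, where `A` is
#' the cell area in hectares (`cell_size_m^2 / 1e4`) and the densities
#' are those of its class. Nodata cells map to `NA` and are excluded
#' from totals.
#'
#' @param r a `categorical_raster` whose classes are covered by `pools`.
#' @param pools a `carbon_pool_table`.
#' @return A `carbon_raster`: list with a numeric `values` matrix (Mg
#'   per cell, `NA` at nodata) plus the grid metadata of `r`.
#' @export
carbon_map <- function(r, pools) {
  pos <- match(r$scheme$codes, pools$class_code)
  if (anyNA(pos)) {
    stop("pool table misses classes: ",
         paste(r$scheme$codes[is.na(pos)], collapse = ", "))
  }
  dens <- with(pools[pos, ], CAG + CBG + CSOIL + CDOM)  # Mg/ha per class
  A_ha <- r$cell_size_m^2 / 1e4
  idx <- scheme_index(r$scheme, r$grid)  # NA at nodata
  vals <- matrix(dens[idx] * A_ha, nrow = nrow(r$grid))
  structure(
    list(values = vals, cell_size_m = r$cell_size_m, origin = r$origin,
         crs_tag = r$crs_tag),
    class = "carbon_raster"
  )
}

#' Total carbon storage of a carbon map
#'
#' Sum of per-cell storage over non-nodata cells, in Mg.
#'
#' @param cm a `carbon_raster` from [carbon_map()].
#' @return Total storage in Mg (0 for an all-nodata map).
#' @export
total_storage <- function(cm) {
  sum(cm$values, na.rm = TRUE)
}

#' Carbon storage from a class-area table
#'
#' Class-aggregate route to the same total: `sum(area_km2 * 100 *
#' (CAG + CBG + CSOIL + CDOM))` (1 km2 = 100 ha). Equals
#' [total_storage()] of [carbon_map()] for the raster underlying the
#' area table, and lets published area tables be assessed without
#' rasters.
#'
#' @param a an `area_table`.
#' @param pools a `carbon_pool_table` covering the table's classes.
#' @return Total storage in Mg.
#' @export
storage_from_areas <- function(a, pools) {
  pos <- match(a$class_code, pools$class_code)
  if (anyNA(pos)) {
    stop("pool table misses classes: ",
         paste(a$class_code[is.na(pos)], collapse = ", "))
  }
  dens <- with(pools[pos, ], CAG + CBG + CSOIL + CDOM)
  sum(a$area_km2 * 100 * dens)
}

#' Carbon sequestered (or lost) between two assessments
#'
#' Signed difference `ct2 - ct1` in Mg C: positive for sequestration,
#' negative for loss.
#'
#' @param ct1,ct2 carbon storage at the earlier and later time, Mg.
#' @return `ct2 - ct1`.
#' @export
sequestration <- function(ct1, ct2) {
  ct2 - ct1
}

#' Carbon to carbon-dioxide equivalence
#'
#' Multiplies elemental carbon mass by the molecular-weight ratio 44/12.
#'
#' @param s carbon mass in Mg C (may be negative for losses).
#' @return CO2-equivalent mass in Mg.
#' @export
co2_equivalent <- function(s) {
  s * 44 / 12
}

#' Valuation parameters
#'
#' @param V monetary value of elemental carbon, EUR/Mg (default 200,
#'   corresponding to a CO2 price of 60 EUR/t).
#' @param r annual market discount rate for the carbon price, percent
#'   (default 3).
#' @param c annual rate of change of the carbon price, percent
#'   (default 0).
#' @param p present (earlier) year.
#' @param q future (later) year; must exceed `p`.
#' @return A `valuation_params` list.
#' @export
valuation_params <- function(V = 200, r = 3, c = 0, p, q) {
  if (V < 0) stop("'V' must be non-negative")
  if (q <= p) stop("future year 'q' must exceed present year 'p'")
  structure(list(V = V, r = r, c = c, p = p, q = q),
            class = "valuation_params")
}

#' Discounted value of sequestered (or lost) carbon
#'
#' The sequestration `s` over the period p..q is valued as if accruing
#' evenly, each annual increment discounted to the present:
#' `V * s / (q - p) * sum_{t=0}^{q-p-1} [(1 + r/100) * (1 + c/100)]^-t`.
#' With `r = c = 0` this is exactly `V * s`; it decreases in `r` for
#' positive `s`.
#'
#' @param vp a [valuation_params()].
#' @param s carbon sequestered (positive) or lost (negative), Mg C.
#' @return Value in EUR (negative for losses).
#' @export
valuation <- function(vp, s) {
  n <- vp$q - vp$p
  g <- (1 + vp$r / 100) * (1 + vp$c / 100)
  vp$V * s / n * sum(g^-(0:(n - 1)))
}

#' Value of a standing carbon stock, in million EUR
#'
#' `stored * V / 1e6`; carried at full precision, round to 2 decimals
#' only for presentation.
#'
#' @param stored carbon stock, Mg.
#' @param V carbon price, EUR/Mg (default 200).
#' @return Value in million EUR.
#' @export
stored_value <- function(stored, V = 200) {
  stored * V / 1e6
}

#' Multi-year carbon ledger
#'
#' Assembles per-year storage and stock value, and per consecutive
#' period the carbon variation (later minus earlier storage, exactly),
#' its CO2 equivalence (x 44/12) and two economic values of the
#' variation: the discounted value via [valuation()] with the pair's
#' years, and the undiscounted `V * s`. The variations telescope: their
#' sum equals the last minus the first year's storage.
#'
#' @param areas list of `area_table`s with strictly increasing `year`
#'   attributes (at least two).
#' @param pools a `carbon_pool_table`.
#' @param V carbon price, EUR/Mg.
#' @param r discount rate, percent/year.
#' @param c carbon-price change rate, percent/year.
#' @return A `carbon_ledger` data frame with columns `year`,
#'   `stored_Mg`, `stored_value_MEUR`, `variation_MgC`, `co2_eq_Mg`,
#'   `variation_value_MEUR`, `variation_value_undiscounted_MEUR`
#'   (period columns are `NA` in the first row).
#' @export
build_ledger <- function(areas, pools, V = 200, r = 3, c = 0) {
  if (length(areas) < 2L) stop("need at least two assessment years")
  years <- vapply(areas, function(a) as.numeric(attr(a, "year")), numeric(1))
  if (anyNA(years) || any(diff(years) <= 0)) {
    stop("area tables must carry strictly increasing years")
  }
  stored <- vapply(areas, storage_from_areas, numeric(1), pools = pools)
  n <- length(areas)
  variation <- c(NA, diff(stored))
  disc <- rep(NA_real_, n)
  for (k in 2:n) {
    vp <- valuation_params(V = V, r = r, c = c, p = years[k - 1], q = years[k])
    disc[k] <- valuation(vp, variation[k]) / 1e6
  }
  out <- data.frame(
    year = years,
    stored_Mg = stored,
    stored_value_MEUR = stored_value(stored, V),
    variation_MgC = variation,
    co2_eq_Mg = co2_equivalent(variation),
    variation_value_MEUR = disc,
    variation_value_undiscounted_MEUR = variation * V / 1e6
  )
  class(out) <- c("carbon_ledger", "data.frame")
  out
}

#' Bundled Calabria class-area tables
#'
#' The published class areas (km2) of the bundled case study for 2000,
#' 2006, 2012 and 2018, plus the 2024 projection.
#'
#' @param years subset of c(2000, 2006, 2012, 2018, 2024).
#' @return Named list of `area_table`s in year order.
#' @export
calabria_area_tables <- function(years = c(2000, 2006, 2012, 2018, 2024)) {
  path <- system.file("extdata", "lulc_areas_calabria.csv",
                      package = "luccarbon", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  scheme <- lulc_scheme()
  out <- lapply(years, function(y) {
    sub <- tab[tab$year == y, ]
    if (nrow(sub) == 0L) stop("no bundled areas for year ", y)
    pos <- match(scheme$codes, sub$class_code)
    area_table_from_km2(sub$area_km2[pos], scheme, year = y)
  })
  names(out) <- as.character(years)
  out
}

#' Write an area table or ledger as delimited text
#'
#' @param x an `area_table` or `carbon_ledger`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "area_table")) df <- cbind(year = attr(x, "year"), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
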