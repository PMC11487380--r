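#' Reclassification map between class schemes
#'
#' A total many-to-one mapping from source class codes to target codes,
#' with a policy for codes encountered outside the map: `"error"` stops,
#' `"nodata"` converts the cell to nodata (and the count is reported via
#' a message).
#'
#' @param source_codes integer vector of source codes (distinct).
#' @param target_codes integer vector, one target per source.
#' @param target_scheme [class_scheme()] the targets must belong to.
#' @param unmapped policy for unmapped codes: `"error"` or `"nodata"`.
#' @return An object of class `reclass_map`.
#' @export
reclass_map <- function(source_codes, target_codes, target_scheme,
                        unmapped = c("error", "nodata")) {
  unmapped <- match.arg(unmapped)
  source_codes <- as.integer(source_codes)
  target_codes <- as.integer(target_codes)
  if (length(source_codes) != length(target_codes)) {
    stop("one target code per source code required")
  }
  if (anyDuplicated(source_codes)) {
    stop("every source code must map to exactly one target")
  }
  if (!all(target_codes %in% target_scheme$codes)) {
    stop("target codes outside the target scheme")
  }
  structure(
    list(source_codes = source_codes, target_codes = target_codes,
         target_scheme = target_scheme, unmapped = unmapped),
    class = "reclass_map"
  )
}

#' Read a reclassification map from delimited text
#'
#' Expects columns `source_code` and `target_code` (extra columns such
#' as names are ignored).
#'
#' @param path CSV path.
#' @param target_scheme [class_scheme()] of the targets.
#' @param unmapped unmapped-code policy, see [reclass_map()].
#' @return A `reclass_map`.
#' @export
read_reclass_map <- function(path, target_scheme, unmapped = "error") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source_code", "target_code") %in% names(tab))) {
    stop("reclass file needs 'source_code' and 'target_code' columns: ", path)
  }
  reclass_map(tab$source_code, tab$target_code, target_scheme, unmapped)
}

#' Default CORINE-to-IPCC reclassification
#'
#' The bundled 44-to-7 mapping from CORINE Land Cover level-3 grid codes
#' (1-44, standard order) to the seven IPCC-derived classes of
#' [lulc_scheme()]: the 11 artificial-surface classes to Settlement; the
#' 9 agricultural classes to Crop land; agro-forestry plus the three
#' forest classes to Forest land; natural grasslands, moors/heathland,
#' sclerophyllous vegetation, transitional woodland-shrub, pastures and
#' sparsely vegetated areas to Grassland; the five inland/coastal wetland
#' classes to Wetland; the five water classes to Water body; and beaches/
#' dunes/sands, bare rocks, burnt areas and glaciers to Other land.
#'
#' Note the standard CLC name "Bare rocks" is used for the bare soil and
#' rock class. CLC distributions vary between 3-digit codes and 1-44 grid
#' codes; supply your own file through [read_reclass_map()] if your
#' raster uses 3-digit codes.
#'
#' @param unmapped unmapped-code policy, see [reclass_map()].
#' @return A `reclass_map`.
#' @export
default_clc_map <- function(unmapped = "error") {
  path <- system.file("extdata", "clc_reclass_table.csv",
                      package = "luccarbon", mustWork = TRUE)
  read_reclass_map(path, lulc_scheme(), unmapped)
}

#' Reclassify a categorical raster
#'
#' Cell-wise code substitution under a [reclass_map()]. Nodata is
#' preserved. Under the `"nodata"` policy, unmapped cells become nodata
#' and their count is reported as a message; under `"error"` they stop.
#'
#' @param r a `categorical_raster` whose codes are map sources.
#' @param m a `reclass_map`.
#' @return A `categorical_raster` on the map's target scheme.
#' @export
reclassify <- function(r, m) {
  g <- r$grid
  valid <- g != r$nodata
  pos <- match(g[valid], m$source_codes)
  if (anyNA(pos)) {
    bad <- unique(g[valid][is.na(pos)])
    if (m$unmapped == "error") {
      stop("unmapped codes in raster: ", paste(bad, collapse = ", "))
    }
    message(sum(is.na(pos)), " cells with unmapped codes (",
            paste(bad, collapse = ", "), ") set to nodata")
  }
  out <- g
  newv <- m$target_codes[pos]
  newv[is.na(newv)] <- r$nodata
  out[valid] <- newv
  categorical_raster(out, m$target_scheme, r$cell_size_m, r$nodata,
                     origin = r$origin, crs_tag = r$crs_tag)
}
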