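#' Class scheme for categorical rasters
#'
#' A class scheme is an ordered legend: distinct integer codes with one
#' label per code. Every categorical raster carries a scheme, and all
#' cross-raster operations (cross-tabulation, confusion matrices,
#' reclassification targets) are defined over it.
#'
#' @param codes integer vector of distinct class codes.
#' @param names character vector of labels, one per code. Defaults to
#'   `"class <code>"`.
#' @return An object of class `class_scheme`: a list with elements
#'   `codes`, `names` and `J` (the class count).
#' @examples
#' class_scheme(1:3, c("urban", "crop", "forest"))
#' @export
class_scheme <- function(codes, names = paste("class", codes)) {
  codes <- as.integer(codes)
  if (length(codes) < 1L) stop("a class scheme needs at least one code")
  if (anyNA(codes)) stop("class codes must be non-missing integers")
  if (anyDuplicated(codes)) stop("class codes must be distinct")
  if (length(names) != length(codes)) {
    stop("'names' must have one label per code")
  }
  structure(
    list(codes = codes, names = as.character(names), J = length(codes)),
    class = "class_scheme"
  )
}

#' The seven-class IPCC-derived land-cover legend
#'
#' The legend used throughout the bundled Calabria case study:
#' Settlement (1), Crop land (2), Forest land (3), Grassland (4),
#' Wetland (5), Water body (6), Other land (7). Codes are fixed so that
#' transition matrices and pool tables are comparable across runs.
#'
#' @return A `class_scheme` with seven classes.
#' @export
lulc_scheme <- function() {
  class_scheme(
    1:7,
    c("Settlement", "Crop land", "Forest land", "Grassland",
      "Wetland", "Water body", "Other land")
  )
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("class_scheme with", x$J, "classes:\n")
  cat(paste0("  ", x$codes, " = ", x$names, collapse = "\n"), "\n")
  invisible(x)
}

# position of each code of `scheme` in 1..J; NA for foreign codes
scheme_index <- function(scheme, codes) {
  match(codes, scheme$codes)
}

same_scheme <- function(a, b) {
  identical(a$codes, b$codes)
}
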