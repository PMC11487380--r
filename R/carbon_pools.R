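#' Forest growing-stock scaling factors
#'
#' The factors that scale standing stem-wood volume (growing stock, GS)
#' into carbon pools: biomass expansion factor (BEF), wood basic density
#' (WBD, Mg d.m./m3), carbon fraction (CF, Mg C/Mg d.m.), root-to-shoot
#' ratio (R) and average mortality rate (AMR, 1/year). `litter_fraction`
#' adds a configurable litter share of the above-ground carbon to the
#' dead-organic-matter pool (the litter regression the Calabrian
#' inventory uses is not published; default 0).
#'
#' @param GS growing stock, m3/ha.
#' @param BEF biomass expansion factor.
#' @param WBD wood basic density, Mg d.m./m3.
#' @param CF carbon fraction, in (0, 1).
#' @param R root-to-shoot ratio, in (0, 1).
#' @param AMR average annual mortality rate, in (0, 1).
#' @param litter_fraction litter carbon as a fraction of CAG.
#' @return A `forest_scaling_factors` list.
#' @export
forest_scaling_factors <- function(GS = 225.4, BEF = 1.34, WBD = 0.58,
                                   CF = 0.47, R = 0.25, AMR = 0.0177,
                                   litter_fraction = 0) {
  vals <- c(GS = GS, BEF = BEF, WBD = WBD, CF = CF, R = R, AMR = AMR,
            litter_fraction = litter_fraction)
  if (any(vals < 0)) stop("factors must be non-negative")
  if (CF <= 0 || CF >= 1) stop("CF must lie in (0, 1)")
  if (R >= 1) stop("R must lie in (0, 1)")
  if (AMR >= 1) stop("AMR must lie in (0, 1)")
  structure(as.list(vals), class = "forest_scaling_factors")
}

#' Bundled per-species forest factors (Calabria)
#'
#' Per-species BEF, WBD, CF, R and AMR for the four tree types assumed
#' to dominate Calabrian forests (European beech, chestnut, turkey oak,
#' larches), as tabulated in the Italian inventory guidance.
#'
#' @return A data frame with one row per tree type.
#' @export
default_forest_factors <- function() {
  path <- system.file("extdata", "forest_scaling_factors.csv",
                      package = "luccarbon", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Forest carbon pools from growing stock
#'
#' Scales growing stock into the four pools:
#' above-ground biomass `BAG = GS * BEF * WBD` (Mg d.m./ha); above-ground
#' carbon `CAG = BAG * CF`; below-ground carbon `CBG = BAG * R * CF`
#' (below-ground biomass is BAG converted through the root-to-shoot
#' ratio, then through the carbon fraction); dead organic matter
#' `CDOM = CAG * AMR + litter_fraction * CAG` (deadwood from mortality
#' plus the configurable litter share). Soil carbon is an inventory
#' input passed through unchanged. All biomass-derived pools are
#' proportional to GS.
#'
#' @param f a [forest_scaling_factors()].
#' @param soil_c soil organic carbon, Mg/ha.
#' @return Named numeric vector `c(CAG, CBG, CSOIL, CDOM)` in Mg/ha.
#' @export
forest_pools <- function(f, soil_c) {
  if (soil_c < 0) stop("soil carbon must be non-negative")
  BAG <- f$GS * f$BEF * f$WBD
  CAG <- BAG * f$CF
  CBG <- BAG * f$R * f$CF
  CDOM <- CAG * f$AMR + f$litter_fraction * CAG
  c(CAG = CAG, CBG = CBG, CSOIL = soil_c, CDOM = CDOM)
}

#' Grassland carbon pools from biomass defaults
#'
#' `CAG = bag * cf`, `CBG = bag * rts * cf` (below-ground biomass from
#' the root-to-shoot ratio), no dead organic matter; soil carbon passed
#' through. Defaults are the IPCC grassland values used in the bundled
#' case study: above-ground biomass 2.7 Mg d.m./ha, root-to-shoot 4.0,
#' carbon fraction 0.5.
#'
#' @param bag above-ground biomass, Mg d.m./ha.
#' @param rts root-to-shoot ratio.
#' @param cf carbon fraction, Mg C/Mg d.m.
#' @param soil_c soil organic carbon, Mg/ha.
#' @return Named numeric vector `c(CAG, CBG, CSOIL, CDOM)` in Mg/ha.
#' @export
grassland_pools <- function(bag = 2.7, rts = 4.0, cf = 0.5, soil_c = 66) {
  if (any(c(bag, rts, cf, soil_c) < 0)) stop("inputs must be non-negative")
  c(CAG = bag * cf, CBG = bag * rts * cf, CSOIL = soil_c, CDOM = 0)
}

#' Unweighted mean of per-type pool rows
#'
#' Averages carbon densities over types (e.g. crop species or wetland
#' types) to obtain one representative row per land-cover class.
#'
#' @param rows data frame (or matrix) of numeric pool columns, one row
#'   per type.
#' @return Named numeric vector of column means.
#' @export
mean_pools <- function(rows) {
  rows <- as.data.frame(rows)
  num <- rows[vapply(rows, is.numeric, logical(1))]
  if (nrow(num) < 1L || ncol(num) < 1L) stop("need at least one numeric row")
  colMeans(num)
}

#' Bundled crop carbon densities (Calabria)
#'
#' Above- and below-ground carbon in the major woody crops grown in
#' Calabria (olive, vineyards, orchards, other fruits); annual crops
#' carry no net biomass accumulation. The mean row feeds the pool table.
#'
#' @return A data frame with columns `crop_type`, `maturity_years`,
#'   `CAG`, `CBG`.
#' @export
default_crop_table <- function() {
  path <- system.file("extdata", "crop_carbon.csv",
                      package = "luccarbon", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Bundled wetland carbon densities
#'
#' Carbon content of six wetland types (swamp, lake-, river-, beach-,
#' pond-related and mangrove wetlands); the mean row feeds the pool
#' table.
#'
#' @return A data frame with columns `wetland_type`, `CAG`, `CBG`,
#'   `CSOIL`, `CDOM`.
#' @export
default_wetland_table <- function() {
  path <- system.file("extdata", "wetland_carbon.csv",
                      package = "luccarbon", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Carbon pool table
#'
#' Per-class CAG, CBG, CSOIL and CDOM densities in Mg/ha, the input of
#' the storage assessment.
#'
#' @param classes [class_scheme()] the rows describe.
#' @param CAG,CBG,CSOIL,CDOM numeric vectors, one entry per class,
#'   Mg/ha, non-negative.
#' @return A `carbon_pool_table` data frame.
#' @export
carbon_pool_table <- function(classes, CAG, CBG, CSOIL, CDOM) {
  J <- classes$J
  for (v in list(CAG, CBG, CSOIL, CDOM)) {
    if (length(v) != J) stop("pool vectors must have one entry per class")
    if (any(v < 0)) stop("pool densities must be non-negative")
  }
  out <- data.frame(
    class_code = classes$codes, class_name = classes$names,
    CAG = CAG, CBG = CBG, CSOIL = CSOIL, CDOM = CDOM,
    stringsAsFactors = FALSE
  )
  class(out) <- c("carbon_pool_table", "data.frame")
  out
}

#' Read a carbon pool table from delimited text
#'
#' @param path CSV with columns `class_code`, `CAG`, `CBG`, `CSOIL`,
#'   `CDOM` (a `class_name` column is used for labels when present).
#' @param scheme [class_scheme()] the rows must cover exactly.
#' @return A `carbon_pool_table`.
#' @export
read_pool_table <- function(path, scheme = lulc_scheme()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class_code", "CAG", "CBG", "CSOIL", "CDOM")
  if (!all(need %in% names(tab))) {
    stop("pool table needs columns ", paste(need, collapse = ", "))
  }
  pos <- match(scheme$codes, tab$class_code)
  if (anyNA(pos)) stop("pool table misses classes: ",
                       paste(scheme$codes[is.na(pos)], collapse = ", "))
  carbon_pool_table(scheme, tab$CAG[pos], tab$CBG[pos],
                    tab$CSOIL[pos], tab$CDOM[pos])
}

#' The bundled Calabria carbon pool table
#'
#' The assessment input of the bundled case study, in Mg/ha:
#' Settlement (2, 1, 5, 0); Crop land (8, 5, 46, 1); Forest land
#' (93, 17, 83, 9); Grassland (1, 5, 66, 0); Wetland (23, 34, 88, 4);
#' Water body (2, 1, 10, 0); Other land (2, 0, 16, 0).
#'
#' The forest row is the inventory-calibrated table value; building the
#' same row bottom-up from the mean scaling factors via [forest_pools()]
#' yields CAG of about 82.3 rather than 93, and deadwood-only CDOM of
#' about 1.5 rather than 9 — the per-species averaging order and litter
#' regression behind the published row are not recoverable, so the table
#' is authoritative for assessment and the equations are provided for
#' methodological reuse.
#'
#' @return A `carbon_pool_table` on [lulc_scheme()].
#' @export
default_pool_table <- function() {
  path <- system.file("extdata", "carbon_pools_calabria.csv",
                      package = "luccarbon", mustWork = TRUE)
  read_pool_table(path, lulc_scheme())
}
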