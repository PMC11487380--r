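#' Confusion matrix between simulated and reference maps
#'
#' Cross-tabulation with rows = simulated class and columns = reference
#' class; cells nodata in either raster are excluded.
#'
#' @param sim,ref aligned `categorical_raster`s on the same scheme.
#' @return A `cross_tab` count matrix.
#' @export
confusion_matrix <- function(sim, ref) {
  cross_tabulate(sim, ref)
}

#' Construct agreement/disagreement components directly
#'
#' Builds an `agreement_components` object from the seven component
#' values, e.g. when they come from a published validation report rather
#' than from rasters. Components must be non-negative and sum to 1
#' (tolerance `tol`, default 5e-4 to accommodate tables printed at 4
#' decimal places).
#'
#' @param chance,quantity,stratum,gridcell agreement components.
#' @param dis_gridcell,dis_stratum,dis_quantity disagreement components.
#' @param J_chance number of categories used for the nominal chance
#'   agreement level 1/J_chance (default 8: map comparison tools
#'   commonly count a background category alongside the 7 map classes).
#' @param tol tolerance on the sum-to-one check.
#' @return An `agreement_components` named numeric vector with a
#'   `J_chance` attribute.
#' @export
make_agreement_components <- function(chance, quantity, stratum, gridcell,
                                      dis_gridcell, dis_stratum,
                                      dis_quantity, J_chance = 8L,
                                      tol = 5e-4) {
  x <- c(chance = chance, quantity = quantity, stratum = stratum,
         gridcell = gridcell, dis_gridcell = dis_gridcell,
         dis_stratum = dis_stratum, dis_quantity = dis_quantity)
  if (any(x < -1e-12)) stop("components must be non-negative")
  if (abs(sum(x) - 1) > tol) {
    stop("components must sum to 1 (got ", sum(x), ")")
  }
  structure(pmax(x, 0), J_chance = as.integer(J_chance),
            class = "agreement_components")
}

#' Pontius-style agreement/disagreement decomposition
#'
#' Decomposes overall map agreement into chance, quantity, stratum and
#' grid-cell (location) parts, plus grid-cell, stratum and quantity
#' disagreement, following the expected-agreement framework of Pontius
#' (2000, 2002). With proportions `p_ij` from the confusion matrix,
#' simulated marginals `c_i` and reference marginals `r_j`:
#' observed agreement `M = sum(p_ii)`, nominal chance `N(n) =
#' 1/J_chance`, expected quantity-informed agreement `N(m) = sum(c_j *
#' r_j)`, maximum location-corrected agreement `P(m) = sum(min(c_j,
#' r_j))`. Then `chance = min(N(n), N(m), M)`, `quantity = max(0,
#' min(N(m), M) - chance)`, `gridcell = max(0, M - N(m))`,
#' `dis_gridcell = P(m) - M`, `dis_quantity = 1 - P(m)`; stratum terms
#' are zero in the single-stratum case (no strata raster supplied). The
#' seven components always sum to 1.
#'
#' @param cm a `cross_tab` confusion matrix with total count > 0.
#' @param J_chance categories counted for the nominal chance level
#'   (default 8; see [make_agreement_components()]).
#' @return An `agreement_components` object.
#' @export
agreement_components <- function(cm, J_chance = 8L) {
  counts <- unclass(cm)
  tot <- sum(counts)
  if (tot <= 0) stop("empty confusion matrix")
  p <- counts / tot
  M <- sum(diag(p))
  c_i <- rowSums(p)  # simulated marginals
  r_j <- colSums(p)  # reference marginals
  Nn <- 1 / J_chance
  Nm <- sum(c_i * r_j)
  Pm <- sum(pmin(c_i, r_j))
  chance <- min(Nn, Nm, M)
  quantity <- max(0, min(Nm, M) - chance)
  gridcell <- max(0, M - Nm)
  out <- make_agreement_components(
    chance = chance, quantity = quantity, stratum = 0,
    gridcell = gridcell, dis_gridcell = Pm - M, dis_stratum = 0,
    dis_quantity = 1 - Pm, J_chance = J_chance, tol = 1e-9
  )
  # exact intermediates: the component decomposition clamps at zero when
  # observed agreement falls below expectation, so keep the raw values
  # for kappa computation (negative kappas stay representable)
  attr(out, "exact") <- c(M = M, Nm = Nm, Pm = Pm)
  out
}

#' Kappa variants from agreement components
#'
#' The four kappa statistics used to validate simulated land-cover maps,
#' computed from an agreement decomposition. With `M` the sum of the
#' four agreement components, `N(n) = 1/J_chance`, `N(m) = chance +
#' quantity` and `P(m) = M + dis_gridcell`:
#' \describe{
#'   \item{Kno}{`(M - N(n)) / (1 - N(n))` — overall agreement against
#'     the no-information baseline.}
#'   \item{Kstd}{`(M - N(m)) / (1 - N(m))` — standard kappa, correcting
#'     for quantity-informed chance.}
#'   \item{Kloc}{`(M - N(m)) / (P(m) - N(m))` — location kappa, the
#'     share of achievable location agreement achieved.}
#'   \item{Klocstrata}{stratum-level location kappa; with a single
#'     stratum it equals Kloc exactly.}
#' }
#' Degenerate denominators (`N(m) = 1` or `P(m) = N(m)`) yield `NA` for
#' the affected statistic rather than a number.
#'
#' @param ac an `agreement_components` object.
#' @return A `kappa_set`: named list with `Kstd`, `Kno`, `Kloc`,
#'   `Klocstrata`.
#' @export
kappa_set <- function(ac) {
  if (!inherits(ac, "agreement_components")) {
    stop("'ac' must be an agreement_components object")
  }
  J_chance <- attr(ac, "J_chance")
  Nn <- 1 / J_chance
  exact <- attr(ac, "exact")
  if (!is.null(exact)) {
    M <- exact[["M"]]; Nm <- exact[["Nm"]]; Pm <- exact[["Pm"]]
  } else {
    M <- ac[["chance"]] + ac[["quantity"]] + ac[["stratum"]] + ac[["gridcell"]]
    Nm <- ac[["chance"]] + ac[["quantity"]]
    Pm <- M + ac[["dis_gridcell"]]
  }
  safe_div <- function(num, den) {
    if (abs(den) < 1e-12) NA_real_ else num / den
  }
  structure(
    list(
      Kstd = safe_div(M - Nm, 1 - Nm),
      Kno = safe_div(M - Nn, 1 - Nn),
      Kloc = safe_div(M - Nm, Pm - Nm),
      Klocstrata = safe_div(M - Nm, Pm - Nm)
    ),
    class = "kappa_set"
  )
}

#' @export
print.kappa_set <- function(x, ...) {
  cat(sprintf("Kstd %.4f  Kno %.4f  Kloc %.4f  Klocstrata %.4f\n",
              x$Kstd, x$Kno, x$Kloc, x$Klocstrata))
  invisible(x)
}

#' Bundled validation components of the Calabria case study
#'
#' The agreement/disagreement decompositions of the two hindcast
#' validation tests of the bundled case study (prediction of the 2012
#' and 2018 maps compared against the observed maps), as published at
#' 4 decimal places.
#'
#' @param year 2012 or 2018.
#' @return An `agreement_components` object with `J_chance = 8`.
#' @export
calabria_agreement_components <- function(year = c(2012, 2018)) {
  year <- match.arg(as.character(year[1]), c("2012", "2018"))
  path <- system.file("extdata", "map_agreement_components.csv",
                      package = "luccarbon", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  v <- tab[[paste0("y", year)]]
  names(v) <- tab$component
  make_agreement_components(
    chance = v[["chance"]], quantity = v[["quantity"]],
    stratum = v[["stratum"]], gridcell = v[["gridcell"]],
    dis_gridcell = v[["dis_gridcell"]], dis_stratum = v[["dis_stratum"]],
    dis_quantity = v[["dis_quantity"]], J_chance = 8L
  )
}

#' Write a validation report as delimited text
#'
#' Emits the seven components and four kappas with their conventional
#' labels.
#'
#' @param ac an `agreement_components` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(ac, path) {
  ks <- kappa_set(ac)
  labels <- c(
    chance = "Agreement due to chance",
    quantity = "Agreement due to quantity",
    stratum = "Agreement at stratum level",
    gridcell = "Agreement at gridcell level",
    dis_gridcell = "Disagreement at gridcell level",
    dis_stratum = "Disagreement at stratum level",
    dis_quantity = "Disagreement due to quantity"
  )
  out <- data.frame(
    statistic = c(unname(labels[names(unclass(ac))]),
                  "Kstd", "Kno", "Kloc", "Klocstrata"),
    value = c(as.numeric(ac), ks$Kstd, ks$Kno, ks$Kloc, ks$Klocstrata)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
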