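#' Transition probability matrix
#'
#' A J x J row-stochastic matrix of class-change probabilities over one
#' period. Rows index the class at the period start, columns the class at
#' the period end. Rows for classes with no population at the start are
#' identity rows (the class persists if it reappears), which keeps
#' Chapman-Kolmogorov products defined.
#'
#' @param P numeric J x J matrix with rows summing to 1 (tolerance 1e-9).
#' @param scheme [class_scheme()] indexing the rows/columns.
#' @param period optional label such as `"2000-2006"`.
#' @return An object of class `transition_matrix` (a matrix with
#'   attributes `scheme` and `period`).
#' @export
transition_matrix <- function(P, scheme, period = NA) {
  P <- as.matrix(P)
  if (nrow(P) != scheme$J || ncol(P) != scheme$J) {
    stop("matrix must be ", scheme$J, " x ", scheme$J)
  }
  if (any(P < 0)) stop("transition probabilities must be non-negative")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("rows must sum to 1 (max deviation ", max(abs(rs - 1)), ")")
  }
  dimnames(P) <- list(scheme$names, scheme$names)
  structure(P, scheme = scheme, period = period,
            class = c("transition_matrix", "matrix", "array"))
}

#' Cross-tabulate two aligned categorical rasters
#'
#' `counts[i, j]` is the number of cells with class i in `r1` and class
#' j in `r2`; cells that are nodata in either raster are excluded. With
#' rows = earlier map and columns = later map this is the raw material
#' of a transition matrix; with rows = simulated and columns = reference
#' it is a confusion matrix.
#'
#' @param r1,r2 aligned `categorical_raster`s on the same scheme.
#' @return A `cross_tab`: an integer J x J matrix with a `scheme`
#'   attribute.
#' @export
cross_tabulate <- function(r1, r2) {
  stop_if_misaligned(r1, r2, "cross_tabulate")
  if (!same_scheme(r1$scheme, r2$scheme)) {
    stop("cross_tabulate requires a common class scheme")
  }
  J <- r1$scheme$J
  ok <- r1$grid != r1$nodata & r2$grid != r2$nodata
  i <- scheme_index(r1$scheme, r1$grid[ok])
  j <- scheme_index(r2$scheme, r2$grid[ok])
  counts <- matrix(tabulate((i - 1L) * J + j, nbins = J * J),
                   nrow = J, byrow = TRUE)
  dimnames(counts) <- list(r1$scheme$names, r2$scheme$names)
  structure(counts, scheme = r1$scheme,
            class = c("cross_tab", "matrix", "array"))
}

#' Convert a cross-tabulation to a transition matrix
#'
#' Row-normalises the counts; rows with zero population become identity
#' rows.
#'
#' @param ct a `cross_tab` from [cross_tabulate()].
#' @param period optional period label.
#' @return A `transition_matrix`.
#' @export
to_probabilities <- function(ct, period = NA) {
  scheme <- attr(ct, "scheme")
  counts <- unclass(ct)
  attr(counts, "scheme") <- NULL
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, 1)
  zero <- which(rs == 0)
  for (z in zero) {
    P[z, ] <- 0
    P[z, z] <- 1
  }
  transition_matrix(P, scheme, period)
}

#' Average transition matrices across periods
#'
#' Unweighted element-wise arithmetic mean; the mean of row-stochastic
#' rows is row-stochastic, and the result is re-validated on
#' construction.
#'
#' @param ms list of `transition_matrix` objects of equal dimension.
#' @param period label for the averaged matrix.
#' @return A `transition_matrix`.
#' @export
average_matrices <- function(ms, period = "average") {
  if (length(ms) < 1L) stop("need at least one matrix")
  scheme <- attr(ms[[1]], "scheme")
  for (m in ms) {
    if (!identical(dim(m), dim(ms[[1]]))) stop("matrix dimension mismatch")
  }
  avg <- Reduce(`+`, lapply(ms, unclass)) / length(ms)
  transition_matrix(avg, scheme, period)
}

#' Read a transition matrix from delimited text
#'
#' Expects a header row of class names and a leading `class` column of
#' row names, as written by [write_transition_matrix()]. Rows may sum to
#' slightly off 1 when the file carries rounded values (e.g. 4 decimal
#' places); they are renormalised when `renormalize = TRUE`, with the
#' maximum adjustment limited to `max_adjust`.
#'
#' @param path CSV path.
#' @param scheme [class_scheme()] for rows/columns.
#' @param period optional label.
#' @param renormalize divide each row by its sum (default TRUE).
#' @param max_adjust largest tolerated |row sum - 1| before renormalising
#'   (default 0.01); beyond it the file is considered corrupt.
#' @return A `transition_matrix`.
#' @export
read_transition_matrix <- function(path, scheme, period = NA,
                                   renormalize = TRUE, max_adjust = 0.01) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  P <- as.matrix(tab[, -1, drop = FALSE])
  if (nrow(P) != scheme$J || ncol(P) != scheme$J) {
    stop("matrix in ", path, " is not ", scheme$J, " x ", scheme$J)
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > max_adjust)) {
    stop("row sums deviate from 1 by more than ", max_adjust, " in ", path)
  }
  if (renormalize) P <- P / rs
  transition_matrix(P, scheme, period)
}

#' Write a transition matrix as delimited text
#'
#' Full precision; round only at presentation.
#'
#' @param P a `transition_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(P, path) {
  scheme <- attr(P, "scheme")
  tab <- data.frame(class = scheme$names, unclass(P), check.names = FALSE)
  names(tab) <- c("class", scheme$names)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' The bundled averaged Calabria transition matrix
#'
#' The average of the 2000-2006, 2006-2012 and 2012-2018 transition
#' matrices estimated for the Calabria case study, printed at 4 decimal
#' places (rows are renormalised on read, adjustments at most 1e-4).
#'
#' @return A `transition_matrix` on [lulc_scheme()].
#' @export
default_transition_matrix <- function() {
  path <- system.file("extdata", "transition_matrix_avg.csv",
                      package = "luccarbon", mustWork = TRUE)
  read_transition_matrix(path, lulc_scheme(), period = "2012-2018 average")
}
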