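#' Configuration for the synthetic landscape generator
#'
#' Describes a multi-year series of spatially autocorrelated categorical
#' rasters whose year-to-year dynamics follow a known row-stochastic
#' matrix, so every pipeline stage can be exercised with no external
#' data. Defaults emulate the bundled case study: a 200 x 200 grid on
#' the seven-class legend whose true dynamics are the bundled averaged
#' transition matrix, evolved over three periods (a four-date series).
#'
#' @param rows,cols grid dimensions (each at least 8).
#' @param scheme [class_scheme()] of the landscape.
#' @param n_patch_seeds number of Voronoi patch seeds (at least J;
#'   default 50 gives a patchy map with every class present).
#' @param P_true `transition_matrix` driving the dynamics (default: the
#'   bundled averaged matrix).
#' @param n_steps number of evolution steps (default 3).
#' @param spatial_mixing probability in \[0, 1\] that a cell's draw is
#'   re-weighted toward classes present in its 3 x 3 neighbourhood,
#'   clustering transitions (default 0.25; use 0 for exact marginal
#'   dynamics, e.g. when recovering the matrix from the series).
#' @param cell_size_m cell size of the generated rasters (default 100).
#' @param seed integer seed; each operation derives its own stream from
#'   it so sub-results are independently reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(rows = 200L, cols = 200L,
                             scheme = lulc_scheme(),
                             n_patch_seeds = 50L,
                             P_true = default_transition_matrix(),
                             n_steps = 3L, spatial_mixing = 0.25,
                             cell_size_m = 100, seed = 1L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 8L || cols < 8L) stop("grid must be at least 8 x 8")
  if (n_patch_seeds < scheme$J) stop("need at least one patch seed per class")
  if (spatial_mixing < 0 || spatial_mixing > 1) {
    stop("'spatial_mixing' must lie in [0, 1]")
  }
  if (!same_scheme(scheme, attr(P_true, "scheme"))) {
    stop("'P_true' must be defined on 'scheme'")
  }
  structure(
    list(rows = rows, cols = cols, scheme = scheme,
         n_patch_seeds = as.integer(n_patch_seeds), P_true = P_true,
         n_steps = as.integer(n_steps), spatial_mixing = spatial_mixing,
         cell_size_m = cell_size_m, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate the initial synthetic landscape
#'
#' Seeded-patch (nearest-seed tessellation) landscape: `n_patch_seeds`
#' cells receive classes — the first J seeds one of each class, the rest
#' uniformly at random — and every other cell takes the class of its
#' nearest seed (squared-distance ties broken by lowest class code, then
#' seed order). By construction every class is present and the map is
#' spatially autocorrelated.
#'
#' @param cfg a [synthetic_config()].
#' @return A `categorical_raster`.
#' @export
generate_initial <- function(cfg) {
  set.seed(cfg$seed)
  J <- cfg$scheme$J
  ncell <- cfg$rows * cfg$cols
  seeds <- sample.int(ncell, cfg$n_patch_seeds)
  seed_cls <- c(sample.int(J), if (cfg$n_patch_seeds > J)
    sample.int(J, cfg$n_patch_seeds - J, replace = TRUE))
  sr <- (seeds - 1L) %% cfg$rows + 1L
  sc <- (seeds - 1L) %/% cfg$rows + 1L
  # order seeds by (class, seed index) so ties.method = "first" breaks
  # distance ties by lowest class code, then seed order
  ord <- order(seed_cls, seq_along(seeds))
  sr <- sr[ord]; sc <- sc[ord]; seed_cls <- seed_cls[ord]
  cr <- rep(seq_len(cfg$rows), times = cfg$cols)
  cc <- rep(seq_len(cfg$cols), each = cfg$rows)
  D <- outer(cr, sr, function(a, b) (a - b)^2) +
    outer(cc, sc, function(a, b) (a - b)^2)
  nearest <- max.col(-D, ties.method = "first")
  grid <- matrix(cfg$scheme$codes[seed_cls[nearest]], nrow = cfg$rows)
  categorical_raster(grid, cfg$scheme, cfg$cell_size_m)
}

#' Evolve a landscape one Markov step
#'
#' Each cell draws its next class from the transition row of its current
#' class. With probability `spatial_mixing` the draw is replaced by one
#' from the same row restricted to classes present in the cell's 3 x 3
#' neighbourhood (renormalised; the unrestricted draw is kept when the
#' row puts no mass on any neighbouring class), which clusters
#' transitions while approximately preserving the marginal dynamics.
#'
#' @param r a `categorical_raster`.
#' @param P a `transition_matrix` on the raster's scheme.
#' @param spatial_mixing clustering probability in \[0, 1\].
#' @param seed integer seed.
#' @return The evolved `categorical_raster`.
#' @export
evolve_markov <- function(r, P, spatial_mixing = 0, seed = 1L) {
  set.seed(seed)
  J <- r$scheme$J
  Pm <- unclass(P)
  valid <- which(r$grid != r$nodata)
  cur <- scheme_index(r$scheme, r$grid[valid])
  nxt <- integer(length(valid))
  for (i in seq_len(J)) {
    sel <- which(cur == i)
    if (length(sel) > 0L) {
      nxt[sel] <- sample.int(J, length(sel), replace = TRUE, prob = Pm[i, ])
    }
  }
  if (spatial_mixing > 0) {
    present <- array(0, c(nrow(r$grid), ncol(r$grid), J))
    vmask <- (r$grid != r$nodata) * 1
    for (c in seq_len(J)) {
      ind <- (r$grid == r$scheme$codes[c] & vmask == 1) * 1
      present[, , c] <- (box_sum(ind, 3L) > 0) * 1
    }
    mix <- which(stats::runif(length(valid)) < spatial_mixing)
    if (length(mix) > 0L) {
      W <- Pm[cur[mix], , drop = FALSE] *
        matrix(present[valid[mix] + (rep(seq_len(J), each = length(mix)) - 1L) *
                         length(r$grid)], nrow = length(mix))
      ws <- rowSums(W)
      ok <- ws > 0
      if (any(ok)) {
        u <- stats::runif(sum(ok)) * ws[ok]
        cw <- W[ok, , drop = FALSE]
        cum <- t(apply(cw, 1, cumsum))
        draw <- max.col(cum >= u, ties.method = "first")
        nxt[mix[ok]] <- draw
      }
    }
  }
  out <- r$grid
  out[valid] <- r$scheme$codes[nxt]
  r$grid <- out
  r
}

#' Generate a multi-year synthetic raster series
#'
#' The initial landscape plus `n_steps` Markov evolutions; step k uses
#' seed `cfg$seed + k` so each raster is independently reproducible.
#'
#' @param cfg a [synthetic_config()].
#' @return Named list of `n_steps + 1` `categorical_raster`s, labelled
#'   `"t0" ... "t<n_steps>"`.
#' @export
generate_series <- function(cfg) {
  out <- vector("list", cfg$n_steps + 1L)
  out[[1]] <- generate_initial(cfg)
  for (k in seq_len(cfg$n_steps)) {
    out[[k + 1L]] <- evolve_markov(out[[k]], cfg$P_true,
                                   spatial_mixing = cfg$spatial_mixing,
                                   seed = cfg$seed + k)
  }
  names(out) <- paste0("t", 0:cfg$n_steps)
  out
}
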