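#' Configuration for CA-Markov prediction
#'
#' @param filter_size odd neighbourhood edge length in cells (default 5,
#'   the conventional contiguity filter).
#' @param iterations number of cellular-automata iterations (default 6,
#'   one per projected year of a six-year step).
#' @param seed integer seed used only when `tie_break = "random"`.
#' @param tie_break `"deterministic"` (suitability, then persistence,
#'   then row-major cell index, then class code) or `"random"` (seeded
#'   jitter among exact ties).
#' @param epsilon floor added to the neighbourhood fraction so that
#'   transitions into locally absent classes stay possible (default
#'   0.01).
#' @return An object of class `prediction_config`.
#' @export
prediction_config <- function(filter_size = 5L, iterations = 6L,
                              seed = 1L,
                              tie_break = c("deterministic", "random"),
                              epsilon = 0.01) {
  tie_break <- match.arg(tie_break)
  filter_size <- as.integer(filter_size)
  iterations <- as.integer(iterations)
  if (filter_size < 3L || filter_size %% 2L == 0L) {
    stop("'filter_size' must be an odd integer >= 3")
  }
  if (iterations < 1L) stop("'iterations' must be >= 1")
  structure(
    list(filter_size = filter_size, iterations = iterations,
         seed = as.integer(seed), tie_break = tie_break,
         epsilon = epsilon),
    class = "prediction_config"
  )
}

#' Markov class-quantity targets
#'
#' Expected future class counts n'P for a count vector n, rounded to
#' integers that conserve the total by largest-remainder rounding.
#'
#' @param counts non-negative integer vector of current class counts
#'   (length J), or an `area_table` (cell counts are inferred from areas
#'   only when a raster is used; pass counts directly otherwise).
#' @param P a `transition_matrix`.
#' @return Integer vector of projected counts, summing to `sum(counts)`.
#' @export
markov_quantities <- function(counts, P) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(counts) != nrow(P)) stop("counts length must match matrix")
  expected <- as.numeric(counts %*% unclass(P))
  largest_remainder(expected, sum(counts))
}

# round non-negative reals to integers with fixed total
largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0L) {
    give <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[give] <- fl[give] + 1
  } else if (rem < 0L) {
    # guard: only possible when x sums below `total` by construction error
    take <- order(x - fl)[seq_len(-rem)]
    fl[take] <- fl[take] - 1
  }
  as.integer(fl)
}

#' Per-class neighbourhood suitability surfaces
#'
#' For each target class c, `suitability(cell, c) =
#' P[current_class(cell), c] * (epsilon + f_c)` where `f_c` is the
#' fraction of class-c cells in the `filter_size` x `filter_size`
#' neighbourhood of the cell (edge-truncated, nodata excluded from the
#' denominator). The two ingredients are exactly the transition
#' probabilities and the contiguity filter: change is most likely where
#' the Markov row allows it and the class is already present nearby.
#'
#' @param r a `categorical_raster`.
#' @param P a `transition_matrix` on the raster's scheme.
#' @param cfg a [prediction_config()].
#' @return A 3-d array `[row, col, class]` of suitabilities; nodata cells
#'   are `NA`.
#' @export
neighborhood_suitability <- function(r, P, cfg = prediction_config()) {
  J <- r$scheme$J
  valid <- (r$grid != r$nodata) * 1
  nb_valid <- box_sum(valid, cfg$filter_size)
  cur_idx <- scheme_index(r$scheme, r$grid)  # NA at nodata
  out <- array(NA_real_, c(nrow(r$grid), ncol(r$grid), J))
  Pm <- unclass(P)
  for (c in seq_len(J)) {
    ind <- (r$grid == r$scheme$codes[c] & valid == 1) * 1
    frac <- box_sum(ind, cfg$filter_size) / pmax(nb_valid, 1)
    p_to_c <- matrix(Pm[cur_idx, c], nrow = nrow(r$grid))
    out[, , c] <- p_to_c * (cfg$epsilon + frac)
  }
  out
}

#' CA-Markov land-cover prediction
#'
#' Predicts a future categorical raster from a current raster and a
#' transition matrix. The Markov chain fixes how much of each class
#' there will be ([markov_quantities()], applied once for the whole
#' step); the cellular automaton decides where, by allocating the
#' class quotas to cells in descending neighbourhood suitability over
#' `cfg$iterations` iterations, with quotas linearly interpolated from
#' the current counts to the Markov targets so change accrues gradually
#' (one iteration per projected year).
#'
#' Allocation within an iteration is greedy over all (cell, class)
#' claims ordered by suitability; exact ties favour persistence (a cell
#' keeps its class when its persistence suitability ties an invader's),
#' then lower row-major cell index, then lower class code — or a seeded
#' random order among ties when `tie_break = "random"`. Cells whose
#' transition row is degenerate (probability 1 of staying) are frozen
#' first, so absorbing classes never lose cells. The output conserves
#' the total non-nodata cell count, and per-class counts equal the
#' interpolated quotas exactly after every iteration.
#'
#' @param r a `categorical_raster`.
#' @param P a `transition_matrix` on the raster's scheme.
#' @param cfg a [prediction_config()].
#' @return The predicted `categorical_raster`.
#' @export
ca_predict <- function(r, P, cfg = prediction_config()) {
  if (!same_scheme(r$scheme, attr(P, "scheme"))) {
    stop("raster and matrix schemes differ")
  }
  n0 <- class_counts(r)
  n_target <- as.numeric(n0 %*% unclass(P))
  cur <- r
  if (cfg$tie_break == "random") set.seed(cfg$seed)
  for (it in seq_len(cfg$iterations)) {
    frac <- it / cfg$iterations
    quota <- largest_remainder(n0 + frac * (n_target - n0), sum(n0))
    cur <- allocate_step(cur, P, quota, cfg)
  }
  cur
}

# one allocation pass: relabel cells so per-class counts equal `quota`
allocate_step <- function(r, P, quota, cfg) {
  J <- r$scheme$J
  suit <- neighborhood_suitability(r, P, cfg)
  valid_idx <- which(r$grid != r$nodata)
  ncell <- length(valid_idx)
  if (sum(quota) != ncell) stop("internal error: infeasible quotas")
  cur_class <- scheme_index(r$scheme, r$grid[valid_idx])
  Pm <- unclass(P)

  assigned <- integer(ncell)  # 0 = unassigned, else class index
  rem <- quota

  # freeze cells whose row is degenerate: they cannot change class
  stay_prob <- Pm[cbind(cur_class, cur_class)]
  frozen <- which(stay_prob >= 1)
  if (length(frozen) > 0L) {
    fr_cls <- cur_class[frozen]
    fr_n <- tabulate(fr_cls, nbins = J)
    if (any(fr_n > rem)) {
      # rare: rounding made the quota dip below the frozen population;
      # release the lowest-suitability frozen cells of those classes
      for (c in which(fr_n > rem)) {
        cells <- frozen[fr_cls == c]
        s <- suit[valid_idx[cells] + (c - 1L) * length(r$grid)]
        drop_n <- fr_n[c] - rem[c]
        cells_drop <- cells[order(s, cells)][seq_len(drop_n)]
        frozen <- setdiff(frozen, cells_drop)
      }
      fr_cls <- cur_class[frozen]
    }
    assigned[frozen] <- fr_cls
    rem <- rem - tabulate(fr_cls, nbins = J)
  }

  free <- which(assigned == 0L)
  if (length(free) > 0L) {
    # claims: every (free cell, class) pair
    cell_rep <- rep(free, times = J)
    cls_rep <- rep(seq_len(J), each = length(free))
    s <- suit[valid_idx[cell_rep] + (cls_rep - 1L) * length(r$grid)]
    persist <- as.integer(cls_rep == cur_class[cell_rep])
    ord <- if (cfg$tie_break == "random") {
      order(-s, stats::runif(length(s)))
    } else {
      order(-s, -persist, valid_idx[cell_rep], cls_rep)
    }
    taken <- logical(ncell)
    taken[assigned != 0L] <- TRUE
    n_left <- length(free)
    for (k in ord) {
      cell <- cell_rep[k]
      if (taken[cell]) next
      cls <- cls_rep[k]
      if (rem[cls] <= 0L) next
      assigned[cell] <- cls
      taken[cell] <- TRUE
      rem[cls] <- rem[cls] - 1L
      n_left <- n_left - 1L
      if (n_left == 0L) break
    }
  }
  out <- r$grid
  out[valid_idx] <- r$scheme$codes[assigned]
  r$grid <- out
  r
}
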