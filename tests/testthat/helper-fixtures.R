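# shared fixture builders; everything generated in code, nothing on disk

two_class_scheme <- function() class_scheme(1:2, c("a", "b"))

# raster from a vector filled by row (reads like the printed grid)
make_raster <- function(vals, nrow, scheme, cell_size_m = 100,
                        nodata = -9999L) {
  grid <- matrix(as.integer(vals), nrow = nrow, byrow = TRUE)
  categorical_raster(grid, scheme, cell_size_m, nodata)
}

# iid uniform random raster on codes 1..J
random_raster <- function(nr, nc, J, seed) {
  set.seed(seed)
  scheme <- class_scheme(seq_len(J))
  categorical_raster(matrix(sample.int(J, nr * nc, replace = TRUE), nr),
                     scheme, 100)
}

# random row-stochastic matrix
random_stochastic <- function(J, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(J * J), J)
  m / rowSums(m)
}

# brute-force kappa oracle: straight from confusion-matrix proportions,
# bypassing agreement_components entirely
kappa_oracle <- function(counts, J_chance) {
  p <- counts / sum(counts)
  M <- sum(diag(p))
  Nm <- sum(rowSums(p) * colSums(p))
  Pm <- sum(pmin(rowSums(p), colSums(p)))
  Nn <- 1 / J_chance
  list(Kstd = (M - Nm) / (1 - Nm),
       Kno = (M - Nn) / (1 - Nn),
       Kloc = (M - Nm) / (Pm - Nm))
}

# bundled published reference ledger (5 assessment years)
reference_ledger <- function() {
  path <- system.file("extdata", "stored_carbon_calabria.csv",
                      package = "luccarbon", mustWork = TRUE)
  utils::read.csv(path)
}
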