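#' Run configuration for the full pipeline
#'
#' Collects everything a full preprocess-predict-assess run needs. Paths
#' are validated up front so a broken configuration fails before any
#' compute.
#'
#' @param raster_paths named character vector of input `.asc` raster
#'   paths, names = strictly increasing years.
#' @param scheme [class_scheme()] of the input rasters (after
#'   reclassification if `reclass_path` is given, the scheme of the
#'   reclass targets applies).
#' @param reclass_path optional reclassification CSV (see
#'   [read_reclass_map()]); `NULL` when inputs are already on the target
#'   legend.
#' @param pools_path carbon pool CSV (default: the bundled table).
#' @param prediction a [prediction_config()].
#' @param predict_years number of years the prediction step projects
#'   beyond the last input year (default 6).
#' @param V,r,c valuation parameters (EUR/Mg, percent, percent).
#' @param out_dir output directory (created if missing).
#' @return A `run_config` list.
#' @export
run_config <- function(raster_paths, scheme = lulc_scheme(),
                       reclass_path = NULL,
                       pools_path = system.file("extdata",
                         "carbon_pools_calabria.csv", package = "luccarbon"),
                       prediction = prediction_config(),
                       predict_years = 6L,
                       V = 200, r = 3, c = 0, out_dir = tempdir()) {
  years <- suppressWarnings(as.numeric(names(raster_paths)))
  if (length(raster_paths) < 2L || length(years) != length(raster_paths) ||
      anyNA(years) || any(diff(years) <= 0)) {
    stop("'raster_paths' must be named by strictly increasing years ",
         "(at least two)")
  }
  for (p in c(raster_paths, reclass_path, pools_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  structure(
    list(raster_paths = raster_paths, years = years, scheme = scheme,
         reclass_path = reclass_path, pools_path = pools_path,
         prediction = prediction, predict_years = as.integer(predict_years),
         V = V, r = r, c = c, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full pipeline: preprocess, predict, assess
#'
#' Executes the three phases on a multi-year raster series:
#' reclassification (optional), per-period transition matrices and their
#' average, CA-Markov prediction of the next map, per-year area tables
#' (including the prediction), and the carbon ledger. All artifacts are
#' written under `cfg$out_dir` as delimited text / `.asc` files; the log
#' reports per-class cell counts at every stage so conservation
#' violations are visible.
#'
#' @param cfg a [run_config()].
#' @param reference optional `categorical_raster` to validate the
#'   prediction against (confusion matrix, components and kappas are
#'   then written as `validation.csv`).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with elements `rasters`, `matrices`,
#'   `avg_matrix`, `prediction`, `areas`, `ledger`, `validation` (NULL
#'   without a reference) and `artifacts` (paths written).
#' @export
run_pipeline <- function(cfg, reference = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(path) {
    artifacts <<- c(artifacts, path)
    path
  }

  # --- preprocess ---------------------------------------------------
  m <- if (!is.null(cfg$reclass_path)) {
    read_reclass_map(cfg$reclass_path, cfg$scheme)
  } else NULL
  rasters <- lapply(seq_along(cfg$raster_paths), function(k) {
    r <- read_asc(cfg$raster_paths[[k]],
                  scheme = if (is.null(m)) cfg$scheme else
                    class_scheme(sort(unique(c(m$source_codes)))),
                  crs_tag = "pipeline")
    if (!is.null(m)) r <- reclassify(r, m)
    say("year ", cfg$years[k], ": class counts ",
        paste(class_counts(r), collapse = " "))
    if (!is.null(m)) {
      emit(write_asc(r, file.path(cfg$out_dir,
                                  paste0("lulc_", cfg$years[k], ".asc"))))
    }
    r
  })

  # --- transitions --------------------------------------------------
  n <- length(rasters)
  matrices <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    period <- paste0(cfg$years[k], "-", cfg$years[k + 1])
    matrices[[k]] <- to_probabilities(
      cross_tabulate(rasters[[k]], rasters[[k + 1]]), period = period)
    emit(write_transition_matrix(
      matrices[[k]],
      file.path(cfg$out_dir, paste0("transitions_", period, ".csv"))))
  }
  avg <- average_matrices(matrices)
  emit(write_transition_matrix(
    avg, file.path(cfg$out_dir, "transitions_average.csv")))

  # --- prediction ---------------------------------------------------
  pred_year <- cfg$years[n] + cfg$predict_years
  say("predicting ", pred_year, " from ", cfg$years[n])
  pred <- ca_predict(rasters[[n]], avg, cfg$prediction)
  say("predicted class counts ", paste(class_counts(pred), collapse = " "))
  emit(write_asc(pred, file.path(cfg$out_dir,
                                 paste0("lulc_", pred_year, "_predicted.asc"))))

  validation <- NULL
  if (!is.null(reference)) {
    ac <- agreement_components(confusion_matrix(pred, reference))
    validation <- list(components = ac, kappas = kappa_set(ac))
    emit(write_validation_report(
      ac, file.path(cfg$out_dir, "validation.csv")))
  }

  # --- carbon assessment --------------------------------------------
  pools <- read_pool_table(cfg$pools_path, rasters[[1]]$scheme)
  areas <- c(
    lapply(seq_len(n), function(k) area_table(rasters[[k]], cfg$years[k])),
    list(area_table(pred, pred_year))
  )
  for (a in areas) {
    emit(write_table(a, file.path(cfg$out_dir,
                                  paste0("areas_", attr(a, "year"), ".csv"))))
  }
  ledger <- build_ledger(areas, pools, V = cfg$V, r = cfg$r, c = cfg$c)
  emit(write_table(ledger, file.path(cfg$out_dir, "carbon_ledger.csv")))
  say("ledger: stored ", paste(round(ledger$stored_Mg), collapse = " "))

  invisible(list(rasters = rasters, matrices = matrices, avg_matrix = avg,
                 prediction = pred, areas = areas, ledger = ledger,
                 validation = validation, artifacts = artifacts))
}
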