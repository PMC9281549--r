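## End-to-end pipeline driver -------------------------------------------------

#' Build a pipeline configuration
#'
#' Either point the pipeline at input files (`meals_path`, `outlets_path`,
#' `polygons_path`) or hand it a synthetic-data [generator_config()] via
#' `generator`.
#'
#' @param meals_path,outlets_path,polygons_path Input file paths (CSV, CSV,
#'   GeoJSON). Ignored when `generator` is given.
#' @param generator Optional `opfe_generator_config`; when set, inputs are
#'   simulated.
#' @param out_dir Output directory; `NULL` (default) skips writing.
#' @param scheme DDS normalization scheme (`"max"` or `"minmax"`).
#' @param quantile_type Sample-quantile type for quartile labels; default 7.
#' @param mmr_cutoff Outlet-dominance cutoff; default 1.5.
#' @param level1_tol Rule-2 tolerance for meal classification; default 0.
#' @param active_rules Exclusion rules to enforce; default all i-x.
#' @param idw_power,idw_cutoff,dist_floor Inverse-distance weight options.
#' @param moran_method `"randomization"` or `"permutation"`.
#' @param kde_cell,kde_bandwidth Kernel density options (metres); bandwidth
#'   `NULL` for the Silverman-style default.
#' @param seed Seed for any stochastic step (permutation tests).
#' @return A validated `opfe_pipeline_config` list.
#' @export
pipeline_config <- function(meals_path = NULL, outlets_path = NULL,
                            polygons_path = NULL, generator = NULL,
                            out_dir = NULL,
                            scheme = c("max", "minmax"), quantile_type = 7,
                            mmr_cutoff = 1.5, level1_tol = 0,
                            active_rules = ROMAN_RULES,
                            idw_power = 1, idw_cutoff = NULL, dist_floor = 15,
                            moran_method = c("randomization", "permutation"),
                            kde_cell = 30, kde_bandwidth = NULL,
                            seed = 1L) {
  scheme <- match.arg(scheme)
  moran_method <- match.arg(moran_method)
  if (is.null(generator) &&
      (is.null(meals_path) || is.null(outlets_path) || is.null(polygons_path))) {
    stop_opfe("supply all three input paths or a generator config",
              "opfetf_config_error")
  }
  if (!is.null(generator) && !inherits(generator, "opfe_generator_config")) {
    stop_opfe("generator must be an opfe_generator_config", "opfetf_config_error")
  }
  structure(list(meals_path = meals_path, outlets_path = outlets_path,
                 polygons_path = polygons_path, generator = generator,
                 out_dir = out_dir, scheme = scheme,
                 quantile_type = quantile_type, mmr_cutoff = mmr_cutoff,
                 level1_tol = level1_tol, active_rules = active_rules,
                 idw_power = idw_power, idw_cutoff = idw_cutoff,
                 dist_floor = dist_floor, moran_method = moran_method,
                 kde_cell = kde_cell, kde_bandwidth = kde_bandwidth,
                 seed = as.integer(seed)),
            class = "opfe_pipeline_config")
}

moran_or_note <- function(x, coords, cfg) {
  tryCatch({
    w <- build_weights(coords, power = cfg$idw_power, cutoff = cfg$idw_cutoff,
                       dist_floor = cfg$dist_floor)
    morans_i(x, w, method = cfg$moran_method)
  }, error = function(e) list(I = NA_real_, expected = NA_real_,
                              variance = NA_real_, Z = NA_real_, p = NA_real_,
                              method = conditionMessage(e)))
}

# per-polygon sums of one indicator column over all polygons (zeros included)
polygon_sums <- function(outlets, col, pid, ids) {
  x <- outlets[[col]]
  x[is.na(x)] <- 0
  out <- vapply(ids, function(id) sum(x[pid == id & !is.na(pid)]), numeric(1))
  unname(out)
}

#' Run the full food-environment pipeline
#'
#' Orchestrates every stage: load (or simulate) meals, outlets and
#' subdistrict polygons; classify meals and apply the exclusion rules; score
#' healthiness and dietary diversity and normalize; aggregate outlet
#' indicators, standardize and label; then run the spatial analysis —
#' inverse-distance Global Moran's I per indicator, weighted kernel density
#' surfaces, per-polygon aggregation, counting-method availability and the
#' Spearman comparison of the two methods. When `out_dir` is set, writes the
#' outlet indicator table, polygon summaries, counting and comparison CSVs,
#' density rasters (`.asc`) and a JSON run manifest with stage counts and
#' file hashes.
#'
#' @param config An `opfe_pipeline_config`.
#' @return Result bundle (list): `meals`, `outlets`, `exclusion_report`,
#'   `moran`, `surfaces`, `polygon_summary`, `counting`, `comparison`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "opfe_pipeline_config"))
  set.seed(config$seed)
  tax <- load_taxonomy()
  reg <- load_food_groups()

  stage <- "load"
  res <- tryCatch({
    if (!is.null(config$generator)) {
      sim <- generate(config$generator)
      meals <- sim$meals; outlets <- sim$outlets; polygons <- sim$polygons
    } else {
      meals <- read_meal_table(config$meals_path, tax, reg)
      outlets <- read_outlet_table(config$outlets_path)
      polygons <- read_polygons(config$polygons_path)
    }
    if (!all(c("x", "y") %in% names(outlets))) {
      xy <- project_lonlat(outlets$lon, outlets$lat)
      outlets$x <- xy[, 1]; outlets$y <- xy[, 2]
    }

    stage <- "classify"
    meals$category <- classify_meals(meals$item_codes, tax, config$level1_tol)

    stage <- "exclude"
    excl <- apply_exclusions(meals, config$active_rules)
    meals_in <- nrow(meals)
    meals <- excl$meals
    if (nrow(meals) == 0L) {
      stop_opfe("no meals retained after exclusion", "opfetf_invalid_input")
    }

    stage <- "score"
    meals <- score_meals(meals, reg, config$scheme)

    stage <- "indicators"
    ind <- outlet_indicators(meals, tax, config$mmr_cutoff)
    ind <- standardize_indicators(ind, config$quantile_type)
    ind <- merge(ind, outlets[, c("outlet_id", "x", "y")], by = "outlet_id")

    stage <- "spatial"
    healthy <- ind$W == 1
    moran <- list(
      TUHII = moran_or_note(ind$z_TUHII, ind[, c("x", "y")], config),
      HII = moran_or_note(ind$HII[healthy],
                          ind[healthy, c("x", "y")], config),
      UHII = moran_or_note(ind$UHII[!healthy],
                           ind[!healthy, c("x", "y")], config)
    )
    surf <- list(
      TUHII = kernel_density(ind[, c("x", "y")], ind$TUHII,
                             config$kde_cell, config$kde_bandwidth),
      HII = if (any(healthy))
        kernel_density(ind[healthy, c("x", "y")], ind$HII[healthy],
                       config$kde_cell, config$kde_bandwidth) else NULL,
      UHII = if (any(!healthy))
        kernel_density(ind[!healthy, c("x", "y")], ind$UHII[!healthy],
                       config$kde_cell, config$kde_bandwidth) else NULL
    )
    poly_sum <- aggregate_by_polygon(ind, polygons,
                                     values = c("z_TUHII", "z_HII", "z_UHII"))
    counting <- list(
      all = counting_availability(ind, polygons, "all"),
      healthy = counting_availability(ind, polygons, "healthy"),
      unhealthy = counting_availability(ind, polygons, "unhealthy")
    )
    ids <- vapply(polygons, function(f) f$id, character(1))
    pid <- assign_polygons(ind[, c("x", "y")], polygons)
    cmp_rows <- lapply(
      list(c("all", "z_TUHII"), c("healthy", "z_HII"), c("unhealthy", "z_UHII")),
      function(spec) {
        sums <- switch(spec[1],
          all = polygon_sums(ind, spec[2], pid, ids),
          healthy = polygon_sums(ind[healthy, , drop = FALSE], spec[2],
                                 pid[healthy], ids),
          unhealthy = polygon_sums(ind[!healthy, , drop = FALSE], spec[2],
                                   pid[!healthy], ids))
        ct <- tryCatch(compare_methods(counting[[spec[1]]]$count, sums),
                       error = function(e) list(rho = NA_real_, p = NA_real_))
        data.frame(sample = spec[1], indicator = spec[2],
                   rho = ct$rho, p = ct$p, stringsAsFactors = FALSE)
      })
    comparison <- do.call(rbind, cmp_rows)

    list(meals = meals, outlets = ind, exclusion_report = excl$report,
         moran = moran, surfaces = surf, polygon_summary = poly_sum,
         counting = counting, comparison = comparison,
         counts = list(meals_in = meals_in, meals_retained = nrow(meals),
                       meals_excluded = meals_in - nrow(meals),
                       n_outlets = nrow(ind),
                       n_healthy = sum(healthy),
                       n_unhealthy = sum(!healthy)))
  }, opfetf_error = function(e) {
    stop(errorCondition(
      paste0("pipeline failed at stage '", stage, "': ", conditionMessage(e)),
      class = c("opfetf_pipeline_error", class(e))))
  })

  res$manifest <- list(
    package = as.character(utils::packageVersion("opfetf")),
    seed = config$seed,
    scheme = config$scheme,
    mmr_cutoff = config$mmr_cutoff,
    counts = res$counts
  )
  if (!is.null(config$out_dir)) {
    res$manifest <- c(res$manifest,
                      write_pipeline_outputs(res, config$out_dir))
  }
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(f) file.path(out_dir, f)
  write.csv(res$outlets, p("outlet_indicators.csv"), row.names = FALSE)
  write_meal_table(res$meals, p("meals_scored.csv"))
  write.csv(res$polygon_summary, p("polygon_summary.csv"), row.names = FALSE)
  counting <- do.call(rbind, lapply(names(res$counting), function(nm) {
    cbind(sample = nm, res$counting[[nm]])
  }))
  write.csv(counting, p("counting.csv"), row.names = FALSE)
  write.csv(res$comparison, p("comparison.csv"), row.names = FALSE)
  moran <- do.call(rbind, lapply(names(res$moran), function(nm) {
    m <- res$moran[[nm]]
    data.frame(indicator = nm, I = m$I, expected = m$expected, Z = m$Z,
               p = m$p, method = m$method, stringsAsFactors = FALSE)
  }))
  write.csv(moran, p("moran.csv"), row.names = FALSE)
  paths <- c(p("outlet_indicators.csv"), p("meals_scored.csv"),
             p("polygon_summary.csv"), p("counting.csv"), p("comparison.csv"),
             p("moran.csv"))
  for (nm in names(res$surfaces)) {
    if (!is.null(res$surfaces[[nm]])) {
      f <- p(paste0("density_", tolower(nm), ".asc"))
      write_surface_asc(res$surfaces[[nm]], f)
      paths <- c(paths, f)
    }
  }
  hashes <- tools::md5sum(paths)
  names(hashes) <- basename(names(hashes))
  manifest_extra <- list(files = as.list(hashes),
                         hash = unname(tools::md5sum(
                           tf <- {
                             tmp <- tempfile()
                             writeLines(paste(names(hashes), hashes), tmp)
                             tmp
                           })))
  jsonlite::write_json(
    c(res$manifest[setdiff(names(res$manifest), c("files", "hash"))],
      manifest_extra),
    p("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(tf)
  manifest_extra
}
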