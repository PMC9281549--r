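## Polygon handling, GeoJSON I/O, projection, aggregation ---------------------

#' Read subdistrict polygons from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features. Each
#' feature's id is taken from `properties$id`, then `feature$id`, then its
#' position in file order. Rings are kept as matrices; the first ring of each
#' polygon is the exterior, the rest are holes.
#'
#' @param path GeoJSON file path.
#' @return An `opfe_polygons` object: a list of features, each a list with
#'   `$id` and `$polys` (list of `list(outer = matrix, holes = list)`).
#' @export
read_polygons <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop_opfe("expected a GeoJSON FeatureCollection", "opfetf_geometry_error")
  }
  feats <- lapply(seq_along(gj$features), function(k) {
    f <- gj$features[[k]]
    id <- f$properties$id
    if (is.null(id)) id <- f$id
    if (is.null(id)) id <- as.character(k)
    geom <- f$geometry
    ring_mat <- function(r) {
      m <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
      storage.mode(m) <- "double"
      m
    }
    polys <- switch(geom$type,
      Polygon = list(list(outer = ring_mat(geom$coordinates[[1]]),
                          holes = lapply(geom$coordinates[-1], ring_mat))),
      MultiPolygon = lapply(geom$coordinates, function(p) {
        list(outer = ring_mat(p[[1]]), holes = lapply(p[-1], ring_mat))
      }),
      stop_opfe(paste0("unsupported geometry type: ", geom$type),
                "opfetf_geometry_error")
    )
    for (p in polys) {
      if (nrow(p$outer) < 4L) {
        stop_opfe("invalid polygon ring (fewer than 4 vertices)",
                  "opfetf_geometry_error")
      }
    }
    list(id = as.character(id), polys = polys)
  })
  structure(feats, class = "opfe_polygons")
}

#' Write polygons to GeoJSON
#'
#' @param polygons An `opfe_polygons` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(polygons, path) {
  stopifnot(inherits(polygons, "opfe_polygons"))
  feats <- lapply(polygons, function(f) {
    coords <- lapply(f$polys, function(p) {
      rings <- c(list(p$outer), p$holes)
      lapply(rings, function(r) lapply(seq_len(nrow(r)), function(i) r[i, ]))
    })
    if (length(coords) == 1L) {
      geom <- list(type = "Polygon", coordinates = coords[[1L]])
    } else {
      geom <- list(type = "MultiPolygon", coordinates = coords)
    }
    list(type = "Feature", properties = list(id = f$id), geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Build a rectangular grid of polygons
#'
#' Convenience constructor for synthetic study areas: an `nx` by `ny` grid of
#' square cells, ids `"P1"`, `"P2"`, ... in row-major order from the
#' lower-left.
#'
#' @param nx,ny Grid dimensions.
#' @param cell Cell side length (metres).
#' @param origin Lower-left corner; default `c(0, 0)`.
#' @return An `opfe_polygons` object.
#' @export
make_grid_polygons <- function(nx, ny, cell, origin = c(0, 0)) {
  feats <- list()
  k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- k + 1L
      x0 <- origin[1] + (i - 1L) * cell
      y0 <- origin[2] + (j - 1L) * cell
      ring <- rbind(c(x0, y0), c(x0 + cell, y0), c(x0 + cell, y0 + cell),
                    c(x0, y0 + cell), c(x0, y0))
      feats[[k]] <- list(id = paste0("P", k),
                         polys = list(list(outer = ring, holes = list())))
    }
  }
  structure(feats, class = "opfe_polygons")
}

# even-odd ray casting for one ring; boundary points are handled separately
ring_contains <- function(ring, x, y) {
  n <- nrow(ring) - 1L      # closed ring: last vertex repeats the first
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# TRUE when the point lies within eps of any ring segment
ring_on_boundary <- function(ring, x, y, eps = 1e-9) {
  out <- rep(FALSE, length(x))
  for (i in seq_len(nrow(ring) - 1L)) {
    ax <- ring[i, 1]; ay <- ring[i, 2]
    bx <- ring[i + 1L, 1]; by <- ring[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(x)) else ((x - ax) * vx + (y - ay) * vy) / L2
    t <- pmin(1, pmax(0, t))
    d2 <- (x - (ax + t * vx))^2 + (y - (ay + t * vy))^2
    out <- out | d2 <= eps^2
  }
  out
}

# membership of points in one feature (outer rings minus holes, or boundary)
feature_contains <- function(feature, x, y) {
  res <- rep(FALSE, length(x))
  for (p in feature$polys) {
    inside <- ring_contains(p$outer, x, y) | ring_on_boundary(p$outer, x, y)
    for (h in p$holes) {
      inside <- inside & !(ring_contains(h, x, y) & !ring_on_boundary(h, x, y))
    }
    res <- res | inside
  }
  res
}

#' Assign points to polygons
#'
#' Point-in-polygon join with a deterministic first-match rule: a point on a
#' shared boundary belongs to the first feature (in file order) that contains
#' it. Points outside every polygon get `NA`.
#'
#' @param coords Two-column matrix/data frame of x/y.
#' @param polygons An `opfe_polygons` object.
#' @return Character vector of polygon ids (or `NA`).
#' @export
assign_polygons <- function(coords, polygons) {
  stopifnot(inherits(polygons, "opfe_polygons"))
  coords <- as.matrix(coords)
  out <- rep(NA_character_, nrow(coords))
  todo <- rep(TRUE, nrow(coords))
  for (f in polygons) {          # first match in file order wins
    if (!any(todo)) break
    hit <- feature_contains(f, coords[todo, 1], coords[todo, 2])
    idx <- which(todo)[hit]
    out[idx] <- f$id
    todo[idx] <- FALSE
  }
  out
}

#' Aggregate outlet indicators by polygon
#'
#' Point-in-polygon join of outlets into subdistrict polygons, then
#' per-polygon, per-category sums of the requested indicator columns and
#' outlet counts. Outlets outside every polygon go to an `"unassigned"`
#' bucket with a warning, so totals are conserved:
#' polygon sums + unassigned = global sums.
#'
#' @param outlets Data frame with `x`, `y`, optionally `category`, and the
#'   indicator columns named in `values`.
#' @param polygons An `opfe_polygons` object.
#' @param values Character vector of outlet columns to sum (e.g.
#'   `"z_TUHII"`); `NA` values are dropped from sums.
#' @return Data frame with one row per polygon-category pair: `polygon_id`,
#'   `category`, `n`, and a `sum_<col>` per requested column.
#' @export
aggregate_by_polygon <- function(outlets, polygons, values = "z_TUHII") {
  if (!all(c("x", "y") %in% names(outlets))) {
    stop_opfe("outlets need projected x/y columns", "opfetf_invalid_input")
  }
  miss <- setdiff(values, names(outlets))
  if (length(miss)) {
    stop_opfe(paste0("missing indicator column(s): ", paste(miss, collapse = ", ")),
              "opfetf_invalid_input")
  }
  pid <- assign_polygons(outlets[, c("x", "y")], polygons)
  if (anyNA(pid)) {
    warning(sum(is.na(pid)), " outlet(s) outside all polygons; ",
            "kept in the 'unassigned' bucket")
    pid[is.na(pid)] <- "unassigned"
  }
  cat_col <- if ("category" %in% names(outlets)) outlets$category else "all"
  key <- data.frame(polygon_id = pid, category = cat_col,
                    stringsAsFactors = FALSE)
  counts <- aggregate(list(n = rep(1L, nrow(key))), key, sum)
  for (v in values) {
    x <- outlets[[v]]
    x[is.na(x)] <- 0
    s <- aggregate(setNames(list(x), paste0("sum_", v)), key, sum)
    counts <- merge(counts, s, by = c("polygon_id", "category"))
  }
  counts[order(counts$polygon_id, counts$category), , drop = FALSE]
}

#' Outlet counts per polygon (the counting method)
#'
#' The traditional availability measure: the number of food outlets per
#' subdistrict, optionally restricted to healthy (`W = 1`) or unhealthy
#' (`W < 1`) outlets, with z-standardized counts across polygons. Polygons
#' with no outlets count zero. Constant counts cannot be standardized and
#' yield `NA` z-scores with a warning.
#'
#' @param outlets Data frame with `x`, `y` and (for subsets) `W`.
#' @param polygons An `opfe_polygons` object.
#' @param subset `"all"`, `"healthy"` or `"unhealthy"`.
#' @return Data frame `polygon_id`, `count`, `z_count` covering every
#'   polygon.
#' @export
counting_availability <- function(outlets, polygons,
                                  subset = c("all", "healthy", "unhealthy")) {
  subset <- match.arg(subset)
  if (subset != "all") {
    if (!"W" %in% names(outlets)) {
      stop_opfe("subset by healthiness needs a W column", "opfetf_invalid_input")
    }
    keep <- if (subset == "healthy") outlets$W == 1 else outlets$W < 1
    outlets <- outlets[keep, , drop = FALSE]
  }
  ids <- vapply(polygons, function(f) f$id, character(1))
  pid <- if (nrow(outlets)) assign_polygons(outlets[, c("x", "y")], polygons)
         else character(0)
  pid <- pid[!is.na(pid)]
  cnt <- as.integer(table(factor(pid, levels = ids)))
  z <- tryCatch(z_standardize(cnt), error = function(e) {
    warning("degenerate counts: ", conditionMessage(e))
    rep(NA_real_, length(cnt))
  })
  data.frame(polygon_id = ids, count = cnt, z_count = z,
             stringsAsFactors = FALSE)
}

#' Compare the counting method with an impact indicator
#'
#' Spearman rank correlation between per-polygon outlet counts and
#' per-polygon indicator sums (the two availability measures). With ties the
#' p-value uses the t approximation, otherwise the exact distribution
#' ([stats::cor.test()] defaults).
#'
#' @param polygon_counts Numeric per-polygon counts.
#' @param polygon_indicator_sums Numeric per-polygon indicator sums, same
#'   order.
#' @return List with `rho` and `p`.
#' @export
compare_methods <- function(polygon_counts, polygon_indicator_sums) {
  if (length(polygon_counts) != length(polygon_indicator_sums)) {
    stop_opfe("count and sum vectors must align", "opfetf_invalid_input")
  }
  if (length(polygon_counts) < 4L) {
    stop_opfe("need at least four polygons", "opfetf_invalid_input")
  }
  if (sd(polygon_counts) == 0 || sd(polygon_indicator_sums) == 0) {
    stop_opfe("constant vector: rank correlation undefined",
              "opfetf_degenerate_input")
  }
  ct <- suppressWarnings(
    cor.test(polygon_counts, polygon_indicator_sums, method = "spearman")
  )
  list(rho = unname(ct$estimate), p = unname(ct$p.value))
}

#' Project longitude/latitude to local metric coordinates
#'
#' Equirectangular projection centred on the data centroid:
#' `x = R * cos(lat0) * (lon - lon0)`, `y = R * (lat - lat0)` (radians,
#' `R = 6378137` m). Over a city-scale extent (tens of km) the distance
#' distortion is below 0.1%, which is ample for inverse-distance weights and
#' kernel density at 30 m resolution.
#'
#' @param lon,lat Numeric vectors of degrees.
#' @param origin Optional `c(lon0, lat0)`; defaults to the centroid.
#' @return Two-column matrix of x/y metres, with the origin as an attribute.
#' @export
project_lonlat <- function(lon, lat, origin = NULL) {
  if (is.null(origin)) origin <- c(mean(lon), mean(lat))
  R <- 6378137
  x <- R * cos(origin[2] * pi / 180) * (lon - origin[1]) * pi / 180
  y <- R * (lat - origin[2]) * pi / 180
  out <- cbind(x = x, y = y)
  attr(out, "origin") <- origin
  out
}
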