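#' Inverse-distance spatial weights
#'
#' Builds pairwise weights `w_ij = 1 / d_ij^power` (zero diagonal) from point
#' coordinates in a metric CRS. Coincident pairs (`d = 0`) are given a
#' distance floor `dist_floor` so weights stay finite; the floor defaults to
#' half the default raster cell size (15 m). An optional distance `cutoff`
#' zeroes weights beyond it, and `row_standardize` rescales each row to sum
#' to 1.
#'
#' @param coords Two-column matrix or data frame of projected x/y (metres).
#' @param power Inverse-distance exponent; default 1.
#' @param cutoff Optional distance beyond which weights are zero.
#' @param dist_floor Distance substituted for coincident pairs; default 15.
#' @param row_standardize Logical; default `FALSE`.
#' @return An `opfe_weights` object (list with the weight matrix `$w` and the
#'   parameters used).
#' @examples
#' w <- build_weights(cbind(c(0, 2), c(0, 0)))
#' w$w[1, 2]   # 0.5
#' @export
build_weights <- function(coords, power = 1, cutoff = NULL, dist_floor = 15,
                          row_standardize = FALSE) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) {
    stop_opfe("need at least two points", "opfetf_invalid_input")
  }
  d <- as.matrix(dist(coords))
  off <- d[upper.tri(d)]
  if (all(off == 0)) {
    stop_opfe("all points are coincident", "opfetf_degenerate_geometry")
  }
  d[d == 0] <- dist_floor
  w <- 1 / d^power
  diag(w) <- 0
  if (!is.null(cutoff)) w[d > cutoff] <- 0
  if (row_standardize) {
    rs <- rowSums(w)
    rs[rs == 0] <- 1
    w <- w / rs
  }
  structure(list(w = w, power = power, cutoff = cutoff,
                 dist_floor = dist_floor, row_standardized = row_standardize),
            class = "opfe_weights")
}

#' Global Moran's I
#'
#' Computes Moran's I,
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z_i = x_i - mean`,
#' its null expectation `E[I] = -1/(n-1)`, and a significance test. The
#' default test uses the randomization-variance formula (Cliff-Ord) with a
#' two-sided normal p-value; `method = "permutation"` instead compares the
#' observed I against `n_perm` random relabellings (two-sided pseudo
#' p-value; seed the RNG for reproducibility).
#'
#' @param x Numeric values at the weight matrix's points; must be
#'   non-constant.
#' @param weights An `opfe_weights` object from [build_weights()].
#' @param method `"randomization"` (default) or `"permutation"`.
#' @param n_perm Number of permutations for the permutation test; default 999.
#' @return List with `I`, `expected`, `variance` (randomization only), `Z`
#'   (randomization only), `p`, and `method`.
#' @export
morans_i <- function(x, weights, method = c("randomization", "permutation"),
                     n_perm = 999) {
  method <- match.arg(method)
  stopifnot(inherits(weights, "opfe_weights"))
  w <- weights$w
  n <- length(x)
  if (n != nrow(w)) {
    stop_opfe("length(x) must match the weight matrix", "opfetf_invalid_input")
  }
  if (sd(x) == 0) {
    stop_opfe("constant values: Moran's I undefined", "opfetf_degenerate_input")
  }
  s0 <- sum(w)
  stat <- function(v) {
    z <- v - mean(v)
    (n / s0) * sum(w * tcrossprod(z)) / sum(z^2)
  }
  I <- stat(x)
  EI <- -1 / (n - 1)
  if (method == "randomization") {
    z <- x - mean(x)
    s1 <- 0.5 * sum((w + t(w))^2)
    s2 <- sum((rowSums(w) + colSums(w))^2)
    b2 <- n * sum(z^4) / sum(z^2)^2
    varI <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
               b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * s0^2) - EI^2
    Z <- (I - EI) / sqrt(varI)
    p <- 2 * pnorm(-abs(Z))
    list(I = I, expected = EI, variance = varI, Z = Z, p = p,
         method = "randomization")
  } else {
    perm <- vapply(seq_len(n_perm), function(k) stat(sample(x)), numeric(1))
    p_hi <- (1 + sum(perm >= I)) / (n_perm + 1)
    p_lo <- (1 + sum(perm <= I)) / (n_perm + 1)
    list(I = I, expected = EI, variance = NA_real_, Z = NA_real_,
         p = min(1, 2 * min(p_hi, p_lo)), method = "permutation")
  }
}

## Weighted quartic kernel density ------------------------------------------

# Silverman-style reference bandwidth on projected coordinates: pooled per-axis
# sd scaled by n^(-1/6) (the planar-kernel rate).
default_bandwidth <- function(coords, cell_size) {
  n <- nrow(coords)
  s <- sqrt((var(coords[, 1]) + var(coords[, 2])) / 2)
  h <- if (is.finite(s) && s > 0) s * n^(-1 / 6) else 0
  max(h, 5 * cell_size)
}

#' Weighted kernel density surface
#'
#' Quartic-kernel density of weighted points on a regular grid:
#' `f(u) = sum_i w_i * K(|u - p_i|)` with
#' `K(d) = 3/(pi h^2) * (1 - (d/h)^2)^2` for `d < h` (the kernel integrates
#' to 1, so the surface's total mass approximates the total weight). The grid
#' covers the points' bounding box padded by one bandwidth; default cell size
#' is 30 m.
#'
#' @param coords Two-column matrix/data frame of projected x/y (metres).
#' @param w Per-point weights (e.g. an outlet's indicator value); default 1.
#' @param cell_size Grid resolution in metres; default 30.
#' @param bandwidth Kernel radius in metres; default a Silverman-style rule on
#'   the projected coordinates (never below 5 cells).
#' @return An `opfe_density` object: list with matrix `$z` (rows = south to
#'   north), `$origin` (lower-left corner), `$cell_size`, `$bandwidth`.
#' @export
kernel_density <- function(coords, w = rep(1, nrow(coords)), cell_size = 30,
                           bandwidth = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop_opfe("no points", "opfetf_invalid_input")
  if (length(w) != nrow(coords)) {
    stop_opfe("weights must match points", "opfetf_invalid_input")
  }
  if (cell_size <= 0) stop_opfe("cell size must be positive", "opfetf_invalid_input")
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(coords, cell_size)
  if (bandwidth <= 0) stop_opfe("bandwidth must be positive", "opfetf_invalid_input")
  h <- bandwidth
  x0 <- min(coords[, 1]) - h
  y0 <- min(coords[, 2]) - h
  nx <- max(1L, ceiling((max(coords[, 1]) + h - x0) / cell_size))
  ny <- max(1L, ceiling((max(coords[, 2]) + h - y0) / cell_size))
  xc <- x0 + (seq_len(nx) - 0.5) * cell_size
  yc <- y0 + (seq_len(ny) - 0.5) * cell_size
  z <- matrix(0, nrow = ny, ncol = nx)
  k0 <- 3 / (pi * h^2)
  for (i in seq_len(nrow(coords))) {
    if (w[i] == 0) next
    cx <- which(abs(xc - coords[i, 1]) < h)
    cy <- which(abs(yc - coords[i, 2]) < h)
    if (!length(cx) || !length(cy)) next
    d2 <- outer((yc[cy] - coords[i, 2])^2, (xc[cx] - coords[i, 1])^2, "+")
    u <- 1 - d2 / h^2
    u[u < 0] <- 0
    z[cy, cx] <- z[cy, cx] + w[i] * k0 * u^2
  }
  structure(list(z = z, origin = c(x0, y0), cell_size = cell_size,
                 bandwidth = h, nx = nx, ny = ny),
            class = "opfe_density")
}

#' Total mass of a density surface
#'
#' Sum of cell values times cell area; approximates the total point weight.
#'
#' @param surface An `opfe_density`.
#' @return Numeric scalar.
#' @export
surface_total <- function(surface) {
  stopifnot(inherits(surface, "opfe_density"))
  sum(surface$z) * surface$cell_size^2
}

#' Coordinates of the maximum-density cell
#'
#' @param surface An `opfe_density`.
#' @return Numeric length-2 vector (x, y) of the peak cell's centre.
#' @export
density_peak <- function(surface) {
  stopifnot(inherits(surface, "opfe_density"))
  k <- which.max(surface$z)
  row <- (k - 1L) %% surface$ny + 1L
  col <- (k - 1L) %/% surface$ny + 1L
  c(x = surface$origin[1] + (col - 0.5) * surface$cell_size,
    y = surface$origin[2] + (row - 0.5) * surface$cell_size)
}

#' Write a density surface as an ESRI ASCII grid
#'
#' Plain-text single-band raster (`.asc`) readable by standard GIS tools.
#'
#' @param surface An `opfe_density`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface_asc <- function(surface, path) {
  stopifnot(inherits(surface, "opfe_density"))
  hdr <- c(
    paste("ncols", surface$nx),
    paste("nrows", surface$ny),
    paste("xllcorner", surface$origin[1]),
    paste("yllcorner", surface$origin[2]),
    paste("cellsize", surface$cell_size),
    "NODATA_value -9999"
  )
  # .asc rows run north to south
  body <- apply(surface$z[rev(seq_len(surface$ny)), , drop = FALSE], 1,
                paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
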