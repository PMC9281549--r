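#' Healthy score of a meal
#'
#' The healthy score `l` counts the unhealthy proxy foods present in a meal:
#' a fried food, a sweetened sugar beverage, and high-salt sauces or pickles.
#' Each contributes one point, so `l` ranges 0 (healthiest) to 3
#' (unhealthiest); a meal is *healthy* iff `l == 0`.
#'
#' Missing labels are an error, never imputed: silently assuming a missing
#' label means "absent" would bias `l` downward.
#'
#' @param meals Data frame with logical or 0/1 columns `fried`,
#'   `sugar_beverage`, `high_salt` (one row per meal).
#' @return Integer vector of scores in 0..3.
#' @examples
#' healthy_score(data.frame(fried = 1, sugar_beverage = 1, high_salt = 1))  # 3
#' healthy_score(data.frame(fried = 0, sugar_beverage = 0, high_salt = 0))  # 0
#' @export
healthy_score <- function(meals) {
  lab <- c("fried", "sugar_beverage", "high_salt")
  if (!all(lab %in% names(meals))) {
    stop_opfe("meals must carry fried, sugar_beverage and high_salt labels",
              "opfetf_invalid_input")
  }
  m <- vapply(lab, function(v) {
    x <- meals[[v]]
    if (is.logical(x)) x <- as.integer(x)
    if (anyNA(x)) {
      stop_opfe(paste0("missing value in label '", v, "'; labels are not imputed"),
                "opfetf_invalid_input")
    }
    if (!all(x %in% c(0L, 1L))) {
      stop_opfe(paste0("label '", v, "' must be 0/1 or logical"),
                "opfetf_invalid_input")
    }
    as.integer(x)
  }, integer(nrow(meals)))
  if (nrow(meals) == 1L) m <- matrix(m, nrow = 1L)
  as.integer(rowSums(m))
}

#' Dietary diversity score (DDS) of a meal
#'
#' DDS counts the distinct food groups present in a meal, over a 12-group
#' registry; each group contributes one point, so DDS ranges 1..12 for a
#' valid meal. Duplicated mentions of a group do not add (set semantics).
#' A meal with no food groups at all is invalid: diversity is undefined when
#' there is no food.
#'
#' @param food_groups Either a character vector of ";"-separated group codes
#'   (the on-disk form) or a list of integer vectors.
#' @param registry Food-group registry, see [load_food_groups()].
#' @return Integer vector of DDS values.
#' @examples
#' dds("1;3;5;6")        # 4
#' dds("1;1;3")          # 2 (set semantics)
#' @export
dds <- function(food_groups, registry = load_food_groups()) {
  if (is.character(food_groups)) {
    food_groups <- lapply(food_groups, split_codes)
  }
  vapply(food_groups, function(g) {
    g <- unique(as.integer(g))
    if (length(g) == 0L || anyNA(g)) {
      stop_opfe("meal with empty or unparseable food groups: DDS undefined",
                "opfetf_invalid_input")
    }
    if (!all(g %in% registry$code)) {
      stop_opfe("food-group code outside the 12-group registry",
                "opfetf_invalid_input")
    }
    length(g)
  }, integer(1))
}

#' Normalize the reciprocal of DDS across the analysis set
#'
#' The unhealthy impact indicators weight each meal's sales by the normalized
#' reciprocal of its DDS, so that low-diversity meals weigh more. Two schemes:
#' \describe{
#'   \item{`"max"` (default)}{`(1/dds) / max(1/dds)`; values in (0, 1] with
#'     the least diverse meal mapped to 1. Chosen as the default because a
#'     min-max map would send the most diverse meal's weight to exactly 0 and
#'     erase its sales contribution from the impact sums.}
#'   \item{`"minmax"`}{`(r - min r) / (max r - min r)` on `r = 1/dds`;
#'     offered for sensitivity analysis.}
#' }
#' Normalization is computed over the full analysis meal set (all outlets
#' post-filter), so outlet indicators are comparable.
#'
#' @param dds_values Integer vector of DDS values (all >= 1).
#' @param scheme `"max"` or `"minmax"`.
#' @return Numeric vector of normalized reciprocal DDS weights.
#' @examples
#' normalize_reciprocal_dds(c(2, 4))   # 1.0, 0.5
#' @export
normalize_reciprocal_dds <- function(dds_values, scheme = c("max", "minmax")) {
  scheme <- match.arg(scheme)
  if (length(dds_values) == 0L) {
    stop_opfe("empty meal set", "opfetf_invalid_input")
  }
  if (any(dds_values < 1)) {
    stop_opfe("all DDS values must be >= 1", "opfetf_invalid_input")
  }
  r <- 1 / dds_values
  norm_scale(r, scheme)
}

#' Normalize DDS across the analysis set
#'
#' Mirror of [normalize_reciprocal_dds()] applied to DDS itself; used by the
#' healthy-outlet impact indicator, where high-diversity meals weigh more.
#' Default scheme divides by the maximum DDS in the analysis set.
#'
#' @inheritParams normalize_reciprocal_dds
#' @return Numeric vector of normalized DDS weights.
#' @examples
#' normalize_dds(c(3, 6))   # 0.5, 1.0
#' @export
normalize_dds <- function(dds_values, scheme = c("max", "minmax")) {
  scheme <- match.arg(scheme)
  if (length(dds_values) == 0L) {
    stop_opfe("empty meal set", "opfetf_invalid_input")
  }
  if (any(dds_values < 1)) {
    stop_opfe("all DDS values must be >= 1", "opfetf_invalid_input")
  }
  norm_scale(as.numeric(dds_values), scheme)
}

norm_scale <- function(x, scheme) {
  if (scheme == "max") return(x / max(x))
  rng <- max(x) - min(x)
  if (rng == 0) {
    warning("constant input under min-max normalization; returning 1s")
    return(rep(1, length(x)))
  }
  (x - min(x)) / rng
}

#' Score a meal table
#'
#' Adds the per-meal healthy score (`l`), dietary diversity (`dds`) and the
#' dataset-normalized weights (`dds_norm`, `recip_dds_norm`) to a meal table.
#' Normalization is over all rows of `meals`, which should therefore be the
#' post-exclusion analysis set.
#'
#' @param meals Meal table (see [read_meal_table()] for the schema).
#' @param registry Food-group registry.
#' @param scheme Normalization scheme, see [normalize_reciprocal_dds()].
#' @return `meals` with columns `l`, `dds`, `dds_norm`, `recip_dds_norm`
#'   appended.
#' @export
score_meals <- function(meals, registry = load_food_groups(),
                        scheme = c("max", "minmax")) {
  scheme <- match.arg(scheme)
  meals$l <- healthy_score(meals)
  meals$dds <- dds(meals$food_groups, registry)
  meals$dds_norm <- normalize_dds(meals$dds, scheme)
  meals$recip_dds_norm <- normalize_reciprocal_dds(meals$dds, scheme)
  meals
}
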