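## Synthetic food-environment generator ---------------------------------------

ROMAN_RULES <- c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x")

MEAL_TYPES <- c(ST = "1-1", ND = "1-2", SET = "1-3", WFF = "1-7", HLR = "1-8")

# per-category food-group inclusion weights (12 groups); HLR favours
# vegetables/fruits/plant groups, WFF dairy and miscellaneous, etc.
default_fg_weights <- function() {
  base <- rep(1, 12)
  list(
    ST  = replace(base, c(1, 5, 6), c(3, 2, 2)),
    ND  = replace(base, c(1, 3, 5), c(3, 2, 2)),
    SET = replace(base, c(1, 3, 5, 6), c(3, 2.5, 2, 1.5)),
    WFF = replace(base, c(1, 5, 10, 12), c(3, 2.5, 2, 2)),
    HLR = replace(base, c(3, 4, 8, 11), c(3, 2, 2, 2.5))
  )
}

#' Build a synthetic-data generator configuration
#'
#' Parameters of the seeded generator that emulates a food-delivery-platform
#' crawl: a grid of subdistrict polygons, outlets of six types (the five meal
#' types ST/ND/SET/WFF/HLR plus mixed-menu UN outlets), and per-meal-category
#' distributions of the three unhealthy labels, the food-group count, and
#' monthly sales. The defaults are the reference study conditions the
#' generator emulates: per-type
#' unhealthy-label probabilities ordered so expected healthy scores run
#' HLR < ND < overall < ST < WFF, and food-group count parameters so expected
#' DDS runs ST < ND < overall < WFF < HLR, with roughly 800 outlets selling
#' 10-35 meals each (about 18,000 meals).
#'
#' @param seed Integer RNG seed.
#' @param n_outlets Number of outlets; default 800.
#' @param grid_nx,grid_ny Polygon grid dimensions; default 5 x 2 (10
#'   subdistricts).
#' @param cell_size Polygon cell side in metres; default 2000.
#' @param type_mix Named mixture over outlet types ST, ND, SET, WFF, HLR, UN;
#'   must sum to 1.
#' @param meal_params Named list (per meal category ST/ND/SET/WFF/HLR) of
#'   lists with `p_fried`, `p_sugar`, `p_salt` (unhealthy-label
#'   probabilities), `fg_p` (success probability of the shifted-binomial
#'   food-group count `1 + Binomial(11, fg_p)`), and `sales_meanlog`,
#'   `sales_sdlog` (log-normal monthly sales).
#' @param meals_range Integer range of meals per outlet; default `c(10, 35)`.
#' @param own_type_prob Probability a typed outlet's meal is of its own
#'   category (the rest spread over the other categories); default 0.8.
#' @param healthy_outlet_rate Fraction of outlets that sell only healthy
#'   meals (all unhealthy-label probabilities forced to zero for their
#'   menus); default 0.15, the share of exclusively-healthy outlets the
#'   generator emulates.
#' @param flag_rate Fraction of meals carrying a random exclusion flag
#'   (rules i-x); default 0.02.
#' @param fg_weights Per-category food-group inclusion weights (length-12
#'   vectors).
#' @param planted_cluster Optional list `(polygon_id, type_mix, sales_mult)`
#'   overriding the outlet-type mixture and scaling sales inside one polygon,
#'   to plant a high-impact cluster for spatial detection.
#' @return A validated `opfe_generator_config` list.
#' @export
generator_config <- function(
    seed = 1L,
    n_outlets = 800L,
    grid_nx = 5L, grid_ny = 2L, cell_size = 2000,
    type_mix = c(ST = 0.12, ND = 0.30, SET = 0.30, WFF = 0.08,
                 HLR = 0.10, UN = 0.10),
    meal_params = list(
      ST  = list(p_fried = 0.40, p_sugar = 0.08, p_salt = 0.16, fg_p = 0.325,
                 sales_meanlog = 4.3, sales_sdlog = 0.8),
      ND  = list(p_fried = 0.15, p_sugar = 0.05, p_salt = 0.10, fg_p = 0.336,
                 sales_meanlog = 4.3, sales_sdlog = 0.8),
      SET = list(p_fried = 0.22, p_sugar = 0.08, p_salt = 0.15, fg_p = 0.359,
                 sales_meanlog = 4.3, sales_sdlog = 0.8),
      WFF = list(p_fried = 0.45, p_sugar = 0.22, p_salt = 0.12, fg_p = 0.418,
                 sales_meanlog = 4.8, sales_sdlog = 0.8),
      HLR = list(p_fried = 0.06, p_sugar = 0.04, p_salt = 0.04, fg_p = 0.485,
                 sales_meanlog = 4.3, sales_sdlog = 0.8)
    ),
    meals_range = c(10L, 35L),
    own_type_prob = 0.8,
    healthy_outlet_rate = 0.15,
    flag_rate = 0.02,
    fg_weights = default_fg_weights(),
    planted_cluster = NULL) {
  cfg <- list(seed = as.integer(seed), n_outlets = as.integer(n_outlets),
              grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
              cell_size = cell_size, type_mix = type_mix,
              meal_params = meal_params, meals_range = as.integer(meals_range),
              own_type_prob = own_type_prob,
              healthy_outlet_rate = healthy_outlet_rate, flag_rate = flag_rate,
              fg_weights = fg_weights, planted_cluster = planted_cluster)
  validate_generator_config(cfg)
  structure(cfg, class = "opfe_generator_config")
}

validate_generator_config <- function(cfg) {
  if (!setequal(names(cfg$type_mix), c(names(MEAL_TYPES), "UN"))) {
    stop_opfe("type_mix must cover ST, ND, SET, WFF, HLR, UN",
              "opfetf_config_error")
  }
  if (abs(sum(cfg$type_mix) - 1) > 1e-8 || any(cfg$type_mix < 0)) {
    stop_opfe("type_mix must be non-negative and sum to 1",
              "opfetf_config_error")
  }
  for (tp in names(MEAL_TYPES)) {
    p <- cfg$meal_params[[tp]]
    if (is.null(p)) {
      stop_opfe(paste0("missing meal_params for ", tp), "opfetf_config_error")
    }
    probs <- c(p$p_fried, p$p_sugar, p$p_salt, p$fg_p)
    if (any(probs < 0 | probs > 1)) {
      stop_opfe(paste0("probabilities for ", tp, " must lie in [0, 1]"),
                "opfetf_config_error")
    }
  }
  if (cfg$meals_range[1] < 1L || cfg$meals_range[2] < cfg$meals_range[1]) {
    stop_opfe("invalid meals_range", "opfetf_config_error")
  }
  if (cfg$flag_rate < 0 || cfg$flag_rate > 1 ||
      cfg$own_type_prob < 0 || cfg$own_type_prob > 1 ||
      cfg$healthy_outlet_rate < 0 || cfg$healthy_outlet_rate > 1) {
    stop_opfe("rates must lie in [0, 1]", "opfetf_config_error")
  }
  if (!is.null(cfg$planted_cluster)) {
    pc <- cfg$planted_cluster
    if (is.null(pc$polygon_id) || is.null(pc$type_mix)) {
      stop_opfe("planted_cluster needs polygon_id and type_mix",
                "opfetf_config_error")
    }
    if (abs(sum(pc$type_mix) - 1) > 1e-8 || any(pc$type_mix < 0)) {
      stop_opfe("planted_cluster type_mix must sum to 1", "opfetf_config_error")
    }
  }
  invisible(cfg)
}

#' The default reference generator configuration
#'
#' Returns [generator_config()] with its defaults: the study conditions the
#' generator emulates, whose per-type parameters order the expected healthy
#' scores HLR < ND < overall < ST < WFF and the expected DDS
#' ST < ND < overall < WFF < HLR.
#'
#' @param seed Integer RNG seed.
#' @param n_outlets Number of outlets; default 800.
#' @param ... Further overrides passed to [generator_config()].
#' @return An `opfe_generator_config`.
#' @export
default_paperlike_config <- function(seed = 1L, n_outlets = 800L, ...) {
  generator_config(seed = seed, n_outlets = n_outlets, ...)
}

#' Expected per-category meal means implied by a configuration
#'
#' Closed-form expectations used to document and test the generator: the
#' expected healthy score of a category is the sum of its three label
#' probabilities, attenuated by the exclusively-healthy outlet fraction
#' (whose meals always score zero), and the expected DDS is `1 + 11 * fg_p`.
#'
#' @param config An `opfe_generator_config`.
#' @return Data frame with `type`, `expected_l`, `expected_dds`.
#' @export
expected_type_means <- function(config) {
  stopifnot(inherits(config, "opfe_generator_config"))
  rows <- lapply(names(MEAL_TYPES), function(tp) {
    p <- config$meal_params[[tp]]
    data.frame(type = tp,
               expected_l = (1 - config$healthy_outlet_rate) *
                 (p$p_fried + p$p_sugar + p$p_salt),
               expected_dds = 1 + 11 * p$fg_p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# sample one meal's distinct food groups given count k and inclusion weights
sample_food_groups <- function(k, wts) {
  sort(sample.int(12L, k, prob = wts))
}

#' Generate a synthetic food-environment dataset
#'
#' Fully reproducible given `config$seed`. Outlets of the configured types
#' are placed uniformly within a grid of subdistrict polygons; each outlet
#' sells `meals_range` meals, mostly of its own category (UN outlets draw
#' categories uniformly, so their menus classify to Unknown). Each meal gets
#' items of its category, Bernoulli unhealthy labels, a shifted-binomial
#' food-group set with category-specific inclusion weights, log-normal
#' monthly sales, and (rarely) an exclusion flag. An optional planted
#' cluster overrides the type mixture and scales sales inside one polygon.
#'
#' @param config An `opfe_generator_config`.
#' @return List with `outlets` (outlet_id, x, y, type), `meals` (the
#'   documented meal-table schema), `polygons` (an `opfe_polygons`), and the
#'   `config`.
#' @export
generate <- function(config = default_paperlike_config()) {
  stopifnot(inherits(config, "opfe_generator_config"))
  validate_generator_config(config)
  set.seed(config$seed)
  nx <- config$grid_nx; ny <- config$grid_ny; cell <- config$cell_size
  polygons <- make_grid_polygons(nx, ny, cell)
  n <- config$n_outlets

  # outlet placement: uniform polygon, uniform position within it
  poly_k <- sample.int(nx * ny, n, replace = TRUE)
  col <- (poly_k - 1L) %% nx
  row <- (poly_k - 1L) %/% nx
  x <- (col + runif(n)) * cell
  y <- (row + runif(n)) * cell
  poly_id <- paste0("P", poly_k)

  type <- sample(names(config$type_mix), n, replace = TRUE,
                 prob = config$type_mix)
  sales_mult <- rep(1, n)
  pc <- config$planted_cluster
  if (!is.null(pc)) {
    in_cl <- poly_id == pc$polygon_id
    if (any(in_cl)) {
      type[in_cl] <- sample(names(pc$type_mix), sum(in_cl), replace = TRUE,
                            prob = pc$type_mix)
      if (!is.null(pc$sales_mult)) sales_mult[in_cl] <- pc$sales_mult
    }
  }
  outlet_id <- sprintf("O%04d", seq_len(n))
  outlets <- data.frame(outlet_id = outlet_id, x = x, y = y, type = type,
                        stringsAsFactors = FALSE)

  # meal-level draws, vectorised over the pooled meal list
  n_meals <- sample(seq(config$meals_range[1], config$meals_range[2]),
                    n, replace = TRUE)
  oi <- rep(seq_len(n), n_meals)
  N <- length(oi)
  cats5 <- names(MEAL_TYPES)
  own <- type[oi]
  cat <- character(N)
  is_un <- own == "UN"
  cat[is_un] <- sample(cats5, sum(is_un), replace = TRUE)
  if (any(!is_un)) {
    keep_own <- runif(sum(!is_un)) < config$own_type_prob
    cat_typed <- own[!is_un]
    if (any(!keep_own)) {
      cat_typed[!keep_own] <- vapply(cat_typed[!keep_own], function(tp) {
        sample(setdiff(cats5, tp), 1L)
      }, character(1))
    }
    cat[!is_un] <- cat_typed
  }

  par <- config$meal_params
  pf <- vapply(par, `[[`, numeric(1), "p_fried")[cat]
  ps <- vapply(par, `[[`, numeric(1), "p_sugar")[cat]
  ph <- vapply(par, `[[`, numeric(1), "p_salt")[cat]
  fgp <- vapply(par, `[[`, numeric(1), "fg_p")[cat]
  ml <- vapply(par, `[[`, numeric(1), "sales_meanlog")[cat]
  sl <- vapply(par, `[[`, numeric(1), "sales_sdlog")[cat]

  # exclusively-healthy outlets: their menus never carry an unhealthy label
  healthy_outlet <- runif(n) < config$healthy_outlet_rate
  zero <- healthy_outlet[oi]
  fried <- ifelse(zero, 0L, rbinom(N, 1L, pf))
  sugar <- ifelse(zero, 0L, rbinom(N, 1L, ps))
  salt <- ifelse(zero, 0L, rbinom(N, 1L, ph))
  k <- 1L + rbinom(N, 11L, fgp)
  fg <- character(N)
  for (tp in cats5) {
    idx <- which(cat == tp)
    wts <- config$fg_weights[[tp]]
    fg[idx] <- vapply(k[idx], function(kk) {
      join_codes(sample_food_groups(kk, wts))
    }, character(1))
  }
  sales <- pmax(0L, as.integer(round(rlnorm(N, ml, sl) * sales_mult[oi])))
  n_items <- sample.int(3L, N, replace = TRUE)
  item_codes <- vapply(seq_len(N), function(i) {
    join_codes(rep(MEAL_TYPES[[cat[i]]], n_items[i]))
  }, character(1))
  flags <- character(N)
  flagged <- runif(N) < config$flag_rate
  flags[flagged] <- sample(ROMAN_RULES, sum(flagged), replace = TRUE)

  meal_seq <- sequence(n_meals)
  meals <- data.frame(
    outlet_id = outlet_id[oi],
    meal_id = paste0(outlet_id[oi], "_m", meal_seq),
    item_codes = item_codes,
    food_groups = fg,
    fried = fried, sugar_beverage = sugar, high_salt = salt,
    monthly_sales = sales,
    exclusion_flags = flags,
    stringsAsFactors = FALSE
  )
  list(outlets = outlets, meals = meals, polygons = polygons, config = config)
}
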