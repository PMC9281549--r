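#' Load the bundled food taxonomy
#'
#' The package ships a two-level classification system for takeaway meals and
#' food outlets: 3 Level I categories (1 = Meal, 2 = Snacks and Beverage,
#' 3 = Other) and 14 Level II categories, each with a code (e.g. `"1-7"`), a
#' short name (e.g. `"WFF"` for western fast-food) and a description.
#'
#' @param path Optional path to a taxonomy CSV with columns `level1`, `code1`,
#'   `level2`, `code2`, `short_name`, `description`. Defaults to the bundled
#'   registry.
#' @return An object of class `opfe_taxonomy`: a list with the category table
#'   (`$categories`) and lookup helpers.
#' @examples
#' tax <- load_taxonomy()
#' nrow(tax$categories)                      # 14
#' taxonomy_lookup(tax, code2 = "1-7")$short_name  # "WFF"
#' @export
load_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "taxonomy.csv", package = "opfetf")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop_opfe("taxonomy resource not found", "opfetf_config_error")
  }
  cats <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("level1", "code1", "level2", "code2", "short_name", "description")
  if (!all(needed %in% names(cats))) {
    stop_opfe("malformed taxonomy resource: missing columns", "opfetf_config_error")
  }
  cats$code1 <- as.integer(cats$code1)
  # registry invariants
  if (anyDuplicated(cats$code2) || anyDuplicated(cats$short_name)) {
    stop_opfe("malformed taxonomy resource: duplicate codes or short names",
              "opfetf_config_error")
  }
  if (!all(sub("-.*", "", cats$code2) == as.character(cats$code1))) {
    stop_opfe("malformed taxonomy resource: code2 prefix must equal code1",
              "opfetf_config_error")
  }
  structure(list(categories = cats), class = "opfe_taxonomy")
}

#' Look up a taxonomy category
#'
#' @param taxonomy An `opfe_taxonomy` from [load_taxonomy()].
#' @param code2,short_name Exactly one of the two selectors.
#' @return A one-row data frame describing the category.
#' @export
taxonomy_lookup <- function(taxonomy, code2 = NULL, short_name = NULL) {
  stopifnot(inherits(taxonomy, "opfe_taxonomy"))
  cats <- taxonomy$categories
  if (!is.null(code2)) {
    hit <- cats[cats$code2 == code2, , drop = FALSE]
  } else if (!is.null(short_name)) {
    hit <- cats[cats$short_name == short_name, , drop = FALSE]
  } else {
    stop_opfe("supply code2 or short_name", "opfetf_invalid_input")
  }
  if (nrow(hit) != 1L) {
    stop_opfe("category not found in taxonomy", "opfetf_invalid_input")
  }
  hit
}

#' Load the bundled 12-group food-group registry
#'
#' Dietary diversity (DDS) is counted over 12 food groups (cereals; roots and
#' tubers; vegetables; mushroom and plant seafood; meat, poultry and offal;
#' eggs; fish and seafood; pulses and legumes; nuts; dairy; fruits;
#' miscellaneous).
#'
#' @param path Optional path to an alternative registry CSV (`code`, `name`).
#' @return A data frame with integer `code` and `name`.
#' @export
load_food_groups <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "food_groups.csv", package = "opfetf")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop_opfe("food-group registry not found", "opfetf_config_error")
  }
  fg <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "name") %in% names(fg)) || anyDuplicated(fg$code)) {
    stop_opfe("malformed food-group registry", "opfetf_config_error")
  }
  fg$code <- as.integer(fg$code)
  fg
}

# natural ordering for level-2 codes: by level-1 code, then numeric suffix
order_codes <- function(codes) {
  l1 <- as.integer(sub("-.*", "", codes))
  l2 <- as.integer(sub(".*-", "", codes))
  order(l1, l2)
}

# modal code with deterministic tie-break to the smallest code under natural
# ordering
modal_code <- function(codes) {
  tab <- table(codes)
  top <- names(tab)[tab == max(tab)]
  top[order_codes(top)][1L]
}

#' Classify a meal from its item categories
#'
#' A meal product is composed of one or more items, each pre-labelled with a
#' Level II category code. Three rules decide the meal's category:
#' \enumerate{
#'   \item All items share one Level II code: the meal is that code.
#'   \item The items split over several Level I categories in the same (or,
#'     under `level1_tol`, similar) quantities: the Level I category with the
#'     smallest code takes priority, and the meal is the modal Level II code
#'     among that Level I's items.
#'   \item Otherwise the meal is the modal Level II code over all items.
#' }
#' Modal ties break deterministically to the smallest code under natural
#' ordering.
#'
#' @param items Character vector (multiset) of Level II codes.
#' @param taxonomy Registry used for code validation.
#' @param level1_tol Relative tolerance for "similar" Level I quantities in
#'   Rule 2: counts are similar when `max - min <= level1_tol * max`. Default 0
#'   (exactly equal).
#' @return A single Level II code.
#' @examples
#' classify_meal(c("1-2", "1-2"))                    # "1-2"
#' classify_meal(c("1-1", "1-1", "2-2", "2-2"))      # "1-1" (Level I priority)
#' classify_meal(c("1-3", "1-3", "1-3", "2-4"))      # "1-3" (majority)
#' @export
classify_meal <- function(items, taxonomy = load_taxonomy(), level1_tol = 0) {
  if (length(items) == 0L) {
    stop_opfe("empty meal composition", "opfetf_invalid_input")
  }
  bad <- setdiff(unique(items), taxonomy$categories$code2)
  if (length(bad)) {
    stop_opfe(paste0("unknown category code(s): ", paste(bad, collapse = ", ")),
              "opfetf_invalid_input")
  }
  if (length(unique(items)) == 1L) return(items[[1L]])     # Rule 1
  lvl1 <- sub("-.*", "", items)
  n1 <- table(lvl1)
  if (length(n1) > 1L && (max(n1) - min(n1)) <= level1_tol * max(n1)) {
    # Rule 2: Level I tie -> smallest Level I code has priority
    top1 <- names(n1)[order(as.integer(names(n1)))][1L]
    return(modal_code(items[lvl1 == top1]))
  }
  modal_code(items)                                        # Rule 3
}

#' Classify meals given as ";"-separated item-code strings
#'
#' Vectorised convenience wrapper around [classify_meal()] for the on-disk
#' meal-table representation (column `item_codes`).
#'
#' @param item_codes Character vector; each element a ";"-separated list of
#'   Level II codes.
#' @inheritParams classify_meal
#' @return Character vector of Level II codes, one per meal.
#' @export
classify_meals <- function(item_codes, taxonomy = load_taxonomy(),
                           level1_tol = 0) {
  out <- character(length(item_codes))
  parsed <- strsplit(item_codes, ";", fixed = TRUE)
  single <- !vapply(parsed, function(p) length(unique(p)) > 1L, logical(1))
  # fast path: single-category compositions classify to themselves (Rule 1)
  if (any(single)) {
    codes <- vapply(parsed[single], function(p) {
      p <- trimws(p)
      p <- p[nzchar(p)]
      if (length(p) == 0L) stop_opfe("empty meal composition", "opfetf_invalid_input")
      p[[1L]]
    }, character(1))
    bad <- setdiff(unique(codes), taxonomy$categories$code2)
    if (length(bad)) {
      stop_opfe(paste0("unknown category code(s): ", paste(bad, collapse = ", ")),
                "opfetf_invalid_input")
    }
    out[single] <- codes
  }
  for (i in which(!single)) {
    out[i] <- classify_meal(trimws(parsed[[i]]), taxonomy, level1_tol)
  }
  out
}

#' Classify a food outlet from its meals' categories
#'
#' An outlet selling a single meal type takes that type. Otherwise it takes
#' the modal meal type, subject to a dominance check: the ratio of the
#' largest to the smallest category count (MMR) must reach `mmr_cutoff`. An
#' exact tie for the mode, or a failed dominance check, yields the Unknown
#' category `"3-1"`.
#'
#' The MMR cutoff is provisional: its value is a tuning parameter of the
#' classification system, here defaulting to 1.5.
#'
#' @param meal_categories Character vector of Level II codes, one per meal.
#' @param taxonomy Registry used for code validation.
#' @param mmr_cutoff Max/min count-ratio an outlet's modal category must reach
#'   to dominate; default 1.5.
#' @return A single Level II code, possibly `"3-1"` (Unknown).
#' @examples
#' classify_outlet(c("1-2", "1-2", "1-2"))     # "1-2"
#' classify_outlet(c("1-2", "1-2", "1-3"))     # "1-2" (MMR 2 >= 1.5)
#' classify_outlet(c("1-2", "1-3"))            # "3-1" (tie)
#' @export
classify_outlet <- function(meal_categories, taxonomy = load_taxonomy(),
                            mmr_cutoff = 1.5) {
  if (length(meal_categories) == 0L) {
    stop_opfe("outlet has no classified meals", "opfetf_invalid_input")
  }
  bad <- setdiff(unique(meal_categories), taxonomy$categories$code2)
  if (length(bad)) {
    stop_opfe(paste0("unknown category code(s): ", paste(bad, collapse = ", ")),
              "opfetf_invalid_input")
  }
  tab <- table(meal_categories)
  if (length(tab) == 1L) return(names(tab))
  if (sum(tab == max(tab)) > 1L) return("3-1")      # modal tie -> Unknown
  if (max(tab) / min(tab) < mmr_cutoff) return("3-1")  # dominance failure
  names(tab)[which.max(tab)]
}
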