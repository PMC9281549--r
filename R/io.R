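## Meal/outlet table I/O and record exclusion ---------------------------------

#' Read and validate a meal table
#'
#' The on-disk meal schema is a CSV with columns `outlet_id`, `meal_id`,
#' `item_codes` (";"-separated Level II codes), `food_groups` (";"-separated
#' integer codes 1-12), `fried`, `sugar_beverage`, `high_salt` (strictly
#' 0/1), `monthly_sales` (non-negative integer) and optionally
#' `exclusion_flags` (";"-separated rule codes i-x).
#'
#' Column-level violations (missing required column, a boolean column with
#' values outside 0/1) are schema errors and abort. Row-level violations
#' (empty or unparseable food groups, unknown codes, negative sales) reject
#' the row; rejected rows are reported with their file line numbers in the
#' `"rejected"` attribute of the result.
#'
#' @param path CSV file path.
#' @param taxonomy Taxonomy registry for item-code validation.
#' @param registry Food-group registry.
#' @return Validated meal data frame with a `"rejected"` attribute
#'   (data frame `line`, `reason`; empty when all rows pass).
#' @export
read_meal_table <- function(path, taxonomy = load_taxonomy(),
                            registry = load_food_groups()) {
  req <- c("outlet_id", "meal_id", "item_codes", "food_groups", "fried",
           "sugar_beverage", "high_salt", "monthly_sales")
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_opfe(paste0("meal table missing required column(s): ",
                     paste(miss, collapse = ", ")), "opfetf_schema_error")
  }
  if (!"exclusion_flags" %in% names(df)) df$exclusion_flags <- ""
  df$exclusion_flags[is.na(df$exclusion_flags)] <- ""
  for (v in c("fried", "sugar_beverage", "high_salt")) {
    if (!all(df[[v]] %in% c("0", "1"))) {
      stop_opfe(paste0("boolean column '", v, "' must be encoded 0/1"),
                "opfetf_schema_error")
    }
    df[[v]] <- as.integer(df[[v]])
  }

  reasons <- rep(NA_character_, nrow(df))
  sales <- suppressWarnings(as.numeric(df$monthly_sales))
  bad_sales <- is.na(sales) | sales < 0 | sales != floor(sales)
  reasons[bad_sales] <- "monthly_sales must be a non-negative integer"
  fg_codes <- lapply(df$food_groups, split_codes)
  for (i in seq_len(nrow(df))) {
    if (!is.na(reasons[i])) next
    g <- suppressWarnings(as.integer(fg_codes[[i]]))
    if (length(g) == 0L || anyNA(g) || !all(g %in% registry$code)) {
      reasons[i] <- "food_groups empty or outside the 12-group registry"
      next
    }
    items <- split_codes(df$item_codes[i])
    if (length(items) == 0L ||
        !all(items %in% taxonomy$categories$code2)) {
      reasons[i] <- "item_codes empty or not in the taxonomy"
      next
    }
    flags <- split_codes(df$exclusion_flags[i])
    if (length(flags) && !all(flags %in% ROMAN_RULES)) {
      reasons[i] <- "exclusion_flags outside rules i-x"
    }
  }
  bad <- !is.na(reasons)
  rejected <- data.frame(line = which(bad) + 1L,   # +1 for the header line
                         reason = reasons[bad], stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    warning(nrow(rejected), " row(s) rejected; see attr(x, 'rejected')")
  }
  out <- df[!bad, , drop = FALSE]
  out$monthly_sales <- as.integer(sales[!bad])
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a meal table
#'
#' Inverse of [read_meal_table()]; writes the documented CSV schema so a
#' write-then-read round trip is lossless.
#'
#' @param meals Meal data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_meal_table <- function(meals, path) {
  write.csv(meals, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an outlet table
#'
#' CSV with `outlet_id` and either projected `x`/`y` (metres) or `lon`/`lat`
#' (degrees; re-projected on demand by the pipeline), plus optional columns.
#'
#' @param path CSV file path.
#' @return Outlet data frame.
#' @export
read_outlet_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"outlet_id" %in% names(df)) {
    stop_opfe("outlet table missing outlet_id", "opfetf_schema_error")
  }
  has_xy <- all(c("x", "y") %in% names(df))
  has_ll <- all(c("lon", "lat") %in% names(df))
  if (!has_xy && !has_ll) {
    stop_opfe("outlet table needs x/y or lon/lat columns", "opfetf_schema_error")
  }
  df
}

#' Apply record-exclusion rules
#'
#' Filters a classified meal table by the ten record-exclusion rules (i-x)
#' plus the meal-category restriction: only single meals of the five
#' categories ST (`1-1`), ND (`1-2`), SET (`1-3`), WFF (`1-7`) and HLR
#' (`1-8`) enter the analysis. Exclusion flags are set upstream (by the
#' interpreter or the generator); this filter is flag-driven. Category-based
#' drops are attributed to rule iv (POT, fried-and-BBQ, seafood), rule ix
#' (snacks and beverages) or rule x (unrecognizable), and each excluded
#' record is attributed to exactly one rule — the first matching in i-x
#' order.
#'
#' @param meals Meal table carrying `exclusion_flags` and a `category`
#'   column (see [classify_meals()]).
#' @param active_rules Subset of `c("i", ..., "x")` whose flags are enforced;
#'   default all ten. The category restriction is always enforced.
#' @return List with `meals` (retained rows) and `report` (named integer
#'   vector of exclusion counts per rule, plus `retained`).
#' @export
apply_exclusions <- function(meals, active_rules = ROMAN_RULES) {
  bad_rule <- setdiff(active_rules, ROMAN_RULES)
  if (length(bad_rule)) {
    stop_opfe(paste0("unknown exclusion rule(s): ",
                     paste(bad_rule, collapse = ", ")), "opfetf_config_error")
  }
  if (!"category" %in% names(meals)) {
    stop_opfe("meals must be classified before exclusion (category column)",
              "opfetf_state_error")
  }
  keep_cats <- unname(MEAL_TYPES)     # "1-1" "1-2" "1-3" "1-7" "1-8"
  flags <- lapply(meals$exclusion_flags, split_codes)
  lvl1 <- sub("-.*", "", meals$category)
  attributed <- rep(NA_character_, nrow(meals))
  for (r in ROMAN_RULES) {            # first matching rule in i-x order wins
    hit <- rep(FALSE, nrow(meals))
    if (r %in% active_rules) {
      hit <- vapply(flags, function(f) r %in% f, logical(1))
    }
    if (r == "iv") hit <- hit | meals$category %in% c("1-4", "1-5", "1-6")
    if (r == "ix") hit <- hit | lvl1 == "2"
    if (r == "x") hit <- hit | (!meals$category %in% keep_cats & lvl1 != "2" &
                                  !meals$category %in% c("1-4", "1-5", "1-6"))
    attributed[is.na(attributed) & hit] <- r
  }
  report <- vapply(ROMAN_RULES, function(r) sum(attributed == r, na.rm = TRUE),
                   integer(1))
  keep <- is.na(attributed)
  report <- c(report, retained = sum(keep))
  list(meals = meals[keep, , drop = FALSE], report = report)
}
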