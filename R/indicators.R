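#' Health weight of a food outlet
#'
#' `W = N_h / N_t`: the fraction of an outlet's meals that are healthy
#' (healthy score `l == 0`). `W = 1` means the outlet sold only healthy
#' meals; `W = 0` means every meal carried at least one unhealthy food.
#'
#' @param l Integer vector of healthy scores for one outlet's meals.
#' @return Health weight in \[0, 1\].
#' @examples
#' health_weight(c(0, 0, 0))   # 1
#' health_weight(c(1, 2, 3))   # 0
#' @export
health_weight <- function(l) {
  if (length(l) == 0L) stop_opfe("outlet has no meals", "opfetf_invalid_input")
  mean(l == 0)
}

#' Total unhealthy impact indicator (TUHII) of an outlet
#'
#' `TUHII = sum_i l_i * r_i * S_i` over the outlet's meals, where `l_i` is the
#' healthy score, `r_i` the normalized reciprocal DDS and `S_i` the monthly
#' sales. Healthy meals (`l = 0`) contribute nothing, so an all-healthy outlet
#' has `TUHII = 0`.
#'
#' @param l Healthy scores of the outlet's meals.
#' @param recip_dds_norm Normalized reciprocal DDS weights (dataset-wide
#'   normalization; see [normalize_reciprocal_dds()]).
#' @param sales Monthly sales counts.
#' @return Non-negative TUHII value.
#' @export
tuhii <- function(l, recip_dds_norm, sales) {
  check_meal_vectors(l, recip_dds_norm, sales)
  sum(l * recip_dds_norm * sales)
}

#' Healthy-outlet impact indicator (HII)
#'
#' Defined only for healthy outlets (`W = 1`): `HII = sum_i d_i * S_i` with
#' `d_i` the normalized DDS. Higher HII means a stronger impact of the healthy
#' outlet.
#'
#' @param l Healthy scores (used to verify the `W = 1` precondition).
#' @param dds_norm Normalized DDS weights.
#' @param sales Monthly sales counts.
#' @return Non-negative HII value.
#' @export
hii <- function(l, dds_norm, sales) {
  check_meal_vectors(l, dds_norm, sales)
  if (health_weight(l) < 1) {
    stop_opfe("HII is defined only for outlets with health weight 1",
              "opfetf_precondition_error")
  }
  sum(dds_norm * sales)
}

#' Unhealthy-outlet impact indicator (UHII)
#'
#' Defined only for unhealthy outlets (`W < 1`):
#' `UHII = sum_i r_i * S_i` with `r_i` the normalized reciprocal DDS. Note the
#' sum runs over *all* the outlet's meals, healthy ones included — the
#' indicator carries no healthy-score factor, unlike TUHII. Higher UHII means
#' a stronger impact of the unhealthy outlet.
#'
#' @param l Healthy scores (used to verify the `W < 1` precondition).
#' @param recip_dds_norm Normalized reciprocal DDS weights.
#' @param sales Monthly sales counts.
#' @return Non-negative UHII value.
#' @export
uhii <- function(l, recip_dds_norm, sales) {
  check_meal_vectors(l, recip_dds_norm, sales)
  if (health_weight(l) == 1) {
    stop_opfe("UHII is defined only for outlets with health weight < 1",
              "opfetf_precondition_error")
  }
  sum(recip_dds_norm * sales)
}

check_meal_vectors <- function(l, w, sales) {
  if (length(l) == 0L) stop_opfe("outlet has no meals", "opfetf_invalid_input")
  if (length(w) != length(l) || length(sales) != length(l)) {
    stop_opfe("meal vectors must have equal length", "opfetf_invalid_input")
  }
  if (anyNA(l) || anyNA(w) || anyNA(sales)) {
    stop_opfe("scores, weights and sales must be complete; run normalization first",
              "opfetf_state_error")
  }
}

#' Z-score standardization
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation; the output has
#' mean 0 and sd 1.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return Standardized vector.
#' @examples
#' z_standardize(c(1, 3))   # -0.707, +0.707
#' @export
z_standardize <- function(x) {
  if (length(x) < 2L) {
    stop_opfe("need at least two values to standardize", "opfetf_degenerate_input")
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop_opfe("constant input cannot be z-standardized", "opfetf_degenerate_input")
  }
  (x - mean(x)) / s
}

#' Quartile group labels
#'
#' Labels values by sample quartiles, following the lower-closed label chain:
#' for the health-weight scheme `"W"`, healthy `H` (`x >= q75`), relatively
#' healthy `rH` (`q50 <= x < q75`), relatively unhealthy `ruH`
#' (`q25 <= x < q50`) and unhealthy `uH` (`x < q25`); for the `"indicator"`
#' scheme the analogous `Q4` (`x >= q75`), `Q3`, `Q2`, `Q1`.
#'
#' With constant input all three quartiles coincide and every value satisfies
#' `x >= q75`, so all labels collapse to the top group (a warning is emitted).
#'
#' @param x Numeric vector, length >= 4.
#' @param scheme `"W"` for health-weight labels, `"indicator"` for Q1..Q4.
#' @param type Sample-quantile type passed to [stats::quantile()]; default 7
#'   (linear interpolation).
#' @return Character vector of labels.
#' @examples
#' quartile_labels(c(0.1, 0.4, 0.6, 0.9), "W")   # uH ruH rH H
#' @export
quartile_labels <- function(x, scheme = c("W", "indicator"), type = 7) {
  scheme <- match.arg(scheme)
  if (length(x) < 4L) {
    stop_opfe("need at least four values for quartile grouping",
              "opfetf_degenerate_input")
  }
  q <- quantile(x, probs = c(0.25, 0.5, 0.75), type = type, names = FALSE)
  labs <- if (scheme == "W") c("uH", "ruH", "rH", "H") else c("Q1", "Q2", "Q3", "Q4")
  out <- ifelse(x >= q[3L], labs[4L],
         ifelse(x >= q[2L], labs[3L],
         ifelse(x >= q[1L], labs[2L], labs[1L])))
  if (q[1L] == q[3L]) {
    warning("degenerate quartiles: all values collapse to the top group")
  }
  out
}

#' Compute outlet-level indicators from a scored meal table
#'
#' Aggregates a scored meal table (see [score_meals()]) to one row per outlet:
#' number of meals, outlet category (via [classify_outlet()] when the meal
#' table carries a `category` column), health weight `W`, `TUHII`, and `HII`
#' (healthy outlets, `W = 1`) or `UHII` (unhealthy outlets, `W < 1`) — for
#' every outlet exactly one of the two is defined, the other is `NA`.
#'
#' @param meals Scored meal table with columns `outlet_id`, `l`, `dds_norm`,
#'   `recip_dds_norm`, `monthly_sales`, and optionally `category`.
#' @param taxonomy Taxonomy used for outlet classification.
#' @param mmr_cutoff Dominance cutoff for [classify_outlet()].
#' @return Data frame with one row per outlet: `outlet_id`, `category`,
#'   `n_meals`, `W`, `TUHII`, `HII`, `UHII`.
#' @export
outlet_indicators <- function(meals, taxonomy = load_taxonomy(),
                              mmr_cutoff = 1.5) {
  need <- c("outlet_id", "l", "dds_norm", "recip_dds_norm", "monthly_sales")
  if (!all(need %in% names(meals))) {
    stop_opfe("meals must be scored and normalized first (see score_meals)",
              "opfetf_state_error")
  }
  idx <- split(seq_len(nrow(meals)), meals$outlet_id)
  rows <- lapply(idx, function(i) {
    l <- meals$l[i]; s <- meals$monthly_sales[i]
    W <- health_weight(l)
    data.frame(
      outlet_id = meals$outlet_id[i][1L],
      category = if ("category" %in% names(meals)) {
        classify_outlet(meals$category[i], taxonomy, mmr_cutoff)
      } else NA_character_,
      n_meals = length(i),
      W = W,
      TUHII = tuhii(l, meals$recip_dds_norm[i], s),
      HII = if (W == 1) hii(l, meals$dds_norm[i], s) else NA_real_,
      UHII = if (W < 1) uhii(l, meals$recip_dds_norm[i], s) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardize outlet indicators and attach quartile labels
#'
#' Z-standardizes `TUHII` over all outlets, `HII` over the healthy subset
#' (`W = 1`) and `UHII` over the unhealthy subset (`W < 1`) — matching the
#' separate group analyses the indicators are designed for — and attaches the
#' health-weight quartile label (`w_label`: H/rH/ruH/uH over all outlets) plus
#' per-indicator quartile labels (`Q1..Q4`, within each standardization
#' group). Subsets too small or constant for a step yield `NA` with a warning.
#'
#' @param outlets Output of [outlet_indicators()].
#' @param quantile_type Sample-quantile type for the labels.
#' @return `outlets` with `z_TUHII`, `z_HII`, `z_UHII`, `w_label`, `q_TUHII`,
#'   `q_HII`, `q_UHII` appended.
#' @export
standardize_indicators <- function(outlets, quantile_type = 7) {
  z_or_na <- function(x) {
    tryCatch(z_standardize(x), error = function(e) {
      warning(conditionMessage(e)); rep(NA_real_, length(x))
    })
  }
  lab_or_na <- function(x, scheme) {
    tryCatch(quartile_labels(x, scheme, type = quantile_type),
             error = function(e) {
               warning(conditionMessage(e)); rep(NA_character_, length(x))
             })
  }
  outlets$z_TUHII <- z_or_na(outlets$TUHII)
  healthy <- !is.na(outlets$HII)
  unhealthy <- !is.na(outlets$UHII)
  outlets$z_HII <- NA_real_
  outlets$z_UHII <- NA_real_
  if (any(healthy)) outlets$z_HII[healthy] <- z_or_na(outlets$HII[healthy])
  if (any(unhealthy)) outlets$z_UHII[unhealthy] <- z_or_na(outlets$UHII[unhealthy])
  outlets$w_label <- lab_or_na(outlets$W, "W")
  outlets$q_TUHII <- lab_or_na(outlets$z_TUHII, "indicator")
  outlets$q_HII <- NA_character_
  outlets$q_UHII <- NA_character_
  if (sum(healthy) >= 4L) {
    outlets$q_HII[healthy] <- lab_or_na(outlets$z_HII[healthy], "indicator")
  }
  if (sum(unhealthy) >= 4L) {
    outlets$q_UHII[unhealthy] <- lab_or_na(outlets$z_UHII[unhealthy], "indicator")
  }
  outlets
}

#' Group-difference test with a homoscedasticity gate
#'
#' Runs Levene's test (centered at the group means, the classic form); when it
#' indicates homoscedasticity (`p >= 0.05`) the group difference is tested by
#' one-way ANOVA, otherwise by Welch's ANOVA. Groups with fewer than two
#' observations are excluded with a warning.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @param alpha Homoscedasticity threshold for the Levene gate; default 0.05.
#' @return List with `levene_F`, `levene_p`, `anova_kind` (`"anova"` or
#'   `"welch"`), `F`, `p`, and the group sizes used.
#' @export
group_difference_test <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding group(s) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2L) {
    stop_opfe("need at least two groups with >= 2 observations",
              "opfetf_invalid_input")
  }
  lev <- car::leveneTest(values ~ groups, center = mean)
  levene_F <- lev[1, "F value"]
  levene_p <- lev[1, "Pr(>F)"]
  homoscedastic <- levene_p >= alpha
  fit <- oneway.test(values ~ groups, var.equal = homoscedastic)
  list(
    levene_F = unname(levene_F),
    levene_p = unname(levene_p),
    anova_kind = if (homoscedastic) "anova" else "welch",
    F = unname(fit$statistic),
    p = unname(fit$p.value),
    group_sizes = as.integer(table(groups))
  )
}
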