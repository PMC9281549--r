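# Shared fixtures and independent brute-force oracles.

# minimal meal table builder
mk_meals <- function(outlet_id, l = NULL, fried = NULL, sugar = 0, salt = 0,
                     dds_norm = 1, recip_dds_norm = 1, sales = 1,
                     category = NULL) {
  n <- length(outlet_id)
  if (is.null(fried)) fried <- as.integer(l > 0)   # encode l via fried copies
  df <- data.frame(outlet_id = outlet_id,
                   fried = fried,
                   sugar_beverage = rep_len(sugar, n),
                   high_salt = rep_len(salt, n),
                   dds_norm = rep_len(dds_norm, n),
                   recip_dds_norm = rep_len(recip_dds_norm, n),
                   monthly_sales = rep_len(sales, n),
                   stringsAsFactors = FALSE)
  if (!is.null(l)) df$l <- l
  if (!is.null(category)) df$category <- category
  df
}

# Moran's I by explicit double loop (independent of the matrix implementation)
moran_brute <- function(x, w) {
  n <- length(x)
  m <- mean(x)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * (x[i] - m) * (x[j] - m)
    }
  }
  (n / sum(w)) * num / sum((x - m)^2)
}

# outlet indicators by explicit per-meal loop
indicators_brute <- function(meals) {
  out <- NULL
  for (id in unique(meals$outlet_id)) {
    sub <- meals[meals$outlet_id == id, ]
    nh <- 0; tu <- 0; hi <- 0; uh <- 0
    for (r in seq_len(nrow(sub))) {
      if (sub$l[r] == 0) nh <- nh + 1
      tu <- tu + sub$l[r] * sub$recip_dds_norm[r] * sub$monthly_sales[r]
      hi <- hi + sub$dds_norm[r] * sub$monthly_sales[r]
      uh <- uh + sub$recip_dds_norm[r] * sub$monthly_sales[r]
    }
    W <- nh / nrow(sub)
    out <- rbind(out, data.frame(
      outlet_id = id, W = W, TUHII = tu,
      HII = if (W == 1) hi else NA_real_,
      UHII = if (W < 1) uh else NA_real_,
      stringsAsFactors = FALSE))
  }
  out[order(out$outlet_id), ]
}

# modal level-2 code by brute-force count, smallest code on ties
modal_brute <- function(items) {
  tab <- table(items)
  cand <- names(tab)[tab == max(tab)]
  sort(cand)[1]
}

split_codes_test <- function(s) {
  p <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  p[nzchar(p)]
}

# attach only the healthy score (no DDS normalization needed)
score_meals_labels_only <- function(meals) {
  meals$l <- healthy_score(meals)
  meals
}

# random scored meal table for property tests
random_scored_meals <- function(n_outlets, meals_per_outlet = 5, seed = 1) {
  set.seed(seed)
  oid <- rep(sprintf("O%04d", seq_len(n_outlets)),
             each = meals_per_outlet)
  n <- length(oid)
  ddsv <- sample(1:12, n, replace = TRUE)
  data.frame(outlet_id = oid,
             l = sample(0:3, n, replace = TRUE),
             dds = ddsv,
             dds_norm = ddsv / max(ddsv),
             recip_dds_norm = (1 / ddsv) / max(1 / ddsv),
             monthly_sales = sample(0:500, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
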