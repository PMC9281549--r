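test_that("health weight is the healthy-meal fraction with its bounds", {
  expect_equal(health_weight(c(0, 0, 0)), 1)
  expect_equal(health_weight(c(1, 2, 3)), 0)
  expect_equal(health_weight(c(rep(0, 5), rep(1, 5))), 0.5)
  expect_error(health_weight(integer(0)), "no meals")
})

test_that("TUHII, HII and UHII match their hand-worked sums", {
  expect_equal(tuhii(l = 1, recip_dds_norm = 0.5, sales = 10), 5)
  expect_equal(tuhii(l = c(0, 0), recip_dds_norm = c(1, 1), sales = c(9, 9)), 0)
  expect_equal(tuhii(l = c(2, 1), recip_dds_norm = c(0.5, 1), sales = c(3, 4)), 7)
  expect_equal(hii(l = 0, dds_norm = 1, sales = 7), 7)
  expect_equal(hii(l = c(0, 0), dds_norm = c(0.5, 1), sales = c(0, 0)), 0)
  expect_equal(hii(l = c(0, 0), dds_norm = c(0.5, 1), sales = c(4, 2)), 4)
  # UHII sums over ALL meals, healthy included (no healthy-score factor)
  expect_equal(uhii(l = c(1, 0), recip_dds_norm = c(1, 0.5), sales = c(3, 2)), 4)
  expect_equal(uhii(l = 2, recip_dds_norm = 0.25, sales = 8), 2)
  expect_equal(uhii(l = 1, recip_dds_norm = 1, sales = 0), 0)
})

test_that("HII and UHII enforce their health-weight preconditions", {
  expect_error(hii(l = c(0, 1), dds_norm = c(1, 1), sales = c(1, 1)),
               "health weight 1")
  expect_error(uhii(l = c(0, 0), recip_dds_norm = c(1, 1), sales = c(1, 1)),
               "health weight < 1")
  expect_error(tuhii(l = 1, recip_dds_norm = NA, sales = 1), "normalization")
})

test_that("exactly one of HII/UHII is defined per outlet and totals add up", {
  meals <- random_scored_meals(60, 6, seed = 11)
  ind <- outlet_indicators(meals)
  expect_equal(nrow(ind), 60L)
  expect_true(all(xor(is.na(ind$HII), is.na(ind$UHII))))
  expect_equal(sum(ind$W == 1), sum(!is.na(ind$HII)))
  expect_equal(sum(ind$W == 1) + sum(ind$W < 1), nrow(ind))
})

test_that("aggregated indicators equal the per-meal brute-force loop", {
  meals <- random_scored_meals(150, 8, seed = 5)
  ind <- outlet_indicators(meals)
  ref <- indicators_brute(meals)
  expect_equal(ind$W, ref$W, tolerance = 1e-12)
  expect_equal(ind$TUHII, ref$TUHII, tolerance = 1e-12)
  expect_equal(ind$HII, ref$HII, tolerance = 1e-12)
  expect_equal(ind$UHII, ref$UHII, tolerance = 1e-12)
})

test_that("adding meals moves W and TUHII in the documented direction", {
  set.seed(21)
  for (rep in 1:20) {
    l <- sample(0:3, 10, replace = TRUE)
    r <- runif(10, 0.1, 1)
    s <- sample(1:100, 10, replace = TRUE)
    base_t <- tuhii(l, r, s)
    base_w <- health_weight(l)
    # unhealthy meal with positive sales: TUHII strictly up, W down
    # (strictly so whenever a healthy meal was present)
    expect_gt(tuhii(c(l, 2), c(r, 0.5), c(s, 10)), base_t)
    if (base_w > 0) expect_lt(health_weight(c(l, 2)), base_w)
    expect_lte(health_weight(c(l, 2)), base_w)
    # healthy meal: TUHII unchanged, W weakly up
    expect_equal(tuhii(c(l, 0), c(r, 0.5), c(s, 10)), base_t)
    expect_gte(health_weight(c(l, 0)), base_w)
  }
})

test_that("z-standardization has mean 0, sd 1 and is idempotent", {
  expect_equal(z_standardize(c(1, 3)), c(-1, 1) / sqrt(2))
  x <- rnorm(50, 10, 4)
  z <- z_standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(z_standardize(z), z, tolerance = 1e-12)
  expect_error(z_standardize(rep(2, 5)), "constant")
  expect_error(z_standardize(1), "at least two")
})

test_that("quartile labels follow the lower-closed label chain", {
  expect_equal(quartile_labels(c(0.1, 0.4, 0.6, 0.9), "W"),
               c("uH", "ruH", "rH", "H"))
  expect_equal(quartile_labels(c(1, 2, 3, 4), "indicator"),
               c("Q1", "Q2", "Q3", "Q4"))
  expect_warning(lab <- quartile_labels(rep(2, 6), "W"), "degenerate")
  expect_equal(lab, rep("H", 6))
  expect_error(quartile_labels(c(1, 2, 3), "W"), "four")
  # quantile boundaries themselves take the upper label (>= chain)
  x <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4)
  lab <- quartile_labels(x, "indicator")
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  expect_true(all(lab[x >= q[3]] == "Q4"))
  expect_true(all(lab[x < q[1]] == "Q1"))
})

test_that("standardize_indicators standardizes within the right groups", {
  meals <- random_scored_meals(80, 5, seed = 9)
  ind <- standardize_indicators(outlet_indicators(meals))
  expect_equal(mean(ind$z_TUHII), 0, tolerance = 1e-9)
  h <- !is.na(ind$z_HII)
  u <- !is.na(ind$z_UHII)
  if (sum(h) >= 2) expect_equal(mean(ind$z_HII[h]), 0, tolerance = 1e-9)
  expect_equal(mean(ind$z_UHII[u]), 0, tolerance = 1e-9)
  expect_true(all(ind$w_label %in% c("H", "rH", "ruH", "uH")))
  expect_true(all(ind$q_TUHII %in% c("Q1", "Q2", "Q3", "Q4")))
})

test_that("group-difference test gates ANOVA on Levene homoscedasticity", {
  # two identical groups: no between-group variance at equal spread
  g <- rep(c("a", "b"), each = 5)
  v <- rep(c(1, 2, 3, 4, 5), 2)
  res <- group_difference_test(v, g)
  expect_equal(res$anova_kind, "anova")
  expect_equal(res$F, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)

  set.seed(123)
  v2 <- c(rnorm(50, 0, 1), rnorm(50, 5, 1))
  g2 <- rep(c("a", "b"), each = 50)
  res2 <- group_difference_test(v2, g2)
  expect_lt(res2$p, 0.001)

  set.seed(124)
  v3 <- c(rnorm(50, 0, 1), rnorm(50, 0, 10))
  res3 <- group_difference_test(v3, g2)
  expect_equal(res3$anova_kind, "welch")

  # a singleton group is excluded with a warning, the rest still tested
  expect_warning(
    res4 <- group_difference_test(c(1, 2, 3, 4, 5, 6, 9),
                                  c("a", "a", "a", "b", "b", "b", "c")),
    "excluding"
  )
  expect_equal(res4$group_sizes, c(3L, 3L))
  expect_error(suppressWarnings(
    group_difference_test(c(1, 2, 9), c("a", "a", "b"))), "two groups")
})
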