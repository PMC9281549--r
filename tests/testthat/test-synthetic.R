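test_that("generator configs are validated", {
  expect_s3_class(default_paperlike_config(), "opfe_generator_config")
  expect_error(generator_config(type_mix = c(ST = 1)), "type_mix")
  bad_mix <- c(ST = 0.5, ND = 0.5, SET = 0.5, WFF = 0, HLR = 0, UN = 0)
  expect_error(generator_config(type_mix = bad_mix), "sum to 1")
  expect_error(generator_config(meals_range = c(5, 2)), "meals_range")
  expect_error(generator_config(flag_rate = 2), "rates")
  cfg <- default_paperlike_config()
  expect_equal(sum(cfg$type_mix), 1)
})

test_that("reference defaults imply the documented expectation orderings", {
  em <- expected_type_means(default_paperlike_config())
  el <- setNames(em$expected_l, em$type)
  ed <- setNames(em$expected_dds, em$type)
  expect_lt(el["HLR"], el["ND"])
  expect_lt(el["ND"], el["ST"])
  expect_lt(el["ST"], el["WFF"])
  expect_gt(ed["HLR"], ed["WFF"])
  expect_gt(ed["WFF"], ed["ND"])
  expect_gt(ed["ND"], ed["ST"])
})

test_that("generation is reproducible byte for byte given the seed", {
  a <- generate(default_paperlike_config(seed = 42, n_outlets = 40))
  b <- generate(default_paperlike_config(seed = 42, n_outlets = 40))
  expect_identical(a$meals, b$meals)
  expect_identical(a$outlets, b$outlets)
  fa <- tempfile(); fb <- tempfile()
  write_meal_table(a$meals, fa)
  write_meal_table(b$meals, fb)
  expect_identical(readLines(fa), readLines(fb))
  c <- generate(default_paperlike_config(seed = 43, n_outlets = 40))
  expect_false(identical(a$meals, c$meals))
})

test_that("generated tables satisfy the record invariants", {
  sim <- generate(default_paperlike_config(seed = 2, n_outlets = 60))
  m <- sim$meals
  expect_true(all(m$fried %in% 0:1))
  expect_true(all(m$monthly_sales >= 0))
  expect_true(all(vapply(m$food_groups,
                         function(s) length(split_codes_test(s)) >= 1,
                         logical(1))))
  expect_false(anyDuplicated(m$meal_id) > 0)
  expect_true(all(m$outlet_id %in% sim$outlets$outlet_id))
  # outlets lie inside the polygon grid
  pid <- assign_polygons(sim$outlets[, c("x", "y")], sim$polygons)
  expect_false(anyNA(pid))
})

test_that("zero unhealthy-label probabilities force all-healthy outlets", {
  cfg <- default_paperlike_config(seed = 5, n_outlets = 30)
  for (tp in names(cfg$meal_params)) {
    cfg$meal_params[[tp]][c("p_fried", "p_sugar", "p_salt")] <- list(0, 0, 0)
  }
  sim <- generate(cfg)
  meals <- score_meals_labels_only(sim$meals)
  W <- tapply(meals$l, meals$outlet_id, health_weight)
  expect_true(all(W == 1))
})

test_that("marginal label frequencies converge to the configured rates", {
  cfg <- default_paperlike_config(seed = 8, n_outlets = 450,
                                  healthy_outlet_rate = 0)
  for (tp in names(cfg$meal_params)) cfg$meal_params[[tp]]$p_fried <- 0.3
  sim <- generate(cfg)
  n <- nrow(sim$meals)
  expect_gt(n, 5000)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(sim$meals$fried) - 0.3), 3 * se)
})

test_that("a planted cluster shifts outlet types and sales inside one polygon", {
  cfg <- default_paperlike_config(
    seed = 13, n_outlets = 200,
    planted_cluster = list(polygon_id = "P7",
                           type_mix = c(ST = 0.5, ND = 0, SET = 0.5,
                                        WFF = 0, HLR = 0, UN = 0),
                           sales_mult = 8))
  sim <- generate(cfg)
  pid <- assign_polygons(sim$outlets[, c("x", "y")], sim$polygons)
  in_cl <- pid == "P7"
  expect_true(any(in_cl))
  expect_true(all(sim$outlets$type[in_cl] %in% c("ST", "SET")))
  sales_in <- sim$meals$monthly_sales[sim$meals$outlet_id %in%
                                        sim$outlets$outlet_id[in_cl]]
  sales_out <- sim$meals$monthly_sales[!sim$meals$outlet_id %in%
                                         sim$outlets$outlet_id[in_cl]]
  expect_gt(mean(sales_in), 3 * mean(sales_out))
})
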