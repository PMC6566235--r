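test_that("published worked examples reproduce", {
  # whole milk: lactose-only numerator diluted by fat and protein
  milk <- predict_gi(whole_milk())
  expect_equal(milk$gi_rounded, 26L)
  # with the worked-example ash coefficient of 0 the raw value is
  # 4.9*47 / (4.9 + 3.3*0.6 + 3.1*0.6); the bundled default (ash b = 0.1)
  # rounds to the same integer
  zero_ash <- set_b_coefficients(default_coefficients(), c(ashes = 0))
  expect_equal(predict_gi(whole_milk(), zero_ash)$gi_raw,
               4.9 * 47 / (4.9 + 3.3 * 0.6 + 3.1 * 0.6))
  expect_equal(predict_gi(whole_milk(), zero_ash)$gi_rounded, 26L)

  # 50 % glucose / 50 % protein
  gp <- predict_gi(composition(glucose = 50, protein = 50))
  expect_equal(gp$gi_raw, 62.5)
  expect_equal(gp$gi_rounded, 63L)

  # sugar/sugar-alcohol syrup: plain weighted mean, water neutral
  sy <- predict_gi(composition(glucose = 3, fructose = 2, maltitol = 5,
                               water = 90))
  expect_equal(sy$gi_raw, (3 * 100 + 2 * 20 + 5 * 35) / (3 + 2 + 5))
  expect_equal(sy$gi_raw, 51.5)
  expect_equal(round_gi(sy$gi_raw, "truncate"), 51L)

  expect_equal(predict_gi(composition(glucose = 100))$gi_raw, 100)
  expect_equal(predict_gi(composition(starch = 60, protein = 10,
                                      starch_availability = 0))$gi_raw, 0)
})

test_that("prediction result is internally consistent", {
  p <- predict_gi(test_cereal(serving_g = 30))
  expect_equal(p$gi_raw, p$numerator / p$denominator)
  expect_equal(p$glycemic_carb_per_serving_g, (11.8 + 61.2) * 30 / 100)
  expect_equal(p$gl_g, p$gi_raw * p$glycemic_carb_per_serving_g / 100)
  # no serving -> no GL
  expect_true(is.na(predict_gi(test_cereal())$gl_g))
})

test_that("pure sugar mixes equal the brute-force weighted mean", {
  gi_tab <- c(glucose = 100, fructose = 20, sucrose = 62, lactose = 47,
              maltose = 105, maltodextrin = 110)
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    nms <- sample(names(gi_tab), k)
    amt <- runif(k, 0.1, 50)
    p <- predict_gi(composition(setNames(amt, nms)))
    expect_equal(p$gi_raw, unname(weighted_mean_gi(amt, gi_tab[nms])),
                 tolerance = 1e-12)
  }
})

test_that("prediction is invariant to uniform rescaling of amounts", {
  set.seed(7)
  for (rep in 1:20) {
    comp <- random_composition(availability = runif(1, 0.5, 1))
    k <- runif(1, 0.01, 50)
    scaled <- composition(comp$amounts * k,
                          starch_availability = comp$starch_availability)
    expect_equal(predict_gi(comp)$gi_raw, predict_gi(scaled)$gi_raw,
                 tolerance = 1e-9)
  }
})

test_that("adding water changes neither GI nor GL", {
  comp <- test_cereal(serving_g = 30)
  watered <- composition(c(comp$amounts, water = 55),
                         starch_availability = 0.88, serving_g = 30)
  expect_equal(predict_gi(watered)$gi_raw, predict_gi(comp)$gi_raw)
  expect_equal(predict_gi(watered)$gl_g, predict_gi(comp)$gl_g)
})

test_that("GI decreases in lowering amounts and increases in availability", {
  base <- test_cereal(availability = 0.75)
  gi0 <- predict_gi(base)$gi_raw
  for (nm in c("fat", "protein", "fiber_sol", "fiber_ins")) {
    amt <- base$amounts
    amt[[nm]] <- amt[[nm]] + 5
    expect_lt(predict_gi(composition(amt, starch_availability = 0.75))$gi_raw,
              gi0)
  }
  # strictly monotone in availability
  gis <- sapply(seq(0, 1, by = 0.1),
                function(a) predict_gi(test_cereal(availability = a))$gi_raw)
  expect_true(all(diff(gis) > 0))
})

test_that("GI stays within availability-weighted coefficient bounds", {
  set.seed(99)
  tbl <- default_coefficients()
  for (rep in 1:25) {
    comp <- random_composition(availability = runif(1))
    p <- predict_gi(comp)
    expect_gte(p$gi_raw, 0)
    expect_lte(p$gi_raw, 110)
    idx <- match(names(comp$amounts), tbl$nutrient)
    gly <- tbl$role[idx] == "glycemic" & comp$amounts > 0
    a <- ifelse(names(comp$amounts) == "starch", comp$starch_availability, 1)
    expect_lte(p$gi_raw, max((a * tbl$gi[idx])[gly]) + 1e-12)
  }
})

test_that("error paths: no glycemic carbohydrate, unknown nutrient, opt-in inert", {
  expect_error(predict_gi(composition(fat = 10, protein = 5)),
               class = "glyco_no_glycemic_error")
  expect_error(predict_gi(composition(glucose = 0, fat = 10)),
               class = "glyco_no_glycemic_error")
  expect_error(predict_gi(composition(glucose = 10, polydextrose = 5)),
               class = "glyco_unknown_nutrient_error")
  expect_warning(
    p <- predict_gi(composition(glucose = 10, polydextrose = 5),
                    unknown = "inert"),
    "inert")
  expect_equal(p$gi_raw, 100)  # unknown treated as b = 0
})

test_that("starch availability resolution: override beats preset beats default", {
  comp <- composition(starch = 50, fat = 5)
  expect_equal(predict_gi(composition(starch = 50, fat = 5,
                                      starch_availability = 0.7),
                          process = "extruded")$starch_availability, 0.7)
  expect_equal(predict_gi(comp, process = "granola")$starch_availability,
               0.65)
  expect_warning(p <- predict_gi(comp), "defaulting to 1")
  expect_equal(p$starch_availability, 1)
  expect_error(predict_gi(comp, process = "boiled"), "preset")
})

test_that("glycemic load follows GI times carbohydrate per serving", {
  cer <- composition(sucrose = 11.8, starch = 61.2, fiber_sol = 2.4,
                     fiber_ins = 7.1, fat = 2.2, protein = 9.1)
  expect_equal(predict_gl(83, cer, 30), 83 * (11.8 + 61.2) * 0.30 / 100)
  expect_equal(round(predict_gl(83, cer, 30), 1), 18.2)
  expect_equal(predict_gl(0, cer, 30), 0)
  # milk: +1.65 g for a 125 g serving, +1.7 g for 125 mL (128.75 g)
  expect_equal(round(predict_gl(27, whole_milk(), 125), 2), 1.65)
  expect_equal(round(predict_gl(27, whole_milk(), whole_milk(125)$serving_g),
                     1), 1.7)
  expect_error(predict_gl(50, cer), "serving")
  # linear in serving size
  expect_equal(predict_gl(83, cer, 60), 2 * predict_gl(83, cer, 30))
  # availability does not weight the carbohydrate grams
  expect_equal(predict_gl(83, composition(c(cer$amounts),
                                          starch_availability = 0.5), 30),
               predict_gl(83, cer, 30))
})

test_that("sugar-alcohol mass can be excluded from the GL carbohydrate sum", {
  syrup <- composition(glucose = 3, fructose = 2, maltitol = 5, water = 90)
  expect_equal(predict_gl(50, syrup, 100), 50 * 10 / 100)
  expect_equal(predict_gl(50, syrup, 100, count_sugar_alcohols = FALSE),
               50 * 5 / 100)
  # the GI itself always keeps the sugar-alcohol contribution
  expect_equal(predict_gi(syrup, count_sugar_alcohols = FALSE)$gi_raw, 51.5)
})

test_that("meal model averages by carbohydrate mass", {
  expect_equal(fao_meal_gi(c(50, 0), c(88, 0)), 88)
  expect_equal(fao_meal_gi(25, 73), 73)
  expect_equal(fao_meal_gi(c(25, 25), c(100, 50)), 75)
  expect_error(fao_meal_gi(c(0, 0), c(88, 10)),
               class = "glyco_no_glycemic_error")
})

test_that("rounding is half-away-from-zero with a truncation mode", {
  expect_identical(round_gi(62.5), 63L)
  expect_identical(round_gi(26.0), 26L)
  expect_identical(round_gi(0.4), 0L)
  expect_identical(round_gi(c(51.5, 51.49), "truncate"), c(51L, 51L))
  expect_error(round_gi(-1))
})
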