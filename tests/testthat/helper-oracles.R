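# Independent brute-force oracle: plain carbohydrate-weighted mean GI of a
# sugar mix (no availability correction, no dilution). Used to cross-check
# predict_gi in the special case it must reduce to.
weighted_mean_gi <- function(amounts, gi_values) {
  stopifnot(length(amounts) == length(gi_values))
  num <- 0; den <- 0
  for (i in seq_along(amounts)) {
    num <- num + amounts[i] * gi_values[i]
    den <- den + amounts[i]
  }
  num / den
}

# a mid-complexity composition reused across property tests (P01-like)
test_cereal <- function(availability = 0.88, serving_g = NULL) {
  composition(sucrose = 11.8, starch = 61.2, fiber_sol = 2.4,
              fiber_ins = 7.1, fat = 2.2, protein = 9.1,
              starch_availability = availability, serving_g = serving_g)
}

# random composition over the main nutrients, for property loops
random_composition <- function(availability = NULL) {
  amt <- c(sucrose = runif(1, 0.5, 40), starch = runif(1, 5, 75),
           fiber_sol = runif(1, 0, 5), fiber_ins = runif(1, 0, 12),
           fat = runif(1, 0, 20), protein = runif(1, 0, 20),
           water = runif(1, 0, 10))
  composition(amt, starch_availability = availability)
}
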