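#' Process presets for starch availability
#'
#' Rapidly digestible starch fractions by manufacturing process. The anchor
#' values are 0.65 for granola and 0.88 for extruded products; the
#' intermediate processes are interpolated defaults and can be overridden.
#'
#' @return Named numeric vector of availability fractions.
#' @export
default_availability_presets <- function() {
  c(granola = 0.65, muesli = 0.70, bar = 0.75, flakes = 0.80,
    extruded = 0.88)
}

#' Predict the glycemic index of a product from its composition
#'
#' Computes the model GI as the availability-weighted mean GI of the
#' glycemic carbohydrates, diluted by the non-glycemic nutrients:
#' \deqn{GI = \frac{\sum_i x_i a_i GI_i}{\sum_i x_i + \sum_j x_j b_j}}
#' where the first sums run over glycemic nutrients (amount \eqn{x_i},
#' availability \eqn{a_i}, tabulated \eqn{GI_i}) and the second denominator
#' sum over the remaining nutrients with their GI-lowering coefficients
#' \eqn{b_j}. Availability is 1 for all glycemic carbohydrates except
#' starch, where it is the rapidly digestible starch fraction.
#'
#' Starch availability is resolved in this order: an explicit
#' `starch_availability` on the composition; the `process` preset; otherwise
#' 1 with a warning.
#'
#' The prediction is invariant to uniform rescaling of all amounts, so any
#' consistent amount basis works; g per 100 g is the convention.
#'
#' @param composition a [composition()].
#' @param coeffs a coefficient table; defaults to [default_coefficients()].
#' @param process optional process name matched against
#'   `availability_presets` (case-insensitive) to resolve starch
#'   availability.
#' @param availability_presets named availability fractions per process.
#' @param unknown `"error"` (default) to fail on nutrients absent from
#'   `coeffs`; `"inert"` to treat them as non-glycemic with `b = 0`, with a
#'   warning.
#' @param serving_g optional serving mass overriding the composition's; when
#'   either is available, glycemic load is computed too.
#' @param count_sugar_alcohols logical; if `FALSE`, sugar-alcohol mass is
#'   excluded from the glycemic-carbohydrate grams used for glycemic load
#'   (their contribution to GI itself is always kept).
#' @return A `glyco_prediction` with elements `gi_raw`, `gi_rounded`,
#'   `numerator`, `denominator`, `starch_availability` (resolved value or
#'   `NA` when no starch), `glycemic_carb_g_per_100g`,
#'   `glycemic_carb_per_serving_g` and `gl_g` (the latter two `NA` without a
#'   serving), and `warnings`.
#' @examples
#' # whole milk: lactose is the only glycemic carbohydrate
#' predict_gi(whole_milk())
#'
#' # an extruded cereal, 30 g serving
#' p <- composition(sucrose = 10.9, starch = 71, fiber_sol = 0.7,
#'                  fiber_ins = 2, fat = 2.1, protein = 6.9, serving_g = 30)
#' predict_gi(p, process = "extruded")
#' @export
predict_gi <- function(composition, coeffs = default_coefficients(),
                       process = NULL,
                       availability_presets = default_availability_presets(),
                       unknown = c("error", "inert"),
                       serving_g = NULL,
                       count_sugar_alcohols = TRUE) {
  stopifnot(inherits(composition, "glyco_composition"))
  unknown <- match.arg(unknown)
  warnings <- character(0)

  x <- composition$amounts
  idx <- match(names(x), coeffs$nutrient)
  if (anyNA(idx)) {
    missing <- names(x)[is.na(idx)]
    if (unknown == "error")
      stop_glyco("unknown_nutrient",
                 "unknown nutrient(s): ", paste(missing, collapse = ", "),
                 " (use unknown = \"inert\" to treat them as b = 0)")
    msg <- paste0("treating unknown nutrient(s) as inert: ",
                  paste(missing, collapse = ", "))
    warnings <- c(warnings, msg)
    warning(msg)
  }
  known <- !is.na(idx)
  role <- ifelse(known, coeffs$role[idx], "inert")
  gly <- role == "glycemic" & x > 0
  if (!any(role == "glycemic" & x > 0))
    stop_glyco("no_glycemic",
               "no glycemic carbohydrate with a positive amount")

  # availability: per-nutrient table value, starch resolved per product
  avail <- ifelse(known, coeffs$availability[idx], NA_real_)
  resolved_starch <- NA_real_
  has_starch <- any(names(x) == "starch" & x > 0)
  if (has_starch) {
    if (!is.null(composition$starch_availability)) {
      resolved_starch <- composition$starch_availability
    } else if (!is.null(process)) {
      p <- tolower(trimws(process))
      if (!p %in% names(availability_presets))
        stop("no availability preset for process '", process, "'")
      resolved_starch <- availability_presets[[p]]
    } else {
      resolved_starch <- 1
      warnings <- c(warnings,
                    "starch availability not specified; defaulting to 1")
      warning("starch availability not specified; defaulting to 1 ",
              "(set starch_availability or a process preset)")
    }
    avail[names(x) == "starch"] <- resolved_starch
  }

  gi_i <- ifelse(known, coeffs$gi[idx], NA_real_)
  b_j <- ifelse(known, coeffs$b[idx], 0)
  b_j[is.na(b_j)] <- 0                      # inert and unknown nutrients
  a_i <- ifelse(is.na(avail), 1, avail)

  numerator <- sum(x[gly] * a_i[gly] * gi_i[gly])
  denominator <- sum(x[gly]) + sum(x[!gly] * b_j[!gly])
  gi_raw <- numerator / denominator

  carb_mass_ok <- gly
  if (!count_sugar_alcohols) {
    sa <- ifelse(known, coeffs$sugar_alcohol[idx], FALSE)
    carb_mass_ok <- gly & !sa
  }
  carb100 <- sum(x[carb_mass_ok])

  serving <- if (!is.null(serving_g)) serving_g else composition$serving_g
  carb_serv <- if (is.null(serving)) NA_real_ else carb100 * serving / 100
  gl <- if (is.null(serving)) NA_real_ else gi_raw * carb_serv / 100

  structure(list(gi_raw = gi_raw,
                 gi_rounded = round_gi(gi_raw),
                 numerator = numerator,
                 denominator = denominator,
                 starch_availability = resolved_starch,
                 glycemic_carb_g_per_100g = carb100,
                 glycemic_carb_per_serving_g = carb_serv,
                 serving_g = if (is.null(serving)) NA_real_ else serving,
                 gl_g = gl,
                 warnings = warnings),
            class = "glyco_prediction")
}

#' @export
print.glyco_prediction <- function(x, ...) {
  cat(sprintf("Predicted GI: %.1f (rounded %d)\n", x$gi_raw, x$gi_rounded))
  if (!is.na(x$gl_g))
    cat(sprintf("Predicted GL: %.2f g glucose equivalent (%.1f g glycemic carbohydrate in a %.0f g serving)\n",
                x$gl_g, x$glycemic_carb_per_serving_g, x$serving_g))
  if (!is.na(x$starch_availability))
    cat(sprintf("Starch availability: %.2f\n", x$starch_availability))
  for (w in x$warnings) cat("note:", w, "\n")
  invisible(x)
}

#' Glycemic load of a serving
#'
#' \eqn{GL = GI \times \text{glycemic carbohydrate per serving (g)} / 100},
#' in grams of glucose equivalent. The carbohydrate mass is the unweighted
#' sum of glycemic-nutrient amounts in the serving — starch availability
#' affects GI, not the carbohydrate grams.
#'
#' @param gi glycemic index (a number or a `glyco_prediction`).
#' @param composition the product [composition()].
#' @param serving_g serving mass in grams; defaults to the composition's.
#' @param coeffs coefficient table used to identify glycemic nutrients.
#' @param count_sugar_alcohols see [predict_gi()].
#' @return Grams of glucose equivalent.
#' @examples
#' cereal <- composition(sucrose = 11.8, starch = 61.2, fat = 2.2,
#'                       protein = 9.1)
#' predict_gl(83, cereal, serving_g = 30)  # 18.2 g
#' @export
predict_gl <- function(gi, composition, serving_g = NULL,
                       coeffs = default_coefficients(),
                       count_sugar_alcohols = TRUE) {
  if (inherits(gi, "glyco_prediction")) gi <- gi$gi_raw
  stopifnot(is.numeric(gi), length(gi) == 1, gi >= 0,
            inherits(composition, "glyco_composition"))
  serving <- if (!is.null(serving_g)) serving_g else composition$serving_g
  if (is.null(serving))
    stop("a serving size (grams) is required for glycemic load")
  if (!is.finite(serving) || serving <= 0) stop("serving_g must be > 0")
  x <- composition$amounts
  idx <- match(names(x), coeffs$nutrient)
  gly <- !is.na(idx) & coeffs$role[idx] == "glycemic"
  if (!count_sugar_alcohols)
    gly <- gly & !coeffs$sugar_alcohol[idx]
  gi * sum(x[gly]) * serving / 100 / 100
}

#' Carbohydrate-weighted meal GI (classical meal model)
#'
#' The classical table-based meal model: the meal GI is the mean of the
#' component-food GIs weighted by their glycemic-carbohydrate grams,
#' \eqn{\sum c_i GI_i / \sum c_i}. It ignores the GI-lowering effect of
#' non-glycemic nutrients across components; [combine_compositions()] +
#' [predict_gi()] is the model that captures it.
#'
#' @param glycemic_carb_g grams of glycemic carbohydrate per food.
#' @param gi GI per food.
#' @return The meal GI.
#' @examples
#' fao_meal_gi(c(50, 0), c(88, 0))  # butter adds no carbs: GI stays 88
#' @export
fao_meal_gi <- function(glycemic_carb_g, gi) {
  stopifnot(length(glycemic_carb_g) == length(gi),
            length(gi) >= 1, all(is.finite(glycemic_carb_g)),
            all(glycemic_carb_g >= 0))
  if (sum(glycemic_carb_g) <= 0)
    stop_glyco("no_glycemic", "no food contributes glycemic carbohydrate")
  sum(glycemic_carb_g * gi) / sum(glycemic_carb_g)
}

#' Round a GI value for display
#'
#' Default is round-half-away-from-zero (62.5 becomes 63), matching how
#' integer GIs are conventionally reported; `"truncate"` discards the
#' fractional part instead.
#'
#' @param gi_raw non-negative GI value(s).
#' @param mode `"half_away"` or `"truncate"`.
#' @return Integer GI value(s).
#' @export
round_gi <- function(gi_raw, mode = c("half_away", "truncate")) {
  mode <- match.arg(mode)
  stopifnot(all(gi_raw >= 0))
  out <- switch(mode,
                half_away = sign(gi_raw) * floor(abs(gi_raw) + 0.5),
                truncate = trunc(gi_raw))
  as.integer(out)
}
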