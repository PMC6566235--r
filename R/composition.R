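#' Product composition
#'
#' A composition holds nutrient amounts in g per 100 g of product. Amounts
#' need not sum to 100: water and ash may simply be omitted (an omitted
#' nutrient counts as 0), and the GI model is invariant to uniform rescaling
#' of all amounts, so the 100 g basis is a convention, not a constraint.
#'
#' @param ... nutrient amounts as named arguments (`starch = 61.2, ...`), or
#'   a single named numeric vector / list.
#' @param starch_availability optional fraction in \[0, 1\]: the rapidly
#'   digestible fraction of the starch in this product. Leave unset to have
#'   prediction resolve it from a process preset or the default.
#' @param serving_g optional serving mass in grams; enables glycemic-load
#'   output.
#' @return A `glyco_composition` object.
#' @examples
#' composition(sucrose = 11.8, starch = 61.2, fiber_sol = 2.4,
#'             fiber_ins = 7.1, fat = 2.2, protein = 9.1,
#'             starch_availability = 0.88, serving_g = 30)
#' @export
composition <- function(..., starch_availability = NULL, serving_g = NULL) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) ||
      (length(dots) == 1L && (is.list(dots[[1]]) || length(dots[[1]]) > 1L) &&
       !is.null(names(dots[[1]])))) {
    amounts <- unlist(dots[[1]])
  } else {
    amounts <- unlist(dots)
  }
  if (is.null(names(amounts)) || any(!nzchar(names(amounts))))
    stop("all nutrient amounts must be named")
  amounts <- stats::setNames(as.numeric(amounts),
                             canonical_nutrient(names(amounts)))
  if (anyDuplicated(names(amounts))) {
    amounts <- tapply(amounts, names(amounts), sum)
    amounts <- stats::setNames(as.numeric(amounts), names(amounts))
  }
  if (any(!is.finite(amounts)) || any(amounts < 0))
    stop("nutrient amounts must be finite and >= 0")
  if (!is.null(starch_availability)) {
    stopifnot(is.numeric(starch_availability), length(starch_availability) == 1)
    if (is.na(starch_availability) ||
        starch_availability < 0 || starch_availability > 1)
      stop("starch_availability must lie in [0, 1]")
  }
  if (!is.null(serving_g)) {
    stopifnot(is.numeric(serving_g), length(serving_g) == 1)
    if (!is.finite(serving_g) || serving_g <= 0)
      stop("serving_g must be a positive mass in grams")
  }
  structure(list(amounts = amounts,
                 starch_availability = starch_availability,
                 serving_g = serving_g),
            class = "glyco_composition")
}

#' @export
print.glyco_composition <- function(x, ...) {
  cat("Composition (g per 100 g):\n")
  print(round(x$amounts, 3))
  if (!is.null(x$starch_availability))
    cat("starch availability:", x$starch_availability, "\n")
  if (!is.null(x$serving_g))
    cat("serving:", x$serving_g, "g\n")
  invisible(x)
}

#' Whole-milk reference composition
#'
#' Whole milk per 100 g: 88 g water, 4.9 g lactose, 3.3 g fat, 3.1 g protein
#' and 0.7 g minerals (ash). Used in the milk-on-cereal meal scenario.
#'
#' @param volume_ml optional volume; when given, the returned composition
#'   carries `serving_g = volume_ml * density_g_per_ml`.
#' @param density_g_per_ml milk density, default 1.03 g/mL.
#' @return A `glyco_composition`.
#' @export
whole_milk <- function(volume_ml = NULL, density_g_per_ml = 1.03) {
  serving <- if (!is.null(volume_ml)) volume_ml * density_g_per_ml
  composition(water = 88, lactose = 4.9, fat = 3.3, protein = 3.1,
              ashes = 0.7, serving_g = serving)
}

#' Pool several components into one meal composition
#'
#' Combines components by pooling their nutrient masses — the meal is treated
#' as a single product whose nutrients jointly enter the GI model, so the
#' non-glycemic nutrients of one component dilute the glycemic carbohydrates
#' of the others. This deliberately differs from carbohydrate-weighted
#' averaging of component GIs ([fao_meal_gi()]), which cannot capture that
#' cross-component dilution.
#'
#' The pooled starch availability is the starch-mass-weighted mean of the
#' component availabilities (components without starch do not contribute).
#' The serving of the result is the total meal mass.
#'
#' @param compositions list of `glyco_composition` objects.
#' @param mass_g numeric vector of component masses in grams (> 0), one per
#'   composition.
#' @return A `glyco_composition` for the pooled meal with
#'   `serving_g = sum(mass_g)`.
#' @examples
#' cereal <- composition(sucrose = 11.8, starch = 61.2, fat = 2.2,
#'                       protein = 9.1, starch_availability = 0.88)
#' combine_compositions(list(cereal, whole_milk()), c(30, 128.75))
#' @export
combine_compositions <- function(compositions, mass_g) {
  if (inherits(compositions, "glyco_composition"))
    compositions <- list(compositions)
  stopifnot(length(compositions) >= 1,
            length(mass_g) == length(compositions))
  if (any(!is.finite(mass_g)) || any(mass_g <= 0))
    stop("component masses must be finite and > 0")
  lapply(compositions, function(cc) {
    if (!inherits(cc, "glyco_composition"))
      stop("all components must be glyco_composition objects")
  })
  total <- sum(mass_g)
  pooled <- numeric(0)
  starch_mass <- 0
  avail_wsum <- 0
  avail_known <- TRUE
  for (k in seq_along(compositions)) {
    comp <- compositions[[k]]
    grams <- comp$amounts * mass_g[k] / 100  # nutrient grams in component k
    for (nm in names(grams))
      pooled[nm] <- (if (nm %in% names(pooled)) pooled[[nm]] else 0) + grams[[nm]]
    st <- if ("starch" %in% names(grams)) grams[["starch"]] else 0
    if (st > 0) {
      starch_mass <- starch_mass + st
      if (is.null(comp$starch_availability)) avail_known <- FALSE
      else avail_wsum <- avail_wsum + st * comp$starch_availability
    }
  }
  avail <- NULL
  if (starch_mass > 0) {
    if (avail_known) avail <- avail_wsum / starch_mass
    else if (avail_wsum > 0)
      warning("some starch-bearing components lack an availability; ",
              "pooled availability left unset")
  }
  composition(pooled / total * 100, starch_availability = avail,
              serving_g = total)
}

#' Read a composition from CSV or JSON
#'
#' Three dialects are accepted and auto-detected:
#' \itemize{
#'   \item long CSV with header `nutrient,amount_g_per_100g`;
#'   \item wide CSV with one row and nutrient-named columns (e.g. the
#'     benchmark headers `sucrose,starch,fiber_sol,fiber_ins,fat,protein`),
#'     optionally plus `starch_availability` and `serving_g` columns;
#'   \item JSON with an `amounts` object and optional `starch_availability`
#'     and `serving_g` fields.
#' }
#'
#' @param path file path.
#' @param format `"auto"` (default), `"long"`, `"wide"` or `"json"`.
#' @return A `glyco_composition`.
#' @export
read_composition <- function(path, format = c("auto", "long", "wide", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    obj <- jsonlite::fromJSON(path)
    amounts <- unlist(if (!is.null(obj$amounts)) obj$amounts else
      obj[setdiff(names(obj), c("starch_availability", "serving_g"))])
    return(composition(amounts,
                       starch_availability = obj$starch_availability,
                       serving_g = obj$serving_g))
  }
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  long <- all(c("nutrient", "amount_g_per_100g") %in% names(d))
  if (format == "long" && !long) stop("long-form CSV needs columns nutrient,amount_g_per_100g")
  if (long && format != "wide") {
    return(composition(stats::setNames(d$amount_g_per_100g, d$nutrient)))
  }
  if (nrow(d) != 1L)
    stop("wide-form composition CSV must contain exactly one data row")
  avail <- if ("starch_availability" %in% names(d)) d$starch_availability[1]
  serving <- if ("serving_g" %in% names(d)) d$serving_g[1]
  keep <- setdiff(names(d), c("starch_availability", "serving_g",
                              "product_id", "process"))
  composition(stats::setNames(as.numeric(d[1, keep]), keep),
              starch_availability = avail, serving_g = serving)
}
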