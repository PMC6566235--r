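#' Nutrient coefficient tables
#'
#' The model distinguishes three nutrient roles. *Glycemic* nutrients
#' (sugars, glycemic polysaccharides and partially glycemic sugar alcohols)
#' carry a tabulated glycemic index `gi` and an availability factor
#' `availability` (1 for everything except starch, whose availability is the
#' rapidly-digestible-starch fraction and is resolved per product).
#' *Lowering* nutrients (fat, protein, fibers, ashes) carry a dimensionless
#' GI-lowering coefficient `b` that dilutes the denominator of the GI
#' prediction. *Inert* nutrients (water) behave as lowering nutrients with
#' `b = 0`.
#'
#' A coefficient table is a data frame with one row per nutrient and columns
#' `nutrient`, `role`, `gi`, `availability`, `b`, `sugar_alcohol`.
#'
#' @param nutrient character vector of canonical nutrient names.
#' @param role one of `"glycemic"`, `"lowering"`, `"inert"` per nutrient.
#' @param gi glycemic index in \[0, 110\] for glycemic nutrients, `NA`
#'   otherwise.
#' @param availability default availability fraction in \[0, 1\] for glycemic
#'   nutrients (`NA` otherwise). Starch has `NA` here: it must be resolved
#'   per product (explicit value, process preset, or default 1 with a
#'   warning).
#' @param b GI-lowering coefficient (>= 0) for lowering nutrients, `NA`
#'   otherwise.
#' @param sugar_alcohol logical; marks partially glycemic sugar alcohols
#'   whose mass can optionally be excluded from the glycemic-load
#'   carbohydrate sum.
#' @return A `glyco_coeffs` data frame.
#' @seealso [default_coefficients()], [read_coefficients()]
#' @export
coefficient_table <- function(nutrient, role, gi = NA_real_,
                              availability = NA_real_, b = NA_real_,
                              sugar_alcohol = FALSE) {
  tbl <- data.frame(
    nutrient = canonical_nutrient(nutrient),
    role = as.character(role),
    gi = as.numeric(gi),
    availability = as.numeric(availability),
    b = as.numeric(b),
    sugar_alcohol = as.logical(sugar_alcohol),
    stringsAsFactors = FALSE
  )
  validate_coefficients(tbl)
  class(tbl) <- c("glyco_coeffs", "data.frame")
  tbl
}

validate_coefficients <- function(tbl) {
  if (anyDuplicated(tbl$nutrient))
    stop("duplicate nutrient names after case-normalization: ",
         paste(tbl$nutrient[duplicated(tbl$nutrient)], collapse = ", "))
  ok_role <- tbl$role %in% c("glycemic", "lowering", "inert")
  if (!all(ok_role))
    stop("unknown role(s): ", paste(unique(tbl$role[!ok_role]), collapse = ", "))
  g <- tbl$role == "glycemic"
  if (any(is.na(tbl$gi[g])))
    stop("glycemic nutrients require a gi value: ",
         paste(tbl$nutrient[g & is.na(tbl$gi)], collapse = ", "))
  if (any(tbl$gi[g] < 0 | tbl$gi[g] > 110, na.rm = TRUE))
    stop("gi values must lie in [0, 110]")
  if (any(!is.na(tbl$gi[!g])))
    stop("gi must be absent for non-glycemic nutrients")
  if (any(!is.na(tbl$b[g])))
    stop("b must be absent for glycemic nutrients")
  low <- tbl$role == "lowering"
  if (any(is.na(tbl$b[low])))
    stop("lowering nutrients require a b coefficient")
  if (any(tbl$b[low] < 0, na.rm = TRUE))
    stop("b coefficients must be >= 0")
  bad_a <- !is.na(tbl$availability) &
    (tbl$availability < 0 | tbl$availability > 1)
  if (any(bad_a)) stop("availability must lie in [0, 1]")
  invisible(tbl)
}

#' Default coefficient registry
#'
#' The bundled defaults: glucose 100, fructose 20, galactose 20, maltose 105,
#' trehalose 70, sucrose 62, lactose 47, isomaltulose 32, maltotriose 110,
#' maltotetraose 110, starch 110 (availability resolved per product),
#' maltodextrin 110, maltitol 35 and xylitol 12 for the glycemic
#' carbohydrates; GI-lowering coefficients 0.6 for beta-glucan, fat and
#' protein, 0.3 for soluble fiber, 0.1 for insoluble fiber and ashes, and 0
#' for water.
#'
#' @return A `glyco_coeffs` data frame.
#' @examples
#' default_coefficients()
#' @export
default_coefficients <- function() {
  g <- function(name, gi, avail = 1, sa = FALSE)
    list(name, "glycemic", gi, avail, NA_real_, sa)
  l <- function(name, b) list(name, "lowering", NA_real_, NA_real_, b, FALSE)
  rows <- list(
    g("glucose", 100), g("fructose", 20), g("galactose", 20),
    g("maltose", 105), g("trehalose", 70), g("sucrose", 62),
    g("lactose", 47), g("isomaltulose", 32),
    g("maltotriose", 110), g("maltotetraose", 110),
    g("starch", 110, avail = NA_real_), g("maltodextrin", 110),
    g("maltitol", 35, sa = TRUE), g("xylitol", 12, sa = TRUE),
    l("beta_glucan", 0.6), l("fiber_sol", 0.3), l("fiber_ins", 0.1),
    l("fat", 0.6), l("protein", 0.6), l("ashes", 0.1),
    list("water", "inert", NA_real_, NA_real_, NA_real_, FALSE)
  )
  col <- function(i) sapply(rows, `[[`, i)
  coefficient_table(col(1), col(2), as.numeric(col(3)), as.numeric(col(4)),
                    as.numeric(col(5)), as.logical(col(6)))
}

# Canonical lowercase names with field-usual aliases; the coefficient lookup
# is case- and punctuation-insensitive so CSV headers like "Fiber Sol." work.
canonical_nutrient <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("β", "beta", x)          # Greek beta
  x <- gsub("[ .\\-]+", "_", x)
  x <- gsub("_+$", "", x)
  x <- gsub("fibre", "fiber", x)
  aliases <- c(
    ash = "ashes", minerals = "ashes", mineral = "ashes",
    betaglucan = "beta_glucan", b_glucan = "beta_glucan",
    fiber_soluble = "fiber_sol", soluble_fiber = "fiber_sol",
    fiber_sol = "fiber_sol",
    fiber_insoluble = "fiber_ins", insoluble_fiber = "fiber_ins",
    fiber_ins = "fiber_ins",
    proteins = "protein", fats = "fat", lipids = "fat", lipid = "fat"
  )
  hit <- match(x, names(aliases))
  x[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  x
}

#' @export
print.glyco_coeffs <- function(x, ...) {
  cat("Nutrient coefficient table (", nrow(x), " nutrients)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Read or write a coefficient table as JSON
#'
#' The JSON layout is a list of records with fields `nutrient`, `role` and,
#' per role, `gi`/`availability` or `b`; it is the same layout
#' [cmd_calibrate()] emits, so a calibration output can be fed straight back
#' in as a coefficient file.
#'
#' @param path file path.
#' @return `read_coefficients()` returns a `glyco_coeffs` table;
#'   `write_coefficients()` returns `path` invisibly.
#' @export
read_coefficients <- function(path) {
  rec <- jsonlite::fromJSON(path)
  if (is.list(rec) && !is.data.frame(rec) && !is.null(rec$nutrients))
    rec <- rec$nutrients
  rec <- as.data.frame(rec)
  for (col in c("gi", "availability", "b"))
    if (is.null(rec[[col]])) rec[[col]] <- NA_real_
  if (is.null(rec$sugar_alcohol)) rec$sugar_alcohol <- FALSE
  rec$sugar_alcohol[is.na(rec$sugar_alcohol)] <- FALSE
  coefficient_table(rec$nutrient, rec$role, rec$gi, rec$availability,
                    rec$b, rec$sugar_alcohol)
}

#' @rdname read_coefficients
#' @param coeffs a `glyco_coeffs` table.
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "glyco_coeffs"))
  jsonlite::write_json(as.data.frame(coeffs), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Replace GI-lowering coefficients in a table
#'
#' Convenience for plugging calibrated `b` values into a registry.
#'
#' @param coeffs a `glyco_coeffs` table.
#' @param b named numeric vector of new coefficients for lowering nutrients.
#' @return The updated table.
#' @export
set_b_coefficients <- function(coeffs, b) {
  nm <- canonical_nutrient(names(b))
  idx <- match(nm, coeffs$nutrient)
  if (anyNA(idx))
    stop_glyco("unknown_nutrient", "unknown nutrient(s): ",
               paste(nm[is.na(idx)], collapse = ", "))
  if (any(coeffs$role[idx] == "glycemic"))
    stop("b coefficients apply only to non-glycemic nutrients")
  coeffs$b[idx] <- as.numeric(b)
  coeffs$role[idx] <- "lowering"
  validate_coefficients(coeffs)
  coeffs
}

# classed conditions so callers can distinguish error families
stop_glyco <- function(class, ...) {
  stop(errorCondition(paste0(...),
                      class = c(paste0("glyco_", class, "_error"),
                                "glyco_error", "error", "condition")))
}
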