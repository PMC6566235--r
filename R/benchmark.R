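#' The 42-breakfast-cereal benchmark
#'
#' Loads the bundled benchmark of 42 breakfast cereals: process type,
#' composition (sucrose, starch, soluble and insoluble fiber, fat, protein
#' in g per 100 g), observed and predicted GI, and observed and predicted GL
#' for a 30 g serving. Products are sorted by descending observed GI
#' (P01-P42).
#'
#' The bundled CSV carries a recorded md5 digest; a mismatch (a corrupted or
#' edited fixture) raises an error unless `check = FALSE`.
#'
#' @param check verify the fixture digest (default `TRUE`).
#' @return A data frame with 42 rows and columns `product_id`, `process`,
#'   `sucrose`, `starch`, `fiber_sol`, `fiber_ins`, `fat`, `protein`,
#'   `gi_obs`, `gi_pred`, `gl_obs`, `gl_pred`.
#' @examples
#' b <- load_benchmark()
#' nrow(b)  # 42
#' @export
load_benchmark <- function(check = TRUE) {
  path <- system.file("extdata", "benchmark_table1.csv", package = "glyco",
                      mustWork = TRUE)
  if (check) {
    digest <- unname(tools::md5sum(path))
    if (!identical(digest, "5c193ffea3b238ec97bb702ef31990fe"))
      stop("benchmark fixture digest mismatch (file corrupted?): ", digest)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(d) == 42)
  d
}

#' Composition of one benchmark product
#'
#' @param record a single row of [load_benchmark()] (or a one-row data frame
#'   with the same nutrient columns).
#' @param starch_availability optional availability override; by default
#'   left unset so prediction resolves it from the process preset.
#' @param serving_g serving mass, default 30 g.
#' @return A [composition()].
#' @export
benchmark_composition <- function(record, starch_availability = NULL,
                                  serving_g = 30) {
  stopifnot(nrow(record) == 1)
  composition(sucrose = record$sucrose, starch = record$starch,
              fiber_sol = record$fiber_sol, fiber_ins = record$fiber_ins,
              fat = record$fat, protein = record$protein,
              starch_availability = starch_availability,
              serving_g = serving_g)
}

#' Benchmark composition ranges
#'
#' Per-nutrient min/max over the 42 benchmark cereals; usable as
#' `composition_ranges` for [generate_panel()] when a cereal-like panel is
#' wanted instead of the heterogeneous default.
#'
#' @return Named list of `c(min, max)` in g per 100 g.
#' @export
benchmark_ranges <- function() {
  list(sucrose = c(0.7, 30.0), starch = c(33.4, 74.7),
       fiber_sol = c(0.7, 3.2), fiber_ins = c(2.0, 9.7),
       fat = c(1.2, 13.7), protein = c(4.9, 14.4))
}
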