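#' Synthetic calibration panels
#'
#' Generates a panel of synthetic products with known ("true") GI-lowering
#' coefficients, for calibration and recovery studies. Each product's
#' composition is drawn uniformly and independently per nutrient within the
#' given bounds, its starch availability uniformly within
#' `availability_range`; the true GI follows from [predict_gi()] under
#' `b_true`, and the observed GI adds Gaussian noise with SD `noise_sd`
#' (3.5 GI points by default, the typical standard error of in-vivo GI
#' measurements).
#'
#' The default composition ranges emulate a heterogeneous calibration set
#' spanning product categories from high-starch cereals to sugar-rich bars
#' and dairy-style recipes (sucrose 0-60, starch 0-75, lactose 0-10,
#' soluble fiber 0-8, insoluble fiber 0-15, fat 0-30, protein 0-25 g/100 g);
#' amounts are not renormalised to 100 g since the model is scale-invariant
#' and water absorbs the remainder. Products that would draw no glycemic
#' carbohydrate get a floor of 1 g starch.
#'
#' @param n_products number of synthetic products (must exceed the number of
#'   lowering nutrients in the ranges).
#' @param b_true named vector of true GI-lowering coefficients; defaults to
#'   the bundled registry values for the lowering nutrients present in
#'   `composition_ranges`.
#' @param noise_sd SD of the additive GI noise, in GI points.
#' @param seed integer seed; identical seeds give identical panels.
#' @param composition_ranges named list of `c(min, max)` bounds in g/100 g.
#' @param availability_range bounds for the uniform starch-availability draw.
#' @param coeffs coefficient table supplying the glycemic GI values.
#' @return A `glyco_panel`: list with `data` (a data frame of nutrient
#'   amounts, `starch_availability`, `gi_true`, `gi_noisy`), `b_true`,
#'   `noise_sd` and `seed`.
#' @examples
#' p <- generate_panel(10, noise_sd = 0, seed = 7)
#' all(p$data$gi_true == p$data$gi_noisy)
#' @export
generate_panel <- function(n_products = 60,
                           b_true = NULL,
                           noise_sd = 3.5,
                           seed = 1,
                           composition_ranges = default_panel_ranges(),
                           availability_range = c(0.65, 0.88),
                           coeffs = default_coefficients()) {
  stopifnot(n_products >= 1, noise_sd >= 0,
            length(availability_range) == 2,
            availability_range[1] <= availability_range[2])
  bad <- vapply(composition_ranges,
                function(r) length(r) != 2 || r[1] > r[2] || r[1] < 0,
                logical(1))
  if (any(bad))
    stop("degenerate composition bounds for: ",
         paste(names(composition_ranges)[bad], collapse = ", "))

  nutrients <- canonical_nutrient(names(composition_ranges))
  names(composition_ranges) <- nutrients
  idx <- match(nutrients, coeffs$nutrient)
  if (anyNA(idx))
    stop_glyco("unknown_nutrient", "unknown nutrient(s) in ranges: ",
               paste(nutrients[is.na(idx)], collapse = ", "))
  lowering <- nutrients[coeffs$role[idx] != "glycemic"]
  glycemic <- setdiff(nutrients, lowering)
  if (length(glycemic) == 0)
    stop("composition_ranges must include at least one glycemic nutrient")
  if (n_products < length(lowering) + 1)
    stop("n_products must be at least the number of lowering nutrients + 1")

  if (is.null(b_true)) {
    b_true <- stats::setNames(coeffs$b[match(lowering, coeffs$nutrient)],
                              lowering)
    b_true[is.na(b_true)] <- 0
  } else {
    names(b_true) <- canonical_nutrient(names(b_true))
    if (!setequal(names(b_true), lowering))
      stop("b_true names must match the lowering nutrients in the ranges")
    b_true <- b_true[lowering]
  }
  work <- set_b_coefficients(coeffs, b_true)

  # draw reproducibly without disturbing the caller's RNG stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  X <- vapply(nutrients,
              function(nm) stats::runif(n_products,
                                        composition_ranges[[nm]][1],
                                        composition_ranges[[nm]][2]),
              numeric(n_products))
  X <- matrix(X, nrow = n_products,
              dimnames = list(NULL, nutrients))
  # guarantee a glycemic floor so every product has a defined GI
  gly_sum <- rowSums(X[, glycemic, drop = FALSE])
  if (any(gly_sum < 1)) {
    anchor <- if ("starch" %in% glycemic) "starch" else glycemic[1]
    X[gly_sum < 1, anchor] <- X[gly_sum < 1, anchor] + 1
  }
  avail <- stats::runif(n_products, availability_range[1],
                        availability_range[2])

  gi_true <- vapply(seq_len(n_products), function(i) {
    comp <- composition(stats::setNames(X[i, ], nutrients),
                        starch_availability = if ("starch" %in% nutrients)
                          avail[i])
    predict_gi(comp, coeffs = work)$gi_raw
  }, numeric(1))
  gi_noisy <- gi_true + stats::rnorm(n_products, 0, noise_sd)

  data <- data.frame(X, check.names = FALSE)
  data$starch_availability <- if ("starch" %in% nutrients) avail else NA_real_
  data$gi_true <- gi_true
  data$gi_noisy <- gi_noisy
  structure(list(data = data, b_true = b_true, noise_sd = noise_sd,
                 seed = as.integer(seed), nutrients = nutrients,
                 lowering = lowering, glycemic = glycemic),
            class = "glyco_panel")
}

#' @rdname generate_panel
#' @export
default_panel_ranges <- function() {
  list(sucrose = c(0, 60), starch = c(0, 75), lactose = c(0, 10),
       fiber_sol = c(0, 8), fiber_ins = c(0, 15),
       fat = c(0, 30), protein = c(0, 25))
}

#' @export
print.glyco_panel <- function(x, ...) {
  cat("Synthetic panel:", nrow(x$data), "products, noise SD",
      x$noise_sd, "GI points, seed", x$seed, "\n")
  cat("true b:", paste(names(x$b_true), "=", x$b_true, collapse = ", "), "\n")
  invisible(x)
}
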