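#' Calibrate GI-lowering coefficients from observed GI data
#'
#' Estimates the coefficients `b_j` of the GI-lowering nutrients by least
#' squares on the exact linearization of the prediction model. Writing
#' \eqn{N_p} for the glycemic numerator \eqn{\sum_i x_{pi} a_{pi} GI_i} of
#' product `p`, the model \eqn{GI_p = N_p / (\sum_i x_{pi} + \sum_j x_{pj}
#' b_j)} rearranges to
#' \deqn{N_p / GI_p - \sum_i x_{pi} = \sum_j x_{pj} b_j,}
#' a linear regression through the origin of the response on the lowering
#' nutrient amounts. Nutrients not being fitted keep their table `b` and are
#' subtracted from the response.
#'
#' Because measurement noise sits on `GI_p`, the linearized response has
#' variance approximately \eqn{(N_p / GI_p^2)^2 \sigma^2}; the default
#' variance-stabilizing weights \eqn{(GI_p^2 / N_p)^2} undo that
#' heteroscedasticity. `weights = "none"` gives the plain unweighted fit,
#' and `method = "nonlinear"` refits by least squares on GI itself
#' (Gauss-Newton via [stats::optim()] from the linearized solution); all
#' variants coincide on noiseless data.
#'
#' Estimates are reported unconstrained: a negative estimate is flagged with
#' a warning, never clipped, so diagnostics stay honest.
#'
#' @param data a `glyco_panel`, or a data frame with one column per nutrient
#'   (g/100 g), an observed-GI column (`gi_observed`, or `gi_noisy` from a
#'   panel), and — when starch is present — a `starch_availability` column.
#' @param coeffs coefficient table providing the glycemic GI/availability
#'   values and the fixed `b` of nutrients not being fitted.
#' @param nutrients_to_fit names of the lowering nutrients to estimate;
#'   default: every non-glycemic nutrient present with a positive amount.
#' @param method `"linearized"` (default) or `"nonlinear"`.
#' @param weights `"variance_stabilizing"` (default) or `"none"`; ignored by
#'   the nonlinear method.
#' @return A `glyco_calibration`: `b_estimates`, `standard_errors`,
#'   `residual_sd` (SD of observed-minus-refitted GI, in GI points),
#'   `n_products`, `method`, `warnings`.
#' @examples
#' panel <- generate_panel(30, noise_sd = 0, seed = 11)
#' calibrate_b(panel)  # recovers the true coefficients exactly
#' @export
calibrate_b <- function(data, coeffs = default_coefficients(),
                        nutrients_to_fit = NULL,
                        method = c("linearized", "nonlinear"),
                        weights = c("variance_stabilizing", "none")) {
  method <- match.arg(method)
  weights <- match.arg(weights)
  if (inherits(data, "glyco_panel")) data <- data$data
  data <- as.data.frame(data)

  gi_col <- intersect(c("gi_observed", "gi_obs", "gi_noisy"), names(data))
  if (length(gi_col) == 0)
    stop("data needs an observed-GI column (gi_observed / gi_noisy)")
  gi <- as.numeric(data[[gi_col[1]]])
  if (any(!is.finite(gi)) || any(gi <= 0))
    stop_glyco("invalid_observation",
               "observed GI must be finite and > 0 for the linearization")

  reserved <- c(gi_col, "starch_availability", "gi_true", "product_id",
                "process")
  nut_cols <- setdiff(names(data), reserved)
  nut_canon <- canonical_nutrient(nut_cols)
  idx <- match(nut_canon, coeffs$nutrient)
  if (anyNA(idx))
    stop_glyco("unknown_nutrient", "unknown nutrient column(s): ",
               paste(nut_cols[is.na(idx)], collapse = ", "))
  X <- as.matrix(data[, nut_cols, drop = FALSE])
  colnames(X) <- nut_canon
  if (any(!is.finite(X)) || any(X < 0))
    stop("nutrient amounts must be finite and >= 0")
  role <- coeffs$role[idx]
  glycemic <- nut_canon[role == "glycemic"]
  lowering <- nut_canon[role != "glycemic"]

  if (is.null(nutrients_to_fit)) {
    present <- colSums(X[, lowering, drop = FALSE]) > 0
    nutrients_to_fit <- lowering[present]
  } else {
    nutrients_to_fit <- canonical_nutrient(nutrients_to_fit)
    if (!all(nutrients_to_fit %in% lowering))
      stop("nutrients_to_fit must be non-glycemic nutrient columns; got: ",
           paste(setdiff(nutrients_to_fit, lowering), collapse = ", "))
  }
  p <- length(nutrients_to_fit)
  n <- nrow(X)
  if (p == 0) stop("no lowering nutrients to fit")
  if (n < p + 1)
    stop("need at least ", p + 1, " products to fit ", p, " coefficients")

  # glycemic numerator N_p with per-product starch availability
  avail_tab <- coeffs$availability[idx]
  a <- matrix(rep(ifelse(is.na(avail_tab), 1, avail_tab), each = n), nrow = n)
  colnames(a) <- nut_canon
  if ("starch" %in% glycemic && any(X[, "starch"] > 0)) {
    if (!"starch_availability" %in% names(data) ||
        anyNA(data$starch_availability))
      stop("starch is present: every product needs a resolved ",
           "starch_availability")
    a[, "starch"] <- data$starch_availability
  }
  gi_i <- coeffs$gi[idx]
  N <- as.vector((X[, glycemic, drop = FALSE] *
                    a[, glycemic, drop = FALSE]) %*% gi_i[role == "glycemic"])
  S <- rowSums(X[, glycemic, drop = FALSE])

  fixed <- setdiff(lowering, nutrients_to_fit)
  b_fixed <- coeffs$b[match(fixed, coeffs$nutrient)]
  b_fixed[is.na(b_fixed)] <- 0
  offset <- if (length(fixed))
    as.vector(X[, fixed, drop = FALSE] %*% b_fixed) else 0

  D <- X[, nutrients_to_fit, drop = FALSE]
  # rank check on the scaled design (relative singular-value tolerance)
  sv <- svd(scale(D, center = FALSE, scale = apply(D, 2, function(c)
    max(abs(c), 1e-300))))$d
  if (min(sv) < 1e-10 * max(sv)) {
    qr_d <- qr(D)
    aliased <- colnames(D)[qr_d$pivot[-seq_len(qr_d$rank)]]
    stop_glyco("collinearity",
               "design is rank deficient; aliased nutrient(s): ",
               paste(aliased, collapse = ", "))
  }

  r <- N / gi - S - offset
  w <- if (weights == "variance_stabilizing") (gi^2 / N)^2 else rep(1, n)
  fit <- stats::lm.wfit(D, r, w)
  b_hat <- fit$coefficients

  if (method == "nonlinear") {
    rss <- function(b) {
      den <- S + offset + as.vector(D %*% b)
      sum((gi - N / den)^2)
    }
    opt <- stats::optim(b_hat, rss, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    b_hat <- opt$par
  }

  # residuals and SEs in GI space
  den_hat <- S + offset + as.vector(D %*% b_hat)
  gi_hat <- N / den_hat
  dfree <- n - p
  residual_sd <- sqrt(sum((gi - gi_hat)^2) / dfree)
  # delta-method SEs from the GI-space Jacobian J = d gi_hat / d b
  J <- -(gi_hat / den_hat) * D
  XtX <- crossprod(J)
  se <- sqrt(diag(solve(XtX)) * residual_sd^2)
  names(b_hat) <- names(se) <- nutrients_to_fit

  warn <- character(0)
  if (any(b_hat < 0)) {
    warn <- paste0("negative coefficient estimate(s): ",
                   paste(nutrients_to_fit[b_hat < 0], collapse = ", "))
    warning(warn)
  }
  structure(list(b_estimates = b_hat, standard_errors = se,
                 residual_sd = residual_sd, n_products = n,
                 method = method, weights = weights, warnings = warn),
            class = "glyco_calibration")
}

#' @export
print.glyco_calibration <- function(x, ...) {
  cat("GI-lowering coefficient calibration (", x$method, ", n = ",
      x$n_products, ")\n", sep = "")
  print(data.frame(estimate = round(x$b_estimates, 4),
                   std_error = round(x$standard_errors, 4)))
  cat("residual SD:", round(x$residual_sd, 3), "GI points\n")
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Back-solve starch availability from a target GI
#'
#' Inverts the GI model for the availability factor of starch: with
#' denominator `D` (which does not involve availability) and the non-starch
#' glycemic contribution `G`, the availability solving
#' \eqn{GI = (G + x_{starch} \, a \, 110) / D} is
#' \deqn{a = (GI \times D - G) / (110 \, x_{starch}).}
#' The result is returned even when it falls outside \[0, 1\] (with a
#' warning), since an out-of-range solution is itself diagnostic — it means
#' no rapidly-digestible-starch fraction can reconcile the composition with
#' the target GI.
#'
#' @param composition a [composition()] containing starch.
#' @param gi_target the GI the model should reproduce (> 0, or 0 when
#'   starch is the only glycemic carbohydrate).
#' @param coeffs coefficient table.
#' @return The availability fraction.
#' @examples
#' p <- composition(sucrose = 10.9, starch = 71, fiber_sol = 0.7,
#'                  fiber_ins = 2, fat = 2.1, protein = 6.9)
#' solve_starch_availability(p, 82)
#' @export
solve_starch_availability <- function(composition, gi_target,
                                      coeffs = default_coefficients()) {
  stopifnot(inherits(composition, "glyco_composition"),
            is.numeric(gi_target), length(gi_target) == 1, gi_target >= 0)
  x <- composition$amounts
  if (!"starch" %in% names(x) || x[["starch"]] <= 0)
    stop("composition has no starch to solve for")
  idx <- match(names(x), coeffs$nutrient)
  if (anyNA(idx))
    stop_glyco("unknown_nutrient", "unknown nutrient(s): ",
               paste(names(x)[is.na(idx)], collapse = ", "))
  role <- coeffs$role[idx]
  gly <- role == "glycemic"
  b <- coeffs$b[idx]; b[is.na(b)] <- 0
  D <- sum(x[gly]) + sum(x[!gly] * b[!gly])
  non_starch <- gly & names(x) != "starch"
  G <- sum(x[non_starch] * coeffs$gi[idx][non_starch])
  gi_starch <- coeffs$gi[match("starch", coeffs$nutrient)]
  a <- (gi_target * D - G) / (x[["starch"]] * gi_starch)
  if (a < 0 || a > 1)
    warning(sprintf("solved availability %.3f lies outside [0, 1]", a))
  unname(a)
}
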