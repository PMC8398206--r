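# Signed errors against references and their MAE aggregations. The signed
# error deliberately keeps its sign (no modulus) so under- vs
# overestimation remains visible; only the MAE summaries take |.|.

#' Signed error of a calculated property against its reference
#'
#' `epsilon = value - reference`, sign preserved. If both unit labels are
#' supplied they must agree.
#'
#' @param x calculated property value.
#' @param x_ref reference value in the same units.
#' @param units,units_ref optional unit labels; a declared mismatch is an
#'   error.
#' @return signed error in the property's units.
#' @export
#' @examples
#' relative_error(82.4, 82.0) # 0.4
#' relative_error(76.9, 83.2) # -6.3
relative_error <- function(x, x_ref, units = NULL, units_ref = NULL) {
  if (!is.null(units) && !is.null(units_ref) && !identical(units, units_ref)) {
    stop("unit mismatch: value in ", units, ", reference in ", units_ref, call. = FALSE)
  }
  stop_if_not_finite(x, x_ref, what = "property value")
  x - x_ref
}

check_error_table <- function(errors) {
  stopifnot(is.data.frame(errors))
  needed <- c("functional", "basis", "epsilon")
  missing <- setdiff(needed, names(errors))
  if (length(missing)) {
    stop("error table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(errors)
}

subset_property <- function(errors, property) {
  if (!is.null(property)) {
    if (!"property" %in% names(errors)) stop("error table has no 'property' column", call. = FALSE)
    errors <- errors[errors$property == property, , drop = FALSE]
  }
  errors
}

#' Mean absolute error of one functional across basis sets
#'
#' Averages `|epsilon|` over every basis set present for the functional;
#' combinations absent from the table are simply skipped (their count is
#' visible through `attr(, "n")`).
#'
#' @param errors data.frame with columns `functional`, `basis`, `epsilon`
#'   (and optionally `property`).
#' @param functional functional name (normalization-tolerant).
#' @param property optional property filter when the table is stacked.
#' @return MAE, with attribute `n` = number of records averaged.
#' @export
mae_by_functional <- function(errors, functional, property = NULL) {
  check_error_table(errors)
  errors <- subset_property(errors, property)
  sel <- normalize_name(errors$functional) == normalize_name(functional)
  if (!any(sel)) stop("no error records for functional '", functional, "'", call. = FALSE)
  structure(mean(abs(errors$epsilon[sel])), n = sum(sel))
}

#' Mean absolute error of one basis set across functionals
#'
#' Mirror of [mae_by_functional()] over the other catalog axis.
#'
#' @inheritParams mae_by_functional
#' @param basis basis-set name.
#' @return MAE, with attribute `n`.
#' @export
mae_by_basis <- function(errors, basis, property = NULL) {
  check_error_table(errors)
  errors <- subset_property(errors, property)
  sel <- normalize_name(errors$basis) == normalize_name(basis)
  if (!any(sel)) stop("no error records for basis set '", basis, "'", call. = FALSE)
  structure(mean(abs(errors$epsilon[sel])), n = sum(sel))
}

#' MAE table over one catalog axis for every property
#'
#' @param errors stacked error table (`functional`, `basis`, `property`,
#'   `epsilon`).
#' @param by `"functional"` or `"basis"`.
#' @return data.frame: axis value, `property`, `mae`, `n`.
#' @export
mae_table <- function(errors, by = c("functional", "basis")) {
  by <- match.arg(by)
  check_error_table(errors)
  agg <- stats::aggregate(abs(errors$epsilon),
                          by = list(key = errors[[by]], property = errors$property),
                          FUN = mean)
  n <- stats::aggregate(errors$epsilon,
                        by = list(key = errors[[by]], property = errors$property),
                        FUN = length)
  out <- data.frame(agg$key, property = agg$property, mae = agg$x, n = n$x)
  names(out)[1] <- by
  out[order(out$property, out[[by]]), , drop = FALSE]
}

#' Validation statistics for calculated-vs-experimental pairs
#'
#' Per-item signed differences `delta = calc - exp`, their mean absolute
#' error and root-mean-square error. Full precision is retained internally;
#' the print method rounds half-up to one decimal, the display convention
#' of benchmark tables.
#'
#' @param calc,exp numeric vectors of equal length (same units).
#' @param labels optional item labels (e.g. compound names).
#' @return list of class `validation_stats`: `delta`, `mae`, `rmse`, `n`.
#' @export
#' @examples
#' v <- validation_stats(c(81.0, 92.6), c(83.0, 85.4))
#' v$mae # 4.6
validation_stats <- function(calc, exp, labels = NULL) {
  if (length(calc) == 0L) stop("empty validation set", call. = FALSE)
  stopifnot(length(calc) == length(exp))
  stop_if_not_finite(calc, exp, what = "validation value")
  delta <- calc - exp
  if (!is.null(labels)) names(delta) <- labels
  structure(list(delta = delta,
                 mae = mean(abs(delta)),
                 rmse = sqrt(mean(delta^2)),
                 n = length(delta)),
            class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat("Validation against experiment (n = ", x$n, ")\n", sep = "")
  if (!is.null(names(x$delta))) {
    for (i in seq_along(x$delta)) {
      cat(sprintf("  %-22s delta = %5.1f\n", names(x$delta)[i],
                  round_half_up(x$delta[i], 1)))
    }
  }
  cat(sprintf("  MAE:  %.1f\n  RMSE: %.1f\n",
              round_half_up(x$mae, 1), round_half_up(x$rmse, 1)))
  invisible(x)
}

#' Packaged flavonoid BDE validation set
#'
#' Eleven flavonoid/phenolic-acid O-H bond dissociation enthalpies
#' calculated at M06-2X/6-311G(d,p) alongside their gas-phase experimental
#' values (kcal/mol), used to validate the recommended level of theory on
#' structures outside the benchmark compound.
#'
#' @return data.frame: `substance`, `site`, `bde_calc`, `bde_exp`.
#' @export
#' @examples
#' v <- bde_validation_set()
#' validation_stats(v$bde_calc, v$bde_exp, v$substance)
bde_validation_set <- function() {
  utils::read.csv(catalog_path("bde_validation.csv"), check.names = FALSE)
}
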