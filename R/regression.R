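# OLS models of a benchmarked property (usually its signed error against
# the reference) on the six functional/basis features, with backward
# elimination of insignificant terms. Fitting is delegated to stats::lm();
# what this module owns is the feature contract, the reduction procedure
# and the reporting conventions (star annotation, reduction trail).

FEATURES <- c("SR", "MR", "LR", "NBF", "zeta", "D")

p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

build_formula <- function(response, terms, intercept) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (!intercept) rhs <- paste(rhs, "- 1")
  stats::as.formula(paste(response, "~", rhs))
}

extract_stats <- function(fit, response, terms, intercept, alpha, trail) {
  sm <- summary(fit)
  tab <- sm$coefficients
  # degenerate zero-residual fits give NaN inference; report p = 1 there
  # (a coefficient indistinguishable from noise of width zero is not
  # evidence of an effect)
  pvals <- tab[, 4]
  pvals[is.na(pvals) | is.nan(pvals)] <- 1
  tab[, 4] <- pvals
  # R^2 is computed on the centered total sum of squares for every model,
  # intercept or not, so reduction can never raise it; it is clamped to
  # [0, 1] and defined as 0 for a constant response (a constant carries no
  # explainable variance, and slope inference there is numerical noise).
  y <- stats::model.response(stats::model.frame(fit))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) {
    r2 <- 0
    slope_rows <- rownames(tab) != "(Intercept)"
    tab[slope_rows, 4] <- 1
  } else {
    r2 <- min(1, max(0, 1 - rss / tss))
  }
  fstat <- sm$fstatistic
  f <- if (is.null(fstat)) {
    list(value = NA_real_, p_value = NA_real_)
  } else {
    list(value = unname(fstat[1]),
         p_value = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  }
  structure(list(response = response,
                 terms = terms,
                 intercept = intercept,
                 coefficients = stats::coef(fit),
                 coef_table = tab,
                 r_squared = r2,
                 residual_std_error = sm$sigma,
                 f_statistic = f$value,
                 f_p_value = f$p_value,
                 n_observations = stats::nobs(fit),
                 alpha = alpha,
                 reduction_trail = trail,
                 fit = fit),
            class = "feature_lm")
}

#' Fit the full feature model for one property
#'
#' Ordinary least squares of `response` on the six method/basis features
#' `SR`, `MR`, `LR`, `NBF`, `zeta`, `D` (all offered to every model, on
#' their raw scales) plus an intercept. Constant (zero-variance) feature
#' columns are dropped with a warning; residual rank deficiency is an error
#' naming the collinear columns.
#'
#' @param data data.frame holding the feature columns and the response,
#'   e.g. the output of [combination_grid()] merged with an error table.
#' @param response name of the response column.
#' @param features feature columns to offer; defaults to all six.
#' @param alpha significance level carried into [reduce_model()]
#'   (default 0.05; the conventional cut behind one-star significance).
#' @return object of class `feature_lm` with coefficient estimates,
#'   classical inference statistics, \eqn{R^2}, residual standard error,
#'   F statistic and an (initially empty) reduction trail. Supports
#'   `print()`, `summary()`, `coef()`, `predict()`, `residuals()`,
#'   `fitted()`.
#' @export
#' @examples
#' grid <- combination_grid()
#' grid$y <- 0.1 * grid$LR - 2 * grid$zeta + rnorm(nrow(grid), sd = 0.5)
#' fit_feature_model(grid, "y")
fit_feature_model <- function(data, response, features = FEATURES, alpha = 0.05) {
  stopifnot(is.data.frame(data), response %in% names(data))
  missing <- setdiff(features, names(data))
  if (length(missing)) {
    stop("feature columns absent from data: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) <= length(features) + 1L) {
    stop("need more observations (", nrow(data), ") than terms (",
         length(features) + 1L, ")", call. = FALSE)
  }
  variances <- vapply(data[features], stats::var, numeric(1))
  if (any(variances == 0)) {
    dropped <- features[variances == 0]
    warning("dropping zero-variance feature column(s): ", paste(dropped, collapse = ", "))
    features <- setdiff(features, dropped)
  }
  fit <- stats::lm(build_formula(response, features, TRUE), data = data)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  extract_stats(fit, response, features, TRUE, alpha, list())
}

#' Backward-eliminate insignificant terms
#'
#' Iteratively refits after removing the non-intercept term with the
#' largest p-value above `alpha` (one term per refit). The intercept
#' becomes eligible for removal only once every remaining slope is
#' significant — it is kept while significant so that it can absorb
#' influences not captured by the offered features. The procedure stops
#' when every remaining term has `p <= alpha`; it may return an
#' intercept-only or even empty model.
#'
#' @param model a [fit_feature_model()] object.
#' @param alpha significance level (defaults to the one stored in the
#'   model).
#' @return a `feature_lm` whose `reduction_trail` lists each dropped term
#'   with the p-value at removal.
#' @export
reduce_model <- function(model, alpha = model$alpha) {
  stopifnot(inherits(model, "feature_lm"))
  data <- model$fit$model
  # refit from the model frame so reduction is self-contained
  terms <- model$terms
  intercept <- model$intercept
  trail <- model$reduction_trail
  repeat {
    fit <- stats::lm(build_formula(model$response, terms, intercept), data = data)
    cur <- extract_stats(fit, model$response, terms, intercept, alpha, trail)
    p <- stats::setNames(cur$coef_table[, 4], rownames(cur$coef_table))
    slope_p <- p[setdiff(rownames(cur$coef_table), "(Intercept)")]
    if (length(slope_p) && max(slope_p) > alpha) {
      worst <- names(slope_p)[which.max(slope_p)]
      trail <- c(trail, list(list(term = worst, p_value = unname(max(slope_p)))))
      terms <- setdiff(terms, worst)
      next
    }
    if (intercept && "(Intercept)" %in% rownames(cur$coef_table) &&
        p[["(Intercept)"]] > alpha) {
      trail <- c(trail, list(list(term = "(Intercept)", p_value = unname(p[["(Intercept)"]]))))
      intercept <- FALSE
      next
    }
    return(cur)
  }
}

#' Evaluate a linear predictor given explicit coefficients
#'
#' Dot product of a named coefficient vector with a named feature vector,
#' plus the `intercept` element if present. Useful both for worked
#' prediction from published coefficient sets and as the mean function of
#' the synthetic generator.
#'
#' @param coefs named numeric vector; any element named `intercept` (or
#'   `(Intercept)`) is additive, all others must be matched by `features`.
#' @param features named numeric feature vector, e.g. from
#'   [encode_features()].
#' @return predicted value.
#' @export
#' @examples
#' linear_predictor(c(LR = 0.012, zeta = 2.416, D = -7.203),
#'                  encode_features("BLYP", "cc-pVDZ")) # 2.416
linear_predictor <- function(coefs, features) {
  nm <- names(coefs)
  if (is.null(nm)) stop("coefs must be named", call. = FALSE)
  is_int <- nm %in% c("intercept", "(Intercept)")
  slopes <- coefs[!is_int]
  missing <- setdiff(names(slopes), names(features))
  if (length(missing)) {
    stop("feature vector lacks: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(slopes * features[names(slopes)]) + sum(coefs[is_int])
}

#' @export
coef.feature_lm <- function(object, ...) object$coefficients

#' @export
residuals.feature_lm <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.feature_lm <- function(object, ...) stats::fitted(object$fit)

#' @export
predict.feature_lm <- function(object, newdata, ...) {
  if (missing(newdata)) return(stats::fitted(object$fit))
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
  }
  missing_f <- setdiff(object$terms, names(newdata))
  if (length(missing_f)) {
    stop("prediction needs feature(s): ", paste(missing_f, collapse = ", "), call. = FALSE)
  }
  unname(stats::predict(object$fit, newdata = newdata))
}

#' @export
print.feature_lm <- function(x, digits = 4, ...) {
  tab <- x$coef_table
  stars <- p_stars(tab[, 4])
  pieces <- character(0)
  for (nm in rownames(tab)) {
    if (nm == "(Intercept)") next
    pieces <- c(pieces, sprintf("%+.*g %s%s", digits, tab[nm, 1], nm, stars[rownames(tab) == nm]))
  }
  if ("(Intercept)" %in% rownames(tab)) {
    pieces <- c(pieces, sprintf("%+.*g%s", digits, tab["(Intercept)", 1],
                                stars[rownames(tab) == "(Intercept)"]))
  }
  cat(sprintf("Feature model for %s (n = %d)\n", x$response, x$n_observations))
  cat("  ", x$response, " = ", paste(pieces, collapse = " "), "\n", sep = "")
  cat(sprintf("  R^2 = %.4f, residual SE = %.4g, F = %.4g (p = %.3g)\n",
              x$r_squared, x$residual_std_error, x$f_statistic, x$f_p_value))
  if (length(x$reduction_trail)) {
    dropped <- vapply(x$reduction_trail, function(d) sprintf("%s (p=%.3g)", d$term, d$p_value), "")
    cat("  dropped: ", paste(dropped, collapse = ", "), "\n", sep = "")
  }
  cat("  stars: * p<0.05, ** p<0.01, *** p<0.001\n")
  invisible(x)
}

#' @export
summary.feature_lm <- function(object, ...) {
  structure(list(model = object), class = "summary.feature_lm")
}

#' @export
print.summary.feature_lm <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nCoefficients:\n")
  tab <- cbind(as.data.frame(m$coef_table), sig = p_stars(m$coef_table[, 4]))
  names(tab) <- c("estimate", "std_error", "t_value", "p_value", "sig")
  print(tab, digits = 4)
  invisible(x)
}

#' Serialize a fitted feature model to a plain list / JSON
#'
#' @param model a `feature_lm`.
#' @return list with coefficients, inference statistics and the reduction
#'   trail, suitable for `jsonlite::toJSON()`.
#' @export
model_report <- function(model) {
  stopifnot(inherits(model, "feature_lm"))
  tab <- model$coef_table
  list(response = model$response,
       terms = rownames(tab),
       coefficients = as.list(stats::setNames(tab[, 1], rownames(tab))),
       std_errors = as.list(stats::setNames(tab[, 2], rownames(tab))),
       p_values = as.list(stats::setNames(tab[, 4], rownames(tab))),
       stars = as.list(stats::setNames(p_stars(tab[, 4]), rownames(tab))),
       r_squared = model$r_squared,
       residual_std_error = model$residual_std_error,
       f_statistic = model$f_statistic,
       f_p_value = model$f_p_value,
       n_observations = model$n_observations,
       alpha = model$alpha,
       reduction_trail = model$reduction_trail)
}
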