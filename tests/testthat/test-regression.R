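grid_with_response <- function(coefs, sd = 0, seed = 1) {
  grid <- combination_grid()
  mu <- apply(as.matrix(grid[, c("SR", "MR", "LR", "NBF", "zeta", "D")]), 1,
              function(fv) linear_predictor(coefs, fv))
  set.seed(seed)
  grid$epsilon <- mu + rnorm(nrow(grid), sd = sd)
  grid
}

test_that("noise-free data from every published surface is recovered exactly", {
  models <- error_model_coefficients()
  for (p in c("bde_c3", "bde_c4", "aip", "aea", "pa_c3", "pa_c4", "vip", "vea")) {
    truth <- models[[p]]$coefficients
    data <- grid_with_response(truth, sd = 0)
    # zero-residual fits trip summary.lm's perfect-fit warning by design
    fit <- suppressWarnings(fit_feature_model(data, "epsilon"))
    est <- coef(fit)
    full_truth <- c("(Intercept)" = unname(truth["intercept"]),
                    SR = 0, MR = 0, LR = 0, NBF = 0, zeta = 0, D = 0)
    full_truth[is.na(full_truth)] <- 0
    slopes <- setdiff(names(truth), "intercept")
    full_truth[slopes] <- truth[slopes]
    expect_lt(max(abs(est[names(full_truth)] - full_truth)), 1e-8)
  }
})

test_that("row duplication changes n but not the coefficients", {
  data <- grid_with_response(c(LR = 0.012, zeta = 2.416, D = -7.203), sd = 0.3)
  fit1 <- fit_feature_model(data, "epsilon")
  fit2 <- fit_feature_model(rbind(data, data), "epsilon")
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-10)
  expect_equal(fit2$n_observations, 2L * fit1$n_observations)
})

test_that("a constant response yields no evidence of any slope", {
  data <- combination_grid()
  data$epsilon <- 5
  fit <- suppressWarnings(fit_feature_model(data, "epsilon"))
  slopes <- setdiff(rownames(fit$coef_table), "(Intercept)")
  expect_true(all(fit$coef_table[slopes, 4] >= 0.99))
  expect_equal(fit$r_squared, 0)
})

test_that("degenerate designs are caught", {
  data <- grid_with_response(c(LR = 0.1), sd = 0.1)
  data$flat <- 1
  expect_warning(fit <- fit_feature_model(data, "epsilon",
                                          features = c("LR", "zeta", "flat")),
                 "zero-variance")
  expect_false("flat" %in% fit$terms)
  data$LR2 <- data$LR
  expect_error(
    suppressWarnings(fit_feature_model(data, "epsilon",
                                       features = c("LR", "LR2", "zeta"))),
    "collinear")
  expect_error(fit_feature_model(data[1:5, ], "epsilon"), "observations")
})

test_that("backward reduction drops the single insignificant term", {
  # zeta truly inert; everything else strong relative to sd = 0.2
  data <- grid_with_response(c(SR = 0.05, LR = 0.05, NBF = 0.01,
                               D = 3, intercept = -5), sd = 0.2, seed = 4)
  red <- reduce_model(fit_feature_model(data, "epsilon"))
  dropped <- vapply(red$reduction_trail, `[[`, "", "term")
  expect_true(all(c("zeta", "MR") %in% dropped))
  expect_true(all(c("SR", "LR", "NBF", "D") %in% red$terms))
  expect_true(red$intercept)
})

test_that("a fully significant model is a fixed point of reduction", {
  data <- grid_with_response(c(SR = 0.1, MR = 0.1, LR = 0.1, NBF = 0.01,
                               zeta = 2, D = -3, intercept = 4), sd = 0.05)
  full <- fit_feature_model(data, "epsilon")
  red <- reduce_model(full)
  expect_length(red$reduction_trail, 0)
  expect_equal(coef(red), coef(full))
})

test_that("reduction of the adiabatic-EA-structured surface keeps {LR, zeta, D}", {
  truth <- c(LR = 0.012, zeta = 2.416, D = -7.203)
  data <- grid_with_response(truth, sd = 0.2, seed = 11)
  red <- reduce_model(fit_feature_model(data, "epsilon"))
  expect_setequal(red$terms, c("LR", "zeta", "D"))
  expect_false(red$intercept)
  # reduced R^2 never exceeds the full model's
  full <- fit_feature_model(data, "epsilon")
  expect_lte(red$r_squared, full$r_squared + 1e-12)
})

test_that("worked predictions from published coefficient sets", {
  aip_coefs <- error_model_coefficients()$aip$coefficients
  feats <- encode_features("CAM-B3LYP", "6-311+G(d,p)")
  expect_equal(linear_predictor(aip_coefs, feats), -1.544, tolerance = 1e-10)
  aea_coefs <- error_model_coefficients()$aea$coefficients
  expect_equal(linear_predictor(aea_coefs, c(LR = 0, zeta = 1, D = 0)), 2.416)
  expect_equal(linear_predictor(c(intercept = 7), c(SR = 0, MR = 0)), 7)
  expect_error(linear_predictor(aea_coefs, c(LR = 0)), "lacks")
})

test_that("predict on the training design reproduces the fit", {
  data <- grid_with_response(c(MR = 0.1, D = 1.2, intercept = -2), sd = 0.4, seed = 2)
  fit <- fit_feature_model(data, "epsilon")
  expect_equal(predict(fit, data), unname(fitted(fit)))
  # residuals orthogonal to every design column
  X <- cbind(1, as.matrix(data[, fit$terms]))
  expect_lt(max(abs(crossprod(X, residuals(fit)))), 1e-8)
  expect_error(predict(fit, c(SR = 1)), "feature")
  # named-vector prediction
  fv <- encode_features("BLYP", "cc-pVTZ")
  expect_equal(predict(fit, fv),
               sum(coef(fit)[fit$terms] * fv[fit$terms]) + coef(fit)[["(Intercept)"]])
})

test_that("simulated estimates land within three standard errors", {
  truth <- error_model_coefficients()$aip
  n_rep <- 30
  hits <- 0L; total <- 0L
  for (i in seq_len(n_rep)) {
    data <- grid_with_response(truth$coefficients, sd = truth$sigma, seed = 100 + i)
    fit <- fit_feature_model(data, "epsilon")
    tab <- fit$coef_table
    full_truth <- c("(Intercept)" = unname(truth$coefficients["intercept"]),
                    SR = 0, MR = 0, LR = 0, NBF = 0, zeta = 0, D = 0)
    sl <- setdiff(names(truth$coefficients), "intercept")
    full_truth[sl] <- truth$coefficients[sl]
    ok <- abs(tab[names(full_truth), 1] - full_truth) <= 3 * tab[names(full_truth), 2]
    hits <- hits + sum(ok); total <- total + length(ok)
  }
  expect_gte(hits / total, 0.97)
})
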