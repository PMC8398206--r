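# End-to-end pipeline: energetics -> indices -> signed errors -> MAE
# tables -> feature regressions -> normalized timings -> score cards ->
# ranking. Deterministic given its inputs; when an output directory is
# supplied, every file is written with a config hash in the run log so
# reruns on unchanged inputs are byte-identical.

#' Tabulate reactivity indices for a set of species records
#'
#' @param energetics list of [species_energetics()].
#' @param h_proton gas-phase proton enthalpy (kcal/mol).
#' @return data.frame `functional`, `basis`, `property`, `value`, `units`
#'   (properties: `bde_<site>`, `aip`, `aea`, `pa_<site>` in kcal/mol;
#'   `vip`, `vea` in eV).
#' @export
indices_table <- function(energetics, h_proton = dft_constants$proton_enthalpy_kcal) {
  rows <- lapply(energetics, function(s) {
    idx <- compute_indices(s, h_proton = h_proton)
    out <- list()
    grab <- function(property, value, units) {
      out[[length(out) + 1L]] <<- data.frame(
        functional = s$functional, basis = s$basis,
        property = property, value = value, units = units)
    }
    for (site in names(idx$bde_by_site)) {
      grab(paste0("bde_", tolower(site)), idx$bde_by_site[[site]], "kcal/mol")
    }
    if (!is.null(idx$aip)) grab("aip", idx$aip, "kcal/mol")
    if (!is.null(idx$aea)) grab("aea", idx$aea, "kcal/mol")
    for (site in names(idx$pa_by_site)) {
      grab(paste0("pa_", tolower(site)), idx$pa_by_site[[site]], "kcal/mol")
    }
    if (!is.null(idx$vip)) grab("vip", idx$vip, "eV")
    if (!is.null(idx$vea)) grab("vea", idx$vea, "eV")
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Signed errors of an index table against references
#'
#' Joins computed property values with the reference table and applies
#' [relative_error()] per row; properties without a reference are dropped.
#' Declared units must match.
#'
#' @param values output of [indices_table()].
#' @param references reference table ([default_references()] schema).
#' @return tidy error table `functional`, `basis`, `property`, `epsilon`,
#'   `units`.
#' @export
error_table <- function(values, references) {
  merged <- merge(values, references, by = "property",
                  suffixes = c("", "_ref"))
  eps <- mapply(relative_error, merged$value, merged$value_ref,
                merged$units, merged$units_ref)
  out <- data.frame(functional = merged$functional, basis = merged$basis,
                    property = merged$property, epsilon = eps,
                    units = merged$units)
  out <- out[order(out$property, out$functional, out$basis), , drop = FALSE]
  rownames(out) <- NULL
  out
}

config_hash <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full benchmark pipeline
#'
#' From species energetics (or a ready-made error table), timings and
#' references to the score ranking: computes indices and signed errors,
#' MAE tables over both catalog axes, reduced feature regressions per
#' property, normalized stage times, per-combination score cards and the
#' final ranking. Geometry (or any other pre-scored) properties enter
#' through `extra_errors` as precomputed signed errors.
#'
#' @param energetics list of [species_energetics()] or a path to the
#'   energetics CSV.
#' @param timings timing data.frame or CSV path.
#' @param references reference table or YAML/JSON path (default: packaged
#'   references).
#' @param extra_errors optional error table for properties not derivable
#'   from the energetics (e.g. geometry), same schema as [error_table()].
#' @param alpha significance level for model reduction.
#' @param config score configuration ([score_config()]).
#' @param h_proton gas-phase proton enthalpy (kcal/mol).
#' @param out_dir optional directory; when given, writes `errors.csv`,
#'   `mae_functional.csv`, `mae_basis.csv`, `regression_report.json`,
#'   `score_matrix.csv`, `ranking.csv` and `run_log.txt` (package version
#'   + input hash, no timestamps, so reruns are byte-identical).
#' @return list of class `benchmark_run`: `errors`, `mae_functional`,
#'   `mae_basis`, `models` (reduced `feature_lm` per property),
#'   `timing_summary`, `cards`, `ranking`, `config_hash`.
#' @export
run_pipeline <- function(energetics, timings, references = default_references(),
                         extra_errors = NULL, alpha = 0.05,
                         config = score_config(),
                         h_proton = dft_constants$proton_enthalpy_kcal,
                         out_dir = NULL) {
  if (is.character(energetics)) energetics <- read_energetics(energetics)
  if (is.character(timings)) timings <- read_timings(timings)
  if (is.character(references)) references <- read_references(references)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  values <- step("indices", indices_table(energetics, h_proton = h_proton))
  errors <- step("errors", error_table(values, references))
  if (!is.null(extra_errors)) {
    check_error_table(extra_errors)
    if (!"units" %in% names(extra_errors)) extra_errors$units <- NA_character_
    errors <- rbind(errors, extra_errors[, names(errors)])
    errors <- errors[order(errors$property, errors$functional, errors$basis), , drop = FALSE]
    rownames(errors) <- NULL
  }
  mae_f <- step("mae", mae_table(errors, "functional"))
  mae_b <- step("mae", mae_table(errors, "basis"))

  grid <- combination_grid()
  models <- step("regression", {
    props <- sort(unique(errors$property))
    fits <- lapply(props, function(p) {
      sub <- merge(grid, errors[errors$property == p, c("functional", "basis", "epsilon")],
                   by = c("functional", "basis"))
      full <- fit_feature_model(sub, "epsilon", alpha = alpha)
      reduce_model(full)
    })
    stats::setNames(fits, props)
  })

  perf <- step("performance", stage_summary(timings, stages = config$performance_stages))

  cards <- step("scoring", {
    refs <- stats::setNames(references$value, references$property)
    combos <- unique(errors[, c("functional", "basis")])
    combos <- combos[order(combos$functional, combos$basis), , drop = FALSE]
    lapply(seq_len(nrow(combos)), function(i) {
      f <- combos$functional[i]; b <- combos$basis[i]
      sel <- errors$functional == f & errors$basis == b
      eps <- stats::setNames(errors$epsilon[sel], errors$property[sel])
      pts <- function(p) property_points(eps[[p]], refs[[p]], config$tier_thresholds)
      need <- function(group) {
        absent <- setdiff(group, names(eps))
        if (length(absent)) {
          stop("combination ", f, "/", b, " lacks error(s) for: ",
               paste(absent, collapse = ", "), call. = FALSE)
        }
      }
      need(config$properties); need(config$janak)
      tsel <- perf$times$functional == f & perf$times$basis == b
      pperf <- vapply(config$performance_stages, function(st) {
        ssel <- tsel & perf$times$stage == st
        if (!any(ssel)) stop("combination ", f, "/", b, " lacks timing for stage ", st,
                             call. = FALSE)
        performance_points(perf$times$normalized_s[ssel][1],
                           perf$max_by_stage[[st]], config$tier_thresholds)
      }, integer(1))
      total_score(f, b,
                  points_property = vapply(config$properties, pts, integer(1)),
                  points_performance = pperf,
                  points_janak = vapply(config$janak, pts, integer(1)),
                  config = config)
    })
  })

  ranking <- step("ranking", rank_combinations(cards))
  hash <- config_hash(list(errors = errors, timings = timings,
                           references = references, alpha = alpha,
                           config = config))

  run <- structure(list(errors = errors, mae_functional = mae_f,
                        mae_basis = mae_b, models = models,
                        timing_summary = perf, cards = cards,
                        ranking = ranking, config_hash = hash),
                   class = "benchmark_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_errors(run$errors, p("errors.csv"))
  utils::write.csv(run$mae_functional, p("mae_functional.csv"), row.names = FALSE)
  utils::write.csv(run$mae_basis, p("mae_basis.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(run$models, model_report), p("regression_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mat <- run$ranking$matrix
  utils::write.csv(data.frame(basis = rownames(mat), mat, check.names = FALSE),
                   p("score_matrix.csv"), row.names = FALSE)
  utils::write.csv(run$ranking$ranking, p("ranking.csv"), row.names = FALSE)
  writeLines(c(paste0("dftbench version: ",
                      as.character(utils::packageVersion("dftbench"))),
               paste0("config hash: ", run$config_hash)),
             p("run_log.txt"))
  invisible(out_dir)
}

#' @export
print.benchmark_run <- function(x, ...) {
  top <- x$ranking$ranking[1, ]
  cat("Benchmark run over", length(x$cards), "combinations\n")
  cat(sprintf("  best: %s/%s at %d%%\n", top$functional, top$basis,
              as.integer(round_half_up(top$percent))))
  cat("  properties modelled:", paste(names(x$models), collapse = ", "), "\n")
  cat("  config hash:", x$config_hash, "\n")
  invisible(x)
}
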