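# The weighted threshold score that ranks levels of theory. Each scored
# quantity earns 0/1/2 points by how far its signed error falls from the
# reference (1% / 5% bands); property points weigh 0.6, computational
# performance 0.3 and the Janak (frontier-orbital) checks 0.1. All
# inequalities are strict, so exact-boundary values fall to the less
# favourable tier (documented convention; see the methods vignette).

#' Default score configuration
#'
#' The nine scored properties (O-H bond lengths at both catechol sites,
#' the intramolecular hydrogen-bond length, BDE at both sites, adiabatic
#' EA and IP, PA at both sites), the two performance stages, the two
#' Janak checks, the category weights and the tier thresholds.
#'
#' @return list with `properties`, `performance_stages`, `janak`,
#'   `weights` (`property`, `performance`, `janak`), `tier_thresholds`
#'   (`inner`, `outer`).
#' @export
score_config <- function() {
  list(properties = c("oh_c3", "oh_c4", "hbond", "bde_c3", "bde_c4",
                      "aea", "aip", "pa_c3", "pa_c4"),
       performance_stages = c("link502", "link703"),
       janak = c("vip", "vea"),
       weights = c(property = 0.6, performance = 0.3, janak = 0.1),
       tier_thresholds = c(inner = 0.01, outer = 0.05))
}

tier_points <- function(value, scale, thresholds) {
  if (value < thresholds[["inner"]] * scale) 2L
  else if (value < thresholds[["outer"]] * scale) 1L
  else 0L
}

#' Points for a property error
#'
#' 2 points if `|xi| < 1%` of `|x_ref|`, 1 point if below 5%, else 0;
#' boundaries go to the lower tier.
#'
#' @param xi signed error (same units as the reference).
#' @param x_ref reference value; must be nonzero (relative thresholds are
#'   undefined at zero).
#' @param thresholds inner/outer relative tier bounds.
#' @return integer in `{0, 1, 2}` (vectorized over `xi`).
#' @export
#' @examples
#' property_points(c(0, 2, 10), 80) # 2 1 0
property_points <- function(xi, x_ref,
                            thresholds = score_config()$tier_thresholds) {
  if (!is.finite(x_ref) || x_ref == 0) {
    stop("reference value must be finite and nonzero", call. = FALSE)
  }
  stop_if_not_finite(xi, what = "error")
  vapply(abs(xi), tier_points, integer(1),
         scale = abs(x_ref), thresholds = thresholds)
}

#' Points for a normalized stage time
#'
#' The per-stage maximum over the combination set plays the role of the
#' reference: 2 points if the combination's normalized time is below 1% of
#' the maximum, 1 if below 5%, else 0.
#'
#' @param t normalized time (s per instance per core), `t >= 0`.
#' @param t_max maximum normalized time over the set; must be positive.
#' @param thresholds inner/outer relative tier bounds.
#' @return integer in `{0, 1, 2}` (vectorized over `t`).
#' @export
#' @examples
#' performance_points(c(0, 3, 100), 100) # 2 1 0
performance_points <- function(t, t_max,
                               thresholds = score_config()$tier_thresholds) {
  if (!is.finite(t_max) || t_max <= 0) stop("t_max must be positive", call. = FALSE)
  stop_if_not_finite(t, what = "time")
  if (any(t < 0)) stop("normalized times must be nonnegative", call. = FALSE)
  vapply(t, tier_points, integer(1), scale = t_max, thresholds = thresholds)
}

#' Points for a Janak (vertical IP/EA) error
#'
#' Same rule as [property_points()]; kept as its own entry point because
#' the Janak checks form their own weighted category.
#'
#' @inheritParams property_points
#' @return integer in `{0, 1, 2}`.
#' @export
janak_points <- function(xi, x_ref,
                         thresholds = score_config()$tier_thresholds) {
  property_points(xi, x_ref, thresholds)
}

#' Assemble a score card for one combination
#'
#' Weighted sum of the category points,
#' `raw = 0.6 * sum(property) + 0.3 * sum(performance) + 0.1 * sum(janak)`
#' by default, normalized by the maximum attainable raw score for the
#' configured category lists and expressed as a percentage. With the
#' default 9 + 2 + 2 lists the maximum raw score is
#' `0.6*18 + 0.3*4 + 0.1*4 = 12.4`.
#'
#' @param functional,basis combination labels.
#' @param points_property named integer vector covering every configured
#'   property.
#' @param points_performance named integer vector covering every
#'   configured stage.
#' @param points_janak named integer vector covering both Janak checks.
#' @param config a [score_config()] list (category lists and weights).
#' @return list of class `score_card`: the point maps, `raw_score`,
#'   `max_raw`, `percent` (full precision; the print method rounds
#'   half-up to an integer, the display convention of the score table).
#' @export
total_score <- function(functional, basis, points_property,
                        points_performance, points_janak,
                        config = score_config()) {
  check_pts <- function(pts, wanted, label) {
    missing <- setdiff(wanted, names(pts))
    if (length(missing)) {
      stop("missing ", label, " points for: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    pts <- pts[wanted]
    if (!all(pts %in% 0:2)) stop(label, " points must lie in {0, 1, 2}", call. = FALSE)
    pts
  }
  pp <- check_pts(points_property, config$properties, "property")
  pc <- check_pts(points_performance, config$performance_stages, "performance")
  pj <- check_pts(points_janak, config$janak, "Janak")
  w <- config$weights
  raw <- w[["property"]] * sum(pp) + w[["performance"]] * sum(pc) + w[["janak"]] * sum(pj)
  max_raw <- 2 * (w[["property"]] * length(config$properties) +
                  w[["performance"]] * length(config$performance_stages) +
                  w[["janak"]] * length(config$janak))
  structure(list(functional = functional, basis = basis,
                 points_property = pp, points_performance = pc,
                 points_janak = pj,
                 raw_score = raw, max_raw = max_raw,
                 percent = 100 * raw / max_raw),
            class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("Score card %s/%s: %d%% (raw %.2f of %.2f)\n",
              x$functional, x$basis,
              as.integer(round_half_up(x$percent)), x$raw_score, x$max_raw))
  cat("  properties:  ", paste(sprintf("%s=%d", names(x$points_property), x$points_property),
                               collapse = " "), "\n")
  cat("  performance: ", paste(sprintf("%s=%d", names(x$points_performance), x$points_performance),
                               collapse = " "), "\n")
  cat("  Janak:       ", paste(sprintf("%s=%d", names(x$points_janak), x$points_janak),
                               collapse = " "), "\n")
  invisible(x)
}

#' Rank a set of score cards
#'
#' Produces both the score-table matrix (basis sets as rows, functionals
#' as columns, percentages rounded half-up to integers for display) and a
#' flat ranking at full precision. Ties share a rank and are ordered
#' alphabetically by functional then basis within the tie.
#'
#' @param cards list of [total_score()] score cards.
#' @return list of class `score_ranking`: `matrix` (display percentages),
#'   `ranking` (data.frame `rank`, `functional`, `basis`, `percent`,
#'   `raw_score`).
#' @export
rank_combinations <- function(cards) {
  stopifnot(length(cards) >= 1L, all(vapply(cards, inherits, TRUE, "score_card")))
  flat <- data.frame(
    functional = vapply(cards, `[[`, "", "functional"),
    basis = vapply(cards, `[[`, "", "basis"),
    percent = vapply(cards, `[[`, 0, "percent"),
    raw_score = vapply(cards, `[[`, 0, "raw_score"))
  ord <- order(-flat$percent, flat$functional, flat$basis)
  flat <- flat[ord, , drop = FALSE]
  # shared (min) rank for ties
  flat$rank <- as.integer(rank(-flat$percent, ties.method = "min"))
  flat <- flat[, c("rank", "functional", "basis", "percent", "raw_score")]
  rownames(flat) <- NULL
  funs <- sort(unique(flat$functional))
  bases <- sort(unique(flat$basis))
  m <- matrix(NA_real_, nrow = length(bases), ncol = length(funs),
              dimnames = list(bases, funs))
  for (i in seq_len(nrow(flat))) {
    m[flat$basis[i], flat$functional[i]] <- round_half_up(flat$percent[i])
  }
  structure(list(matrix = m, ranking = flat), class = "score_ranking")
}

#' @export
print.score_ranking <- function(x, n = 10, ...) {
  cat("Score matrix (% of maximum, basis sets x functionals):\n")
  print(x$matrix)
  cat("\nTop combinations:\n")
  print(utils::head(x$ranking, n), row.names = FALSE)
  invisible(x)
}
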