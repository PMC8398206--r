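# Independent brute-force tier coder used as the oracle for the point
# assignment: written directly from the strict-inequality rule, with no
# shared helpers with the package implementation.
brute_tier <- function(err, ref_scale) {
  a <- abs(err)
  if (a < 0.01 * ref_scale) return(2L)
  if (a >= 0.01 * ref_scale && a < 0.05 * ref_scale) return(1L)
  0L
}

full_points <- function(value) {
  cfg <- score_config()
  list(prop = setNames(rep(value, 9L), cfg$properties),
       perf = setNames(rep(value, 2L), cfg$performance_stages),
       janak = setNames(rep(value, 2L), cfg$janak))
}

test_that("property points follow the 1%/5% tiers with strict boundaries", {
  expect_equal(property_points(0, 80), 2L)
  expect_equal(property_points(2, 80), 1L)
  expect_equal(property_points(10, 80), 0L)
  # boundary values fall to the less favourable tier
  expect_equal(property_points(0.8, 80), 1L)
  expect_equal(property_points(4.0, 80), 0L)
  # sign of the error is irrelevant
  expect_equal(property_points(-2, 80), 1L)
  expect_equal(property_points(2, -80), 1L)
  expect_error(property_points(0.1, 0), "nonzero")
})

test_that("performance points compare against the stage maximum", {
  expect_equal(performance_points(0, 100), 2L)
  expect_equal(performance_points(3, 100), 1L)
  expect_equal(performance_points(100, 100), 0L)
  expect_equal(performance_points(1, 100), 1L)   # boundary down
  expect_equal(performance_points(5, 100), 0L)   # boundary down
  expect_error(performance_points(1, 0), "positive")
  expect_error(performance_points(-1, 10), "nonnegative")
})

test_that("Janak points reuse the property rule on eV references", {
  expect_equal(janak_points(0, 7.16), 2L)
  expect_equal(janak_points(0.2, 7.16), 1L)
  expect_equal(janak_points(1.0, 0.67), 0L)
})

test_that("point assignment agrees with a brute-force coder on a dense grid", {
  set.seed(33)
  refs <- c(runif(500, 0.1, 400), -runif(500, 0.1, 400))
  errs <- runif(1000, 0, 0.08) * abs(refs) * sample(c(-1, 1), 1000, replace = TRUE)
  got <- mapply(function(e, r) property_points(e, r), errs, refs)
  want <- mapply(function(e, r) brute_tier(e, abs(r)), errs, refs)
  expect_equal(got, want)
  got_perf <- mapply(function(e, r) performance_points(abs(e), abs(r)), errs, refs)
  expect_equal(got_perf, want)
})

test_that("total score weights categories 0.6/0.3/0.1 and normalizes to 12.4", {
  top <- full_points(2L)
  card <- total_score("M06-2X", "6-311G(d,p)", top$prop, top$perf, top$janak)
  expect_equal(card$max_raw, 12.4)
  expect_equal(card$percent, 100)
  zero <- full_points(0L)
  expect_equal(total_score("BLYP", "cc-pVDZ", zero$prop, zero$perf, zero$janak)$percent, 0)
  mixed <- full_points(0L)
  mixed$prop[] <- 1L
  mixed$janak[] <- 2L
  card <- total_score("X", "Y", mixed$prop, mixed$perf, mixed$janak)
  expect_equal(card$raw_score, 5.8)
  expect_equal(card$percent, 100 * 5.8 / 12.4, tolerance = 1e-12)
  expect_equal(round(card$percent), 47)
})

test_that("missing categories are reported by name", {
  top <- full_points(2L)
  expect_error(total_score("A", "B", top$prop[-1], top$perf, top$janak),
               names(top$prop)[1])
  expect_error(total_score("A", "B", top$prop, top$perf, top$janak[1]), "vea")
})

test_that("max_raw adapts to a reduced property list", {
  cfg <- score_config()
  cfg$properties <- cfg$properties[1:4]
  pts <- setNames(rep(2L, 4L), cfg$properties)
  perf <- setNames(rep(2L, 2L), cfg$performance_stages)
  janak <- setNames(rep(2L, 2L), cfg$janak)
  card <- total_score("A", "B", pts, perf, janak, config = cfg)
  expect_equal(card$max_raw, 0.6 * 8 + 0.3 * 4 + 0.1 * 4)
  expect_equal(card$percent, 100)
})

test_that("shrinking any error magnitude never lowers the percent", {
  cfg <- score_config()
  refs <- setNames(c(0.97, 0.97, 2.1, 92.6, 80.1, -12.8, 184.1, 340.3, 320.4),
                   cfg$properties)
  jrefs <- c(vip = 7.16, vea = 0.67)
  set.seed(91)
  for (rep in 1:20) {
    eps <- setNames(rnorm(9, sd = 0.06) * abs(refs), names(refs))
    jeps <- setNames(rnorm(2, sd = 0.06) * abs(jrefs), names(jrefs))
    perf <- setNames(sample(0:2, 2, replace = TRUE), cfg$performance_stages)
    card <- function(e, je) {
      total_score("F", "B",
                  mapply(function(x, r) property_points(x, r), e, refs),
                  perf,
                  mapply(function(x, r) janak_points(x, r), je, jrefs))
    }
    before <- card(eps, jeps)$percent
    k <- sample(9, 1)
    eps2 <- eps; eps2[k] <- eps2[k] * runif(1)
    expect_gte(card(eps2, jeps)$percent, before)
  }
})

test_that("ranking orders cards, shares tied ranks, ignores input order", {
  top <- full_points(2L); zero <- full_points(0L); mid <- full_points(1L)
  cards <- list(
    total_score("BLYP", "cc-pVDZ", zero$prop, zero$perf, zero$janak),
    total_score("M06-2X", "6-311G(d,p)", top$prop, top$perf, top$janak),
    total_score("B3LYP", "cc-pVTZ", mid$prop, mid$perf, mid$janak),
    total_score("TPSSh", "def2-SVP", mid$prop, mid$perf, mid$janak))
  r <- rank_combinations(cards)
  expect_equal(r$ranking$functional[1], "M06-2X")
  expect_equal(r$ranking$rank, c(1L, 2L, 2L, 4L))
  # tied cards ordered alphabetically
  expect_equal(r$ranking$functional[2:3], c("B3LYP", "TPSSh"))
  r2 <- rank_combinations(rev(cards))
  expect_equal(r2$ranking, r$ranking)
  expect_equal(r$matrix["6-311G(d,p)", "M06-2X"], 100)
})

test_that("percent is 100 exactly when all thirteen entries are 2", {
  top <- full_points(2L)
  for (i in 1:5) {
    p <- top
    slot <- sample(c("prop", "perf", "janak"), 1)
    j <- sample(length(p[[slot]]), 1)
    p[[slot]][j] <- sample(0:1, 1)
    card <- total_score("A", "B", p$prop, p$perf, p$janak)
    expect_lt(card$percent, 100)
    expect_gte(card$percent, 0)
  }
})
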