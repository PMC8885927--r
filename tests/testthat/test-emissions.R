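tr_one <- tibble::tibble(source = "s", technology = "old",
                         x0 = 1, xf = 0, t0 = 1990, s = 10)

test_that("the technology S-curve hits its closed-form anchors", {
  # at t = t0 the exponent vanishes
  expect_equal(technology_fraction(tr_one, 1990)$fraction, 1)
  # constant (clamped) before the transition starts
  expect_equal(technology_fraction(tr_one, c(1950, 1970, 1989))$fraction,
               rep(1, 3))
  # far beyond the transition the final fraction is reached
  x_far <- technology_fraction(tr_one, 1990 + 10 * 10)$fraction
  expect_lt(abs(x_far - 0), 1e-10 * 1 + 1e-15)
  # one rate-parameter past t0: (x0 - xf) exp(-1/2) + xf
  expect_equal(technology_fraction(tr_one, 2000)$fraction, exp(-0.5),
               tolerance = 1e-12)
})

test_that("the S-curve is monotone from x0 toward xf and bounded", {
  tr_up <- tibble::tibble(source = "s", technology = "new",
                          x0 = 0.1, xf = 0.8, t0 = 1995, s = 8)
  years <- 1995:2080
  x <- technology_fraction(tr_up, years)$fraction
  expect_true(all(diff(x) >= 0))
  expect_true(all(x >= 0.1 - 1e-12 & x <= 0.8 + 1e-12))
  x_down <- technology_fraction(tr_one, 1990:2080)$fraction
  expect_true(all(diff(x_down) <= 0))
  expect_error(technology_fraction(dplyr::mutate(tr_one, s = 0), 2000),
               "positive")
  expect_error(technology_fraction(dplyr::mutate(tr_one, x0 = 1.2), 2000),
               "\\[0, 1\\]")
})

make_ef <- function(vals_by_division) {
  # vals_by_division: named list division label -> length-16 EF vector
  meta <- tibble::tibble(
    source = sub(":.*", "", names(vals_by_division)),
    technology = sub(".*:", "", names(vals_by_division))
  )
  dplyr::bind_cols(meta, do.call(congener_row_tbl, unname(vals_by_division)))
}

test_that("effective EFs blend divisions by renormalised fractions", {
  ef <- make_ef(list("a:only" = rep(2, 16)))
  for (yr in c(1980, 2000, 2050)) {
    out <- effective_ef(ef, NULL, "a", yr)
    expect_equal(as.numeric(out[1, panel]), rep(2, 16))
  }

  ef2 <- make_ef(list("b:old" = rep(2, 16), "b:new" = rep(4, 16)))
  tr <- tibble::tibble(source = "b", technology = c("old", "new"),
                       x0 = c(0.5, 0.5), xf = c(0.5, 0.5), t0 = 2000, s = 5)
  out2 <- effective_ef(ef2, tr, "b", 2010)
  expect_equal(as.numeric(out2[1, panel]), rep(3, 16))
  expect_error(effective_ef(ef2, tr, "nope", 2010), "unknown source")
})

test_that("three-division blends match a hand-computed weighted sum", {
  ef3 <- make_ef(list("c:t1" = rep(1, 16), "c:t2" = rep(10, 16),
                      "c:t3" = rep(100, 16)))
  tr3 <- tibble::tibble(
    source = "c", technology = c("t1", "t2", "t3"),
    x0 = c(0.7, 0.2, 0.1), xf = c(0.1, 0.3, 0.6), t0 = 2000, s = 10
  )
  yr <- 2012
  g <- exp(-(yr - 2000)^2 / (2 * 10^2))
  x_raw <- c(0.7 - 0.1, 0.2 - 0.3, 0.1 - 0.6) * g + c(0.1, 0.3, 0.6)
  w <- x_raw / sum(x_raw)
  expected <- sum(w * c(1, 10, 100))
  out <- effective_ef(ef3, tr3, "c", yr)
  expect_equal(as.numeric(out[1, panel]), rep(expected, 16), tolerance = 1e-12)
})

test_that("the inventory applies the g/t x 1e4 t unit conversion exactly", {
  ef <- make_ef(list("s:only" = rep(2, 16)))
  act <- tibble::tibble(region = "r", year = 2000L, source = "s", activity = 1)
  em <- total_emission(ef, NULL, act)
  # 2 g/t x 1e4 t = 2e4 g = 0.02 t
  expect_equal(as.numeric(em[1, panel]), rep(0.02, 16))
  expect_equal(em$total, 0.32)

  em0 <- total_emission(ef, NULL, dplyr::mutate(act, activity = 0))
  expect_equal(as.numeric(em0[1, panel]), rep(0, 16))
})

test_that("emissions are linear in activity and additive over sources", {
  ef <- make_ef(list("s1:only" = 1:16, "s2:only" = rep(5, 16)))
  act <- tibble::tibble(region = "r", year = 2000L,
                        source = c("s1", "s2"), activity = c(3, 7))
  em <- total_emission(ef, NULL, act)
  em_dbl <- total_emission(ef, NULL, dplyr::mutate(act, activity = activity * 2))
  expect_equal(as.numeric(em_dbl[1, panel]), 2 * as.numeric(em[1, panel]))
  # additivity: the two sources alone sum to the joint inventory
  em_s1 <- total_emission(ef, NULL, act[1, ])
  em_s2 <- total_emission(ef, NULL, act[2, ])
  expect_equal(as.numeric(em[1, panel]),
               as.numeric(em_s1[1, panel]) + as.numeric(em_s2[1, panel]))
  expect_error(total_emission(ef, NULL, dplyr::mutate(act, source = "zz")),
               "unknown source")
})

test_that("congener emission shares within one division equal its EF shares", {
  ef_vals <- as.numeric(simulate_ef_table(sim_config(seed = 4))[3, panel])
  ef <- make_ef(list("s:only" = ef_vals))
  act <- tibble::tibble(region = "r", year = 2005L, source = "s", activity = 11)
  em <- as.numeric(total_emission(ef, NULL, act)[1, panel])
  expect_equal(em / sum(em), ef_vals / sum(ef_vals), tolerance = 1e-12)
})

test_that("the by-source breakdown reconciles with the region totals", {
  st <- sim_config(seed = 6, n_samples = 40, regions = c("A", "B"),
                   years = 2010L)
  ef <- simulate_ef_table(st)
  acts <- simulate_activities(st)
  em <- total_emission(ef, simulate_transitions(st), acts)
  long <- attr(em, "by_source")
  recon <- long |>
    dplyr::group_by(region, year, congener) |>
    dplyr::summarise(emission_t = sum(emission_t), .groups = "drop") |>
    tidyr::pivot_wider(names_from = congener, values_from = emission_t)
  recon <- recon[order(recon$region), ]
  expect_equal(as.matrix(recon[panel]), as.matrix(em[order(em$region), panel]),
               tolerance = 1e-12)
})
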