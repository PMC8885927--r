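test_that("concentration tables round-trip through CSV with full panel validation", {
  toy <- toy_concentration(n = 2)
  path <- write_toy_csv(toy)
  tbl <- read_pah_table(path, "concentration")
  expect_s3_class(tbl, "tbl_df")
  expect_equal(nrow(tbl), 2)
  expect_equal(as.matrix(tbl[panel]), as.matrix(toy[panel]), tolerance = 1e-12)
  expect_equal(tbl$sample_id, toy$sample_id)
  # write-then-read reproduces values
  path2 <- write_toy_csv(tbl, "roundtrip.csv")
  tbl2 <- read_pah_table(path2, "concentration")
  expect_equal(as.matrix(tbl2[panel]), as.matrix(tbl[panel]))
})

test_that("schema violations are rejected with the offending column named", {
  toy <- toy_concentration(n = 2)
  toy$DahA <- NULL
  expect_error(read_pah_table(write_toy_csv(toy), "concentration"), "DahA")

  bad <- toy_concentration(n = 2)
  bad$Phe[1] <- -4
  expect_error(read_pah_table(write_toy_csv(bad), "concentration"),
               "negative")

  junk <- toy_concentration(n = 2)
  junk$Flu <- as.character(junk$Flu)
  junk$Flu[2] <- "n.d."
  expect_error(read_pah_table(write_toy_csv(junk), "concentration"),
               "Flu")
})

test_that("left-censored cells are substituted with half the LOD", {
  toy <- toy_concentration(n = 3)
  toy$Nap <- as.character(toy$Nap)
  toy$Nap[1] <- "<LOD"
  toy$Nap_lod <- 0.2
  toy$Ant <- as.character(toy$Ant)
  toy$Ant[2] <- "<0.5" # inline LOD
  tbl <- read_pah_table(write_toy_csv(toy), "concentration")
  expect_equal(tbl$Nap[1], 0.1)
  expect_equal(tbl$Ant[2], 0.25)
  cens <- attr(tbl, "censored")
  expect_true(cens$Nap[1])
  expect_true(cens$Ant[2])
  expect_false(any(cens$Nap[-1]))
  # substitution never exceeds the LOD
  expect_lt(tbl$Nap[1], 0.2)

  # boolean flag encoding maps to LOD/2 too
  flagged <- toy_concentration(n = 2)
  flagged$Pyr_cens <- c(TRUE, FALSE)
  flagged$Pyr_lod <- 0.8
  tbl2 <- read_pah_table(write_toy_csv(flagged), "concentration")
  expect_equal(tbl2$Pyr[1], 0.4)
  expect_equal(tbl2$Pyr[2], flagged$Pyr[2])

  # sentinel without an LOD column is an error
  orphan <- toy_concentration(n = 2)
  orphan$BaP <- as.character(orphan$BaP)
  orphan$BaP[1] <- "<LOD"
  expect_error(read_pah_table(write_toy_csv(orphan), "concentration"), "LOD")
})

test_that("exact zeros without an LOD are rejected", {
  toy <- toy_concentration(n = 2)
  toy$Acy[2] <- 0
  expect_error(read_pah_table(write_toy_csv(toy), "concentration"), "zero")
})

test_that("foc is normalised to percent", {
  toy <- toy_concentration(n = 3)
  toy$foc <- c(0.064, 0.041, 0.020) # fractions
  tbl <- read_pah_table(write_toy_csv(toy), "concentration")
  expect_equal(tbl$foc, c(6.4, 4.1, 2.0))
  toy$foc <- c(6.4, 4.1, 2.0) # already percent
  tbl2 <- read_pah_table(write_toy_csv(toy), "concentration")
  expect_equal(tbl2$foc, c(6.4, 4.1, 2.0))
})

test_that("row totals sum the full panel and are linear in the table", {
  ones <- congener_row_tbl(rep(1, 16))
  expect_equal(pah_total(ones)$total, 16)
  zeros <- congener_row_tbl(rep(0, 16))
  expect_equal(pah_total(zeros)$total, 0)

  toy <- toy_concentration(n = 5)
  tot <- pah_total(toy)$total
  expect_equal(tot, rowSums(as.matrix(toy[panel])))
  expect_true(all(tot >= apply(as.matrix(toy[panel]), 1, max)))
  # linearity under positive scaling
  scaled <- toy
  scaled[panel] <- scaled[panel] * 2.5
  expect_equal(pah_total(scaled)$total, 2.5 * tot)
})

test_that("geometric-mean aggregation matches hand arithmetic and AM-GM", {
  tbl <- toy_concentration(n = 2)
  tbl$region <- "A"
  tbl[panel] <- 1
  tbl$Nap <- c(1, 100)
  agg <- aggregate_geomean(tbl, region)
  expect_equal(agg$Nap, 10)

  tbl3 <- toy_concentration(n = 3)
  tbl3$region <- "A"
  tbl3$Phe <- c(2, 4, 8)
  agg3 <- aggregate_geomean(tbl3, region)
  expect_equal(agg3$Phe, 4) # exp((ln2 + ln4 + ln8)/3)

  # a single-sample group aggregates to itself
  single <- toy_concentration(n = 1)
  agg1 <- aggregate_geomean(single, region)
  expect_equal(as.numeric(agg1[1, panel]), as.numeric(single[1, panel]))

  # permutation invariance and AM-GM on a random table
  rnd <- toy_concentration(n = 8, seed = 5)
  rnd$region <- "Z"
  shuffled <- rnd[sample(nrow(rnd)), ]
  expect_equal(aggregate_geomean(rnd, region)[panel],
               aggregate_geomean(shuffled, region)[panel])
  gm <- as.numeric(aggregate_geomean(rnd, region)[1, panel])
  am <- colMeans(as.matrix(rnd[panel]))
  expect_true(all(gm <= am + 1e-12))

  # nonpositive values must not reach the geometric mean
  bad <- toy_concentration(n = 2)
  bad$Nap[1] <- 0
  expect_error(aggregate_geomean(bad, region), "positive")
})

test_that("K-S normality screen agrees with the reference implementation", {
  set.seed(11)
  x_norm <- rnorm(1000)
  x_unif <- runif(1000)
  res_norm <- normality_check(x_norm)
  res_unif <- normality_check(x_unif)
  expect_true(res_norm$normal)
  expect_false(res_unif$normal)
  ref <- suppressWarnings(ks.test(x_unif, "pnorm", mean(x_unif), sd(x_unif)))
  expect_equal(res_unif$statistic, unname(ref$statistic))
  expect_equal(res_unif$p_value, ref$p.value)

  expect_error(normality_check(c(1, 2)), "at least 3")
  expect_error(normality_check(rep(1, 10)), "constant")
  # log-scale option
  expect_true(normality_check(exp(x_norm), log = TRUE)$normal)
  expect_error(normality_check(c(-1, 1, 2), log = TRUE), "positive")
})

test_that("the panel is fixed, ordered, and complete", {
  p <- pah_panel()
  expect_equal(nrow(p), 16)
  expect_equal(p$congener[c(1, 2, 5, 9, 16)],
               c("Nap", "Acy", "Phe", "BaA", "DahA"))
  expect_false(anyDuplicated(p$congener) > 0)
  expect_true(all(p$ring_count %in% 2:6))
  expect_true(all(is.finite(p$logkow) & p$logkow > 0))
})
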