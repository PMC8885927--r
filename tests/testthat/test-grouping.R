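test_that("profile distance is 1 - Pearson r with the documented boundary cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  tbl <- toy_concentration(n = 6)
  tbl$Nap <- x
  tbl$Acy <- 10 * x + 3       # identical profile up to affine scale
  tbl$Ace <- -x               # perfectly anti-correlated
  d <- profile_distance(tbl)
  expect_equal(d["Nap", "Acy"], 0)
  expect_equal(d["Nap", "Ace"], 2)
  expect_equal(diag(d), setNames(rep(0, 16), panel))
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 2))
})

test_that("profile distance matches a double-loop Pearson oracle on a random table", {
  tbl <- toy_concentration(n = 10, seed = 21)
  d <- profile_distance(tbl)
  m <- as.matrix(tbl[panel])
  for (i in seq_len(16)) {
    for (j in seq_len(16)) {
      expect_equal(d[i, j], 1 - cor(m[, i], m[, j]), tolerance = 1e-12)
    }
  }
})

test_that("degenerate inputs are rejected with the congener named", {
  tbl <- toy_concentration(n = 5)
  tbl$BkF <- 7
  expect_error(profile_distance(tbl), "BkF")
  expect_error(profile_distance(toy_concentration(n = 2)), "at least 3")
})

test_that("average-linkage clustering merges identical profiles first and cuts nestedly", {
  tbl <- toy_concentration(n = 8, seed = 3)
  tbl$Chr <- tbl$BaP * 2 # identical profile pair
  grp2 <- cluster_congeners(profile_distance(tbl), 2)
  asg2 <- setNames(grp2$assignments$subgroup, grp2$assignments$congener)
  expect_equal(asg2[["Chr"]], asg2[["BaP"]])
  expect_error(cluster_congeners(profile_distance(tbl), 1), "between 2 and")
  expect_error(cluster_congeners(profile_distance(tbl), 17), "between 2 and")

  # partitions at successive g are refinements of each other
  d <- profile_distance(toy_concentration(n = 12, seed = 8))
  for (g in 2:8) {
    a <- cluster_congeners(d, g)$assignments
    b <- cluster_congeners(d, g + 1)$assignments
    merged <- dplyr::left_join(a, b, by = "congener", suffix = c("_g", "_g1"))
    # every finer subgroup maps into exactly one coarser subgroup
    expect_true(all(tapply(merged$subgroup_g, merged$subgroup_g1,
                           function(z) length(unique(z))) == 1))
  }
})

test_that("clustering recovers planted four-block structure on synthetic tables", {
  ef <- simulate_ef_table(sim_config(seed = 1))
  grp <- cluster_congeners(profile_distance(ef), 4)
  asg <- setNames(grp$assignments$subgroup, grp$assignments$congener)[names(truth_blocks)]
  expect_true(same_partition(asg, truth_blocks))

  sed <- simulate_study(sim_config(seed = 1))$sediments
  grp_sed <- cluster_congeners(profile_distance(sed), 4)
  asg_sed <- setNames(grp_sed$assignments$subgroup,
                      grp_sed$assignments$congener)[names(truth_blocks)]
  expect_true(same_partition(asg_sed, truth_blocks))
})

test_that("representatives maximise R2 against subgroup totals including themselves", {
  tbl <- toy_concentration(n = 10, seed = 13)
  grp <- cluster_congeners(profile_distance(tbl), 4)
  sel <- select_representatives(tbl, grp)
  expect_equal(sort(unique(sel$subgroup)), seq_len(4))
  # singleton subgroups score exactly 1
  singles <- sel$subgroup %in% sel$subgroup[sel$subgroup_size == 1]
  expect_true(all(sel$r_squared[singles] == 1))
  # the representative's R2 is the subgroup maximum
  by_grp <- split(sel, sel$subgroup)
  for (gdf in by_grp) {
    expect_equal(gdf$r_squared[gdf$representative], max(gdf$r_squared))
    expect_equal(sum(gdf$representative), 1L)
  }
})

test_that("a member tracking the subgroup total exactly is selected with R2 = 1", {
  tbl <- toy_concentration(n = 8, seed = 30)
  grp <- cluster_congeners(profile_distance(tbl), 4)
  asg <- setNames(grp$assignments$subgroup, grp$assignments$congener)
  # engineer Phe to equal half its subgroup total, holding the grouping fixed
  g <- asg[["Phe"]]
  members <- setdiff(names(asg)[asg == g], "Phe")
  expect_gt(length(members), 0)
  tbl$Phe <- rowSums(as.matrix(tbl[members])) # total = 2 * Phe in every row
  sel <- select_representatives(tbl, grp)
  row <- sel[sel$congener == "Phe", ]
  expect_true(row$representative)
  expect_equal(row$r_squared, 1, tolerance = 1e-12)
})

test_that("distances and clusters are invariant to per-congener rescaling", {
  # Pearson distance is affine-invariant, so the dendrogram cannot depend on
  # per-congener units. Representative selection is deliberately NOT
  # invariant: the subgroup total is a raw sum, so magnitudes carry
  # information there (units are uniform by the table contract).
  tbl <- toy_concentration(n = 12, seed = 44)
  scaled <- tbl
  scaled$Nap <- scaled$Nap * 1000
  scaled$DahA <- scaled$DahA * 0.001
  expect_equal(profile_distance(tbl), profile_distance(scaled), tolerance = 1e-9)
  expect_equal(cluster_congeners(profile_distance(tbl), 4)$assignments,
               cluster_congeners(profile_distance(scaled), 4)$assignments)
})

test_that("the characteristic set recovers planted representatives in panel order", {
  sed <- simulate_study(sim_config(seed = 1))$sediments
  expect_equal(characteristic_set(sed, 4), characteristic_four)
  # panel order is preserved whatever the subgroup numbering
  cs <- characteristic_set(toy_concentration(n = 10, seed = 2), 6)
  expect_equal(cs, intersect(panel, cs))
  expect_length(cs, 6)
})
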