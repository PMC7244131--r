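suit_layer <- function(m, dx = 50, crs_kind = "projected") {
  grid_layer(m, xmin = 0, ymax = nrow(m) * dx, dx = dx, crs_kind = crs_kind,
             criterion = "suitability")
}

make_ensemble <- function(offsets, mults = rep(1, length(offsets)),
                          base_values = optimal_values(), nr = 3, nc = 3) {
  baseline <- constant_stack(base_values, nr = nr, nc = nc)
  members <- lapply(seq_along(offsets), function(k) {
    tl <- baseline$layers$temperature
    rl <- baseline$layers$rainfall
    tl$values <- tl$values + offsets[k]
    rl$values <- rl$values * mults[k]
    layer_stack(list(temperature = tl, rainfall = rl))
  })
  scenario_ensemble("test", members, baseline)
}

test_that("ensemble_suitability averages member suitabilities", {
  # identical members: mean equals the single-member map
  ens <- make_ensemble(offsets = c(0, 0, 0))
  single <- suitability_map(ens$baseline, FINAL)
  expect_equal(ensemble_suitability(ens, FINAL)$values, single$values)

  # two members with pixel scores 40 and 60 average to 50:
  # temperature 36.8 scores (1 - 3.8/7)*100 ~ 45.71... use rainfall ramps
  base <- optimal_values()
  base$rainfall <- 1500
  ens2 <- make_ensemble(offsets = c(0, 0), mults = c(0.6, 0.7), base_values = base)
  # rain 900 -> (150/750)*100 = 20; rain 1050 -> 40; mean = 30
  expect_equal(ensemble_suitability(ens2, FINAL)$values[1, 1], 30)

  expect_error(scenario_ensemble("x", list(), ens$baseline), "zero members")
})

test_that("ensemble mean is bounded by per-member values", {
  set.seed(13)
  baseline <- random_stack(FINAL, nr = 6, nc = 6)
  members <- lapply(1:5, function(k) {
    tl <- baseline$layers$temperature; tl$values <- tl$values + rnorm(1, 0, 3)
    rl <- baseline$layers$rainfall; rl$values <- rl$values * runif(1, 0.7, 1.3)
    layer_stack(list(temperature = tl, rainfall = rl))
  })
  ens <- scenario_ensemble("x", members, baseline)
  per <- lapply(members, function(mem) {
    layers <- baseline$layers
    layers[names(mem$layers)] <- mem$layers
    suitability_map(layer_stack(layers), FINAL)$values
  })
  avg <- ensemble_suitability(ens, FINAL)$values
  lo <- Reduce(pmin, per); hi <- Reduce(pmax, per)
  ok <- !is.na(avg)
  expect_true(all(avg[ok] >= lo[ok] - 1e-9 & avg[ok] <= hi[ok] + 1e-9))
})

test_that("one suitable member among 17 leaves a marginal ensemble mean", {
  base <- optimal_values()
  base$temperature <- 16 # below the final profile's absolute minimum
  offsets <- c(rep(0, 16), 6) # only the last member warms into range
  ens <- make_ensemble(offsets = offsets, base_values = base)
  avg <- ensemble_suitability(ens, FINAL)$values[1, 1]
  expect_gt(avg, 0)
  expect_lte(avg, 100 / 17)
})

test_that("change_map classifies unchanged and minimal pixels", {
  m <- matrix(runif(100, 0, 100), 10, 10)
  base <- suit_layer(m)
  expect_equal(change_map(base, base)$fraction_unchanged, 1)

  up5 <- suit_layer(pmin(m + 5, 100))
  ch <- change_map(up5, base)
  expect_equal(ch$fraction_minimal, 1)
  expect_equal(ch$fraction_unchanged, 0)

  m2 <- m; m2[1, 1] <- m[1, 1] + 20
  ch2 <- change_map(suit_layer(m2), base)
  expect_equal(ch2$fraction_unchanged, 99 / 100)
  expect_equal(ch2$fraction_minimal, 0)
  expect_equal(ch2$delta$values[1, 1], 20)

  shifted <- suit_layer(m, dx = 60)
  expect_error(change_map(shifted, base), "not aligned")
})

test_that("area_table enforces structure and the <1-exclusion total", {
  tab <- area_table(TABLE3_BINS$current)
  expect_equal(unname(tab$groups[1]), sum(TABLE3_BINS$current[1:4]))
  expect_equal(unname(tab$groups[2]), sum(TABLE3_BINS$current[5:8]))
  expect_equal(unname(tab$groups[3]), sum(TABLE3_BINS$current[9:11]))
  expect_equal(tab$total, sum(TABLE3_BINS$current) - TABLE3_BINS$current[["<1"]])
  expect_equal(sum(tab$bins), sum(tab$groups))
  expect_error(area_table(1:5), "11 bin")
  expect_error(area_table(stats::setNames(rep(-1, 11), names(TABLE3_BINS$current))), ">= 0")
})

test_that("bin_areas bins by nearest integer with the <1 convention", {
  all95 <- suit_layer(matrix(95, 10, 10), dx = 1000) # 1 km^2 cells
  tab <- bin_areas(all95)
  expect_equal(unname(tab$bins[["91-100"]]), 100 / 1e6)
  expect_equal(unname(tab$total), 100 / 1e6)
  expect_equal(sum(tab$bins[names(tab$bins) != "91-100"]), 0)

  low <- suit_layer(matrix(0.4, 10, 10), dx = 1000)
  tab2 <- bin_areas(low)
  expect_equal(unname(tab2$bins[["<1"]]), 100 / 1e6)
  expect_equal(unname(tab2$total), 0)

  # boundary scores: 0.5 rounds up into 1-10; 10.5 rounds up into 11-20
  edge <- suit_layer(matrix(c(0.49, 0.5, 10.49, 10.5), 2, 2), dx = 1000)
  tabe <- bin_areas(edge)
  expect_equal(unname(tabe$bins[c("<1", "1-10", "11-20")]) * 1e6, c(1, 2, 1))

  expect_error(bin_areas(suit_layer(matrix(101, 2, 2))), "outside")
})

test_that("bin_areas conserves area and is resolution/permutation invariant", {
  set.seed(17)
  m <- matrix(runif(400, 0, 100), 20, 20)
  l <- suit_layer(m, dx = 500)
  tab <- bin_areas(l)
  total_area <- sum(cell_areas(l)) / 1e6
  expect_equal(sum(tab$bins), total_area)
  expect_equal(sum(tab$groups) + 0 * tab$total, sum(tab$bins))

  perm <- matrix(sample(as.vector(m)), 20, 20)
  expect_equal(bin_areas(suit_layer(perm, dx = 500))$bins, tab$bins)

  # doubling resolution of a uniform grid leaves areas unchanged
  u <- suit_layer(matrix(42, 5, 5), dx = 1000)
  u2 <- suit_layer(matrix(42, 10, 10), dx = 500)
  expect_equal(bin_areas(u)$bins, bin_areas(u2)$bins)
})

test_that("percent_change reports rounded percentages per group", {
  tab <- area_table(TABLE3_BINS$current)
  same <- percent_change(tab, tab)
  expect_equal(same$change_pct_rounded, c(0, 0, 0))
  fut <- area_table(TABLE3_BINS$rcp45)
  pc <- percent_change(fut, tab)
  expect_equal(pc$quantity, c("total", "moderate", "high"))
  expect_equal(pc$baseline[1], tab$total)
  zero <- area_table(stats::setNames(rep(0, 11), names(TABLE3_BINS$current)))
  expect_warning(pc0 <- percent_change(tab, zero), "zero baseline")
  expect_true(all(is.na(pc0$change_pct)))
})

test_that("mean_suitability is area-weighted", {
  expect_equal(mean_suitability(suit_layer(matrix(80, 4, 4))), 80)
  expect_equal(mean_suitability(suit_layer(matrix(c(0, 100), 1, 2))), 50)

  # geographic grid: compare against a fine equal-area subdivision oracle
  m <- matrix(seq(0, 100, length.out = 18), 18, 1)
  l <- grid_layer(m, xmin = 0, ymax = 90, dx = 10, crs_kind = "geographic")
  sub <- 100
  lat_edges <- seq(90, -90, length.out = 18 * sub + 1)
  w <- abs(diff(sin(lat_edges * pi / 180)))
  v <- rep(m[, 1], each = sub)
  expect_equal(mean_suitability(l), sum(v * w) / sum(w), tolerance = 1e-10)

  na_l <- suit_layer(matrix(NA_real_, 2, 2))
  expect_error(mean_suitability(na_l), "no valid")
})

test_that("crosstab_categorical matches an exhaustive pixel-count oracle", {
  set.seed(23)
  scores <- matrix(runif(64, 0, 100), 8, 8)
  suit <- suit_layer(scores, dx = 1000)
  ref_m <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
  ref_m[1, 1] <- NA
  ref <- grid_layer(ref_m, xmin = 0, ymax = 8000, dx = 1000, crs_kind = "projected")
  tab <- crosstab_categorical(ref, suit)

  for (cl in 0:2) {
    sel <- !is.na(ref_m) & ref_m == cl
    row <- tab[tab$class == cl, ]
    expect_equal(row$total_area_mkm2, sum(sel) * 1 / 1e6)
    expect_equal(row$mean_suitability, mean(scores[sel]))
    expect_equal(row$frac_ge90, sum(scores[sel] >= 90) / sum(sel))
  }
  # disjoint class masks partition the jointly valid area
  expect_equal(sum(tab$total_area_mkm2), 63 / 1e6)

  all_best <- grid_layer(matrix(2, 2, 2), xmin = 0, ymax = 2, dx = 1)
  hi <- suit_layer(matrix(95, 2, 2), dx = 1)
  tb <- crosstab_categorical(all_best, hi)
  expect_equal(tb$mean_suitability, 95)
  expect_equal(tb$frac_ge90, 1)

  bad <- grid_layer(matrix(3, 8, 8), xmin = 0, ymax = 8000, dx = 1000)
  expect_error(crosstab_categorical(bad, suit), "0, 1 or 2")
})

test_that("area tables round-trip through CSV", {
  tab <- area_table(TABLE3_BINS$rcp85)
  path <- file.path(withr::local_tempdir(), "areas.csv")
  write_area_table(tab, path)
  back <- read_area_table(path)
  expect_equal(back$bins, tab$bins)
  expect_equal(back$total, tab$total)
})
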