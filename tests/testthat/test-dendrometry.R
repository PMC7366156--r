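test_that("height approximation matches hand evaluation of the closed form", {
  al <- default_allometry()
  # h = 1.3 + (d/(a + b d))^3 with the spruce stand-in (a = 1.6, b = 0.335)
  expect_equal(approximate_height("spruce", 20, al),
               1.3 + (20 / (1.6 + 0.335 * 20))^3)
  expect_equal(approximate_height("pine", 12, al),
               1.3 + (12 / (1.9 + 0.345 * 12))^3)
})

test_that("height is monotone in dbh and approaches the asymptote 1.3 + b^-3", {
  al <- default_allometry()
  d <- seq(5, 80, by = 0.5)
  h <- approximate_height("deciduous", d, al)
  expect_true(all(diff(h) >= 0))
  b <- al$height$deciduous[["b"]]
  expect_equal(approximate_height("deciduous", 1e6, al), 1.3 + b^-3,
               tolerance = 1e-3)
})

test_that("missing coefficients raise an error naming the species", {
  al <- default_allometry()
  expect_error(approximate_height("larch_hybrid", 20, al), "larch_hybrid")
})

test_that("correction factor is exactly 1 when measured equals approximated height", {
  set.seed(10)
  for (uniform in c(TRUE, FALSE)) {
    n <- 10
    h <- data.frame(
      species_group = sample(c("spruce", "pine", "deciduous"), n, TRUE),
      dbh = runif(n, 5, 40), selection_prob = runif(n, 0.05, 1))
    h$height_measured <- approximate_height(h$species_group, h$dbh)
    out <- plot_correction_factors(h, uniform_weights = uniform)
    expect_equal(out$factor, rep(1, nrow(out)), tolerance = 1e-12)
  }
})

test_that("weighted correction factor reproduces hand arithmetic", {
  al <- default_allometry()
  # two spruce h-trees, dbh 20; choose measured heights so that
  # v_meas/v_app = 1.2 and 0.9; weights 2 and 1 -> (2*1.2+0.9)/(2+1) = 1.1
  h_app <- approximate_height("spruce", 20, al)
  c1 <- al$volume$spruce[["c1"]]; c2 <- al$volume$spruce[["c2"]]
  h_for_ratio <- function(rr) (rr * (c1 * h_app + c2) - c2) / c1
  h <- data.frame(species_group = "spruce", dbh = c(20, 20),
                  height_measured = c(h_for_ratio(1.2), h_for_ratio(0.9)),
                  selection_prob = c(0.5, 1))  # weights 1/pi = 2 and 1
  out <- plot_correction_factors(h)
  expect_equal(out$factor, 1.1, tolerance = 1e-12)
})

test_that("inverse-probability weighting boosts small trees' influence on the factor", {
  al <- default_allometry()
  mk <- function(dbh_perturbed, uniform) {
    h <- data.frame(species_group = "spruce", dbh = c(8, 35))
    # BAF 6: both inclusion limits are inside the plot, no probability cap
    h$selection_prob <- (h$dbh * 0.5 / sqrt(6) / sqrt(250 / pi))^2
    h$height_measured <- approximate_height("spruce", h$dbh, al)
    i <- match(dbh_perturbed, h$dbh)
    h$height_measured[i] <- h$height_measured[i] + 1
    plot_correction_factors(h, al, uniform_weights = uniform)$factor
  }
  # response ratio small/large under each weighting; inverse-probability
  # weights raise the small tree's relative influence far above uniform
  ratio_weighted <- abs(mk(8, FALSE) - 1) / abs(mk(35, FALSE) - 1)
  ratio_uniform <- abs(mk(8, TRUE) - 1) / abs(mk(35, TRUE) - 1)
  expect_gt(ratio_weighted, 10 * ratio_uniform)
  expect_gt(ratio_weighted, 0.9)  # near-equal absolute influence
})

test_that("volume back-solve round trips to better than 1 mm", {
  set.seed(12)
  for (k in 1:30) {
    sp <- sample(c("spruce", "pine", "deciduous", "sitka_spruce"), 1)
    dbh <- runif(1, 5, 60); h <- runif(1, 2, 30)
    v <- tree_volume(sp, dbh, h)
    expect_lt(abs(height_from_volume(sp, dbh, v) - h), 1e-3)
  }
})

test_that("corrected volumes back-solve to the height a bisection oracle finds", {
  al <- default_allometry()
  h_app <- approximate_height("spruce", 20, al)
  v_target <- 1.1 * tree_volume("spruce", 20, h_app, al)
  got <- height_from_volume("spruce", 20, v_target, al)
  # independent bisection
  lo <- 0; hi <- 100
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (tree_volume("spruce", 20, mid, al) < v_target) lo <- mid else hi <- mid
  }
  expect_equal(got, (lo + hi) / 2, tolerance = 1e-6)
  expect_equal(tree_volume("spruce", 20, got, al), v_target,
               tolerance = 1e-9)
})

test_that("correction factor 1 leaves the approximated height unchanged", {
  trees <- data.frame(species_group = "pine", species_code = "scots_pine",
                      dbh = c(12, 25), height_measured = NA_real_)
  out <- predict_tree_volume(trees, corrections = NULL, fallback = 1)
  expect_equal(out$height_m, approximate_height("pine", trees$dbh),
               tolerance = 1e-6)
})

test_that("species routing follows the spruce/Sitka/pine/birch rules", {
  expect_equal(route_volume_species("sitka_spruce", "spruce"), "sitka_spruce")
  expect_equal(route_volume_species("fir", "spruce"), "spruce")
  expect_equal(route_volume_species("norway_spruce", "spruce"), "spruce")
  expect_equal(route_volume_species("juniper", "pine"), "pine")
  expect_equal(route_volume_species("scots_pine", "pine"), "pine")
  expect_equal(route_volume_species("aspen", "deciduous"), "deciduous")
  # Sitka gets its own function: volumes must differ from Norway spruce
  expect_false(tree_volume("sitka_spruce", 25, 18) ==
                 tree_volume("spruce", 25, 18))
})

test_that("broken trees lose the cone-top fraction only when the break diameter is >= 10 cm", {
  trees <- data.frame(species_group = "spruce", species_code = "norway_spruce",
                      dbh = c(40, 40, 12), height_measured = 20,
                      break_rel_height = c(0.5, NA, 0.5))
  out <- predict_tree_volume(trees, fallback = 1)
  v_intact <- tree_volume("spruce", 40, 20)
  expect_equal(out$volume_m3[1], v_intact * (1 - 0.5^3))
  expect_equal(out$volume_m3[2], v_intact)
  # dbh 12 at half height -> 6 cm < 10 cm: no adjustment
  expect_equal(out$volume_m3[3], tree_volume("spruce", 12, 20))
})

test_that("growing seasons hit the 4.00 and 6.00 extremes of a 5-year cycle", {
  cal <- season_calendar(season_start = 152, season_length = 100)
  # same mid-season day-of-year, 5 years apart (leap years shift the date)
  expect_equal(growing_seasons(as.Date("2015-01-01") + 195,
                               as.Date("2020-01-01") + 195, cal), 5)
  # season start (s = 0) to season end (s = 100)
  d_start <- as.Date("2015-01-01") + 151   # day-of-year 152
  d_end <- as.Date("2020-01-01") + 251     # day-of-year 252
  expect_equal(growing_seasons(d_start, d_end, cal), 6)
  expect_equal(growing_seasons(as.Date("2015-01-01") + 251,
                               as.Date("2020-01-01") + 151, cal), 4)
})

test_that("growing seasons over n years stay within [n-1, n+1] and 5-year pairs within [4, 6]", {
  set.seed(6)
  for (k in 1:50) {
    y <- sample(1:8, 1)
    d1 <- as.Date("2010-01-01") + sample(0:364, 1)
    d2 <- as.Date(format(d1, "%Y-%m-%d"))
    d2 <- as.Date(paste0(as.integer(format(d1, "%Y")) + y,
                         format(d1, "-%m-%d")))
    if (is.na(d2)) next  # 29 Feb edge
    s <- growing_seasons(d1, d2 + sample(-100:100, 1) * 0)
    expect_gte(s, y - 1); expect_lte(s, y + 1)
  }
  for (k in 1:50) {
    d1 <- as.Date("2013-01-01") + sample(0:364, 1)
    d2 <- as.Date("2018-01-01") + sample(0:364, 1)
    s <- growing_seasons(d1, d2)
    expect_gte(s, 4); expect_lte(s, 6)
  }
})

test_that("annual increment follows the two-step dbh interpolation chain", {
  al <- default_allometry()
  expect_equal(annual_volume_increment("spruce", 20, 20, 5, al), 0)
  # dbh 20 -> 21.5 over 5.00 seasons: dbh one year back = 21.2
  got <- annual_volume_increment("spruce", 20, 21.5, 5, al)
  v <- function(d) tree_volume("spruce", d, approximate_height("spruce", d, al), al)
  expect_equal(got, v(21.5) - v(21.2), tolerance = 1e-12)
  # previous correction factor scales both terms
  got2 <- annual_volume_increment("spruce", 20, 21.5, 5, al,
                                  correction_prev = 1.2)
  expect_equal(got2, 1.2 * (v(21.5) - v(21.2)), tolerance = 1e-12)
})

test_that("population increment on a no-mortality plot matches simulated growth", {
  # deterministic growth, no mortality/harvest: summed annual increment over
  # 5 years should approximate the true simulated volume change per year
  cfg <- tiny_config(extent = c(0, 400, 0, 400), cell_size = 100,
                     stems_per_ha = c(0, 0, 600, 0, 0),
                     dynamics = list(growth_mean = 0.3, growth_sd = 0,
                                     mortality = 0, harvest_5yr = 0,
                                     ingrowth_per_ha_yr = 0))
  suppressWarnings(ls1 <- simulate_landscape(cfg))
  ls2 <- simulate_remeasurement(ls1, 5)
  t1 <- ls1$trees; t2 <- ls2$trees
  m <- match(t1$tree_id, t2$tree_id)
  al <- default_allometry()
  # per-tree annual increments under the previous height relationship
  incr <- annual_volume_increment(t1$species_group, t1$dbh, t2$dbh[m], 5, al)
  v_of <- function(tr) sum(tree_volume(
    route_volume_species(tr$species_code, tr$species_group), tr$dbh,
    approximate_height(tr$species_group, tr$dbh, al), al))
  true_annual <- (v_of(t2[m, ]) - v_of(t1)) / 5
  # the chain predicts volume at dbh_curr - delta/5; with linear-in-time
  # growth this is close to, not identical to, the mean annual change
  expect_equal(sum(incr), true_annual, tolerance = 0.05)
})

test_that("removal volume adds 2.5 years of previous increment", {
  expect_equal(removal_volume(1.00, 0.02), 1.05)
  expect_equal(removal_volume(2.5, 0), 2.5)
})

test_that("imputed dbh increments use the cell hierarchy", {
  matched <- data.frame(
    species_group = c("spruce", "spruce", "pine"),
    dbh = c(12, 13, 12), maturity_class = c(3, 3, 3),
    site_index_class = c(14, 14, 14),
    annual_dbh_incr = c(0.2, 0.4, 0.6))
  # exact cell: spruce, class 10-15 cm, young, SI 14 -> mean(0.2, 0.4)
  t1 <- data.frame(species_group = "spruce", dbh = 11, maturity_class = 2,
                   site_index_class = 14)
  expect_equal(impute_dbh_increment(t1, matched), 0.3)
  # SI missing from cells -> widened over SI
  t2 <- data.frame(species_group = "spruce", dbh = 11, maturity_class = 2,
                   site_index_class = 20)
  expect_equal(impute_dbh_increment(t2, matched), 0.3)
  # unknown species falls back to the overall mean
  t3 <- data.frame(species_group = "deciduous", dbh = 30,
                   maturity_class = 5, site_index_class = 6)
  expect_equal(impute_dbh_increment(t3, matched), mean(c(0.2, 0.4, 0.6)))
})

test_that("site index classes bin dominant height into the H40 ladder", {
  expect_equal(site_index_class(12.5), 14)  # lower edge inclusive
  expect_equal(site_index_class(15.5), 17)  # half-open upper edge
  expect_equal(site_index_class(14.0), 14)
  expect_equal(site_index_class(0.5), 6)    # clamped low
  expect_equal(site_index_class(35), 26)    # clamped high
})

test_that("stand age is the basal-area weighted mean, overstory only in two-layer stands", {
  expect_equal(stand_age(c(40, 60), c(20, 20)), 50)
  expect_equal(stand_age(c(80, 20), c(30, 10),
                         layer = c("overstory", "understory"),
                         n_layers = 2), 80)
  set.seed(2)
  ages <- runif(25, 10, 150); dbh <- runif(25, 5, 50)
  g <- pi / 4 * (dbh / 100)^2
  expect_equal(stand_age(ages, dbh), sum(g * ages) / sum(g))
  expect_error(stand_age(numeric(0), numeric(0)), "no aged trees")
  expect_equal(update_stand_age(60), 65)
  expect_equal(update_stand_age(60, harvested = TRUE), 0)
})

test_that("maturity classes honour the printed entry-age ranges", {
  tab <- default_maturity_table()
  # class-5 entry spans 40 (best site) to 120 (poorest site)
  expect_equal(unname(tab[1, "class5"]), 120)
  expect_equal(unname(tab[8, "class5"]), 40)
  expect_true(all(tab[, "class3"] >= 15 & tab[, "class3"] < 85))
  expect_true(all(tab[, "class4"] >= 25 & tab[, "class4"] < 120))
  expect_true(all(tab[, "class5"] >= 40 & tab[, "class5"] <= 120))
  # entries strictly decrease with site index within each class
  for (cl in c("class3", "class4", "class5")) {
    expect_true(all(diff(tab[, cl]) < 0))
  }
  expect_equal(maturity_class(0, "spruce", 14)$class, 1L)
  expect_equal(maturity_class(119, "spruce", 6)$class, 4L)
  expect_equal(maturity_class(120, "spruce", 6)$class, 5L)
  expect_equal(maturity_class(40, "spruce", 26)$class, 5L)
  # for fixed age, class non-decreasing in site index (exhaustive scan)
  si <- c(6, 8, 11, 14, 17, 20, 23, 26)
  for (age in seq(0, 150, by = 5)) {
    cls <- vapply(si, function(s) maturity_class(age, "pine", s)$class,
                  integer(1))
    expect_true(all(diff(cls) >= 0))
  }
})

test_that("stocking flags use crop trees in class 2 and basal area above", {
  out2 <- maturity_class(20, "spruce", 6,
                         stocking = list(crop_trees_per_ha = 1500))
  expect_equal(out2$class, 2L)
  expect_equal(out2$stocking_flag, "sufficiently")
  out5 <- maturity_class(130, "spruce", 6,
                         stocking = list(basal_area_m2ha = 4))
  expect_equal(out5$class, 5L)
  expect_equal(out5$stocking_flag, "poorly")
})

test_that("biomass matches hand evaluation, is monotone, and routes deciduous separately", {
  al <- default_allometry()
  cf <- al$biomass$conifer_above
  expect_equal(predict_biomass("spruce", 20, al)$above_kg,
               exp(cf[["c0"]] + cf[["c1"]] * 20 / (20 + cf[["k"]])))
  b <- predict_biomass("pine", seq(5, 60, by = 5), al)
  expect_true(all(diff(b$above_kg) > 0))
  expect_true(all(diff(b$below_kg) > 0))
  expect_false(predict_biomass("deciduous", 20, al)$above_kg ==
                 predict_biomass("spruce", 20, al)$above_kg)
})

test_that("fallback correction factors resolve through the key hierarchy", {
  tab <- data.frame(species_group = c("spruce", "spruce", NA),
                    maturity_group = c("young", "old", NA),
                    site_index_class = c(14, NA, NA),
                    region = c(NA, NA, NA),
                    factor = c(1.05, 1.10, 1.02))
  expect_equal(fallback_correction(tab, "spruce", 3, 14), mean(c(1.05, 1.02)))
  expect_equal(fallback_correction(tab, "spruce", 5, 20), mean(c(1.10, 1.02)))
  expect_equal(fallback_correction(tab, "pine", 4, 11), 1.02)
  expect_error(fallback_correction(tab[0, ], "pine", 4, 11), "no fallback")
})
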