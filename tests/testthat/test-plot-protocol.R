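test_that("nested plot radii follow sqrt(area/pi)", {
  g <- layout_plot(c(0, 0))
  expect_equal(round(g$tree_plot_radius, 2), 8.92)
  expect_equal(round(g$regen_subplots$radius[1], 2), 2.26)
  expect_equal(round(pi * 1.3^2, 1), 5.3)
  expect_equal(g$habitat_plot_radius, sqrt(2000 / pi))
  # subplot offsets: 12 m regen, 5 m small trees / berries
  expect_equal(sort(unique(abs(c(g$regen_subplots$x, g$regen_subplots$y)))),
               c(0, 12))
  expect_equal(sort(unique(abs(c(g$smalltree_subplots$x,
                                 g$smalltree_subplots$y)))), c(0, 5))
  # two 18 m transects through the center
  len <- with(g$transects, sqrt((x1 - x0)^2 + (y1 - y0)^2))
  expect_equal(len, c(18, 18))
})

test_that("a chord cutting off less than 37.5 m2 does not split the plot", {
  g <- layout_plot(c(0, 0))
  r <- g$tree_plot_radius
  # distance at which the segment area is exactly 30 m2 (independent solve)
  d30 <- uniroot(function(d) r^2 * acos(d / r) - d * sqrt(r^2 - d^2) - 30,
                 c(0, r - 1e-9), tol = 1e-12)$root
  parts <- split_plot(g, boundary_offset = d30 + 1e-9,
                      attributes_near = list(maturity_class = 3),
                      attributes_far = list(maturity_class = 5))
  expect_length(parts, 1)
  expect_equal(parts[[1]]$area_m2, 250, tolerance = 1e-6)
})

test_that("a diameter chord with differing stands gives two 125 m2 parts", {
  g <- layout_plot(c(0, 0))
  parts <- split_plot(g, boundary_offset = 0, boundary_azimuth = 90,
                      attributes_near = list(land_use = "forest"),
                      attributes_far = list(land_use = "other"))
  expect_length(parts, 2)
  areas <- vapply(parts, `[[`, numeric(1), "area_m2")
  expect_equal(areas, c(125, 125), tolerance = 1e-6)
})

test_that("identical stand attributes never split, whatever the chord", {
  g <- layout_plot(c(0, 0))
  parts <- split_plot(g, boundary_offset = 1,
                      attributes_near = list(maturity_class = 3,
                                             site_index_class = 14),
                      attributes_far = list(maturity_class = 3,
                                            site_index_class = 14))
  expect_length(parts, 1)
})

test_that("segment areas agree with Monte-Carlo point-in-segment integration", {
  g <- layout_plot(c(0, 0))
  r <- g$tree_plot_radius
  set.seed(77)
  for (d in c(1.5, 3.5, 5.0)) {
    parts <- split_plot(g, boundary_offset = d, boundary_azimuth = 37,
                        attributes_near = list(maturity_class = 2),
                        attributes_far = list(maturity_class = 5))
    areas <- vapply(parts, `[[`, numeric(1), "area_m2")
    expect_equal(sum(areas), 250, tolerance = 0.01)
    n <- 2e6
    az <- 37 * pi / 180
    px <- runif(n, -r, r); py <- runif(n, -r, r)
    in_disc <- px^2 + py^2 <= r^2
    far <- px * sin(az) + py * cos(az) > d
    mc_far <- (2 * r)^2 * mean(in_disc & far)
    se <- (2 * r)^2 * sd(in_disc & far) / sqrt(n)
    expect_lt(abs(areas[2] - mc_far), 4 * se)
  }
})

test_that("tree tally is boundary-inclusive at the 8.92 m radius and 5 cm dbh", {
  ctr <- c(100, 100)
  trees <- polar_trees(ctr, distance = c(8.91, 8.93, 3, 3),
                       azimuth_deg = c(0, 90, 180, 270),
                       dbh = c(12, 12, 5.0, 4.99))
  ls <- make_test_landscape(trees)
  b <- measure_plot(ls, ctr)
  expect_setequal(b$trees$tree_id, c(1L, 3L))
})

test_that("the tally equals a brute-force distance/dbh filter on random landscapes", {
  set.seed(14)
  for (k in 1:5) {
    n <- 150
    trees <- data.frame(
      tree_id = 1:n, stand_id = 1L,
      x = runif(n, 80, 120), y = runif(n, 80, 120),
      species_group = sample(c("spruce", "pine", "deciduous"), n, TRUE),
      species_code = "norway_spruce",
      dbh = runif(n, 3, 40), height = 15, height_resid = 0,
      age = 50, status = sample(c("live", "dead"), n, TRUE, c(0.9, 0.1)),
      death_cause = NA_character_, event_epoch = NA_integer_,
      has_pendant_lichens = FALSE, has_bark_lichens = FALSE,
      stringsAsFactors = FALSE)
    ls <- make_test_landscape(trees)
    b <- measure_plot(ls, c(100, 100))
    r <- sqrt(250 / pi)
    keep <- sqrt((trees$x - 100)^2 + (trees$y - 100)^2) <= r & trees$dbh >= 5
    expect_setequal(b$trees$tree_id, trees$tree_id[keep])
  }
})

test_that("ten or fewer trees are all height-measured", {
  trees <- polar_trees(c(0, 0), distance = seq(1, 8, length.out = 8),
                       azimuth_deg = seq(0, 315, by = 45), dbh = 15)
  out <- select_h_trees(trees)
  expect_true(all(out$h_tree))
  expect_equal(out$selection_prob, rep(1, 8))
  expect_true(is.na(attr(out, "baf")))
})

test_that("the angle-count inclusion limit is dbh * 50/sqrt(BAF)", {
  # 12 trees dbh 20: ladder counts force BAF 4, limit = 20*0.5/2 = 5.0 m
  trees <- polar_trees(c(0, 0), distance = c(rep(4.9, 8), rep(5.1, 4)),
                       azimuth_deg = seq(0, 330, by = 30), dbh = 20)
  out <- select_h_trees(trees)
  expect_equal(attr(out, "baf"), 4)
  expect_equal(out$h_tree, c(rep(TRUE, 8), rep(FALSE, 4)))
  # hand evaluation of the selection probability: (5/8.9206)^2
  expect_equal(out$selection_prob,
               rep(min(1, (5 / sqrt(250 / pi))^2), 12), tolerance = 1e-9)
})

test_that("selection frequency is proportional to basal area over random placements", {
  set.seed(99)
  dbhs <- c(rep(8, 11), 16)
  r <- sqrt(250 / pi)
  reps <- 1500
  sel <- matrix(FALSE, reps, 12)
  expd <- matrix(0, reps, 12)
  for (i in seq_len(reps)) {
    d <- r * sqrt(runif(12))
    trees <- data.frame(dbh = dbhs, distance = d)
    out <- select_h_trees(trees)
    baf <- attr(out, "baf")
    sel[i, ] <- out$h_tree
    expd[i, ] <- if (is.na(baf)) 1 else
      pmin(1, (dbhs * 0.5 / sqrt(baf) / r)^2)
  }
  got <- colSums(sel); want <- colSums(expd)
  se <- sqrt(colSums(expd * (1 - expd)))
  expect_true(all(abs(got - want) <= pmax(4 * se, 4)))
  # basal-area proportionality, allowing for the probability cap at 1
  ratio <- got[12] / mean(got[1:11])
  ratio_expected <- want[12] / mean(want[1:11])
  expect_lt(abs(ratio - ratio_expected) / ratio_expected, 0.2)
})

test_that("h-tree count never exceeds the count at the chosen BAF and equals n when n <= 10", {
  set.seed(3)
  for (k in 1:20) {
    n <- sample(1:40, 1)
    trees <- data.frame(dbh = runif(n, 5, 45),
                        distance = sqrt(250 / pi) * sqrt(runif(n)))
    out <- select_h_trees(trees)
    if (n <= 10) {
      expect_equal(sum(out$h_tree), n)
    } else {
      baf <- attr(out, "baf")
      expect_equal(sum(out$h_tree),
                   sum(trees$distance <= trees$dbh * 0.5 / sqrt(baf)))
    }
  }
})

test_that("deadwood transect intersections interpolate the diameter", {
  g <- layout_plot(c(0, 0))
  dw <- data.frame(piece_id = 1L, x = 3, y = -1, azimuth = 0, length = 2,
                   diam_root = 20, diam_top = 10, decay_class = 2L,
                   species_group = "pine", stringsAsFactors = FALSE)
  out <- transect_intersections(g, dw)
  expect_equal(nrow(out), 1)
  expect_equal(out$transect_id, "EW")
  expect_equal(out$diameter_at_intersection, 15)  # crossing at mid-length
  # a piece far from both transects does not intersect
  dw2 <- transform(dw, x = 50)
  expect_equal(nrow(transect_intersections(g, dw2)), 0)
})

test_that("nine chained standing dead trees on 0.2 ha trigger the habitat", {
  ctr <- c(0, 0)
  trees <- polar_trees(ctr, distance = seq(2, 18, by = 2),
                       azimuth_deg = rep(45, 9), dbh = 15, status = "dead")
  out <- classify_chi_habitats(trees, empty_deadwood())
  sd_row <- out[out$habitat == "standing_deadwood", ]
  expect_true(sd_row$present)
  expect_equal(sd_row$density_per_ha, 45)
})

test_that("an empty plot yields no habitats", {
  out <- classify_chi_habitats(empty_trees(), empty_deadwood())
  expect_false(any(out$present %in% TRUE))
})

test_that("missing lichen attributes mark categories as not assessed", {
  trees <- polar_trees(c(0, 0), distance = 5, azimuth_deg = 0, dbh = 15)
  trees$has_pendant_lichens <- NULL
  trees$has_bark_lichens <- NULL
  out <- classify_chi_habitats(trees, empty_deadwood())
  expect_false(out$assessed[out$habitat == "pendant_lichens"])
  expect_true(is.na(out$present[out$habitat == "pendant_lichens"]))
})

test_that("chaining matches an igraph components oracle and is order-invariant", {
  skip_if_not_installed("igraph")
  set.seed(8)
  for (k in 1:10) {
    n <- sample(5:25, 1)
    x <- runif(n, 0, 50); y <- runif(n, 0, 50)
    limit <- runif(1, 5, 20)
    got <- chain_patches(x, y, limit)
    d <- as.matrix(dist(cbind(x, y))) <= limit
    diag(d) <- FALSE
    gr <- igraph::graph_from_adjacency_matrix(d, mode = "undirected")
    want <- igraph::components(gr)$membership
    # same partition (label-invariant comparison)
    expect_equal(outer(got, got, "=="), outer(want, want, "=="),
                 ignore_attr = TRUE)
    perm <- sample(n)
    got_p <- chain_patches(x[perm], y[perm], limit)
    expect_equal(outer(got_p, got_p, "=="),
                 outer(want[perm], want[perm], "=="), ignore_attr = TRUE)
  }
})

test_that("CHI classification equals a brute-force rule evaluation", {
  skip_if_not_installed("igraph")
  set.seed(4)
  for (k in 1:8) {
    n <- 30
    trees <- polar_trees(c(0, 0), distance = sqrt(2000 / pi) * sqrt(runif(n)),
                         azimuth_deg = runif(n, 0, 360),
                         dbh = runif(n, 5, 45),
                         status = sample(c("live", "dead"), n, TRUE,
                                         c(0.5, 0.5)))
    trees$tree_id <- 1:n
    out <- classify_chi_habitats(trees, empty_deadwood())
    # brute force for standing deadwood: density of the densest 15 m patch
    obj <- trees[trees$status == "dead" & trees$dbh >= 10, ]
    present <- FALSE
    if (nrow(obj)) {
      d <- as.matrix(dist(cbind(obj$x, obj$y))) <= 15
      diag(d) <- FALSE
      gr <- igraph::graph_from_adjacency_matrix(d, mode = "undirected")
      biggest <- max(igraph::components(gr)$csize)
      present <- biggest / 0.2 >= 40
    }
    expect_equal(out$present[out$habitat == "standing_deadwood"], present)
  }
})

test_that("part areas and tree part assignment are consistent on a split plot", {
  ctr <- c(100, 100)
  trees <- polar_trees(ctr, distance = c(3, 3), azimuth_deg = c(0, 180),
                       dbh = c(20, 20))
  ls <- make_test_landscape(trees)
  g <- layout_plot(ctr)
  parts <- split_plot(g, boundary_offset = 1, boundary_azimuth = 0,
                      attributes_near = list(maturity_class = 3),
                      attributes_far = list(maturity_class = 5))
  b <- measure_plot(ls, ctr, parts = parts)
  expect_equal(sum(b$parts$area_m2), 250, tolerance = 0.01)
  # tree to the north (projection +3 > 1) is in part 2, south tree in part 1
  expect_equal(sort(b$trees$part_id), c(1L, 2L))
})

test_that("subplot counts and berry cover come from the containing stand", {
  ls <- make_test_landscape()
  b <- measure_plot(ls, c(100, 100))
  expect_equal(nrow(b$regen), 5)
  expect_equal(b$regen$count, rep(round(1000 * 16e-4), 5))
  expect_equal(b$smalltrees$class1,
               rep(round(600 * pi * 1.3^2 / 1e4), 4))
  expect_equal(b$berry$bilberry, rep(0.25, 4))
  expect_equal(b$droppings, 0)
})
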