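#' Nested permanent-plot geometry
#'
#' Instantiates the nested sampling units of an NFI permanent plot around a
#' center point: the 250 m^2 tree plot (radius 8.92 m), the concentric
#' 0.1 ha stand plot and 0.2 ha habitat plot, five 16 m^2 regeneration
#' subplots (center and 12 m in the cardinal directions), four 5.3 m^2
#' small-tree subplots and four 0.25 m^2 berry quadrats at 5 m in the
#' cardinal directions, two perpendicular 18 m deadwood transects (E-W and
#' N-S) through the center, and the 100 m^2 dropping-count plot. All radii
#' are `sqrt(area/pi)`.
#'
#' @param center plot center `c(x, y)` in projected m.
#' @return an object of class `plot_geometry`.
#' @export
layout_plot <- function(center = c(0, 0)) {
  stopifnot(length(center) == 2, all(is.finite(center)))
  card <- function(dist) {
    data.frame(direction = c("north", "east", "south", "west"),
               x = center[1] + c(0, dist, 0, -dist),
               y = center[2] + c(dist, 0, -dist, 0),
               stringsAsFactors = FALSE)
  }
  regen <- rbind(data.frame(direction = "center", x = center[1],
                            y = center[2], stringsAsFactors = FALSE),
                 card(12))
  structure(list(
    center = center,
    tree_plot_radius = sqrt(250 / pi),
    stand_plot_area_m2 = 1000,
    habitat_plot_radius = sqrt(2000 / pi),
    dropping_plot_radius = sqrt(100 / pi),
    regen_subplots = cbind(regen, radius = sqrt(16 / pi)),
    smalltree_subplots = cbind(card(5), radius = 1.3),
    berry_quadrats = cbind(card(5), side = 0.5),
    transect_halflength = 9,
    transects = data.frame(
      transect_id = c("EW", "NS"),
      x0 = center[1] + c(-9, 0), y0 = center[2] + c(0, -9),
      x1 = center[1] + c(9, 0), y1 = center[2] + c(0, 9),
      stringsAsFactors = FALSE)
  ), class = "plot_geometry")
}

#' @export
print.plot_geometry <- function(x, ...) {
  cat(sprintf(
    "<plot_geometry> center (%.1f, %.1f)\n  tree plot r=%.2f m (250 m2), habitat r=%.2f m (0.2 ha)\n  5 regen subplots r=%.2f m, 4 small-tree subplots r=1.30 m, 2x18 m transects\n",
    x$center[1], x$center[2], x$tree_plot_radius, x$habitat_plot_radius,
    x$regen_subplots$radius[1]))
  invisible(x)
}

#' Area of a circular segment
#'
#' Area cut off a disc of radius `r` by a chord at perpendicular distance
#' `d` from the center (the segment on the far side of the chord).
#'
#' @param r disc radius.
#' @param d chord distance from center, `0 <= d <= r`.
#' @export
circular_segment_area <- function(r, d) {
  stopifnot(all(d >= 0))
  d <- pmin(d, r)
  r^2 * acos(d / r) - d * sqrt(r^2 - d^2)
}

#' Do two stands differ enough to split a plot?
#'
#' The split triggers: different land-use category, or stands markedly
#' different in maturity class, site index class, or growing stock volume
#' (relative difference above `volume_rel_threshold`).
#'
#' @param a,b stand attribute lists/rows with (any of) `land_use`,
#'   `maturity_class`, `site_index_class`, `volume_m3_ha`.
#' @param volume_rel_threshold relative volume difference that counts as
#'   markedly different.
#' @export
attributes_differ <- function(a, b, volume_rel_threshold = 0.5) {
  neq <- function(field) {
    va <- a[[field]]; vb <- b[[field]]
    !is.null(va) && !is.null(vb) && !is.na(va) && !is.na(vb) && va != vb
  }
  if (neq("land_use") || neq("maturity_class") || neq("site_index_class")) {
    return(TRUE)
  }
  va <- a[["volume_m3_ha"]]; vb <- b[["volume_m3_ha"]]
  if (!is.null(va) && !is.null(vb) && !is.na(va) && !is.na(vb)) {
    base <- max(va, vb)
    if (base > 0 && abs(va - vb) / base > volume_rel_threshold) return(TRUE)
  }
  FALSE
}

#' Split a plot at a stand boundary
#'
#' A straight stand boundary (chord) at perpendicular distance
#' `boundary_offset` from the plot center, with outward normal azimuth
#' `boundary_azimuth`, splits the 250 m^2 tree plot into two
#' circular-segment parts if (a) both parts reach the minimum part area of
#' 37.5 m^2 (15 % of the plot) and (b) the stand attributes on the two
#' sides differ per [attributes_differ()]. Otherwise the plot stays one
#' 250 m^2 part carrying the center-side attributes.
#'
#' @param geometry a [layout_plot()] geometry.
#' @param boundary_offset chord distance from center (m); `Inf` or a value
#'   `>= tree_plot_radius` means the boundary misses the plot.
#' @param boundary_azimuth azimuth (degrees, clockwise from north) of the
#'   normal pointing from the center towards the far side.
#' @param attributes_near stand attributes on the center side.
#' @param attributes_far stand attributes beyond the boundary.
#' @param min_part_area_m2 minimum part area (37.5 m^2).
#' @return an object of class `plot_parts`: list of parts, each with
#'   `part_id`, `area_m2`, `side` (`"near"`/`"far"`) and `attributes`; the
#'   boundary is kept as attributes for point-to-part assignment.
#' @export
split_plot <- function(geometry, boundary_offset = Inf,
                       boundary_azimuth = 0, attributes_near = list(),
                       attributes_far = list(), min_part_area_m2 = 37.5) {
  r <- geometry$tree_plot_radius
  plot_area <- pi * r^2
  single <- function() {
    structure(list(list(part_id = 1L, area_m2 = plot_area, side = "near",
                        attributes = attributes_near)),
              class = "plot_parts",
              boundary_offset = Inf, boundary_azimuth = boundary_azimuth,
              center = geometry$center)
  }
  if (!is.finite(boundary_offset) || abs(boundary_offset) >= r) {
    return(single())
  }
  far_area <- circular_segment_area(r, abs(boundary_offset))
  near_area <- plot_area - far_area
  if (min(far_area, near_area) < min_part_area_m2 ||
      !attributes_differ(attributes_near, attributes_far)) {
    return(single())
  }
  structure(list(
    list(part_id = 1L, area_m2 = near_area, side = "near",
         attributes = attributes_near),
    list(part_id = 2L, area_m2 = far_area, side = "far",
         attributes = attributes_far)
  ), class = "plot_parts",
  boundary_offset = boundary_offset, boundary_azimuth = boundary_azimuth,
  center = geometry$center)
}

#' Assign points to plot parts
#'
#' @param parts a [split_plot()] result.
#' @param x,y point coordinates (m).
#' @return integer part ids.
#' @export
point_part <- function(parts, x, y) {
  off <- attr(parts, "boundary_offset")
  if (!is.finite(off) || length(parts) == 1) return(rep(1L, length(x)))
  az <- attr(parts, "boundary_azimuth") * pi / 180
  ctr <- attr(parts, "center")
  proj <- (x - ctr[1]) * sin(az) + (y - ctr[2]) * cos(az)
  ifelse(proj > off, 2L, 1L)
}

#' Height-tree subsampling by angle count
#'
#' Selects the height-measurement subsample (h-trees): if the plot holds 10
#' or fewer trees, all are selected; otherwise trees are selected by angle
#' count, tree `i` being in if its distance from the center does not exceed
#' the inclusion limit `dbh_i(cm) * 0.5 / sqrt(BAF)` m. The basal area
#' factor is the smallest of a fixed ladder whose expected count — judged
#' on the previous visit's dbh/distance data when available, else on the
#' current tally — does not exceed `max_h`.
#'
#' @param trees data.frame with `dbh` (cm) and `distance` (m from center).
#' @param previous optional data.frame with `dbh`, `distance` from the
#'   previous visit, used to choose the BAF.
#' @param baf_ladder candidate basal area factors (m^2/ha).
#' @param max_h target maximum number of h-trees.
#' @param plot_radius tree plot radius (m), for selection probabilities.
#' @return `trees` with columns `h_tree` (logical), `selection_prob`
#'   (probability of selection under a uniformly random position in the
#'   plot, proportional to basal area and capped at 1) and attribute
#'   `baf` (NA when all trees are selected).
#' @export
select_h_trees <- function(trees, previous = NULL,
                           baf_ladder = c(0.5, 1, 2, 3, 4, 6, 9),
                           max_h = 10, plot_radius = sqrt(250 / pi)) {
  n <- nrow(trees)
  if (n <= max_h) {
    trees$h_tree <- rep(TRUE, n)
    trees$selection_prob <- rep(1, n)
    attr(trees, "baf") <- NA_real_
    return(trees)
  }
  basis <- if (!is.null(previous) && nrow(previous)) previous else trees
  counts <- vapply(baf_ladder, function(b)
    sum(basis$distance <= basis$dbh * 0.5 / sqrt(b)), numeric(1))
  ok <- which(counts <= max_h)
  baf <- if (length(ok)) baf_ladder[min(ok)] else max(baf_ladder)
  limit <- trees$dbh * 0.5 / sqrt(baf)
  trees$h_tree <- trees$distance <= limit
  trees$selection_prob <- pmin(1, (limit / plot_radius)^2)
  attr(trees, "baf") <- baf
  trees
}

seg_cross <- function(x0, y0, x1, y1, x2, y2, x3, y3) {
  # intersection parameter t on segment (x0,y0)-(x1,y1) with (x2,y2)-(x3,y3)
  dx1 <- x1 - x0; dy1 <- y1 - y0
  dx2 <- x3 - x2; dy2 <- y3 - y2
  den <- dx1 * dy2 - dy1 * dx2
  if (abs(den) < 1e-12) return(NA_real_)
  t <- ((x2 - x0) * dy2 - (y2 - y0) * dx2) / den
  u <- ((x2 - x0) * dy1 - (y2 - y0) * dx1) / den
  if (t >= 0 && t <= 1 && u >= 0 && u <= 1) t else NA_real_
}

#' Deadwood intersections on the plot transects
#'
#' Finds downed pieces crossing the two 18 m transects and interpolates
#' the piece diameter at each intersection point linearly between the
#' root-end and top-end diameters.
#'
#' @param geometry a [layout_plot()] geometry.
#' @param deadwood data.frame with `x`, `y` (root end), `azimuth`
#'   (degrees), `length` (m), `diam_root`, `diam_top` (cm) and optionally
#'   `piece_id`, `species_group`, `decay_class`.
#' @return data.frame of intersections with `transect_id` and
#'   `diameter_at_intersection` (cm).
#' @export
transect_intersections <- function(geometry, deadwood) {
  out <- list()
  if (nrow(deadwood)) {
    az <- deadwood$azimuth * pi / 180
    ex <- deadwood$x + deadwood$length * sin(az)
    ey <- deadwood$y + deadwood$length * cos(az)
    for (ti in seq_len(nrow(geometry$transects))) {
      tr <- geometry$transects[ti, ]
      for (i in seq_len(nrow(deadwood))) {
        t <- seg_cross(deadwood$x[i], deadwood$y[i], ex[i], ey[i],
                       tr$x0, tr$y0, tr$x1, tr$y1)
        if (!is.na(t)) {
          d <- deadwood$diam_root[i] +
            t * (deadwood$diam_top[i] - deadwood$diam_root[i])
          rec <- data.frame(
            piece_id = if (!is.null(deadwood$piece_id))
              deadwood$piece_id[i] else i,
            transect_id = tr$transect_id,
            diameter_at_intersection = d,
            length = deadwood$length[i],
            species_group = if (!is.null(deadwood$species_group))
              deadwood$species_group[i] else NA_character_,
            decay_class = if (!is.null(deadwood$decay_class))
              deadwood$decay_class[i] else NA_integer_,
            stringsAsFactors = FALSE)
          out[[length(out) + 1L]] <- rec
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(piece_id = integer(), transect_id = character(),
                      diameter_at_intersection = numeric(),
                      length = numeric(), species_group = character(),
                      decay_class = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Union-find chaining of habitat objects
#'
#' Groups objects into patches where every member lies within `limit` m of
#' some other member (transitive chaining); the result is independent of
#' object order.
#'
#' @param x,y object coordinates.
#' @param limit chaining distance (m); `Inf` puts everything in one patch.
#' @return integer patch ids.
#' @export
chain_patches <- function(x, y, limit) {
  n <- length(x)
  if (!n) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (is.infinite(limit)) return(rep(1L, n))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= limit^2) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

chi_rules <- function(region = "south") {
  west_north <- region %in% c("west", "north")
  list(
    standing_deadwood = list(threshold = 40, chain = 15),
    downed_deadwood = list(threshold = 40, chain = 15),
    nutrient_rich_bark = list(threshold = if (west_north) 60 else 20,
                              chain = if (west_north) 15 else 25),
    pendant_lichens = list(threshold = 100, chain = Inf),
    late_successional_deciduous = list(threshold = 40, chain = Inf),
    old_trees = list(threshold = 30, chain = 20),
    luxuriant_vegetation = list(threshold = NA, chain = NA)
  )
}

#' Classify woodland key habitats on the 0.2 ha plot
#'
#' Evaluates the Complementary Hot-spot Inventory (CHI) habitat categories
#' by their density thresholds (per-ha counts on the 0.2 ha plot),
#' proximity chaining (qualifying objects within the stated distance of
#' another qualifying object form one patch; the densest patch is judged
#' against the threshold) and regional variants. A category whose
#' discriminating attribute is missing (e.g. lichen flags not recorded) is
#' reported as not assessed rather than absent. The habitat-extent rule
#' (>= 0.2 ha) is taken from the stand attribute `extent_ok`.
#'
#' @param habitat_trees data.frame of trees on the 0.2 ha plot with `x`,
#'   `y`, `dbh`, `age`, `species_group`, `species_code`, `status`, and
#'   optionally `has_pendant_lichens`, `has_bark_lichens`.
#' @param habitat_deadwood data.frame of downed pieces with `x`, `y`,
#'   `diam_root`.
#' @param region `"south"`, `"west"`, `"north"` or `"east"`.
#' @param luxuriant_vegetation stand-level flag (NA = not assessed).
#' @param extent_ok does the habitat reach the 0.2 ha minimum extent?
#' @param area_ha assessment area (0.2 ha).
#' @return data.frame with one row per category: `habitat`, `assessed`,
#'   `present`, `n_objects` (densest qualifying patch), `density_per_ha`.
#' @export
classify_chi_habitats <- function(habitat_trees, habitat_deadwood,
                                  region = "south",
                                  luxuriant_vegetation = NA,
                                  extent_ok = TRUE, area_ha = 0.2) {
  rules <- chi_rules(region)
  tr <- habitat_trees
  standing <- tr[tr$status %in% c("live", "dead"), , drop = FALSE]

  objects <- list(
    standing_deadwood = standing[standing$status == "dead" &
                                   standing$dbh >= 10, , drop = FALSE],
    downed_deadwood = habitat_deadwood[
      habitat_deadwood$diam_root >= 10, , drop = FALSE],
    nutrient_rich_bark = local({
      if (is.null(tr$has_bark_lichens)) return(NULL)
      standing[standing$status == "live" &
                 (standing$species_code %in% "maple" |
                    standing$has_bark_lichens %in% TRUE), , drop = FALSE]
    }),
    pendant_lichens = local({
      if (is.null(tr$has_pendant_lichens)) return(NULL)
      standing[standing$status == "live" &
                 standing$has_pendant_lichens %in% TRUE, , drop = FALSE]
    }),
    late_successional_deciduous = local({
      species <- c("aspen", "rowan", "grey_alder", "goat_willow",
                   "bird_cherry", "birch")
      if (region == "north") species <- "aspen"
      standing[standing$status == "live" &
                 standing$species_code %in% species &
                 standing$dbh >= 20, , drop = FALSE]
    }),
    old_trees = local({
      old <- (standing$species_group == "spruce" & standing$age >= 150) |
        (standing$species_group == "pine" & standing$age >= 200) |
        (standing$species_group == "deciduous" &
           standing$dbh >= ifelse(standing$species_code %in%
                                    c("oak", "ash", "elm", "lime", "maple"),
                                  40, 30))
      standing[standing$status == "live" & old, , drop = FALSE]
    })
  )

  rows <- lapply(names(objects), function(nm) {
    obj <- objects[[nm]]
    rule <- rules[[nm]]
    if (is.null(obj)) {
      return(data.frame(habitat = nm, assessed = FALSE, present = NA,
                        n_objects = NA_integer_, density_per_ha = NA_real_,
                        stringsAsFactors = FALSE))
    }
    n_patch <- if (nrow(obj)) {
      max(tabulate(chain_patches(obj$x, obj$y, rule$chain)))
    } else 0L
    dens <- n_patch / area_ha
    data.frame(habitat = nm, assessed = TRUE,
               present = extent_ok && dens >= rule$threshold,
               n_objects = as.integer(n_patch), density_per_ha = dens,
               stringsAsFactors = FALSE)
  })
  lux <- data.frame(habitat = "luxuriant_vegetation",
                    assessed = !is.na(luxuriant_vegetation),
                    present = if (is.na(luxuriant_vegetation)) NA else
                      extent_ok && isTRUE(luxuriant_vegetation),
                    n_objects = NA_integer_, density_per_ha = NA_real_,
                    stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), lux)
  rownames(out) <- NULL
  out
}

#' Measure one permanent plot in a landscape
#'
#' Emulates the field visit: tallies all trees with dbh >= 5 cm within the
#' 250 m^2 plot (closed disc, inclusive thresholds) with polar coordinates
#' and part assignment, selects h-trees and records their measured
#' heights, collects small-tree and regeneration counts on the subplots
#' (deterministic expected counts from the stand densities), berry cover
#' on the quadrats, deadwood transect intersections, the dropping count on
#' the 100 m^2 plot, and the CHI habitat classification on the 0.2 ha
#' plot.
#'
#' @param landscape an `nfi_landscape`.
#' @param center plot center `c(x, y)`.
#' @param parts optional [split_plot()] result; default single part.
#' @param previous optional previous-visit tree table (for BAF choice).
#' @param region CHI region.
#' @return an object of class `plot_bundle`: list with `center`, `parts`
#'   (data.frame `part_id`, `area_m2`, `side`), `stand`, `trees`,
#'   `smalltrees`, `regen`, `berry`, `deadwood`, `droppings`, `habitats`.
#' @export
measure_plot <- function(landscape, center, parts = NULL, previous = NULL,
                         region = "south") {
  geom <- layout_plot(center)
  if (is.null(parts)) parts <- split_plot(geom)
  tr <- landscape$trees
  dx <- tr$x - center[1]; dy <- tr$y - center[2]
  dist <- sqrt(dx^2 + dy^2)

  stand_at <- function(x, y) {
    sid <- raster_extract(landscape$stand_raster, x, y)
    # nearest-seed fallback for points on/over the working-lattice edge
    bad <- is.na(sid)
    if (any(bad)) {
      sid[bad] <- nearest_seed(cbind(x[bad], y[bad]),
                               cbind(landscape$stands$seed_x,
                                     landscape$stands$seed_y))
    }
    as.integer(sid)
  }
  center_stand <- landscape$stands[stand_at(center[1], center[2]), ]

  keep <- dist <= geom$tree_plot_radius & tr$dbh >= 5 &
    tr$status %in% c("live", "dead", "removed")
  tally <- tr[keep, , drop = FALSE]
  tally$distance <- dist[keep]
  tally$azimuth <- (atan2(dx[keep], dy[keep]) * 180 / pi) %% 360
  tally$part_id <- point_part(parts, tally$x, tally$y)
  standing <- tally[tally$status %in% c("live", "dead"), , drop = FALSE]
  standing <- select_h_trees(standing, previous = previous)
  tally$h_tree <- rep(FALSE, nrow(tally))
  tally$selection_prob <- rep(NA_real_, nrow(tally))
  idx <- match(standing$tree_id, tally$tree_id)
  tally$h_tree[idx] <- standing$h_tree
  tally$selection_prob[idx] <- standing$selection_prob
  tally$measured_height <- ifelse(tally$h_tree, tally$height, NA_real_)

  subplot_counts <- function(sub, col) {
    sid <- stand_at(sub$x, sub$y)
    area_ha <- pi * sub$radius^2 / 1e4
    data.frame(direction = sub$direction,
               count = round(landscape$stands[[col]][sid] * area_ha),
               stringsAsFactors = FALSE)
  }
  regen <- subplot_counts(geom$regen_subplots, "regen_per_ha")
  st1 <- subplot_counts(geom$smalltree_subplots, "smalltree1_per_ha")
  st2 <- subplot_counts(geom$smalltree_subplots, "smalltree2_per_ha")
  smalltrees <- data.frame(direction = st1$direction,
                           class1 = st1$count, class2 = st2$count,
                           stringsAsFactors = FALSE)
  bsid <- stand_at(geom$berry_quadrats$x, geom$berry_quadrats$y)
  berry <- data.frame(direction = geom$berry_quadrats$direction,
                      bilberry = landscape$stands$bilberry_cover[bsid],
                      lingonberry = landscape$stands$lingonberry_cover[bsid],
                      stringsAsFactors = FALSE)

  dw <- transect_intersections(geom, landscape$deadwood)

  ddx <- landscape$droppings$x - center[1]
  ddy <- landscape$droppings$y - center[2]
  droppings <- sum(ddx^2 + ddy^2 <= geom$dropping_plot_radius^2)

  hab_keep <- dist <= geom$habitat_plot_radius & tr$dbh >= 5
  hdx <- landscape$deadwood$x - center[1]
  hdy <- landscape$deadwood$y - center[2]
  hab_dw <- landscape$deadwood[
    sqrt(hdx^2 + hdy^2) <= geom$habitat_plot_radius, , drop = FALSE]
  habitats <- classify_chi_habitats(
    tr[hab_keep, , drop = FALSE], hab_dw, region = region,
    luxuriant_vegetation = center_stand$luxuriant_vegetation,
    extent_ok = isTRUE(center_stand$habitat_extent_ok))

  structure(list(
    center = center,
    parts = data.frame(
      part_id = vapply(parts, `[[`, integer(1), "part_id"),
      area_m2 = vapply(parts, `[[`, numeric(1), "area_m2"),
      side = vapply(parts, `[[`, character(1), "side"),
      stringsAsFactors = FALSE),
    stand = center_stand,
    trees = tally, smalltrees = smalltrees, regen = regen, berry = berry,
    deadwood = dw, droppings = droppings, habitats = habitats
  ), class = "plot_bundle")
}

#' @export
print.plot_bundle <- function(x, ...) {
  cat(sprintf(
    "<plot_bundle> center (%.0f, %.0f): %d trees (%d h-trees), %d deadwood intersections, %d habitats present\n",
    x$center[1], x$center[2], nrow(x$trees), sum(x$trees$h_tree),
    nrow(x$deadwood), sum(x$habitats$present %in% TRUE)))
  invisible(x)
}
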