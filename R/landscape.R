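#' Configuration for a synthetic forest landscape
#'
#' Bundles all parameters of the synthetic-landscape generator: the spatial
#' extent and resolution, the spherical variogram of the latent
#' (logit-scale) elevation field, the alpine stratification threshold,
#' per-stratum dominant-species mixes, stocking densities and diameter
#' distributions by maturity class, deadwood intensity, and the
#' remeasurement dynamics (growth, mortality, harvest, ingrowth).
#'
#' Defaults emulate the published structure of the Norwegian NFI sampling
#' frame: the latent elevation field uses the spherical variogram with zero
#' nugget, sill 0.73 and range 5600 m reported for the NFI stratum map, and
#' the default species mixes and forest proportions per stratum reproduce
#' the published stratum summary (e.g. stratum 4: 0/4.2/94.9/0.8 %
#' spruce/pine/deciduous/unstocked, 20.5 % forest).
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in projected m.
#' @param cell_size elevation raster resolution in m (default 16, the
#'   forest-resource-map convention).
#' @param elevation_variogram [spherical_variogram()] of the latent field.
#' @param elev_max upper end (m) of the affine logistic back-transform from
#'   the latent scale to elevation, mapping the field into (0, `elev_max`).
#' @param alpine_threshold elevation (m a.s.l.) above which land is alpine
#'   (stratum 2/4); the national thresholds range from 100 to 800 m.
#' @param finnmark_xmin if finite, land with `x >= finnmark_xmin` belongs to
#'   the Finnmark region (strata 3/4).
#' @param species_mix 4 x 4 matrix of dominant-group proportions
#'   (spruce, pine, deciduous, unstocked) by stratum 1-4; rows sum to 1.
#' @param forest_prob probability that a stand is forest, by stratum.
#' @param stand_density stand seed points per km^2 (Voronoi tessellation).
#' @param stems_per_ha expected live stems (dbh >= 5 cm) per ha by maturity
#'   class 1-5.
#' @param dbh_weibull 5 x 2 matrix (shape, scale cm) of the Weibull
#'   distribution of dbh in excess of the 5 cm caliper threshold, by
#'   maturity class.
#' @param height_sd_log log-scale SD of individual height deviations around
#'   the h-dbh curve.
#' @param deadwood_per_ha downed deadwood pieces per ha in forest.
#' @param droppings_per_ha cervid dropping patches per ha.
#' @param dynamics list with `growth_mean`, `growth_sd` (cm per growing
#'   season), `mortality` (annual probability), `harvest_5yr` (stand-level
#'   probability per 5 years), `ingrowth_per_ha_yr`.
#' @param epoch calendar year of the landscape state.
#' @param seed integer RNG seed.
#' @return an object of class `landscape_config`.
#' @export
landscape_config <- function(extent = c(0, 2000, 0, 2000),
                             cell_size = 16,
                             elevation_variogram = spherical_variogram(0, 0.73, 5600),
                             elev_max = 1500,
                             alpine_threshold = 800,
                             finnmark_xmin = Inf,
                             species_mix = default_species_mix(),
                             forest_prob = c(0.664, 0.095, 0.80, 0.205),
                             stand_density = 25,
                             stems_per_ha = c(100, 900, 1100, 800, 550),
                             dbh_weibull = default_dbh_weibull(),
                             height_sd_log = 0.07,
                             deadwood_per_ha = 8,
                             droppings_per_ha = 2,
                             dynamics = list(growth_mean = 0.3, growth_sd = 0.1,
                                             mortality = 0.005,
                                             harvest_5yr = 0.05,
                                             ingrowth_per_ha_yr = 5),
                             epoch = 2020,
                             seed = 1L) {
  species_mix <- as.matrix(species_mix)
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
            cell_size > 0,
            inherits(elevation_variogram, "variogram_model"),
            nrow(species_mix) == 4, ncol(species_mix) == 4,
            all(species_mix >= 0),
            all(abs(rowSums(species_mix) - 1) < 1e-8),
            length(forest_prob) == 4, all(forest_prob >= 0 & forest_prob <= 1),
            length(stems_per_ha) == 5, all(stems_per_ha >= 0),
            all(dbh_weibull > 0),
            dynamics$mortality >= 0, dynamics$mortality <= 1,
            dynamics$harvest_5yr >= 0, dynamics$harvest_5yr <= 1)
  structure(
    list(extent = extent, cell_size = cell_size,
         elevation_variogram = elevation_variogram, elev_max = elev_max,
         alpine_threshold = alpine_threshold, finnmark_xmin = finnmark_xmin,
         species_mix = species_mix, forest_prob = forest_prob,
         stand_density = stand_density, stems_per_ha = stems_per_ha,
         dbh_weibull = dbh_weibull, height_sd_log = height_sd_log,
         deadwood_per_ha = deadwood_per_ha,
         droppings_per_ha = droppings_per_ha,
         dynamics = dynamics, epoch = epoch, seed = as.integer(seed)),
    class = "landscape_config"
  )
}

#' @rdname landscape_config
#' @export
default_species_mix <- function() {
  m <- rbind(
    c(34.0, 33.7, 31.8, 0.6),
    c(3.6, 8.1, 87.8, 0.5),
    c(0.0, 64.2, 35.8, 0.0),
    c(0.0, 4.2, 94.9, 0.8)
  )
  colnames(m) <- c("spruce", "pine", "deciduous", "unstocked")
  rownames(m) <- paste0("stratum", 1:4)
  sweep(m, 1, rowSums(m), "/")
}

#' @rdname landscape_config
#' @export
default_dbh_weibull <- function() {
  m <- cbind(shape = c(1.4, 1.7, 2.0, 2.2, 2.3),
             scale = c(2, 5, 10, 15, 21))
  rownames(m) <- paste0("class", 1:5)
  m
}

#' Simulate the elevation raster
#'
#' Draws a Gaussian random field with the configured spherical variogram on
#' the landscape grid and back-transforms it to an elevation-like covariate
#' by the affine logistic map `elev_max * plogis(z)`; the latent field is
#' exactly recoverable as `qlogis(elev/elev_max)`. Fields with more than
#' `max_sim_nodes` cells are simulated on a coarsened lattice and
#' bilinearly interpolated to the target resolution.
#'
#' @param config a [landscape_config()].
#' @param seed RNG seed; default `config$seed`.
#' @param max_sim_nodes largest node count factorised densely.
#' @return elevation [nfi_raster()] in m.
#' @export
simulate_elevation <- function(config, seed = config$seed,
                               max_sim_nodes = 4000) {
  ex <- config$extent
  vg <- config$elevation_variogram
  if (min(ex[2] - ex[1], ex[4] - ex[3]) < vg$range) {
    warning("extent is smaller than the variogram range; ",
            "variogram parameters are not identifiable from this field")
  }
  width <- ex[2] - ex[1]; height <- ex[4] - ex[3]
  nx <- max(1L, ceiling(width / config$cell_size))
  ny <- max(1L, ceiling(height / config$cell_size))
  xs <- ex[1] + (seq_len(nx) - 0.5) * config$cell_size
  ys <- ex[3] + height - (seq_len(ny) - 0.5) * config$cell_size
  if (nx * ny <= max_sim_nodes) {
    # simulate the field at the cell centers themselves
    cells <- cbind(rep(xs, times = ny), rep(ys, each = nx))
    zz <- simulate_gaussian_field(cells, vg, seed = seed)
  } else {
    # coarsened simulation lattice, bilinear refinement to cell centers
    cs_sim <- config$cell_size
    while ((ceiling(width / cs_sim) + 1) * (ceiling(height / cs_sim) + 1) >
           max_sim_nodes) {
      cs_sim <- cs_sim * 2
    }
    sx <- seq(ex[1], ex[1] + ceiling(width / cs_sim) * cs_sim, by = cs_sim)
    sy <- seq(ex[3], ex[3] + ceiling(height / cs_sim) * cs_sim, by = cs_sim)
    nodes <- cbind(rep(sx, times = length(sy)), rep(sy, each = length(sx)))
    z <- simulate_gaussian_field(nodes, vg, seed = seed)
    zr <- nfi_raster(matrix(z[order(-nodes[, 2], nodes[, 1])],
                            nrow = length(sy), ncol = length(sx),
                            byrow = TRUE),
                     ex[1] - cs_sim / 2, ex[3] - cs_sim / 2, cs_sim)
    zz <- raster_interpolate(zr, rep(xs, times = ny), rep(ys, each = nx))
  }
  elev <- config$elev_max * stats::plogis(zz)
  nfi_raster(matrix(elev, nrow = ny, ncol = nx, byrow = TRUE),
             ex[1], ex[3], config$cell_size)
}

#' Simulate stands, trees, deadwood and droppings
#'
#' Builds the forest state on top of an elevation raster: stand seed points
#' are placed as a homogeneous Poisson process and the landscape is
#' partitioned into stands by nearest-seed (Voronoi) assignment on a
#' working lattice; each stand gets a stratum (elevation/region rule), a
#' land use, a dominant species group (drawn from the per-stratum mix, with
#' individual trees following the dominant group with 90 % fidelity), a
#' site index class, a stand age and the maturity class implied by the
#' class-entry table. Tree positions are homogeneous Poisson within stands;
#' dbh is 5 cm plus a Weibull excess by maturity class; heights follow the
#' h-dbh curve with lognormal individual deviations (kept as residuals so
#' remeasurement preserves them). Downed deadwood pieces and cervid
#' dropping patches are independent Poisson point processes in forest.
#'
#' @param config a [landscape_config()].
#' @param elevation elevation raster from [simulate_elevation()]; simulated
#'   on the fly if `NULL`.
#' @param seed RNG seed; default `config$seed + 1`.
#' @param allometry an [allometry_set()] for tree heights.
#' @param stand_cell working lattice resolution (m) for stand areas.
#' @return an object of class `nfi_landscape`: list with `config`, `epoch`,
#'   `elevation`, `stands`, `trees`, `deadwood`, `droppings`,
#'   `stand_raster`.
#' @export
simulate_forest <- function(config, elevation = NULL,
                            seed = config$seed + 1L,
                            allometry = default_allometry(),
                            stand_cell = 25) {
  if (is.null(elevation)) elevation <- simulate_elevation(config)
  set.seed(seed)
  ex <- config$extent
  area_km2 <- (ex[2] - ex[1]) * (ex[4] - ex[3]) / 1e6

  n_stand <- max(1L, stats::rpois(1, config$stand_density * area_km2))
  seeds <- cbind(x = stats::runif(n_stand, ex[1], ex[2]),
                 y = stats::runif(n_stand, ex[3], ex[4]))

  # nearest-seed partition on a working lattice -> stand areas + membership
  nx <- max(1L, ceiling((ex[2] - ex[1]) / stand_cell))
  ny <- max(1L, ceiling((ex[4] - ex[3]) / stand_cell))
  cx <- ex[1] + (seq_len(nx) - 0.5) * stand_cell
  cy <- ex[3] + (seq_len(ny) - 0.5) * stand_cell
  cells <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  cell_stand <- nearest_seed(cells, seeds)
  cell_area <- stand_cell^2

  elev_seed <- raster_interpolate(elevation, seeds[, 1], seeds[, 2])
  finnmark <- seeds[, 1] >= config$finnmark_xmin
  alpine <- elev_seed >= config$alpine_threshold
  stratum <- ifelse(finnmark, ifelse(alpine, 4L, 3L), ifelse(alpine, 2L, 1L))

  land_use <- ifelse(stats::runif(n_stand) < config$forest_prob[stratum],
                     "forest", "other")
  dom <- character(n_stand)
  groups <- colnames(config$species_mix)
  for (s in 1:4) {
    idx <- which(stratum == s)
    if (length(idx))
      dom[idx] <- sample(groups, length(idx), replace = TRUE,
                         prob = config$species_mix[s, ])
  }
  dom[land_use != "forest"] <- NA_character_

  si_ladder <- c(6, 8, 11, 14, 17, 20, 23, 26)
  # productivity declines with elevation
  si_w <- function(e) {
    pos <- pmax(1, 8 - floor(e / 180))
    pmax(stats::dnorm(seq_len(8), mean = pos, sd = 1.5), 1e-6)
  }
  site_index <- vapply(elev_seed, function(e)
    sample(si_ladder, 1, prob = si_w(e)), numeric(1))
  stand_age <- round(stats::runif(n_stand, 0, 150))
  stand_age[dom %in% "unstocked"] <- 0L
  mature <- mapply(function(a, sp, si) maturity_class(a, sp, si)$class,
                   stand_age, ifelse(is.na(dom) | dom == "unstocked",
                                     "deciduous", dom), site_index)
  stands <- data.frame(
    stand_id = seq_len(n_stand), seed_x = seeds[, 1], seed_y = seeds[, 2],
    area_m2 = as.numeric(tabulate(cell_stand, n_stand)) * cell_area,
    elevation = elev_seed, stratum = stratum, land_use = land_use,
    dominant_species = dom, site_index_class = site_index,
    stand_age = stand_age, maturity_class = as.integer(mature),
    bilberry_cover = stats::rbeta(n_stand, 2, 5),
    lingonberry_cover = stats::rbeta(n_stand, 2, 8),
    habitat_extent_ok = stats::runif(n_stand) < 0.8,
    luxuriant_vegetation = stats::runif(n_stand) < 0.03,
    regen_per_ha = round(stats::rgamma(n_stand, 2, scale = 800)),
    smalltree1_per_ha = round(stats::rgamma(n_stand, 2, scale = 500)),
    smalltree2_per_ha = round(stats::rgamma(n_stand, 2, scale = 300)),
    stringsAsFactors = FALSE
  )
  stands$bilberry_cover[stands$land_use != "forest"] <- 0
  stands$lingonberry_cover[stands$land_use != "forest"] <- 0

  trees <- simulate_trees(config, stands, cells, cell_stand, cell_area,
                          allometry)
  deadwood <- simulate_deadwood(config, stands, cells, cell_stand, cell_area)
  n_drop <- stats::rpois(1, config$droppings_per_ha * area_km2 * 100)
  droppings <- data.frame(x = stats::runif(n_drop, ex[1], ex[2]),
                          y = stats::runif(n_drop, ex[3], ex[4]))

  structure(
    list(config = config, epoch = config$epoch, elevation = elevation,
         stands = stands, trees = trees, deadwood = deadwood,
         droppings = droppings,
         stand_raster = nfi_raster(
           matrix(cell_stand[order(-cells[, 2], cells[, 1])],
                  nrow = ny, ncol = nx, byrow = TRUE),
           ex[1], ex[3], stand_cell)),
    class = "nfi_landscape"
  )
}

nearest_seed <- function(points, seeds, chunk = 5000L) {
  n <- nrow(points)
  out <- integer(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(points[idx, 1], seeds[, 1], "-")^2 +
      outer(points[idx, 2], seeds[, 2], "-")^2
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}

simulate_trees <- function(config, stands, cells, cell_stand, cell_area,
                           allometry) {
  groups <- c("spruce", "pine", "deciduous")
  rows <- vector("list", nrow(stands))
  for (i in seq_len(nrow(stands))) {
    st <- stands[i, ]
    if (st$land_use != "forest" || st$area_m2 == 0) next
    dens <- config$stems_per_ha[st$maturity_class] / 1e4  # per m2
    if (identical(st$dominant_species, "unstocked")) dens <- dens * 0.1
    n <- stats::rpois(1, dens * st$area_m2)
    if (n == 0) next
    own <- which(cell_stand == st$stand_id)
    pick <- own[sample.int(length(own), n, replace = TRUE)]
    half <- sqrt(cell_area) / 2
    x <- cells[pick, 1] + stats::runif(n, -half, half)
    y <- cells[pick, 2] + stats::runif(n, -half, half)
    wb <- config$dbh_weibull[st$maturity_class, ]
    dbh <- 5 + stats::rweibull(n, shape = wb[1], scale = wb[2])
    if (is.na(st$dominant_species) || st$dominant_species == "unstocked") {
      sp <- sample(groups, n, replace = TRUE)
    } else {
      keep <- stats::runif(n) < 0.9
      sp <- ifelse(keep, st$dominant_species,
                   sample(groups, n, replace = TRUE))
    }
    code <- species_code_for(sp)
    resid <- stats::rnorm(n, 0, config$height_sd_log)
    h <- approximate_height(sp, dbh, allometry) * exp(resid)
    age <- pmax(5, round(st$stand_age + stats::rnorm(n, 0, 5)))
    status <- ifelse(stats::runif(n) < 0.03, "dead", "live")
    rows[[i]] <- data.frame(
      stand_id = st$stand_id, x = x, y = y, species_group = sp,
      species_code = code, dbh = dbh, height = h, height_resid = resid,
      age = age, status = status, death_cause = NA_character_,
      event_epoch = NA_integer_,
      has_pendant_lichens = stats::runif(n) < 0.02,
      has_bark_lichens = stats::runif(n) < 0.01,
      stringsAsFactors = FALSE
    )
  }
  trees <- do.call(rbind, rows)
  if (is.null(trees)) {
    trees <- data.frame(stand_id = integer(), x = numeric(), y = numeric(),
                        species_group = character(),
                        species_code = character(), dbh = numeric(),
                        height = numeric(), height_resid = numeric(),
                        age = numeric(), status = character(),
                        death_cause = character(),
                        event_epoch = integer(),
                        has_pendant_lichens = logical(),
                        has_bark_lichens = logical(),
                        stringsAsFactors = FALSE)
  }
  trees <- cbind(tree_id = seq_len(nrow(trees)), trees)
  rownames(trees) <- NULL
  trees
}

species_code_for <- function(group) {
  n <- length(group)
  code <- character(n)
  u <- stats::runif(n)
  code[group == "spruce"] <- ifelse(u[group == "spruce"] < 0.03, "sitka_spruce",
                                    ifelse(u[group == "spruce"] < 0.06, "fir",
                                           "norway_spruce"))
  code[group == "pine"] <- ifelse(u[group == "pine"] < 0.05, "juniper",
                                  "scots_pine")
  code[group == "deciduous"] <- c("birch", "aspen", "rowan", "grey_alder",
                                  "goat_willow")[
    findInterval(u[group == "deciduous"], c(0.7, 0.8, 0.9, 0.95)) + 1L]
  code
}

simulate_deadwood <- function(config, stands, cells, cell_stand, cell_area) {
  forest <- stands$land_use == "forest"
  area_forest <- sum(stands$area_m2[forest])
  n <- stats::rpois(1, config$deadwood_per_ha * area_forest / 1e4)
  empty <- data.frame(piece_id = integer(), stand_id = integer(),
                      x = numeric(), y = numeric(), azimuth = numeric(),
                      length = numeric(), diam_root = numeric(),
                      diam_top = numeric(), decay_class = integer(),
                      species_group = character(), stringsAsFactors = FALSE)
  if (n == 0 || area_forest == 0) return(empty)
  forest_cells <- which(cell_stand %in% stands$stand_id[forest])
  if (!length(forest_cells)) return(empty)
  pick <- forest_cells[sample.int(length(forest_cells), n, replace = TRUE)]
  half <- sqrt(cell_area) / 2
  x <- cells[pick, 1] + stats::runif(n, -half, half)
  y <- cells[pick, 2] + stats::runif(n, -half, half)
  sid <- cell_stand[pick]
  dom <- stands$dominant_species[sid]
  dom[is.na(dom) | dom == "unstocked"] <- "deciduous"
  data.frame(
    piece_id = seq_len(n), stand_id = sid, x = x, y = y,
    azimuth = stats::runif(n, 0, 360),
    length = 1 + stats::rexp(n, 1 / 3),
    diam_root = 10 + stats::rweibull(n, 1.8, 10),
    diam_top = NA_real_, decay_class = sample(1:5, n, replace = TRUE),
    species_group = dom, stringsAsFactors = FALSE
  ) -> dw
  dw$diam_top <- dw$diam_root * stats::runif(n, 0.2, 0.5)
  dw
}

#' @export
print.nfi_landscape <- function(x, ...) {
  ex <- x$config$extent
  cat(sprintf(
    "<nfi_landscape> epoch %d, %.3g km x %.3g km\n  %d stands (%d forest), %d trees (%d live), %d deadwood pieces\n",
    x$epoch, (ex[2] - ex[1]) / 1000, (ex[4] - ex[3]) / 1000,
    nrow(x$stands), sum(x$stands$land_use == "forest"),
    nrow(x$trees), sum(x$trees$status == "live"), nrow(x$deadwood)))
  invisible(x)
}

#' Simulate a full landscape
#'
#' Convenience wrapper: [simulate_elevation()] then [simulate_forest()].
#'
#' @inheritParams simulate_forest
#' @export
simulate_landscape <- function(config, allometry = default_allometry(),
                               stand_cell = 25) {
  elev <- simulate_elevation(config)
  simulate_forest(config, elev, allometry = allometry,
                  stand_cell = stand_cell)
}

#' Advance a landscape by remeasurement dynamics
#'
#' Applies `years` annual steps of growth, mortality, stand-level harvest
#' and ingrowth, returning the landscape at `epoch + years`. Surviving
#' trees accumulate one Gaussian diameter increment per growing season;
#' trees dying keep their last diameter and are flagged with a death cause
#' and epoch; harvested stands have all trees flagged `removed` with the
#' removal epoch and restart at age 0; ingrowth enters at the 5 cm caliper
#' threshold. Heights are re-derived from the h-dbh curve keeping each
#' tree's individual lognormal residual. The input landscape is not
#' modified, so differencing the two epochs yields the increment,
#' mortality and removal components exactly (survivors + ingrowth = new
#' state; survivors + dead + removed = old live state).
#'
#' @param landscape an `nfi_landscape`.
#' @param years number of annual steps (> 0).
#' @param seed RNG seed; default derived from the config seed and epoch.
#' @param allometry an [allometry_set()] for height updates.
#' @return the advanced `nfi_landscape`.
#' @export
simulate_remeasurement <- function(landscape, years,
                                   seed = landscape$config$seed + 97L +
                                     landscape$epoch %% 1000L,
                                   allometry = default_allometry()) {
  stopifnot(inherits(landscape, "nfi_landscape"), years > 0)
  set.seed(seed)
  cfg <- landscape$config
  dyn <- cfg$dynamics
  trees <- landscape$trees
  stands <- landscape$stands
  p_harv_yr <- 1 - (1 - dyn$harvest_5yr)^(1 / 5)
  next_id <- if (nrow(trees)) max(trees$tree_id) + 1L else 1L
  harvested <- logical(nrow(stands))

  for (step in seq_len(years)) {
    year <- landscape$epoch + step
    live <- trees$status == "live"
    # stand harvest
    forest <- stands$land_use == "forest"
    hit <- forest & stats::runif(nrow(stands)) < p_harv_yr
    if (any(hit)) {
      rem <- live & trees$stand_id %in% stands$stand_id[hit]
      trees$status[rem] <- "removed"
      trees$death_cause[rem] <- "harvest"
      trees$event_epoch[rem] <- year
      harvested <- harvested | hit
      live <- trees$status == "live"
    }
    # mortality
    die <- live & stats::runif(nrow(trees)) < dyn$mortality
    if (any(die)) {
      trees$status[die] <- "dead"
      trees$death_cause[die] <- "mortality"
      trees$event_epoch[die] <- year
      live <- trees$status == "live"
    }
    # growth
    n_live <- sum(live)
    if (n_live) {
      trees$dbh[live] <- trees$dbh[live] +
        stats::rnorm(n_live, dyn$growth_mean, dyn$growth_sd)
    }
    # ingrowth
    open <- which(forest & !hit)
    if (length(open) && dyn$ingrowth_per_ha_yr > 0) {
      lam <- dyn$ingrowth_per_ha_yr * stands$area_m2[open] / 1e4
      n_new <- stats::rpois(length(open), lam)
      tot <- sum(n_new)
      if (tot) {
        sid <- rep(stands$stand_id[open], n_new)
        newt <- place_ingrowth(landscape, sid, next_id, year, cfg)
        next_id <- next_id + tot
        trees <- rbind(trees, newt)
      }
    }
  }
  live <- trees$status == "live"
  trees$height[live] <- approximate_height(trees$species_group[live],
                                           trees$dbh[live], allometry) *
    exp(trees$height_resid[live])
  trees$age[live] <- trees$age[live] + years

  stands$stand_age <- ifelse(harvested, pmax(0, years - 1),
                             stands$stand_age + years)
  keep_sp <- ifelse(is.na(stands$dominant_species) |
                      stands$dominant_species == "unstocked",
                    "deciduous", stands$dominant_species)
  stands$maturity_class <- as.integer(mapply(
    function(a, sp, si) maturity_class(a, sp, si)$class,
    stands$stand_age, keep_sp, stands$site_index_class))

  out <- landscape
  out$trees <- trees
  out$stands <- stands
  out$epoch <- landscape$epoch + years
  out
}

place_ingrowth <- function(landscape, stand_ids, next_id, year, cfg) {
  stands <- landscape$stands
  n <- length(stand_ids)
  idx <- match(stand_ids, stands$stand_id)
  # uniform position near the stand seed, clipped to the extent
  r <- sqrt(pmax(stands$area_m2[idx], 100) / pi) * sqrt(stats::runif(n))
  a <- stats::runif(n, 0, 2 * pi)
  ex <- cfg$extent
  x <- pmin(pmax(stands$seed_x[idx] + r * cos(a), ex[1]), ex[2])
  y <- pmin(pmax(stands$seed_y[idx] + r * sin(a), ex[3]), ex[4])
  dom <- stands$dominant_species[idx]
  dom[is.na(dom) | dom == "unstocked"] <- "deciduous"
  keep <- stats::runif(n) < 0.9
  sp <- ifelse(keep, dom,
               sample(c("spruce", "pine", "deciduous"), n, replace = TRUE))
  dbh <- 5 + stats::rexp(n, 1 / 0.3)
  resid <- stats::rnorm(n, 0, cfg$height_sd_log)
  data.frame(
    tree_id = next_id + seq_len(n) - 1L, stand_id = stand_ids, x = x, y = y,
    species_group = sp, species_code = species_code_for(sp), dbh = dbh,
    height = NA_real_, height_resid = resid,
    age = 5, status = "live", death_cause = NA_character_,
    event_epoch = year,
    has_pendant_lichens = FALSE, has_bark_lichens = FALSE,
    stringsAsFactors = FALSE
  )
}
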