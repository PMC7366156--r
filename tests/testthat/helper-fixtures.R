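# Fixture builders: all test data is generated in code.

empty_trees <- function() {
  data.frame(tree_id = integer(), stand_id = integer(), x = numeric(),
             y = numeric(), species_group = character(),
             species_code = character(), dbh = numeric(),
             height = numeric(), height_resid = numeric(), age = numeric(),
             status = character(), death_cause = character(),
             event_epoch = integer(), has_pendant_lichens = logical(),
             has_bark_lichens = logical(), stringsAsFactors = FALSE)
}

empty_deadwood <- function() {
  data.frame(piece_id = integer(), stand_id = integer(), x = numeric(),
             y = numeric(), azimuth = numeric(), length = numeric(),
             diam_root = numeric(), diam_top = numeric(),
             decay_class = integer(), species_group = character(),
             stringsAsFactors = FALSE)
}

# a hand-built single-stand landscape for protocol tests
make_test_landscape <- function(trees = empty_trees(),
                                deadwood = empty_deadwood(),
                                droppings = data.frame(x = numeric(),
                                                       y = numeric()),
                                extent = c(0, 200, 0, 200),
                                land_use = "forest",
                                luxuriant_vegetation = FALSE,
                                habitat_extent_ok = TRUE) {
  cfg <- landscape_config(extent = extent, cell_size = max(extent) / 4,
                          seed = 1)
  stands <- data.frame(
    stand_id = 1L, seed_x = mean(extent[1:2]), seed_y = mean(extent[3:4]),
    area_m2 = (extent[2] - extent[1]) * (extent[4] - extent[3]),
    elevation = 300, stratum = 1L, land_use = land_use,
    dominant_species = "spruce", site_index_class = 14, stand_age = 60,
    maturity_class = 3L, bilberry_cover = 0.25, lingonberry_cover = 0.1,
    habitat_extent_ok = habitat_extent_ok,
    luxuriant_vegetation = luxuriant_vegetation,
    regen_per_ha = 1000, smalltree1_per_ha = 600, smalltree2_per_ha = 400,
    stringsAsFactors = FALSE)
  nx <- 4L
  structure(list(
    config = cfg, epoch = 2020,
    elevation = nfi_raster(matrix(300, nx, nx), extent[1], extent[3],
                           (extent[2] - extent[1]) / nx),
    stands = stands, trees = trees, deadwood = deadwood,
    droppings = droppings,
    stand_raster = nfi_raster(matrix(1L, nx, nx), extent[1], extent[3],
                              (extent[2] - extent[1]) / nx)),
    class = "nfi_landscape")
}

# tree-record rows around a plot center, by polar position
polar_trees <- function(center, distance, azimuth_deg, dbh,
                        species_group = "spruce", status = "live",
                        age = 60, height = NULL, species_code = NULL,
                        pendant = FALSE, bark = FALSE) {
  n <- max(length(distance), length(dbh), length(azimuth_deg))
  distance <- rep_len(distance, n); azimuth_deg <- rep_len(azimuth_deg, n)
  dbh <- rep_len(dbh, n)
  species_group <- rep_len(species_group, n)
  status <- rep_len(status, n)
  if (is.null(species_code)) {
    species_code <- c(spruce = "norway_spruce", pine = "scots_pine",
                      deciduous = "birch")[species_group]
  }
  if (is.null(height)) {
    height <- approximate_height(species_group, dbh)
  }
  a <- azimuth_deg * pi / 180
  data.frame(
    tree_id = seq_len(n), stand_id = 1L, distance = distance,
    x = center[1] + distance * sin(a), y = center[2] + distance * cos(a),
    species_group = species_group, species_code = unname(species_code),
    dbh = dbh, height = rep_len(height, n),
    height_resid = 0, age = rep_len(age, n), status = status,
    death_cause = NA_character_, event_epoch = NA_integer_,
    has_pendant_lichens = rep_len(pendant, n),
    has_bark_lichens = rep_len(bark, n), stringsAsFactors = FALSE)
}

# fast low-density config for full-generator tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(extent = c(0, 1000, 0, 1000), cell_size = 100,
                   alpine_threshold = 1200, stand_density = 15,
                   stems_per_ha = c(20, 120, 150, 120, 80),
                   deadwood_per_ha = 4, seed = 42)
  do.call(landscape_config, utils::modifyList(defaults, args))
}
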