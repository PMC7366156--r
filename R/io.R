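#' Lossless plain-text table I/O
#'
#' CSV writer/reader pair used for all plot and landscape tables. Doubles
#' are serialised with 17 significant digits so that a write-then-read
#' round trip reproduces every value bit-exactly; column types are stored
#' in a sidecar schema (JSON) per directory. Missing character values are
#' written as the empty string.
#'
#' @param df data.frame with numeric, integer, logical or character
#'   columns.
#' @param path output file.
#' @keywords internal
write_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    col <- out[[j]]
    out[[j]] <- switch(class(col)[1],
      numeric = ifelse(is.na(col), "NA", sprintf("%.17g", col)),
      integer = ifelse(is.na(col), "NA", as.character(col)),
      logical = ifelse(is.na(col), "NA", as.character(col)),
      ifelse(is.na(col), "", enc2utf8(as.character(col)))
    )
  }
  utils::write.table(out, path, sep = ",", quote = TRUE, qmethod = "double",
                     row.names = FALSE, fileEncoding = "UTF-8")
  vapply(df, function(c) class(c)[1], character(1))
}

read_table <- function(path, types) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8", na.strings = NULL)
  stopifnot(identical(names(raw), names(types)))
  for (j in seq_along(raw)) {
    col <- raw[[j]]
    raw[[j]] <- switch(types[[j]],
      numeric = as.numeric(ifelse(col == "NA", NA, col)),
      integer = as.integer(ifelse(col == "NA", NA, col)),
      logical = as.logical(ifelse(col == "NA", NA, col)),
      { col[col == ""] <- NA_character_; col }
    )
  }
  raw
}

#' Write / read a set of named tables with a schema sidecar
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @return `write_tables()`: the directory; `read_tables()`: the named
#'   list of data.frames, value-identical to what was written.
#' @export
write_tables <- function(tables, dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  schema <- lapply(tables, function(df) {
    as.list(vapply(df, function(c) class(c)[1], character(1)))
  })
  for (nm in names(tables)) {
    write_table(tables[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(schema, file.path(dir, "schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_tables
#' @export
read_tables <- function(dir) {
  schema <- jsonlite::read_json(file.path(dir, "schema.json"))
  out <- lapply(names(schema), function(nm) {
    read_table(file.path(dir, paste0(nm, ".csv")),
               lapply(schema[[nm]], as.character))
  })
  names(out) <- names(schema)
  out
}

#' Flatten measured plot bundles to relational tables
#'
#' Turns a list of [measure_plot()] bundles into the flat CSV-ready tables
#' (`plots`, `parts`, `trees`, `smalltrees`, `regen`, `berry`, `deadwood`,
#' `habitats`), each keyed by `plot_id`.
#'
#' @param bundles named or unnamed list of `plot_bundle`s; plot ids default
#'   to the list index.
#' @param plot_ids integer ids, one per bundle.
#' @return named list of data.frames.
#' @export
bundles_to_tables <- function(bundles, plot_ids = seq_along(bundles)) {
  stopifnot(length(bundles) == length(plot_ids))
  add_id <- function(df, id) {
    if (nrow(df)) cbind(plot_id = id, df) else cbind(plot_id = integer(0), df)
  }
  pull <- function(field) {
    do.call(rbind, lapply(seq_along(bundles), function(i)
      add_id(bundles[[i]][[field]], plot_ids[i])))
  }
  plots <- do.call(rbind, lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    data.frame(plot_id = plot_ids[i], x = b$center[1], y = b$center[2],
               droppings = b$droppings,
               stand_id = b$stand$stand_id,
               land_use = b$stand$land_use,
               stratum = b$stand$stratum,
               site_index_class = b$stand$site_index_class,
               stand_age = b$stand$stand_age,
               maturity_class = b$stand$maturity_class,
               stringsAsFactors = FALSE)
  }))
  list(plots = plots, parts = pull("parts"), trees = pull("trees"),
       smalltrees = pull("smalltrees"), regen = pull("regen"),
       berry = pull("berry"), deadwood = pull("deadwood"),
       habitats = pull("habitats"))
}

serialize_config <- function(config) {
  vg <- config$elevation_variogram
  out <- unclass(config)
  out$elevation_variogram <- list(kind = vg$kind, nugget = vg$nugget,
                                  sill = vg$sill, range = vg$range)
  out$species_mix <- as.list(as.data.frame(config$species_mix))
  out$dbh_weibull <- as.list(as.data.frame(config$dbh_weibull))
  out$finnmark_xmin <- if (is.finite(config$finnmark_xmin))
    config$finnmark_xmin else "Inf"
  out
}

deserialize_config <- function(lst) {
  vg <- lst$elevation_variogram
  landscape_config(
    extent = unlist(lst$extent), cell_size = lst$cell_size,
    elevation_variogram = spherical_variogram(vg$nugget, vg$sill, vg$range),
    elev_max = lst$elev_max, alpine_threshold = lst$alpine_threshold,
    finnmark_xmin = if (identical(lst$finnmark_xmin, "Inf")) Inf else
      lst$finnmark_xmin,
    # renormalise rows against YAML rounding of the stored doubles
    species_mix = local({
      m <- do.call(cbind, lapply(lst$species_mix, unlist))
      sweep(m, 1, rowSums(m), "/")
    }),
    forest_prob = unlist(lst$forest_prob),
    stand_density = lst$stand_density,
    stems_per_ha = unlist(lst$stems_per_ha),
    dbh_weibull = do.call(cbind, lapply(lst$dbh_weibull, unlist)),
    height_sd_log = lst$height_sd_log,
    deadwood_per_ha = lst$deadwood_per_ha,
    droppings_per_ha = lst$droppings_per_ha,
    dynamics = lst$dynamics, epoch = lst$epoch, seed = lst$seed
  )
}

#' Write / read a landscape directory
#'
#' Serialises an `nfi_landscape` as plain text: tables (trees, stands,
#' deadwood, droppings) as CSV with a schema sidecar, the elevation and
#' stand rasters as ESRI ASCII grids, the configuration as YAML, and the
#' stand seed points as a GeoJSON point collection.
#'
#' @param landscape an `nfi_landscape`.
#' @param dir target directory.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tables(list(trees = landscape$trees, stands = landscape$stands,
                    deadwood = landscape$deadwood,
                    droppings = landscape$droppings), dir)
  write_asc(landscape$elevation, file.path(dir, "elevation.asc"))
  write_asc(landscape$stand_raster, file.path(dir, "stand_raster.asc"))
  cfg <- serialize_config(landscape$config)
  cfg$.epoch <- landscape$epoch
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"), precision = 12)
  write_stands_geojson(landscape, file.path(dir, "stands.geojson"))
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  tabs <- read_tables(dir)
  cfg_l <- yaml::read_yaml(file.path(dir, "config.yaml"))
  epoch <- cfg_l$.epoch
  cfg_l$.epoch <- NULL
  structure(list(
    config = deserialize_config(cfg_l), epoch = epoch,
    elevation = read_asc(file.path(dir, "elevation.asc")),
    stands = tabs$stands, trees = tabs$trees, deadwood = tabs$deadwood,
    droppings = tabs$droppings,
    stand_raster = read_asc(file.path(dir, "stand_raster.asc"))
  ), class = "nfi_landscape")
}

#' GeoJSON writers for stands, plot locations and design blocks
#'
#' Minimal GeoJSON (planar coordinates) for interoperability: stand seed
#' points with their attributes, plot locations as points, Latin-square
#' blocks as rectangular polygons.
#'
#' @param landscape an `nfi_landscape`.
#' @param path output file.
#' @export
write_stands_geojson <- function(landscape, path) {
  st <- landscape$stands
  feats <- lapply(seq_len(nrow(st)), function(i) {
    props <- as.list(st[i, setdiff(names(st), c("seed_x", "seed_y"))])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(st$seed_x[i], st$seed_y[i])),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stands_geojson
#' @param blocks data.frame from [tessellate_latin_squares()].
#' @export
write_blocks_geojson <- function(blocks, path) {
  feats <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    ring <- list(c(b$xmin, b$ymin), c(b$xmax, b$ymin), c(b$xmax, b$ymax),
                 c(b$xmin, b$ymax), c(b$xmin, b$ymin))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(panel = b$panel, block_i = b$block_i,
                           block_j = b$block_j))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Published stratum-level summary of the Norwegian NFI frame
#'
#' The stratum summary shipped with the package (forest area by dominant
#' species group in the four NFI design strata, 2014-2018 cycle): per
#' stratum the dominant-species shares of the forest area, the land area,
#' the forest proportion, the number of plots in forest and the forest
#' area. Used for calibrating the synthetic generator and for internal
#' consistency checks of the estimators.
#'
#' @return data.frame with one row per stratum.
#' @export
nfi_stratum_summary <- function() {
  path <- system.file("extdata", "nfi_stratum_summary.csv",
                      package = "nfisim", mustWork = TRUE)
  utils::read.csv(path)
}

#' Per-plot summary values for estimation
#'
#' Reduces a measured (and volume-predicted) bundle to the plot-level
#' per-hectare values entering the expansion estimators.
#'
#' @param bundle a `plot_bundle` after [predict_plot_volumes()].
#' @return one-row data.frame: `forest` (0/1), `volume_m3_ha`,
#'   `agb_kg_ha`, `deadwood_m3_ha`, `n_trees`.
#' @export
summarise_plot <- function(bundle) {
  live <- bundle$trees$status == "live"
  to_ha <- 1e4 / 250
  data.frame(
    forest = as.integer(bundle$stand$land_use == "forest"),
    volume_m3_ha = sum(bundle$trees$volume_m3[live]) * to_ha,
    agb_kg_ha = sum(bundle$trees$agb_kg[live]) * to_ha,
    deadwood_m3_ha = lis_plot_volume(bundle$deadwood$diameter_at_intersection),
    n_trees = sum(live)
  )
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (file.exists(p)) jsonlite::read_json(p) else
    list(seed = NULL, stages = list())
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, manifest_path(out_dir), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

stage_hashes <- function(files) {
  h <- as.list(tools::md5sum(files))
  names(h) <- basename(names(h))
  h
}

stage_current <- function(manifest, stage, files) {
  rec <- manifest$stages[[stage]]
  if (is.null(rec)) return(FALSE)
  if (!all(file.exists(files))) return(FALSE)
  identical(lapply(stage_hashes(files), unname),
            lapply(rec, function(x) unname(unlist(x))))
}

#' Run the full inventory pipeline
#'
#' Executes simulate, sample, measure and estimate in order under one
#' output directory, recording a manifest with the seed and the MD5 hash
#' of every stage output. A rerun with the same configuration and seed is
#' bit-identical; stages whose outputs are present and match the manifest
#' are skipped, so a partially deleted run resumes from the last completed
#' stage.
#'
#' @param config a [landscape_config()] (or YAML path written by
#'   [write_landscape()]-style serialisation) defining the landscape; its
#'   `seed` drives every stage.
#' @param out_dir output directory.
#' @param design list of design options: `alpine_threshold` (default from
#'   config), `origin` (`NULL` = random within one grid cell, from seed),
#'   `phase`, `reserve_polygons`.
#' @param resume skip stages whose outputs match the manifest.
#' @return invisibly, a list with the estimates data.frame and the paths
#'   of all stage outputs.
#' @export
run_pipeline <- function(config, out_dir, design = list(), resume = TRUE) {
  if (is.character(config)) config <- deserialize_config(
    yaml::read_yaml(config))
  stopifnot(inherits(config, "landscape_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- if (resume) read_manifest(out_dir) else
    list(seed = NULL, stages = list())
  if (!is.null(manifest$seed) && !identical(manifest$seed, config$seed)) {
    manifest <- list(seed = NULL, stages = list())
  }
  manifest$seed <- config$seed

  land_dir <- file.path(out_dir, "landscape")
  land_files <- file.path(land_dir, c("trees.csv", "stands.csv",
                                      "deadwood.csv", "droppings.csv",
                                      "schema.json", "elevation.asc",
                                      "stand_raster.asc", "config.yaml",
                                      "stands.geojson"))
  if (!stage_current(manifest, "simulate", land_files)) {
    landscape <- simulate_landscape(config)
    write_landscape(landscape, land_dir)
    manifest$stages$simulate <- stage_hashes(land_files)
    write_manifest(manifest, out_dir)
  } else {
    landscape <- read_landscape(land_dir)
  }

  design_dir <- file.path(out_dir, "design")
  design_files <- file.path(design_dir, c("locations.csv", "schema.json",
                                          "blocks.geojson"))
  alpine <- if (is.null(design$alpine_threshold))
    config$alpine_threshold else design$alpine_threshold
  if (!stage_current(manifest, "sample", design_files)) {
    locs <- build_sample(
      config$extent, landscape$elevation, alpine_threshold = alpine,
      finnmark_xmin = config$finnmark_xmin,
      origin = design$origin, phase = if (is.null(design$phase)) 0 else
        design$phase,
      reserve_polygons = if (is.null(design$reserve_polygons)) list() else
        design$reserve_polygons,
      seed = config$seed + 11L)
    blocks <- tessellate_latin_squares(config$extent,
                                       origin = attr(locs, "origin") - 1500)
    write_tables(list(locations = locs), design_dir)
    write_blocks_geojson(blocks, file.path(design_dir, "blocks.geojson"))
    manifest$stages$sample <- stage_hashes(design_files)
    write_manifest(manifest, out_dir)
  } else {
    locs <- read_tables(design_dir)$locations
  }

  plots_dir <- file.path(out_dir, "plots")
  plot_files <- file.path(plots_dir, c("plots.csv", "parts.csv", "trees.csv",
                                       "smalltrees.csv", "regen.csv",
                                       "berry.csv", "deadwood.csv",
                                       "habitats.csv", "summaries.csv",
                                       "schema.json"))
  if (!stage_current(manifest, "measure", plot_files)) {
    bundles <- lapply(seq_len(nrow(locs)), function(i) {
      predict_plot_volumes(
        measure_plot(landscape, c(locs$x[i], locs$y[i])))
    })
    tabs <- bundles_to_tables(bundles, locs$plot_id)
    summaries <- cbind(
      plot_id = locs$plot_id, stratum = locs$stratum, panel = locs$panel,
      is_reserve_extra = locs$is_reserve_extra,
      do.call(rbind, lapply(bundles, summarise_plot)))
    tabs$summaries <- summaries
    write_tables(tabs, plots_dir)
    manifest$stages$measure <- stage_hashes(plot_files)
    write_manifest(manifest, out_dir)
  } else {
    summaries <- read_tables(plots_dir)$summaries
  }

  est_files <- file.path(out_dir, "estimates.csv")
  if (!stage_current(manifest, "estimate", est_files)) {
    s <- summaries[!summaries$is_reserve_extra, , drop = FALSE]
    frame <- stratum_frame(
      stratum = sort(unique(s$stratum)),
      weight_km2 = stratum_definitions()$weight_km2[sort(unique(s$stratum))])
    ests <- rbind(
      as.data.frame(proportion_with_se(s$forest, s$stratum, frame,
                                       domain = "forest area share")),
      as.data.frame(expand_total(s$forest, s$stratum, frame,
                                 domain = "forest area (ha)", units = "ha")),
      as.data.frame(expand_total(s$volume_m3_ha * s$forest, s$stratum, frame,
                                 domain = "growing stock volume",
                                 units = "m3")),
      as.data.frame(lis_deadwood_volume(
        ifelse(s$forest == 1, s$deadwood_m3_ha, 0), s$stratum, frame,
        domain = "downed deadwood"))
    )
    utils::write.csv(ests, est_files, row.names = FALSE)
    manifest$stages$estimate <- stage_hashes(est_files)
    write_manifest(manifest, out_dir)
    estimates <- ests
  } else {
    estimates <- utils::read.csv(est_files)
  }

  invisible(list(estimates = estimates, landscape_dir = land_dir,
                 design_dir = design_dir, plots_dir = plots_dir,
                 estimates_file = est_files))
}

#' Write / read a landscape configuration as YAML
#'
#' @param config a [landscape_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(serialize_config(config), path, precision = 12)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  deserialize_config(yaml::read_yaml(path))
}
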