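#' Stratum definitions of the sampling frame
#'
#' The four design strata of the NFI grid: stratum 1 (lowland outside
#' Finnmark) on a 3 km x 3 km grid, stratum 2 (alpine outside Finnmark) on
#' 3 km x 9 km, stratum 3 (productive Finnmark) on 3 km x 3 km, stratum 4
#' (remaining Finnmark) on 9 km x 9 km. The published sampling weights are
#' approximately 9, 27, 9 and 82 km^2 per plot; by default the stratum-4
#' weight is stored as the exact planar lattice area 81 km^2 (= 9 km x
#' 9 km), which keeps expansion internally consistent on synthetic planar
#' landscapes — the published 82 km^2 reflects real-grid meridian
#' convergence and can be supplied through `weights`.
#'
#' @param weights sampling weights (km^2 per plot) for strata 1-4.
#' @return data.frame with `stratum`, `dx_km`, `dy_km`, `weight_km2`.
#' @export
stratum_definitions <- function(weights = c(9, 27, 9, 81)) {
  stopifnot(length(weights) == 4, all(weights > 0))
  data.frame(
    stratum = 1:4,
    dx_km = c(3, 3, 3, 9),
    dy_km = c(3, 9, 3, 9),
    weight_km2 = weights
  )
}

#' Generate a systematic lattice of plot locations
#'
#' All nodes of the lattice `origin + (i*dx, j*dy)` that fall inside the
#' extent, with half-open inclusion on the east and north edges (a node on
#' `xmax` or `ymax` is excluded). Locations are returned row-major: rows
#' from south to north, west to east within a row.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in m.
#' @param spacing lattice spacing in m, length 1 or `c(dx, dy)`.
#' @param origin lattice anchor `c(x0, y0)` in m (any lattice node).
#' @return data.frame with columns `x`, `y`.
#' @export
generate_grid <- function(extent, spacing, origin = c(0, 0)) {
  stopifnot(length(extent) == 4, all(spacing > 0))
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) {
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  ks <- function(lo, hi, o, s) {
    k <- seq(ceiling((lo - o) / s - 1e-9), floor((hi - o) / s + 1e-9))
    v <- o + k * s
    v[v >= lo - 1e-9 & v < hi - 1e-9]
  }
  xs <- ks(extent[1], extent[2], origin[1], spacing[1])
  ys <- ks(extent[3], extent[4], origin[2], spacing[2])
  data.frame(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
}

#' Latin-square block tessellation
#'
#' Tiles the extent with 45 km x 45 km Latin squares of 5 x 5 blocks, each
#' block 9 km x 9 km (81 km^2) and holding 9 locations of the 3 km grid.
#' The panel (measurement year, 1-5) of block (i, j) — counted globally
#' from the tessellation origin — is the cyclic Latin assignment
#' `((i + 2 j) mod 5) + 1`, which is a Latin square within every 45 km
#' square and, because the same square repeats across the tiling, ensures
#' that no two edge-adjacent blocks anywhere share a panel.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in m; every block intersecting
#'   the extent is returned.
#' @param origin tessellation anchor (south-west corner of a square).
#' @return data.frame with `square_row`, `square_col`, `block_i`, `block_j`
#'   (0-4 within the square), `panel`, `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
tessellate_latin_squares <- function(extent, origin = c(0, 0)) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  b <- 9000
  j0 <- floor((extent[1] - origin[1]) / b)
  j1 <- ceiling((extent[2] - origin[1]) / b) - 1
  i0 <- floor((extent[3] - origin[2]) / b)
  i1 <- ceiling((extent[4] - origin[2]) / b) - 1
  grid <- expand.grid(i = i0:i1, j = j0:j1)
  mod5 <- function(k) ((k %% 5) + 5) %% 5
  data.frame(
    square_row = floor(grid$i / 5),
    square_col = floor(grid$j / 5),
    block_i = mod5(grid$i),
    block_j = mod5(grid$j),
    panel = mod5(grid$i + 2 * grid$j) + 1L,
    xmin = origin[1] + grid$j * b,
    xmax = origin[1] + (grid$j + 1) * b,
    ymin = origin[2] + grid$i * b,
    ymax = origin[2] + (grid$i + 1) * b
  )
}

#' Panel of the block containing a location
#'
#' @param x,y coordinates (m).
#' @param origin tessellation anchor as in [tessellate_latin_squares()].
#' @export
panel_at <- function(x, y, origin = c(0, 0)) {
  b <- 9000
  i <- floor((y - origin[2]) / b)
  j <- floor((x - origin[1]) / b)
  mod5 <- function(k) ((k %% 5) + 5) %% 5
  as.integer(mod5(i + 2 * j) + 1)
}

#' Assign design strata to grid locations
#'
#' Implements the stratum membership rules: outside the Finnmark region,
#' locations below the alpine elevation threshold are stratum 1 (3 km x
#' 3 km); alpine locations belong to stratum 2 but are retained in the
#' sample only if they lie on the 3 km x 9 km sub-lattice. In Finnmark the
#' analogous split is stratum 3 (3 km x 3 km, productive) versus stratum 4
#' on the 9 km x 9 km sub-lattice. Alpine/non-productive locations off
#' their coarser lattice get `in_sample = FALSE`; locations outside the
#' mapped elevation raster get stratum `NA` (unsampled).
#'
#' @param locations data.frame with `x`, `y` on the 3 km lattice.
#' @param elevation elevation [nfi_raster()] (or a function `(x, y) ->`
#'   elevation).
#' @param alpine_threshold elevation threshold(s) in m; scalar or a
#'   function `(x, y) -> threshold` for regionally varying thresholds.
#' @param finnmark_xmin locations with `x >= finnmark_xmin` are Finnmark.
#' @param grid_origin anchor of the 3 km lattice.
#' @param phase which 3 km row (0-2 north of origin) carries the 9 km
#'   sub-lattice; also used for the column phase of stratum 4.
#' @return `locations` with columns `stratum` (1-4 or `NA`) and
#'   `in_sample` added.
#' @export
assign_stratum <- function(locations, elevation, alpine_threshold = 800,
                           finnmark_xmin = Inf, grid_origin = c(0, 0),
                           phase = 0) {
  elev <- if (is.function(elevation)) {
    elevation(locations$x, locations$y)
  } else {
    raster_extract(elevation, locations$x, locations$y)
  }
  thr <- if (is.function(alpine_threshold)) {
    alpine_threshold(locations$x, locations$y)
  } else alpine_threshold
  on_coarse <- function(v, o, fine = 3000, factor = 3) {
    k <- round((v - o) / fine)
    (k - phase) %% factor == 0
  }
  row9 <- on_coarse(locations$y, grid_origin[2])
  col9 <- on_coarse(locations$x, grid_origin[1])
  finnmark <- locations$x >= finnmark_xmin
  alpine <- elev >= thr
  stratum <- ifelse(finnmark, ifelse(alpine, 4L, 3L), ifelse(alpine, 2L, 1L))
  stratum[is.na(elev)] <- NA_integer_
  in_sample <- !is.na(stratum) &
    ifelse(is.na(stratum), FALSE,
           ifelse(stratum == 2L, row9,
                  ifelse(stratum == 4L, row9 & col9, TRUE)))
  locations$stratum <- stratum
  locations$in_sample <- in_sample
  locations
}

#' Ray-casting point-in-polygon test
#'
#' @param x,y point coordinates.
#' @param polygon two-column matrix of vertices (closed implicitly).
#' @return logical vector; points exactly on an edge count as inside.
#' @export
point_in_polygon <- function(x, y, polygon) {
  polygon <- as.matrix(polygon)
  n <- nrow(polygon)
  px <- polygon[, 1]; py <- polygon[, 2]
  out <- logical(length(x))
  for (k in seq_along(x)) {
    inside <- FALSE
    on_edge <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
      # edge membership
      cross <- (x[k] - xi) * (yj - yi) - (y[k] - yi) * (xj - xi)
      if (abs(cross) < 1e-9 &&
          x[k] >= min(xi, xj) - 1e-9 && x[k] <= max(xi, xj) + 1e-9 &&
          y[k] >= min(yi, yj) - 1e-9 && y[k] <= max(yi, yj) + 1e-9) {
        on_edge <- TRUE
        break
      }
      if ((yi > y[k]) != (yj > y[k]) &&
          x[k] < (xj - xi) * (y[k] - yi) / (yj - yi) + xi) {
        inside <- !inside
      }
      j <- i
    }
    out[k] <- inside || on_edge
  }
  out
}

#' Densified plots inside forest reserves
#'
#' For every base plot, candidate plots 1.5 km north and 1.5 km east are
#' generated and retained if they fall inside a forest-reserve polygon
#' (the reserve-grid doubling applied since 2012).
#'
#' @param locations data.frame with `x`, `y` (base plot locations).
#' @param reserve_polygons list of two-column vertex matrices.
#' @param offset densification offset in m (default 1500).
#' @return data.frame of retained extra plots with `x`, `y`, `base_x`,
#'   `base_y`, `offset_dir` (`"north"`/`"east"`), `is_reserve_extra = TRUE`.
#' @export
densify_reserve_plots <- function(locations, reserve_polygons,
                                  offset = 1500) {
  if (!length(reserve_polygons) || !nrow(locations)) {
    return(data.frame(x = numeric(0), y = numeric(0), base_x = numeric(0),
                      base_y = numeric(0), offset_dir = character(0),
                      is_reserve_extra = logical(0)))
  }
  cand <- rbind(
    data.frame(x = locations$x, y = locations$y + offset,
               base_x = locations$x, base_y = locations$y,
               offset_dir = "north", stringsAsFactors = FALSE),
    data.frame(x = locations$x + offset, y = locations$y,
               base_x = locations$x, base_y = locations$y,
               offset_dir = "east", stringsAsFactors = FALSE)
  )
  inside <- rep(FALSE, nrow(cand))
  for (poly in reserve_polygons) {
    inside <- inside | point_in_polygon(cand$x, cand$y, poly)
  }
  out <- cand[inside, , drop = FALSE]
  out$is_reserve_extra <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Build the full plot sample over an extent
#'
#' Generates the 3 km base lattice (optionally with a random origin inside
#' one grid cell, which makes design-unbiasedness testable), assigns Latin
#' square panels and strata, drops alpine/non-productive locations that
#' miss their coarser sub-lattice, and optionally adds reserve
#' densification plots.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in m.
#' @param elevation elevation [nfi_raster()] or function.
#' @param alpine_threshold,finnmark_xmin,phase see [assign_stratum()].
#' @param origin lattice origin `c(x0, y0)`; `NULL` draws it uniformly
#'   within one 3 km cell.
#' @param reserve_polygons optional list of reserve polygons.
#' @param seed RNG seed for the random origin.
#' @return data.frame of sampled plot locations: `plot_id`, `x`, `y`,
#'   `stratum`, `panel`, `is_reserve_extra`, plus the `origin` used as an
#'   attribute.
#' @export
build_sample <- function(extent, elevation, alpine_threshold = 800,
                         finnmark_xmin = Inf, origin = NULL, phase = 0,
                         reserve_polygons = list(), seed = NULL) {
  if (is.null(origin)) {
    if (!is.null(seed)) set.seed(seed)
    origin <- c(stats::runif(1, 0, 3000), stats::runif(1, 0, 3000))
  }
  locs <- generate_grid(extent, 3000, origin)
  locs <- assign_stratum(locs, elevation, alpine_threshold, finnmark_xmin,
                         grid_origin = origin, phase = phase)
  locs <- locs[locs$in_sample %in% TRUE, , drop = FALSE]
  locs$panel <- panel_at(locs$x, locs$y, origin = origin - 1500)
  locs$is_reserve_extra <- rep(FALSE, nrow(locs))
  extra <- densify_reserve_plots(locs, reserve_polygons)
  if (nrow(extra)) {
    extra$stratum <- locs$stratum[match(paste(extra$base_x, extra$base_y),
                                        paste(locs$x, locs$y))]
    extra$panel <- panel_at(extra$x, extra$y, origin = origin - 1500)
    extra$in_sample <- TRUE
    locs <- rbind(locs[c("x", "y", "stratum", "panel", "in_sample",
                         "is_reserve_extra")],
                  extra[c("x", "y", "stratum", "panel", "in_sample",
                          "is_reserve_extra")])
  }
  locs <- locs[c("x", "y", "stratum", "panel", "is_reserve_extra")]
  locs <- cbind(plot_id = seq_len(nrow(locs)), locs)
  rownames(locs) <- NULL
  attr(locs, "origin") <- origin
  locs
}
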