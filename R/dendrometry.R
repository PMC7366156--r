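#' Allometric function set
#'
#' Containers for the height-diameter, volume and biomass functions used by
#' the prediction chain. The functional families follow Nordic practice:
#'
#' * height: \eqn{h = 1.3 + (d/(a + b d))^3} (m; `d` = dbh in cm), with
#'   asymptote \eqn{1.3 + b^{-3}};
#' * volume: \eqn{v = (c_1 d^2 h + c_2 d^2)/1000} (m^3), strictly
#'   increasing in `h` so that height can be back-solved from volume;
#' * biomass: \eqn{\ln B = c_0 + c_1\, d/(d + k)} (kg).
#'
#' The shipped coefficients are documented stand-ins of the correct
#' functional families, not the published Norwegian/Swedish coefficient
#' sets; any coefficient table of the same shape (e.g. loaded from YAML
#' with [read_allometry()]) can be dropped in. All package-level
#' computations (correction factors, back-solving, increment) are
#' allometry-agnostic.
#'
#' @param height named list of `c(a, b)` per height key
#'   (`spruce`, `pine`, `deciduous`, `sitka_spruce`).
#' @param volume named list of `c(c1, c2)` per volume key.
#' @param biomass named list with entries `conifer_above`, `conifer_below`,
#'   `deciduous_above`, `deciduous_below`, each `c(c0, c1, k)`.
#' @return an object of class `allometry_set`.
#' @export
allometry_set <- function(height, volume, biomass) {
  stopifnot(is.list(height), is.list(volume), is.list(biomass))
  structure(list(height = height, volume = volume, biomass = biomass),
            class = "allometry_set")
}

#' @rdname allometry_set
#' @export
default_allometry <- function() {
  allometry_set(
    height = list(
      spruce = c(a = 1.6, b = 0.335),
      pine = c(a = 1.9, b = 0.345),
      deciduous = c(a = 2.2, b = 0.360),
      sitka_spruce = c(a = 1.5, b = 0.325)
    ),
    volume = list(
      spruce = c(c1 = 0.040, c2 = 0.30),
      pine = c(c1 = 0.042, c2 = 0.25),
      deciduous = c(c1 = 0.045, c2 = 0.20),
      sitka_spruce = c(c1 = 0.038, c2 = 0.32)
    ),
    biomass = list(
      conifer_above = c(c0 = -1.2, c1 = 10.0, k = 12),
      conifer_below = c(c0 = -2.6, c1 = 9.6, k = 12),
      deciduous_above = c(c0 = -1.3, c1 = 10.1, k = 11),
      deciduous_below = c(c0 = -3.0, c1 = 9.9, k = 11)
    )
  )
}

#' Species-to-function routing
#'
#' Maps a species code (with its field group) to the volume-function key,
#' following NFI practice: the spruce functions serve all spruce and fir
#' species except Sitka spruce, which has its own function; the pine
#' functions serve all other conifers; the birch (deciduous) functions
#' serve all broadleaves.
#'
#' @param species_code species code string(s) (e.g. `"norway_spruce"`,
#'   `"sitka_spruce"`, `"fir"`, `"scots_pine"`, `"juniper"`, `"birch"`).
#' @param species_group field group: `"spruce"`, `"pine"` or `"deciduous"`.
#' @return character vector of volume keys.
#' @export
route_volume_species <- function(species_code, species_group) {
  out <- ifelse(species_group == "deciduous", "deciduous",
                ifelse(species_group == "spruce", "spruce", "pine"))
  out[species_code %in% "sitka_spruce"] <- "sitka_spruce"
  out[species_code %in% "fir"] <- "spruce"
  out
}

get_coef <- function(set, key, what) {
  cf <- set[[what]][[key]]
  if (is.null(cf)) {
    cf <- set[[what]][[sub("^sitka_", "", key)]]
  }
  if (is.null(cf)) stop("no ", what, " coefficients for species '", key, "'")
  cf
}

#' Approximate tree height from dbh
#'
#' Evaluates the h-dbh curve \eqn{h = 1.3 + (d/(a + b d))^3}; the first
#' step of the volume prediction chain for trees without a height
#' measurement.
#'
#' @param species_group height key per tree (vectorised).
#' @param dbh dbh in cm (>= 5).
#' @param allometry an [allometry_set()].
#' @return heights in m.
#' @export
approximate_height <- function(species_group, dbh, allometry = default_allometry()) {
  stopifnot(length(species_group) %in% c(1, length(dbh)))
  if (length(species_group) == 1) species_group <- rep(species_group, length(dbh))
  out <- numeric(length(dbh))
  for (key in unique(species_group)) {
    cf <- get_coef(allometry, key, "height")
    i <- species_group == key
    out[i] <- 1.3 + (dbh[i] / (cf[["a"]] + cf[["b"]] * dbh[i]))^3
  }
  out
}

#' Tree stem volume from dbh and height
#'
#' @param species volume key per tree (see [route_volume_species()]).
#' @param dbh dbh in cm.
#' @param height height in m.
#' @param allometry an [allometry_set()].
#' @return stem volume in m^3.
#' @export
tree_volume <- function(species, dbh, height, allometry = default_allometry()) {
  stopifnot(length(species) %in% c(1, length(dbh)))
  if (length(species) == 1) species <- rep(species, length(dbh))
  out <- numeric(length(dbh))
  for (key in unique(species)) {
    cf <- get_coef(allometry, key, "volume")
    i <- species == key
    out[i] <- (cf[["c1"]] * dbh[i]^2 * height[i] + cf[["c2"]] * dbh[i]^2) / 1000
  }
  out
}

#' Back-solve height from a predicted volume
#'
#' Inverts the volume function in height for a given dbh, the NFI procedure
#' for assigning heights to trees without a height measurement after their
#' volume has been corrected. Solved numerically by root bracketing to a
#' volume tolerance of 1e-6 m^3 (monotonicity of `v` in `h` guarantees a
#' unique root).
#'
#' @param species volume key per tree.
#' @param dbh dbh in cm.
#' @param volume target volume m^3.
#' @param allometry an [allometry_set()].
#' @param h_max upper bracket for height (m).
#' @return heights in m.
#' @export
height_from_volume <- function(species, dbh, volume,
                               allometry = default_allometry(), h_max = 60) {
  stopifnot(length(species) %in% c(1, length(dbh)))
  if (length(species) == 1) species <- rep(species, length(dbh))
  n <- length(dbh)
  out <- numeric(n)
  for (i in seq_len(n)) {
    f <- function(h) tree_volume(species[i], dbh[i], h, allometry) - volume[i]
    lo <- 0; hi <- h_max
    while (f(hi) < 0 && hi < 1e4) hi <- hi * 2
    r <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
    if (abs(f(r$root)) > 1e-6)
      stop("height back-solve did not converge for tree ", i)
    out[i] <- r$root
  }
  out
}

#' Plot-level volume correction factors
#'
#' From the height-measured subsample (h-trees) of one plot, computes per
#' species group the ratio of the sum of volumes predicted with measured
#' heights to the sum of volumes predicted with approximated heights, each
#' tree inversely weighted by its angle-count selection probability (so
#' small trees, which are selected with low probability, get more
#' influence). When all trees on the plot were height-measured (n <= 10)
#' the weights are uniform.
#'
#' @param h_trees data.frame with columns `species_group`, `species_code`
#'   (optional), `dbh`, `height_measured`, and `selection_prob` (in (0,1\];
#'   ignored when `uniform_weights`).
#' @param allometry an [allometry_set()].
#' @param uniform_weights use weight 1 for every tree.
#' @return data.frame with `species_group`, `factor`, `n_h`,
#'   `source = "plot"`.
#' @export
plot_correction_factors <- function(h_trees, allometry = default_allometry(),
                                    uniform_weights = FALSE) {
  if (!nrow(h_trees)) {
    return(data.frame(species_group = character(), factor = numeric(),
                      n_h = integer(), source = character(),
                      stringsAsFactors = FALSE))
  }
  code <- if (!is.null(h_trees$species_code)) h_trees$species_code else
    h_trees$species_group
  vkey <- route_volume_species(code, h_trees$species_group)
  h_app <- approximate_height(h_trees$species_group, h_trees$dbh, allometry)
  v_app <- tree_volume(vkey, h_trees$dbh, h_app, allometry)
  v_mea <- tree_volume(vkey, h_trees$dbh, h_trees$height_measured, allometry)
  w <- if (uniform_weights || is.null(h_trees$selection_prob)) {
    rep(1, nrow(h_trees))
  } else {
    1 / pmin(pmax(h_trees$selection_prob, 1e-12), 1)
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(h_trees)),
                                     h_trees$species_group), function(i) {
    data.frame(species_group = h_trees$species_group[i[1]],
               factor = sum(w[i] * v_mea[i]) / sum(w[i] * v_app[i]),
               n_h = length(i), source = "plot", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fallback correction factors
#'
#' Region-wide average correction factors looked up by maturity-class
#' group, site index class, species group and region, used when a plot has
#' no h-tree of a species group.
#'
#' @param table data.frame with columns `species_group`, `maturity_group`
#'   (`"young"` = classes 1-3, `"old"` = 4-5), `site_index_class`, `region`,
#'   `factor`; `NA` in a key column matches anything.
#' @param species_group,maturity_class,site_index_class,region lookup keys.
#' @return the factor (scalar); error if no row matches.
#' @export
fallback_correction <- function(table, species_group, maturity_class,
                                site_index_class, region = NA) {
  mg <- if (maturity_class >= 4) "old" else "young"
  match_col <- function(col, val) is.na(col) | col == val
  hit <- match_col(table$species_group, species_group) &
    match_col(table$maturity_group, mg) &
    match_col(table$site_index_class, site_index_class) &
    match_col(table$region, region)
  if (!any(hit)) stop("no fallback correction factor for species '",
                      species_group, "'")
  mean(table$factor[hit])
}

#' Predict tree volumes and final heights for one plot
#'
#' The full chain: h-trees get `v = v(dbh, measured h)` and keep their
#' measured height; other trees get `v = correction * v(dbh, approximated
#' h)` with the plot-level (or fallback) correction factor of their species
#' group, and a final height back-solved from that volume. Trees flagged
#' broken lose the cone-top volume above the break when the stem diameter
#' at the break is >= 10 cm (stand-in taper: linear from dbh to zero at the
#' top, so a break at relative height `p` removes the fraction
#' \eqn{(1-p)^3}); the correction factor is applied before the breakage
#' adjustment.
#'
#' @param trees data.frame with `species_group`, `species_code` (optional),
#'   `dbh`, `height_measured` (`NA` for non-h-trees), and optionally
#'   `break_rel_height` (`NA` = intact).
#' @param allometry an [allometry_set()].
#' @param corrections data.frame from [plot_correction_factors()]; groups
#'   absent from it fall back to `fallback` (a factor of 1 keeps the
#'   approximation).
#' @param fallback scalar correction for groups without a plot factor, or a
#'   function `(species_group) -> factor`.
#' @param breakage_adjustment apply the broken-top reduction.
#' @return `trees` with columns `volume_m3` and `height_m` added.
#' @export
predict_tree_volume <- function(trees, allometry = default_allometry(),
                                corrections = NULL, fallback = 1,
                                breakage_adjustment = TRUE) {
  n <- nrow(trees)
  if (!n) {
    trees$volume_m3 <- numeric(0)
    trees$height_m <- numeric(0)
    return(trees)
  }
  code <- if (!is.null(trees$species_code)) trees$species_code else
    trees$species_group
  vkey <- route_volume_species(code, trees$species_group)
  fac <- rep(NA_real_, n)
  if (!is.null(corrections) && nrow(corrections)) {
    fac <- corrections$factor[match(trees$species_group,
                                    corrections$species_group)]
  }
  miss <- is.na(fac)
  if (any(miss)) {
    fac[miss] <- if (is.function(fallback)) {
      vapply(trees$species_group[miss], fallback, numeric(1))
    } else fallback
  }
  hm <- trees$height_measured
  is_h <- !is.na(hm)
  vol <- numeric(n); hgt <- numeric(n)
  if (any(is_h)) {
    vol[is_h] <- tree_volume(vkey[is_h], trees$dbh[is_h], hm[is_h], allometry)
    hgt[is_h] <- hm[is_h]
  }
  if (any(!is_h)) {
    h_app <- approximate_height(trees$species_group[!is_h], trees$dbh[!is_h],
                                allometry)
    v_app <- tree_volume(vkey[!is_h], trees$dbh[!is_h], h_app, allometry)
    vol[!is_h] <- fac[!is_h] * v_app
    hgt[!is_h] <- height_from_volume(vkey[!is_h], trees$dbh[!is_h],
                                     vol[!is_h], allometry)
  }
  if (breakage_adjustment && !is.null(trees$break_rel_height)) {
    p <- trees$break_rel_height
    brk <- !is.na(p) & p > 0 & p < 1
    if (any(brk)) {
      d_break <- trees$dbh[brk] * (1 - p[brk])
      adj <- ifelse(d_break >= 10, (1 - p[brk])^3, 0)
      vol[brk] <- vol[brk] * (1 - adj)
    }
  }
  trees$volume_m3 <- vol
  trees$height_m <- hgt
  trees
}

#' Growing-season calendar
#'
#' @param season_start first day-of-year of the growing season (default
#'   152, 1 June).
#' @param season_length season length in days (default 100).
#' @export
season_calendar <- function(season_start = 152, season_length = 100) {
  stopifnot(season_start >= 1, season_start <= 366 - season_length + 1 ||
              season_start <= 265, season_length > 0)
  structure(list(season_start = season_start, season_length = season_length),
            class = "season_calendar")
}

#' Number of growing seasons between two measurement dates
#'
#' With a 100-day season, `seasons = (calendar years elapsed) +
#' (s(curr) - s(prev))/100`, where `s(d)` counts season days elapsed at
#' date `d`, clamped to \[0, 100\]. Over a 5-year inventory cycle the value
#' therefore lies between 4.00 and 6.00.
#'
#' @param date_prev,date_curr `Date` (or coercible) measurement dates,
#'   `date_prev < date_curr`.
#' @param calendar a [season_calendar()].
#' @return seasons as a float.
#' @export
growing_seasons <- function(date_prev, date_curr,
                            calendar = season_calendar()) {
  date_prev <- as.Date(date_prev); date_curr <- as.Date(date_curr)
  stopifnot(all(date_prev < date_curr))
  s <- function(d) {
    doy <- as.integer(strftime(d, "%j"))
    pmin(pmax(doy - calendar$season_start, 0), calendar$season_length)
  }
  years <- as.integer(format(date_curr, "%Y")) -
    as.integer(format(date_prev, "%Y"))
  years + (s(date_curr) - s(date_prev)) / calendar$season_length
}

#' Annual volume increment of a remeasured tree
#'
#' The dbh one year before the current measurement is interpolated as
#' `dbh_curr - (dbh_curr - dbh_prev)/seasons`; its volume is predicted
#' under the previous cycle's diameter-height relationship (approximated
#' height times the previous correction factor); the annual increment is
#' the difference between the current volume and that volume.
#'
#' @param species_group,species_code species of the tree.
#' @param dbh_prev,dbh_curr dbh (cm) at the previous and current visits.
#' @param seasons growing seasons between the visits (> 0).
#' @param allometry an [allometry_set()].
#' @param correction_prev previous-cycle correction factor.
#' @param v_curr current volume prediction; if `NULL`, predicted with the
#'   previous relationship at `dbh_curr`.
#' @return annual volume increment in m^3 per year.
#' @export
annual_volume_increment <- function(species_group, dbh_prev, dbh_curr,
                                    seasons, allometry = default_allometry(),
                                    correction_prev = 1, v_curr = NULL,
                                    species_code = species_group) {
  stopifnot(all(seasons > 0))
  vkey <- route_volume_species(species_code, species_group)
  prev_rel_volume <- function(d) {
    correction_prev *
      tree_volume(vkey, d, approximate_height(species_group, d, allometry),
                  allometry)
  }
  dbh_m1 <- dbh_curr - (dbh_curr - dbh_prev) / seasons
  if (is.null(v_curr)) v_curr <- prev_rel_volume(dbh_curr)
  v_curr - prev_rel_volume(dbh_m1)
}

#' Impute annual dbh increments for ingrowth or new plots
#'
#' Mean annual dbh difference of matched (remeasured) trees in the cell
#' (species group, 5 cm diameter class, maturity-class group, site index
#' class); empty cells are widened hierarchically by dropping site index,
#' then the maturity group, then the diameter class (species is kept
#' throughout, then dropped as a last resort).
#'
#' @param targets data.frame with `species_group`, `dbh`, `maturity_class`,
#'   `site_index_class`.
#' @param matched data.frame with the same columns plus `annual_dbh_incr`.
#' @return numeric vector of imputed annual dbh increments (cm/yr).
#' @export
impute_dbh_increment <- function(targets, matched) {
  if (!nrow(matched)) stop("no matched trees to impute from")
  cellify <- function(df) {
    list(sp = df$species_group,
         dc = floor(df$dbh / 5),
         mg = ifelse(df$maturity_class >= 4, "old", "young"),
         si = df$site_index_class)
  }
  tc <- cellify(targets); mc <- cellify(matched)
  lookup <- function(keys_t, keys_m) {
    kt <- do.call(paste, c(keys_t, sep = "|"))
    km <- do.call(paste, c(keys_m, sep = "|"))
    means <- tapply(matched$annual_dbh_incr, km, mean)
    as.numeric(means[kt])
  }
  out <- lookup(tc, mc)
  widenings <- list(c("sp", "dc", "mg"), c("sp", "dc"), c("sp"), character(0))
  for (w in widenings) {
    if (!anyNA(out)) break
    miss <- is.na(out)
    if (length(w)) {
      out[miss] <- lookup(lapply(w, function(k) tc[[k]][miss]),
                          lapply(w, function(k) mc[[k]]))
    } else {
      out[miss] <- mean(matched$annual_dbh_incr)
    }
  }
  out
}

#' Volume of a removed tree
#'
#' Removed (harvested) trees get the previous volume prediction plus 2.5
#' years of the previous annual increment, accounting for the unobserved
#' growth between the last visit and the (on average mid-cycle) removal.
#'
#' @param v_prev previous-cycle volume prediction (m^3).
#' @param increment_prev_annual previous annual increment (m^3/yr).
#' @export
removal_volume <- function(v_prev, increment_prev_annual) {
  v_prev + 2.5 * increment_prev_annual
}

#' H40 site index class from dominant height
#'
#' Site productivity as dominant height (m) at a breast-height base age of
#' 40 years, binned into the class ladder 6, 8, 11, 14, ..., 26 with bins
#' extending 1.5 m around the class value (half-open upwards; e.g. class 14
#' covers \[12.5, 15.5) m) and clamping at the ends.
#'
#' @param dominant_height dominant height (m) at base age, > 0.
#' @param ladder class values.
#' @return site index class (element of `ladder`).
#' @export
site_index_class <- function(dominant_height,
                             ladder = c(6, 8, 11, 14, 17, 20, 23, 26)) {
  stopifnot(all(dominant_height > 0))
  breaks <- (ladder[-1] + ladder[-length(ladder)]) / 2
  breaks[-1] <- ladder[-c(1, length(ladder))] + 1.5
  ladder[findInterval(dominant_height, breaks) + 1L]
}

#' Basal-area weighted stand age
#'
#' Age is the basal-area weighted mean age of all trees; in two-layered
#' stands only the overstory counts. Biological (not chronological) ages
#' are expected as input.
#'
#' @param age tree ages (yrs).
#' @param dbh tree dbh (cm) for the basal-area weights.
#' @param layer optional per-tree layer (`"overstory"`/`"understory"`).
#' @param n_layers number of stand layers; the overstory restriction
#'   applies only when `n_layers == 2`.
#' @return stand age in years.
#' @export
stand_age <- function(age, dbh, layer = NULL, n_layers = 1) {
  keep <- !is.na(age)
  if (n_layers == 2) {
    if (is.null(layer)) stop("two-layered stand needs a 'layer' vector")
    keep <- keep & layer == "overstory"
  }
  if (!any(keep)) stop("no aged trees in the relevant layer")
  g <- pi / 4 * (dbh[keep] / 100)^2
  sum(g * age[keep]) / sum(g)
}

#' Update stand age between inventory cycles
#'
#' @param previous_age previously recorded stand age.
#' @param harvested was the stand harvested since the previous visit?
#' @param cycle_years cycle length (default 5).
#' @export
update_stand_age <- function(previous_age, harvested = FALSE,
                             cycle_years = 5) {
  ifelse(harvested, 0, previous_age + cycle_years)
}

#' Maturity-class entry-age table
#'
#' Entry ages (years) for maturity classes 2-5 by H40 site index class,
#' decreasing in site index so that productive stands advance earlier. The
#' realized entries span the published class ranges: class 3 entry 15-55
#' (inside 15-84), class 4 entry 25-90 (inside 25-119), class 5 entry 40 at
#' the highest site index up to 120 at the lowest.
#'
#' @return matrix (site index class x maturity class entry age).
#' @export
default_maturity_table <- function() {
  m <- cbind(
    class2 = rep(1, 8),
    class3 = c(55, 49, 43, 38, 32, 26, 21, 15),
    class4 = c(90, 81, 71, 62, 53, 44, 34, 25),
    class5 = c(120, 109, 97, 86, 74, 63, 51, 40)
  )
  rownames(m) <- c(6, 8, 11, 14, 17, 20, 23, 26)
  m
}

#' Maturity class and stocking flag of a stand
#'
#' Class 1 is forest under regeneration (age 0); classes 2-5 are reached at
#' the entry ages of the site-index dependent threshold table, so that at a
#' fixed age the class is non-decreasing in site index. The stocking flag
#' is `"sufficiently"` or `"poorly"` stocked, judged by the number of
#' potential crop trees in class 2 and by basal area in classes 3-5; `NA`
#' when the relevant metric is not supplied.
#'
#' @param stand_age stand age in years.
#' @param dominant_species species group (kept for per-species override
#'   tables; the default table is shared).
#' @param site_index_class H40 class; values outside the table are clamped.
#' @param stocking list with optional `crop_trees_per_ha` and
#'   `basal_area_m2ha`.
#' @param table entry-age table as [default_maturity_table()].
#' @param min_crop_trees,min_basal_area sufficiency thresholds.
#' @return list with `class` (1-5) and `stocking_flag`.
#' @export
maturity_class <- function(stand_age, dominant_species = "spruce",
                           site_index_class = 14, stocking = NULL,
                           table = default_maturity_table(),
                           min_crop_trees = 1000, min_basal_area = 10) {
  si_vals <- as.numeric(rownames(table))
  row <- which.min(abs(si_vals - site_index_class))
  entries <- table[row, ]
  cls <- if (stand_age <= 0) 1L else {
    1L + sum(stand_age >= entries)
  }
  flag <- NA_character_
  if (!is.null(stocking) && cls >= 2) {
    if (cls == 2 && !is.null(stocking$crop_trees_per_ha)) {
      flag <- ifelse(stocking$crop_trees_per_ha >= min_crop_trees,
                     "sufficiently", "poorly")
    } else if (cls >= 3 && !is.null(stocking$basal_area_m2ha)) {
      flag <- ifelse(stocking$basal_area_m2ha >= min_basal_area,
                     "sufficiently", "poorly")
    }
  }
  list(class = as.integer(cls), stocking_flag = flag)
}

#' Above- and below-ground tree biomass
#'
#' Evaluates the stand-in biomass regressions
#' \eqn{\ln B = c_0 + c_1 d/(d+k)}; conifer species groups are routed to
#' the conifer set and broadleaves to the deciduous (birch-type) set.
#'
#' @param species_group `"spruce"`, `"pine"` or `"deciduous"` (vectorised).
#' @param dbh dbh in cm (>= 5).
#' @param allometry an [allometry_set()].
#' @return data.frame with `above_kg` and `below_kg`.
#' @export
predict_biomass <- function(species_group, dbh,
                            allometry = default_allometry()) {
  stopifnot(length(species_group) %in% c(1, length(dbh)))
  if (length(species_group) == 1) species_group <- rep(species_group, length(dbh))
  set_key <- ifelse(species_group == "deciduous", "deciduous", "conifer")
  eval_b <- function(cf, d) exp(cf[["c0"]] + cf[["c1"]] * d / (d + cf[["k"]]))
  above <- numeric(length(dbh)); below <- numeric(length(dbh))
  for (key in unique(set_key)) {
    i <- set_key == key
    above[i] <- eval_b(get_coef(allometry, paste0(key, "_above"), "biomass"),
                       dbh[i])
    below[i] <- eval_b(get_coef(allometry, paste0(key, "_below"), "biomass"),
                       dbh[i])
  }
  data.frame(above_kg = above, below_kg = below)
}

#' Read / write allometry coefficients as YAML
#'
#' @param path YAML file with top-level keys `height`, `volume`, `biomass`.
#' @export
read_allometry <- function(path) {
  y <- yaml::read_yaml(path)
  allometry_set(
    height = lapply(y$height, function(v) unlist(v)),
    volume = lapply(y$volume, function(v) unlist(v)),
    biomass = lapply(y$biomass, function(v) unlist(v))
  )
}

#' @rdname read_allometry
#' @param allometry an [allometry_set()].
#' @export
write_allometry <- function(allometry, path) {
  yaml::write_yaml(lapply(unclass(allometry), function(part)
    lapply(part, as.list)), path)
  invisible(path)
}

#' Run the volume chain on a measured plot
#'
#' Integration helper: computes plot-level correction factors from the
#' h-trees of a [measure_plot()] bundle, then predicts volume, final
#' height and biomass for every standing tree on the plot.
#'
#' @param bundle a `plot_bundle` from [measure_plot()].
#' @param allometry an [allometry_set()].
#' @param fallback correction factor for species groups without h-trees.
#' @return the bundle with `trees` gaining `volume_m3`, `height_m`,
#'   `agb_kg`, `bgb_kg`; corrections stored as `bundle$corrections`.
#' @export
predict_plot_volumes <- function(bundle, allometry = default_allometry(),
                                 fallback = 1) {
  trees <- bundle$trees
  h <- trees[trees$h_tree %in% TRUE, , drop = FALSE]
  if (nrow(h)) {
    h$height_measured <- h$measured_height
    uniform <- all(trees$h_tree %in% TRUE | !trees$status %in% "live")
    corr <- plot_correction_factors(h, allometry,
                                    uniform_weights = uniform)
  } else {
    corr <- plot_correction_factors(data.frame(), allometry)
  }
  trees$height_measured <- trees$measured_height
  trees <- predict_tree_volume(trees, allometry, corrections = corr,
                               fallback = fallback)
  bm <- predict_biomass(trees$species_group, trees$dbh, allometry)
  trees$agb_kg <- bm$above_kg
  trees$bgb_kg <- bm$below_kg
  bundle$trees <- trees
  bundle$corrections <- corr
  bundle
}
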