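#' Stratum frame for design-based estimation
#'
#' Per-stratum bookkeeping for the expansion estimators: the sampling
#' weight (km^2 of land each plot represents) and, optionally, an official
#' stratum land area. When no area is given, the self-consistent expansion
#' area `n_h * w_h` is used.
#'
#' @param stratum stratum ids.
#' @param weight_km2 sampling weight per plot (km^2), > 0.
#' @param area_km2 optional known stratum land areas (km^2).
#' @return data.frame of class `stratum_frame`.
#' @export
stratum_frame <- function(stratum = 1:4,
                          weight_km2 = stratum_definitions()$weight_km2,
                          area_km2 = NA_real_) {
  stopifnot(length(stratum) == length(weight_km2), all(weight_km2 > 0),
            !anyDuplicated(stratum))
  out <- data.frame(stratum = stratum, weight_km2 = weight_km2,
                    area_km2 = area_km2)
  class(out) <- c("stratum_frame", "data.frame")
  out
}

#' Estimation result container
#'
#' @param domain domain label.
#' @param estimate point estimate.
#' @param se standard error (same units), >= 0.
#' @param n_plots number of plots used.
#' @param estimator one of `"expansion"`, `"proportion"`, `"lis"`,
#'   `"synthetic"`.
#' @param units units label.
#' @export
estimation_result <- function(domain, estimate, se, n_plots, estimator,
                              units = "") {
  stopifnot(is.na(se) || se >= 0, n_plots >= 0)
  structure(list(domain = domain, estimate = estimate, se = se,
                 n_plots = as.integer(n_plots), estimator = estimator,
                 units = units),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf("<estimation_result> %s [%s]\n  %.6g %s (SE %.4g, n = %d)\n",
              x$domain, x$estimator, x$estimate, x$units, x$se, x$n_plots))
  invisible(x)
}

#' @export
as.data.frame.estimation_result <- function(x, ...) {
  data.frame(domain = x$domain, estimator = x$estimator,
             estimate = x$estimate, se = x$se, n_plots = x$n_plots,
             units = x$units, stringsAsFactors = FALSE)
}

check_frame <- function(plot_stratum, frame) {
  if (!all(plot_stratum %in% frame$stratum)) {
    stop("plots reference strata missing from the frame")
  }
}

#' Stratified expansion estimator of a population total
#'
#' Expands per-hectare plot values to the population total
#' \deqn{\hat T = \sum_h w_h \cdot 100 \cdot \sum_{i \in h} y_i,}
#' where `w_h` is the stratum sampling weight in km^2 per plot (x100
#' converts to ha). The variance uses the within-stratum sample variance
#' of plot values under a simple-random-sampling assumption (the NFI's
#' conservative choice for its systematic design), without finite
#' population correction:
#' \eqn{\widehat{Var} = \sum_h (100 w_h)^2 n_h s_h^2.}
#' Domain totals are obtained by passing indicator-multiplied values.
#' Strata with a single plot are collapsed into the nearest-id stratum for
#' variance estimation.
#'
#' @param values per-plot values per hectare (0 for plots outside the
#'   domain; every sampled plot must appear).
#' @param plot_stratum stratum id per plot.
#' @param frame a [stratum_frame()].
#' @param domain label.
#' @param units units label for the total.
#' @return an [estimation_result()].
#' @export
expand_total <- function(values, plot_stratum, frame, domain = "population",
                         units = "") {
  stopifnot(length(values) == length(plot_stratum))
  check_frame(plot_stratum, frame)
  idx <- match(plot_stratum, frame$stratum)
  w_ha <- frame$weight_km2[idx] * 100
  total <- sum(w_ha * values)
  # collapse singleton strata with their nearest neighbour for the variance
  var_stratum <- plot_stratum
  tab <- table(var_stratum)
  singletons <- as.numeric(names(tab)[tab < 2])
  for (s in singletons) {
    others <- setdiff(unique(var_stratum), s)
    if (!length(others)) break
    var_stratum[var_stratum == s] <- others[which.min(abs(others - s))]
  }
  v <- 0
  for (s in unique(var_stratum)) {
    i <- var_stratum == s
    n_h <- sum(i)
    if (n_h < 2) next
    w_h <- frame$weight_km2[match(s, frame$stratum)] * 100
    v <- v + w_h^2 * n_h * stats::var(values[i])
  }
  estimation_result(domain, total, sqrt(v), length(values), "expansion",
                    units)
}

#' Stratified proportion with SRS variance
#'
#' Combines within-stratum proportions by stratum area shares, with the
#' simple-random-sampling variance `p_h (1 - p_h) / (n_h - 1)` per
#' stratum. Stratum areas default to the self-consistent `n_h * w_h`.
#'
#' @param indicator 0/1 values per plot.
#' @param plot_stratum stratum id per plot.
#' @param frame a [stratum_frame()].
#' @param domain label.
#' @return an [estimation_result()] on the percentage scale.
#' @export
proportion_with_se <- function(indicator, plot_stratum, frame,
                               domain = "population") {
  stopifnot(length(indicator) == length(plot_stratum),
            all(indicator %in% 0:1))
  if (!length(indicator)) stop("no plots supplied")
  check_frame(plot_stratum, frame)
  strata <- unique(plot_stratum)
  p_h <- n_h <- a_h <- numeric(length(strata))
  for (k in seq_along(strata)) {
    i <- plot_stratum == strata[k]
    n_h[k] <- sum(i)
    p_h[k] <- mean(indicator[i])
    row <- match(strata[k], frame$stratum)
    a_h[k] <- if (!is.na(frame$area_km2[row])) frame$area_km2[row] else
      n_h[k] * frame$weight_km2[row]
  }
  share <- a_h / sum(a_h)
  p <- sum(share * p_h)
  v <- sum(share^2 * ifelse(n_h > 1, p_h * (1 - p_h) / (n_h - 1), 0))
  estimation_result(domain, 100 * p, 100 * sqrt(v), sum(n_h), "proportion",
                    units = "%")
}

#' Line-intersect estimate of downed deadwood volume
#'
#' Per-plot line-intersect-sampling (LIS) estimator from the diameters of
#' pieces crossing the transects:
#' \deqn{\hat v = \frac{\pi^2}{8 L} \sum_i d_i^2 \times 10^4
#' \quad [\mathrm{m^3\,ha^{-1}}],}
#' with `d_i` the intersection diameters in m and `L` the total transect
#' length in m (2 x 18 m unless truncated). Plot values are aggregated
#' over strata with [expand_total()] semantics on the mean per ha.
#'
#' @param diameters_cm intersection diameters (cm) on one plot.
#' @param transect_length_m total transect length on the plot (m).
#' @return deadwood volume in m^3 per ha for the plot.
#' @export
lis_plot_volume <- function(diameters_cm, transect_length_m = 36) {
  if (transect_length_m <= 0) {
    warning("zero transect length; plot excluded (NA)")
    return(NA_real_)
  }
  d_m <- diameters_cm / 100
  pi^2 / (8 * transect_length_m) * sum(d_m^2) * 1e4
}

#' @rdname lis_plot_volume
#' @param plot_values per-plot LIS volumes (m^3/ha), `NA` for excluded
#'   plots.
#' @param plot_stratum,frame,domain see [expand_total()].
#' @return `lis_deadwood_volume()`: an [estimation_result()] with the
#'   population mean in m^3/ha (area-weighted over strata) and its SRS
#'   standard error.
#' @export
lis_deadwood_volume <- function(plot_values, plot_stratum, frame,
                                domain = "deadwood") {
  keep <- !is.na(plot_values)
  if (!any(keep)) stop("no plots with usable transects")
  plot_values <- plot_values[keep]
  plot_stratum <- plot_stratum[keep]
  check_frame(plot_stratum, frame)
  strata <- unique(plot_stratum)
  m_h <- v_h <- n_h <- a_h <- numeric(length(strata))
  for (k in seq_along(strata)) {
    i <- plot_stratum == strata[k]
    n_h[k] <- sum(i)
    m_h[k] <- mean(plot_values[i])
    v_h[k] <- if (n_h[k] > 1) stats::var(plot_values[i]) / n_h[k] else 0
    row <- match(strata[k], frame$stratum)
    a_h[k] <- if (!is.na(frame$area_km2[row])) frame$area_km2[row] else
      n_h[k] * frame$weight_km2[row]
  }
  share <- a_h / sum(a_h)
  estimation_result(domain, sum(share * m_h), sqrt(sum(share^2 * v_h)),
                    sum(n_h), "lis", units = "m3/ha")
}

#' Synthetic small-area harvest estimate from raster maps
#'
#' Aggregates a standing-volume raster over change-mask cells within each
#' region and applies the utilization rate (by default 0.8: 20 % of the
#' standing volume is assumed to remain in the forest), mirroring how
#' harvested volume is derived as a map product by zeroing predicted
#' attributes in cells with a detected stand-replacing change. The
#' standing-volume raster is returned with changed cells set to zero.
#'
#' @param volume_raster standing volume [nfi_raster()] in m^3/ha.
#' @param change_mask 0/1 [nfi_raster()] on the same grid.
#' @param regions region membership: an [nfi_raster()] of region ids on
#'   the same grid, or a named list of polygons (two-column vertex
#'   matrices) rasterised by cell-center point-in-polygon.
#' @param utilization harvested fraction of standing volume.
#' @return list with `estimates` (data.frame `region`, `harvest_m3`,
#'   `n_cells`) and `updated_volume` (raster with changed cells zeroed).
#' @export
synthetic_harvest_estimate <- function(volume_raster, change_mask, regions,
                                       utilization = 0.8) {
  dv <- dim(volume_raster$values)
  same_grid <- function(r) {
    identical(dim(r$values), dv) &&
      isTRUE(all.equal(c(r$xmin, r$ymin, r$cellsize),
                       c(volume_raster$xmin, volume_raster$ymin,
                         volume_raster$cellsize)))
  }
  if (!same_grid(change_mask)) {
    stop("change mask is not co-registered with the volume raster")
  }
  if (inherits(regions, "nfi_raster")) {
    if (!same_grid(regions)) stop("region raster is not co-registered")
    region_id <- as.vector(regions$values)
    region_names <- sort(unique(region_id[!is.na(region_id)]))
  } else {
    xy <- raster_xy(volume_raster)
    region_id <- rep(NA_character_, nrow(xy))
    for (nm in names(regions)) {
      hit <- point_in_polygon(xy$x, xy$y, regions[[nm]])
      region_id[hit & is.na(region_id)] <- nm
    }
    region_id <- matrix(region_id, nrow = dv[1], ncol = dv[2], byrow = TRUE)
    region_id <- as.vector(region_id)
    region_names <- names(regions)
  }
  cell_ha <- volume_raster$cellsize^2 / 1e4
  vol <- as.vector(volume_raster$values)
  chg <- as.vector(change_mask$values) %in% 1
  est <- do.call(rbind, lapply(region_names, function(nm) {
    in_region <- !is.na(region_id) & region_id == nm
    cells <- in_region & chg
    data.frame(region = nm,
               harvest_m3 = utilization *
                 sum(vol[cells] * cell_ha, na.rm = TRUE),
               n_cells = sum(cells), stringsAsFactors = FALSE)
  }))
  updated <- volume_raster
  updated$values[matrix(chg, nrow = dv[1], ncol = dv[2])] <- 0
  list(estimates = est, updated_volume = updated)
}
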