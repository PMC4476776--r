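# Fishing effort in kW-days.
#
# AIS route: every message classified as fishing represents one reporting
# interval (default 300 s) of fishing by its vessel, so it contributes
# power_kW * interval / 86400 kW-days to the 1x1 nautical-mile grid cell
# containing it. Logbook route: a trip's whole duration (departure to
# arrival, fractional days) is allocated to the ICES rectangles where its
# catches were notified, proportionally to catch weight, and multiplied by
# engine power.

#' AIS fishing-effort grid
#'
#' Aggregates fishing-labelled messages to a regular grid of (nominally)
#' `cell_nm` x `cell_nm` nautical miles. The grid is a local equirectangular
#' grid anchored at the south-west corner of `region` (or of the fishing
#' messages' bounding box): cell height `cell_nm/60` degrees of latitude,
#' cell width `cell_nm / (60 cos(lat0))` degrees of longitude; cells are
#' half-open `[lo, hi)`.
#'
#' @param labeled labelled message table (`vessel_id`, `lon`, `lat`,
#'   `label`).
#' @param register table with `power` (kW) keyed by vessel: either a
#'   register with `register_id == vessel_id` or any data.frame with
#'   `vessel_id` and `power`.
#' @param interval seconds of fishing represented by one message.
#' @param cell_nm cell size in nautical miles.
#' @param region optional `c(lon_min, lon_max, lat_min, lat_max)` anchor.
#' @param weight_by_gap if TRUE, weight each message by the time gap to the
#'   vessel's next message, capped at `2 * interval` (for irregular feeds),
#'   instead of the fixed nominal interval.
#' @return object of class `effort_grid`: data.frame with `ix`, `iy` (cell
#'   indices), `lon`, `lat` (cell centroids) and `kw_days`; grid geometry,
#'   the grand total and the number of messages skipped for missing power
#'   are in attributes `origin`, `dlon`, `dlat`, `total`, `n_skipped`.
#' @export
ais_effort <- function(labeled, register, interval = 300, cell_nm = 1,
                       region = NULL, weight_by_gap = FALSE) {
  key <- if ("vessel_id" %in% names(register)) "vessel_id" else "register_id"
  power <- stats::setNames(register$power, register[[key]])
  fish <- labeled[labeled$label == "fishing", , drop = FALSE]
  pw <- power[fish$vessel_id]
  skipped <- sum(is.na(pw))
  fish <- fish[!is.na(pw), , drop = FALSE]
  pw <- pw[!is.na(pw)]

  if (weight_by_gap && nrow(fish)) {
    o <- order(labeled$vessel_id, labeled$timestamp)
    srt <- labeled[o, ]
    gap <- c(diff(as.numeric(srt$timestamp)), NA)
    gap[c(srt$vessel_id[-1] != srt$vessel_id[-nrow(srt)], TRUE)] <- NA
    gap <- pmin(gap, 2 * interval)
    gap[is.na(gap)] <- interval
    wmap <- stats::setNames(gap, srt$msg_id)
    w <- wmap[fish$msg_id]
  } else {
    w <- rep(interval, nrow(fish))
  }

  if (is.null(region)) {
    region <- if (nrow(fish))
      c(min(fish$lon), max(fish$lon), min(fish$lat), max(fish$lat))
    else c(0, 1, 0, 1)
  }
  lat0 <- region[3]; lon0 <- region[1]
  dlat <- cell_nm / 60
  dlon <- cell_nm / (60 * cos(lat0 * pi / 180))

  grid <- if (nrow(fish)) {
    ix <- floor((fish$lon - lon0) / dlon)
    iy <- floor((fish$lat - lat0) / dlat)
    eff <- pw * w / 86400
    agg <- aggregate(list(kw_days = eff), by = list(ix = ix, iy = iy),
                     FUN = sum)
    agg$lon <- lon0 + (agg$ix + 0.5) * dlon
    agg$lat <- lat0 + (agg$iy + 0.5) * dlat
    agg[, c("ix", "iy", "lon", "lat", "kw_days")]
  } else {
    data.frame(ix = integer(0), iy = integer(0), lon = numeric(0),
               lat = numeric(0), kw_days = numeric(0))
  }
  structure(grid, class = c("effort_grid", "data.frame"),
            origin = c(lon0, lat0), dlon = dlon, dlat = dlat,
            total = sum(grid$kw_days), n_skipped = skipped)
}

#' Logbook effort by ICES rectangle
#'
#' Each trip's duration (departure to arrival, fractional days) is split
#' across the ICES rectangles where it notified catches, proportionally to
#' catch weight, then multiplied by engine power to give kW-days. A
#' multi-rectangle trip with zero total catch is split equally and flagged.
#'
#' @param logbook one row per fishing operation: `trip_id`, `vessel_id`,
#'   `departure`, `arrival`, `catch_kg`, and either `ices_rect` or
#'   `op_lon`/`op_lat` (rectangles then computed).
#' @param register table with vessel `power` (kW), as in [ais_effort()].
#' @return data.frame `ices_rect`, `kw_days`; trips that needed the
#'   equal-split fallback are listed in `attr(, "zero_catch_trips")`, and
#'   the per-trip allocation table in `attr(, "allocation")`.
#' @export
logbook_effort <- function(logbook, register) {
  key <- if ("vessel_id" %in% names(register)) "vessel_id" else "register_id"
  power <- stats::setNames(register$power, register[[key]])
  lb <- logbook
  if (!"ices_rect" %in% names(lb))
    lb$ices_rect <- ices_encode(lb$op_lat, lb$op_lon)
  stopifnot(all(lb$catch_kg >= 0))
  zero_trips <- character(0)
  alloc <- list()
  for (tid in unique(lb$trip_id)) {
    tr <- lb[lb$trip_id == tid, , drop = FALSE]
    dur_days <- as.numeric(difftime(tr$arrival[1], tr$departure[1],
                                    units = "days"))
    if (dur_days <= 0) stop("trip ", tid, " has departure >= arrival")
    by_rect <- aggregate(list(catch = tr$catch_kg),
                         by = list(ices_rect = tr$ices_rect), FUN = sum)
    if (sum(by_rect$catch) > 0) {
      share <- by_rect$catch / sum(by_rect$catch)
    } else {
      share <- rep(1 / nrow(by_rect), nrow(by_rect))
      if (nrow(by_rect) > 1) zero_trips <- c(zero_trips, tid)
    }
    pw <- power[tr$vessel_id[1]]
    if (is.na(pw)) stop("no register power for vessel ", tr$vessel_id[1])
    alloc[[tid]] <- data.frame(trip_id = tid, ices_rect = by_rect$ices_rect,
                               days = dur_days * share,
                               kw_days = dur_days * share * pw,
                               stringsAsFactors = FALSE)
  }
  alloc <- do.call(rbind, c(alloc, list(make.row.names = FALSE)))
  out <- aggregate(list(kw_days = alloc$kw_days),
                   by = list(ices_rect = alloc$ices_rect), FUN = sum)
  attr(out, "zero_catch_trips") <- zero_trips
  attr(out, "allocation") <- alloc
  out
}

#' Compare AIS-derived and logbook-derived effort
#'
#' Re-aggregates the AIS effort grid to ICES rectangles (by cell centroid)
#' and joins it with the logbook effort. The AIS figures count fishing time
#' only while logbooks count the whole trip, so logbook values are expected
#' to be systematically higher; what should agree is the spatial pattern,
#' summarised by the Spearman rank correlation across occupied rectangles.
#'
#' @param grid an `effort_grid` from [ais_effort()].
#' @param lb_effort output of [logbook_effort()].
#' @return data.frame `ices_rect`, `ais_kw_days`, `logbook_kw_days`
#'   (absent values filled with 0); the rank correlation is in
#'   `attr(, "rank_correlation")` (`NA` with a flag when the supports are
#'   disjoint or degenerate).
#' @export
compare_efforts <- function(grid, lb_effort) {
  ais_rect <- if (nrow(grid)) {
    g <- data.frame(rect = ices_encode(grid$lat, grid$lon),
                    kw = grid$kw_days)
    aggregate(list(ais_kw_days = g$kw), by = list(ices_rect = g$rect),
              FUN = sum)
  } else data.frame(ices_rect = character(0), ais_kw_days = numeric(0))
  out <- merge(ais_rect,
               stats::setNames(lb_effort[, c("ices_rect", "kw_days")],
                               c("ices_rect", "logbook_kw_days")),
               by = "ices_rect", all = TRUE)
  out$ais_kw_days[is.na(out$ais_kw_days)] <- 0
  out$logbook_kw_days[is.na(out$logbook_kw_days)] <- 0
  rc <- if (nrow(out) >= 2 && stats::sd(out$ais_kw_days) > 0 &&
            stats::sd(out$logbook_kw_days) > 0)
    stats::cor(out$ais_kw_days, out$logbook_kw_days, method = "spearman")
  else NA_real_
  attr(out, "rank_correlation") <- rc
  attr(out, "flag") <- if (is.na(rc)) "correlation undefined" else ""
  out
}
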