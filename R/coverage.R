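# AIS reception coverage from trajectory densities.
#
# Terrestrial AIS reception is line-of-sight, so message density understates
# traffic far from receivers. Per-vessel position series are split into
# trajectory segments at large time or distance gaps, interpolated at the
# nominal cadence, and both point sets are gridded at 0.1 degrees; the
# observed/expected ratio per cell estimates reception probability. Cells
# with no expected traffic are indeterminate (absence of ships vs absence
# of coverage cannot be distinguished there).

#' Split per-vessel messages into trajectory segments
#'
#' A new segment starts whenever the time gap to the previous message
#' exceeds `max_gap` seconds or the great-circle distance exceeds
#' `max_jump` nautical miles (which also separates two physical ships
#' sharing one identifier). Singleton segments are allowed.
#'
#' @param messages message table (`vessel_id`, `timestamp`, `lon`, `lat`),
#'   sorted per vessel by time (see [read_ais()]).
#' @param max_gap seconds.
#' @param max_jump nautical miles.
#' @return `messages` with a `segment` column (`vessel_id` + running index).
#' @export
build_trajectories <- function(messages, max_gap = 21600, max_jump = 20) {
  out <- messages[order(messages$vessel_id, messages$timestamp), ,
                  drop = FALSE]
  seg <- character(nrow(out))
  for (v in unique(out$vessel_id)) {
    idx <- which(out$vessel_id == v)
    if (length(idx) == 1L) {
      seg[idx] <- paste0(v, "-1")
      next
    }
    dt <- diff(as.numeric(out$timestamp[idx]))
    dd <- geosphere::distHaversine(
      cbind(out$lon[idx[-length(idx)]], out$lat[idx[-length(idx)]]),
      cbind(out$lon[idx[-1]], out$lat[idx[-1]])) / 1852
    brk <- dt > max_gap | dd > max_jump
    seg[idx] <- paste0(v, "-", cumsum(c(1L, as.integer(brk))))
  }
  out$segment <- seg
  rownames(out) <- NULL
  out
}

#' Interpolate trajectories at a fixed time step
#'
#' Linear interpolation in longitude/latitude between consecutive observed
#' points of each segment, at times `t1 + k * step < t2`; observed points
#' are included. Singleton segments contribute their single observed point.
#'
#' @param traj output of [build_trajectories()].
#' @param step seconds.
#' @return data.frame `vessel_id`, `segment`, `timestamp`, `lon`, `lat`,
#'   `interpolated` (logical).
#' @export
interpolate_trajectories <- function(traj, step = 300) {
  o <- order(traj$segment, traj$timestamp)
  tr <- traj[o, , drop = FALSE]
  n <- nrow(tr)
  obs <- data.frame(vessel_id = tr$vessel_id, segment = tr$segment,
                    timestamp = tr$timestamp, lon = tr$lon, lat = tr$lat,
                    interpolated = FALSE, stringsAsFactors = FALSE)
  out <- obs
  if (n >= 2L) {
    same <- tr$segment[-1L] == tr$segment[-n]
    i1 <- which(same)
    if (length(i1)) {
      dt <- as.numeric(tr$timestamp[i1 + 1L]) - as.numeric(tr$timestamp[i1])
      ki <- pmax(0, ceiling(dt / step) - 1L)
      keep <- ki > 0
      if (any(keep)) {
        idx <- rep(i1[keep], ki[keep])
        off <- sequence(ki[keep]) * step
        f <- off / rep(dt[keep], ki[keep])
        interp <- data.frame(
          vessel_id = tr$vessel_id[idx], segment = tr$segment[idx],
          timestamp = tr$timestamp[idx] + off,
          lon = tr$lon[idx] + f * (tr$lon[idx + 1L] - tr$lon[idx]),
          lat = tr$lat[idx] + f * (tr$lat[idx + 1L] - tr$lat[idx]),
          interpolated = TRUE, stringsAsFactors = FALSE)
        out <- rbind(obs, interp)
      }
    }
  }
  out <- out[order(out$vessel_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage grid: observed vs expected position densities
#'
#' Counts observed messages and interpolated trajectory points per
#' `cell` x `cell` degree cell (half-open, anchored at multiples of `cell`)
#' and reports their ratio. Cells with interpolated (expected) count zero
#' but observed points are flagged `indeterminate`; only cells touched by
#' either point set appear.
#'
#' @param messages observed message table (`lon`, `lat`).
#' @param interpolated interpolated point set from
#'   [interpolate_trajectories()] (observed + interpolated points: the
#'   expected density under full reception).
#' @param cell cell size, degrees.
#' @return object of class `coverage_grid`: data.frame `lon`, `lat` (cell
#'   centroids), `observed`, `expected`, `ratio`, `flag` (`ok` or
#'   `indeterminate`).
#' @export
coverage_grid <- function(messages, interpolated, cell = 0.1) {
  cell_key <- function(lon, lat) {
    paste(floor(lon / cell), floor(lat / cell), sep = ":")
  }
  obs <- table(cell_key(messages$lon, messages$lat))
  exp_ <- table(cell_key(interpolated$lon, interpolated$lat))
  keys <- union(names(obs), names(exp_))
  ij <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  observed <- as.integer(ifelse(keys %in% names(obs), obs[keys], 0L))
  expected <- as.integer(ifelse(keys %in% names(exp_), exp_[keys], 0L))
  out <- data.frame(
    lon = (as.numeric(ij[, 1]) + 0.5) * cell,
    lat = (as.numeric(ij[, 2]) + 0.5) * cell,
    observed = observed, expected = expected,
    ratio = ifelse(expected > 0, observed / expected, NA_real_),
    flag = ifelse(expected > 0, "ok", "indeterminate"),
    stringsAsFactors = FALSE)
  out <- out[order(out$lon, out$lat), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("coverage_grid", "data.frame"), cell = cell)
}

#' Query a coverage grid at a point
#'
#' Returns the coverage row of the cell containing `(lon, lat)`. Cells never
#' touched by any expected traffic are reported as indeterminate (ratio
#' `NA`), never as 0: absence of expected traffic cannot distinguish empty
#' sea from missing reception.
#'
#' @param grid a `coverage_grid`.
#' @param lon,lat query position, decimal degrees.
#' @return one-row data.frame with `observed`, `expected`, `ratio`, `flag`.
#' @export
coverage_at <- function(grid, lon, lat) {
  cell <- attr(grid, "cell")
  hit <- floor(grid$lon / cell) == floor(lon / cell) &
    floor(grid$lat / cell) == floor(lat / cell)
  if (any(hit)) return(grid[which(hit)[1], c("observed", "expected",
                                             "ratio", "flag")])
  data.frame(observed = 0L, expected = 0L, ratio = NA_real_,
             flag = "indeterminate", stringsAsFactors = FALSE)
}
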