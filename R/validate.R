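# Validation of the fishing classification against logbooks.
#
# Logbooks give one point per fishing operation. Rather than a binary
# confusion matrix against an arbitrary spatio-temporal window, the
# classification is scored stochastically: a kernel utilisation distribution
# (UD) of each vessel's fishing grounds is estimated from its logbook
# points, every AIS message is assigned the UD raster value at its position
# (normalised per vessel to [0, 1]; higher = closer to the core fishing
# grounds), and a paired t test compares per-vessel mean scores of
# fishing-labelled vs non-fishing-labelled messages.

#' Estimate a kernel utilisation distribution from logbook points
#'
#' Bivariate Gaussian kernel density on a regular lon/lat grid, computed
#' with [MASS::kde2d()]. The bandwidth follows the ad hoc reference rule
#' `h = 0.5 * (sd(lon) + sd(lat)) * n^(-1/6)` (one `h` for both axes); the
#' grid covers the points' bounding box padded by `3 h` and the density is
#' renormalised to integrate to 1 over the raster.
#'
#' @param points data.frame of fishing-operation positions with `lon` and
#'   `lat` (decimal degrees); at least 5 points.
#' @param cell target cell size, degrees.
#' @param bandwidth optional bandwidth override, degrees.
#' @param pad_factor padding of the bounding box, in bandwidths.
#' @return object of class `ud_raster`: list with `x`, `y` (cell-centre
#'   coordinates), `z` (density matrix, `length(x)` x `length(y)`), `dx`,
#'   `dy` (actual cell sizes), `h`, `n_points`.
#' @export
estimate_ud <- function(points, cell = 0.01, bandwidth = NULL,
                        pad_factor = 3) {
  x <- points$lon; y <- points$lat
  n <- length(x)
  if (n < 5) stop("need at least 5 fishing-operation points")
  h <- if (is.null(bandwidth)) 0.5 * (stats::sd(x) + stats::sd(y)) * n^(-1/6)
       else bandwidth
  if (!is.finite(h) || h <= 0) h <- cell  # co-located points
  pad <- pad_factor * h
  lims <- c(min(x) - pad, max(x) + pad, min(y) - pad, max(y) + pad)
  nx <- max(2L, round((lims[2] - lims[1]) / cell) + 1L)
  ny <- max(2L, round((lims[4] - lims[3]) / cell) + 1L)
  # kde2d treats its h as 4x the Gaussian kernel SD
  k <- MASS::kde2d(x, y, h = 4 * h, n = c(nx, ny), lims = lims)
  dx <- k$x[2] - k$x[1]; dy <- k$y[2] - k$y[1]
  k$z <- k$z / (sum(k$z) * dx * dy)
  out <- list(x = k$x, y = k$y, z = k$z, dx = dx, dy = dy, h = h,
              n_points = n)
  class(out) <- "ud_raster"
  out
}

#' Score messages against a utilisation distribution
#'
#' Spatial overlay: each message takes the raster value of the cell
#' containing it (0 outside the raster), normalised by the vessel's maximum
#' raster value so scores live in [0, 1].
#'
#' @param messages message table with `lon`, `lat` (and ideally `msg_id`).
#' @param ud a `ud_raster` for the same vessel.
#' @return data.frame with `msg_id` (if present), `raw` and `score`.
#' @export
score_messages <- function(messages, ud) {
  zmax <- max(ud$z)
  if (zmax <= 0) stop("utilisation distribution is identically zero")
  ix <- round((messages$lon - ud$x[1]) / ud$dx) + 1L
  iy <- round((messages$lat - ud$y[1]) / ud$dy) + 1L
  inside <- ix >= 1L & ix <= length(ud$x) & iy >= 1L & iy <= length(ud$y)
  raw <- numeric(nrow(messages))
  raw[inside] <- ud$z[cbind(ix[inside], iy[inside])]
  out <- data.frame(raw = raw, score = raw / zmax)
  if ("msg_id" %in% names(messages)) out <- cbind(msg_id = messages$msg_id,
                                                  out)
  out
}

#' Paired comparison of fishing vs non-fishing validation scores
#'
#' Two-sided paired t test on per-vessel differences (fishing mean minus
#' non-fishing mean). If the differences have zero variance the t statistic
#' is undefined: identical score vectors are reported as `t = 0, p = 1`,
#' and a constant non-zero difference as `p = 0` with `degenerate = TRUE`.
#'
#' @param fishing,nonfishing per-vessel mean scores, aligned by vessel.
#' @return object of class `validation_summary`: list with `n_pairs`, `df`,
#'   `statistic`, `p_value`, `mean_fishing`, `sd_fishing`,
#'   `mean_nonfishing`, `sd_nonfishing`, `degenerate`.
#' @export
paired_test <- function(fishing, nonfishing) {
  ok <- is.finite(fishing) & is.finite(nonfishing)
  fishing <- fishing[ok]; nonfishing <- nonfishing[ok]
  n <- length(fishing)
  if (n < 2) stop("need at least 2 vessels with both label groups")
  d <- fishing - nonfishing
  degenerate <- stats::sd(d) == 0 && any(d != 0)
  if (all(d == 0)) {
    stat <- 0; p <- 1
  } else if (degenerate) {
    stat <- sign(d[1]) * Inf; p <- 0
  } else {
    tt <- stats::t.test(fishing, nonfishing, paired = TRUE)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  out <- list(n_pairs = n, df = n - 1L, statistic = stat, p_value = p,
              mean_fishing = mean(fishing), sd_fishing = stats::sd(fishing),
              mean_nonfishing = mean(nonfishing),
              sd_nonfishing = stats::sd(nonfishing),
              degenerate = degenerate)
  class(out) <- "validation_summary"
  out
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("Validation of fishing classification (paired t test)\n")
  cat(sprintf("  fishing     : %.3f +/- %.3f\n", x$mean_fishing,
              x$sd_fishing))
  cat(sprintf("  non-fishing : %.3f +/- %.3f\n", x$mean_nonfishing,
              x$sd_nonfishing))
  cat(sprintf("  t = %.3f, df = %d, p = %.3g%s\n", x$statistic, x$df,
              x$p_value,
              if (x$degenerate) " (zero-variance differences)" else ""))
  invisible(x)
}

#' Validate a fleet's classification against its logbooks
#'
#' Per vessel: estimate the UD from its logbook fishing-operation points
#' (vessels with fewer than `min_points` are excluded and logged), score
#' all its labelled messages, and average scores by label. Vessels missing
#' either label group are excluded from the paired test.
#'
#' @param labeled labelled message table (see [detect_fishing()]).
#' @param logbook logbook table with `vessel_id`, `op_lon`, `op_lat`.
#' @param cell UD raster cell size, degrees.
#' @param min_points minimum logbook points per vessel.
#' @return list with `per_vessel` (vessel_id, mean_fishing,
#'   mean_nonfishing, n_fishing, n_nonfishing), `summary`
#'   (a `validation_summary`), and `excluded` (vessel ids).
#' @export
validate_classification <- function(labeled, logbook, cell = 0.01,
                                    min_points = 5) {
  vessels <- intersect(unique(labeled$vessel_id),
                       unique(logbook$vessel_id))
  rows <- list(); excluded <- character(0)
  for (v in vessels) {
    pts <- logbook[logbook$vessel_id == v, , drop = FALSE]
    pts <- data.frame(lon = pts$op_lon, lat = pts$op_lat)
    if (nrow(pts) < min_points) {
      excluded <- c(excluded, v)
      next
    }
    ud <- estimate_ud(pts, cell = cell)
    mv <- labeled[labeled$vessel_id == v, , drop = FALSE]
    sc <- score_messages(mv, ud)
    fi <- mv$label == "fishing"
    rows[[v]] <- data.frame(
      vessel_id = v,
      mean_fishing = if (any(fi)) mean(sc$score[fi]) else NA_real_,
      mean_nonfishing = if (any(!fi)) mean(sc$score[!fi]) else NA_real_,
      n_fishing = sum(fi), n_nonfishing = sum(!fi),
      stringsAsFactors = FALSE)
  }
  per_vessel <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  summary <- if (!is.null(per_vessel) &&
                 sum(stats::complete.cases(
                   per_vessel[, c("mean_fishing", "mean_nonfishing")])) >= 2)
    paired_test(per_vessel$mean_fishing, per_vessel$mean_nonfishing)
  else NULL
  list(per_vessel = per_vessel, summary = summary, excluded = excluded)
}
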