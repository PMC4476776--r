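# Synthetic fleet simulator. Emulates the statistical structure the pipeline
# assumes: bimodal per-vessel speed profiles (slow towing mode, fast steaming
# mode), regular 5-minute AIS cadence, spatially clustered fishing grounds,
# register typos and spatially varying reception dropout.

#' Simulator configuration
#'
#' Builds and validates the configuration for [simulate_fleet()]. Defaults
#' describe a small demersal-trawler fleet working the Skagerrak/Kattegat:
#' towing at 3 +/- 0.5 kn, steaming at 10 +/- 1 kn, reporting every 300 s,
#' and spending 60% of its at-sea time fishing.
#'
#' @param n_vessels number of vessels in the fleet.
#' @param region bounding box `c(lon_min, lon_max, lat_min, lat_max)` in
#'   WGS84 decimal degrees; must be non-degenerate.
#' @param nominal_interval AIS reporting interval, seconds.
#' @param fishing_speed_mean,fishing_speed_sd towing-mode speed, knots.
#' @param steaming_speed_mean,steaming_speed_sd steaming-mode speed, knots.
#' @param fishing_fraction fraction of at-sea time spent fishing, in (0, 1).
#' @param trips_per_vessel trips per vessel over the simulated period.
#' @param dropout_map AIS reception probability: either a single number in
#'   `[0, 1]` or a `function(lon, lat)` returning per-position reception
#'   probabilities (a per-cell map is a step function). 1 = perfect
#'   reception.
#' @param typo_rate fraction of register rows corrupted by [inject_typos()]
#'   when the register is written with typos.
#' @param steam_hours,fishing_hours optional fixed per-leg durations (hours).
#'   By default the steaming time follows from the port-to-ground distance at
#'   the steaming speed and the fishing time from `fishing_fraction`.
#' @param port_dwell_hours in-port dwell before each trip, hours (speed 0).
#' @param ground_scatter_sd spatial scatter of towing positions around the
#'   fishing-ground centroid, degrees.
#' @param seed integer seed; the whole simulation is a pure function of the
#'   configuration.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_vessels = 30,
                       region = c(9.5, 13.5, 56.5, 58.5),
                       nominal_interval = 300,
                       fishing_speed_mean = 3, fishing_speed_sd = 0.5,
                       steaming_speed_mean = 10, steaming_speed_sd = 1,
                       fishing_fraction = 0.6,
                       trips_per_vessel = 8,
                       dropout_map = 1,
                       typo_rate = 0,
                       steam_hours = NULL,
                       fishing_hours = NULL,
                       port_dwell_hours = 1,
                       ground_scatter_sd = 0.02,
                       seed = 1L) {
  cfg <- list(n_vessels = as.integer(n_vessels), region = as.numeric(region),
              nominal_interval = as.numeric(nominal_interval),
              fishing_speed_mean = fishing_speed_mean,
              fishing_speed_sd = fishing_speed_sd,
              steaming_speed_mean = steaming_speed_mean,
              steaming_speed_sd = steaming_speed_sd,
              fishing_fraction = fishing_fraction,
              trips_per_vessel = as.integer(trips_per_vessel),
              dropout_map = dropout_map, typo_rate = typo_rate,
              steam_hours = steam_hours, fishing_hours = fishing_hours,
              port_dwell_hours = port_dwell_hours,
              ground_scatter_sd = ground_scatter_sd,
              seed = as.integer(seed))
  if (cfg$n_vessels < 1L || cfg$trips_per_vessel < 1L)
    stop("configuration error: counts must be positive")
  if (length(cfg$region) != 4 || cfg$region[1] >= cfg$region[2] ||
      cfg$region[3] >= cfg$region[4])
    stop("configuration error: degenerate region")
  if (cfg$nominal_interval <= 0)
    stop("configuration error: nominal_interval must be positive")
  if (!(cfg$fishing_fraction > 0 && cfg$fishing_fraction < 1))
    stop("configuration error: fishing_fraction must be in (0, 1)")
  if (cfg$fishing_speed_mean >= cfg$steaming_speed_mean)
    stop("configuration error: fishing speed mode must lie below steaming mode")
  if (cfg$fishing_speed_sd <= 0 || cfg$steaming_speed_sd <= 0)
    stop("configuration error: speed SDs must be positive")
  if (!(cfg$typo_rate >= 0 && cfg$typo_rate <= 1))
    stop("configuration error: typo_rate must be in [0, 1]")
  if (is.numeric(cfg$dropout_map) &&
      !(cfg$dropout_map >= 0 && cfg$dropout_map <= 1))
    stop("configuration error: dropout_map probability must be in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# Gaussian truncated at 0 by rejection; modes sit well above 0 so the
# rejection rate is negligible.
.rtnorm0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

# Snap a duration (seconds) to a whole number of reporting intervals, at
# least one, so that segment message counts are exactly duration/interval.
.snap <- function(sec, interval) pmax(interval, round(sec / interval) * interval)

.dropout_prob <- function(dropout_map, lon, lat) {
  if (is.function(dropout_map)) dropout_map(lon, lat)
  else rep_len(as.numeric(dropout_map), length(lon))
}

.SIM_EPOCH <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

#' Simulate a fleet: register, AIS messages, logbook and ground truth
#'
#' Each vessel repeats a port -> steam -> fish -> steam -> port cycle.
#' Per-message speeds are drawn from the behavioural state's Gaussian
#' truncated at 0 kn (port messages report exactly 0 kn); positions are
#' piecewise linear between port and fishing ground, with towing positions
#' scattered around the ground centroid. Messages are emitted at the segment
#' start and every `nominal_interval` thereafter, half-open at the segment
#' end; segment durations are whole multiples of the interval, so a segment
#' of duration `d` emits exactly `d / nominal_interval` messages. Each
#' message is then retained independently with the reception probability of
#' the dropout map at its position. One logbook fishing-operation record is
#' emitted per fishing segment, located at the ground centroid, with a
#' positive catch weight.
#'
#' @param config a [sim_config()] object.
#' @return list with components
#'   \describe{
#'     \item{register}{fleet register: `register_id`, `callsign`, `name`,
#'       `length`, `power` (kW), `port_id`, `port_lat`, `port_lon`.}
#'     \item{messages}{AIS messages: `msg_id`, `vessel_id`, `callsign`,
#'       `name`, `timestamp` (POSIXct UTC), `lat`, `lon`, `speed` (kn).}
#'     \item{logbook}{one row per fishing operation: `trip_id`, `vessel_id`,
#'       `departure`, `arrival`, `op_lat`, `op_lon`, `catch_kg`, `gear`,
#'       `ices_rect`.}
#'     \item{truth}{ground truth: `states` (per retained message behavioural
#'       state), `emitted` (pre-dropout per-state message counts),
#'       `params` (per-vessel true mixture parameters), `grounds`
#'       (fishing-ground centroids), `segments` (the segment plan).}
#'   }
#' @export
#' @examples
#' sim <- simulate_fleet(sim_config(n_vessels = 2, trips_per_vessel = 2))
#' table(sim$truth$states$state)
simulate_fleet <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  rg <- config$region
  dt <- config$nominal_interval
  n <- config$n_vessels

  register <- data.frame(
    register_id = sprintf("REG%03d", seq_len(n)),
    callsign = sprintf("S%s%s%04d",
                       sample(LETTERS, n, replace = TRUE),
                       sample(LETTERS, n, replace = TRUE),
                       sample(0:9999, n)),
    name = paste0("FV ",
                  sample(c("NORD", "VEST", "STELLA", "BRIS", "SKAGEN",
                           "HAVET", "DELFIN", "ORION", "MARINA", "FALKEN"),
                         n, replace = TRUE),
                  " ", sample(LETTERS, n, replace = TRUE), seq_len(n)),
    length = round(stats::runif(n, 15, 40), 1),
    power = round(stats::runif(n, 200, 1500)),
    stringsAsFactors = FALSE
  )
  n_ports <- max(1L, ceiling(n / 10))
  ports <- data.frame(
    port_id = sprintf("PORT%02d", seq_len(n_ports)),
    port_lon = stats::runif(n_ports, rg[1], rg[2]),
    port_lat = stats::runif(n_ports, rg[3], rg[4])
  )
  pidx <- sample(n_ports, n, replace = TRUE)
  register$port_id <- ports$port_id[pidx]
  register$port_lat <- ports$port_lat[pidx]
  register$port_lon <- ports$port_lon[pidx]

  # fishing-ground centroids: 1-3 per vessel, inside the inner 80% of region
  pad_lon <- 0.1 * (rg[2] - rg[1]); pad_lat <- 0.1 * (rg[4] - rg[3])
  grounds <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    data.frame(vessel_id = register$register_id[i],
               ground_id = seq_len(k),
               lon = stats::runif(k, rg[1] + pad_lon, rg[2] - pad_lon),
               lat = stats::runif(k, rg[3] + pad_lat, rg[4] - pad_lat))
  }))

  seg_list <- list(); msg_list <- list(); log_list <- list()
  for (i in seq_len(n)) {
    vid <- register$register_id[i]
    p_lon <- register$port_lon[i]; p_lat <- register$port_lat[i]
    g <- grounds[grounds$vessel_id == vid, , drop = FALSE]
    t_cur <- .SIM_EPOCH
    for (trip in seq_len(config$trips_per_vessel)) {
      gi <- g[sample(nrow(g), 1), ]
      dist_nm <- geosphere::distHaversine(c(p_lon, p_lat),
                                          c(gi$lon, gi$lat)) / 1852
      steam_sec <- if (is.null(config$steam_hours))
        .snap(dist_nm / config$steaming_speed_mean * 3600, dt)
      else .snap(config$steam_hours * 3600, dt)
      fish_sec <- if (is.null(config$fishing_hours))
        .snap(config$fishing_fraction / (1 - config$fishing_fraction) *
                2 * steam_sec, dt)
      else .snap(config$fishing_hours * 3600, dt)
      port_sec <- .snap(config$port_dwell_hours * 3600, dt)

      durs <- c(port_sec, steam_sec, fish_sec, steam_sec)
      states <- c("in-port", "steaming", "fishing", "steaming")
      t0 <- t_cur
      for (s in seq_along(durs)) {
        seg_list[[length(seg_list) + 1L]] <- data.frame(
          vessel_id = vid, trip_id = sprintf("%s-T%02d", vid, trip),
          segment = s, state = states[s],
          t_start = t0, t_end = t0 + durs[s],
          from_lon = switch(states[s], "in-port" = p_lon,
                            "fishing" = gi$lon,
                            if (s == 2) p_lon else gi$lon),
          from_lat = switch(states[s], "in-port" = p_lat,
                            "fishing" = gi$lat,
                            if (s == 2) p_lat else gi$lat),
          to_lon = switch(states[s], "in-port" = p_lon, "fishing" = gi$lon,
                          if (s == 2) gi$lon else p_lon),
          to_lat = switch(states[s], "in-port" = p_lat, "fishing" = gi$lat,
                          if (s == 2) gi$lat else p_lat),
          ground_lon = gi$lon, ground_lat = gi$lat
        )
        t0 <- t0 + durs[s]
      }
      # logbook: one operation per fishing segment, at the ground centroid
      dep <- t_cur + port_sec
      arr <- t_cur + port_sec + 2 * steam_sec + fish_sec
      log_list[[length(log_list) + 1L]] <- data.frame(
        trip_id = sprintf("%s-T%02d", vid, trip), vessel_id = vid,
        departure = dep, arrival = arr,
        op_lat = gi$lat, op_lon = gi$lon,
        catch_kg = round(stats::rlnorm(1, log(500 * fish_sec / 3600), 0.4), 1),
        gear = "OTB",
        ices_rect = ices_encode(gi$lat, gi$lon),
        stringsAsFactors = FALSE
      )
      t_cur <- t0
    }
  }
  segments <- do.call(rbind, seg_list)
  logbook <- do.call(rbind, log_list)

  # emit messages segment by segment
  msg <- do.call(rbind, lapply(seq_len(nrow(segments)), function(k) {
    s <- segments[k, ]
    dur <- as.numeric(difftime(s$t_end, s$t_start, units = "secs"))
    nm <- floor(dur / dt)
    if (nm < 1) return(NULL)
    tt <- s$t_start + (seq_len(nm) - 1L) * dt
    frac <- (as.numeric(tt - s$t_start)) / dur
    if (s$state == "fishing") {
      lon <- s$ground_lon + stats::rnorm(nm, 0, config$ground_scatter_sd)
      lat <- s$ground_lat + stats::rnorm(nm, 0, config$ground_scatter_sd)
      spd <- .rtnorm0(nm, config$fishing_speed_mean, config$fishing_speed_sd)
    } else if (s$state == "steaming") {
      lon <- s$from_lon + frac * (s$to_lon - s$from_lon)
      lat <- s$from_lat + frac * (s$to_lat - s$from_lat)
      spd <- .rtnorm0(nm, config$steaming_speed_mean, config$steaming_speed_sd)
    } else {
      lon <- rep(s$from_lon, nm); lat <- rep(s$from_lat, nm)
      spd <- rep(0, nm)
    }
    data.frame(vessel_id = s$vessel_id, trip_id = s$trip_id,
               segment = s$segment, state = s$state,
               timestamp = tt, lat = lat, lon = lon,
               speed = round(spd, 2), stringsAsFactors = FALSE)
  }))
  msg$msg_id <- sprintf("M%07d", seq_len(nrow(msg)))
  emitted <- as.data.frame(table(state = msg$state),
                           responseName = "n_emitted")

  keep <- stats::runif(nrow(msg)) < .dropout_prob(config$dropout_map,
                                                  msg$lon, msg$lat)
  msg <- msg[keep, , drop = FALSE]

  ri <- match(msg$vessel_id, register$register_id)
  messages <- data.frame(msg_id = msg$msg_id, vessel_id = msg$vessel_id,
                         callsign = register$callsign[ri],
                         name = register$name[ri],
                         timestamp = msg$timestamp,
                         lat = round(msg$lat, 5), lon = round(msg$lon, 5),
                         speed = msg$speed, stringsAsFactors = FALSE)
  rownames(messages) <- NULL
  states <- data.frame(msg_id = msg$msg_id, vessel_id = msg$vessel_id,
                       trip_id = msg$trip_id, state = msg$state,
                       stringsAsFactors = FALSE)
  rownames(states) <- NULL

  params <- data.frame(vessel_id = register$register_id,
                       fishing_speed_mean = config$fishing_speed_mean,
                       fishing_speed_sd = config$fishing_speed_sd,
                       steaming_speed_mean = config$steaming_speed_mean,
                       steaming_speed_sd = config$steaming_speed_sd)

  list(register = register, messages = messages, logbook = logbook,
       truth = list(states = states, emitted = emitted, params = params,
                    grounds = grounds, segments = segments))
}

#' Corrupt register identifiers with typing errors
#'
#' Applies one random single-character substitution, deletion or adjacent
#' transposition to the callsign (and, independently, the name) of a
#' `typo_rate` fraction of register rows, emulating the hand-keyed
#' misspellings that defeat exact register joins. The mapping from corrupted
#' to original values is returned so linkage recall can be measured.
#'
#' @param register a fleet register data.frame with `callsign` and `name`.
#' @param typo_rate fraction of rows to corrupt, in `[0, 1]`.
#' @param seed integer seed.
#' @return the register with corrupted identifiers; the original values are
#'   attached as `attr(, "typo_map")` (columns `register_id`, `field`,
#'   `original`, `corrupted`).
#' @export
inject_typos <- function(register, typo_rate, seed = 1L) {
  stopifnot(all(nchar(register$callsign) > 0))
  if (!(typo_rate >= 0 && typo_rate <= 1))
    stop("typo_rate must be in [0, 1]")
  set.seed(as.integer(seed))
  n <- nrow(register)
  n_bad <- round(typo_rate * n)
  map <- data.frame(register_id = character(0), field = character(0),
                    original = character(0), corrupted = character(0),
                    stringsAsFactors = FALSE)
  if (n_bad > 0) {
    rows <- sample(n, n_bad)
    for (i in rows) {
      for (field in c("callsign", "name")) {
        orig <- register[[field]][i]
        corr <- .one_typo(orig)
        register[[field]][i] <- corr
        map <- rbind(map, data.frame(register_id = register$register_id[i],
                                     field = field, original = orig,
                                     corrupted = corr,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  attr(register, "typo_map") <- map
  register
}

# One keystroke error: substitution by a different character, deletion, or
# an adjacent transposition of two distinct characters. Each leaves the
# string at optimal-string-alignment distance exactly 1 from the original.
.one_typo <- function(s) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  alphabet <- c(LETTERS, 0:9)
  ops <- c("sub", "del", if (L >= 2) "swap")
  op <- sample(ops, 1)
  if (op == "swap") {
    cand <- which(ch[-L] != ch[-1])
    if (!length(cand)) op <- "sub" else {
      j <- if (length(cand) == 1) cand else sample(cand, 1)
      ch[c(j, j + 1)] <- ch[c(j + 1, j)]
      return(paste(ch, collapse = ""))
    }
  }
  if (op == "del" && L >= 2) {
    j <- sample(L, 1)
    return(paste(ch[-j], collapse = ""))
  }
  j <- sample(L, 1)
  ch[j] <- sample(setdiff(alphabet, ch[j]), 1)
  paste(ch, collapse = "")
}

#' Write a simulated fleet to CSV files
#'
#' Writes `register.csv`, `ais.csv`, `logbook.csv` and the ground-truth
#' sidecar `truth_states.csv` into `dir`, with ISO-8601 UTC timestamps and
#' WGS84 decimal-degree coordinates.
#'
#' @param sim output of [simulate_fleet()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  msg <- sim$messages
  msg$timestamp <- format(msg$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  lb <- sim$logbook
  lb$departure <- format(lb$departure, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  lb$arrival <- format(lb$arrival, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(sim$register, file.path(dir, "register.csv"),
                   row.names = FALSE)
  utils::write.csv(msg, file.path(dir, "ais.csv"), row.names = FALSE)
  utils::write.csv(lb, file.path(dir, "logbook.csv"), row.names = FALSE)
  utils::write.csv(sim$truth$states, file.path(dir, "truth_states.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Draw an at-sea speed profile from the two-regime model
#'
#' Samples `n` per-message speeds from the simulator's at-sea speed model:
#' with probability `fishing_fraction` the towing Gaussian, otherwise the
#' steaming Gaussian, both truncated at 0 kn. The true state of every draw
#' is returned, which makes the sample a labelled test bed for the mixture
#' fit and the fishing-band classifier.
#'
#' @param n number of speeds.
#' @param fishing_fraction probability a draw is a fishing speed.
#' @param fishing_speed_mean,fishing_speed_sd towing mode, knots.
#' @param steaming_speed_mean,steaming_speed_sd steaming mode, knots.
#' @param seed integer seed.
#' @return data.frame with `speed` (kn) and `state`
#'   (`fishing`/`steaming`).
#' @export
simulate_speeds <- function(n, fishing_fraction = 0.6,
                            fishing_speed_mean = 3, fishing_speed_sd = 0.5,
                            steaming_speed_mean = 10,
                            steaming_speed_sd = 1, seed = 1L) {
  set.seed(as.integer(seed))
  fishing <- stats::runif(n) < fishing_fraction
  speed <- numeric(n)
  speed[fishing] <- .rtnorm0(sum(fishing), fishing_speed_mean,
                             fishing_speed_sd)
  speed[!fishing] <- .rtnorm0(sum(!fishing), steaming_speed_mean,
                              steaming_speed_sd)
  data.frame(speed = speed,
             state = ifelse(fishing, "fishing", "steaming"),
             stringsAsFactors = FALSE)
}
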