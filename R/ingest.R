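# Ingestion and record linkage: read/validate the three input tables, link
# AIS-observed vessels to the fleet register by exact then fuzzy string
# matching, and compute uptake statistics.

#' Read and validate an AIS message table
#'
#' Reads a headered CSV of position messages (or validates a data.frame with
#' the same columns). Rows with unparsable timestamps, out-of-range
#' coordinates (|lat| > 90, |lon| > 180) or negative/non-numeric speeds are
#' dropped and counted in a rejection log; duplicate (vessel, timestamp)
#' rows are reduced to one. Output is stably sorted by vessel then
#' timestamp.
#'
#' @param path CSV path, or a data.frame.
#' @return the cleaned message data.frame, with the rejection log (columns
#'   `reason`, `n`) attached as `attr(, "rejections")`.
#' @export
read_ais <- function(path) {
  x <- if (is.data.frame(path)) path
       else utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("vessel_id", "timestamp", "lat", "lon", "speed")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("format error: missing required column(s): ",
         paste(miss, collapse = ", "))
  rej <- list()
  if (!inherits(x$timestamp, "POSIXct")) {
    ts <- as.POSIXct(as.character(x$timestamp),
                     tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                    "%Y-%m-%dT%H:%M:%OS",
                                    "%Y-%m-%d %H:%M:%OS"),
                     optional = TRUE)
    x$timestamp <- ts
  }
  for (col in c("lat", "lon", "speed"))
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  bad_ts <- is.na(x$timestamp)
  bad_coord <- !is.finite(x$lat) | !is.finite(x$lon) |
    abs(x$lat) > 90 | abs(x$lon) > 180
  bad_speed <- !is.finite(x$speed) | x$speed < 0
  rej$bad_timestamp <- sum(bad_ts)
  rej$bad_coordinates <- sum(bad_coord & !bad_ts)
  rej$bad_speed <- sum(bad_speed & !bad_ts & !bad_coord)
  x <- x[!(bad_ts | bad_coord | bad_speed), , drop = FALSE]
  x <- x[order(x$vessel_id, x$timestamp), , drop = FALSE]  # stable
  dup <- duplicated(x[, c("vessel_id", "timestamp")])
  rej$duplicate <- sum(dup)
  x <- x[!dup, , drop = FALSE]
  rownames(x) <- NULL
  attr(x, "rejections") <- data.frame(reason = names(rej),
                                      n = unlist(rej, use.names = FALSE))
  x
}

#' Distinct AIS-observed vessels
#'
#' Collapses a message table to one row per transmitting vessel with its
#' broadcast static identifiers, the AIS-side input to [link_register()].
#'
#' @param messages an AIS message table with `vessel_id` and, optionally,
#'   `callsign` and `name`.
#' @return data.frame with columns `ais_vessel_id`, `callsign`, `name`.
#' @export
ais_vessels <- function(messages) {
  first <- !duplicated(messages$vessel_id)
  data.frame(ais_vessel_id = messages$vessel_id[first],
             callsign = if ("callsign" %in% names(messages))
               messages$callsign[first] else "",
             name = if ("name" %in% names(messages))
               messages$name[first] else "",
             stringsAsFactors = FALSE)
}

#' Link AIS-observed vessels to the fleet register
#'
#' Three-step record linkage. Step 0 joins exactly on the (normalised)
#' callsign. The remaining rows go through two fuzzy steps — first on vessel
#' names, then on callsigns — where a candidate pair is accepted only when
#' its similarity reaches `threshold` *and* it is the unique mutual best:
#' each side is the other's argmax with a strictly positive margin over the
#' runner-up (exact ties reject both sides). Similarity is the larger of the
#' normalised Levenshtein similarity (`1 - d/max(len)`) and the Jaro
#' similarity, so both character edits and adjacent transpositions are
#' tolerated. The result is one-to-one by construction.
#'
#' @param register fleet register with `register_id`, `callsign`, `name`.
#' @param ais AIS vessel list with `ais_vessel_id`, `callsign`, `name`
#'   (see [ais_vessels()]).
#' @param threshold minimum normalised similarity for a fuzzy match.
#' @param exact_first keep the exact-callsign step before the fuzzy steps.
#' @return data.frame with one row per register vessel and per unmatched AIS
#'   vessel: `register_id`, `ais_vessel_id`, `method` (`exact`,
#'   `fuzzy-name`, `fuzzy-callsign` or `unmatched`), `similarity`. The
#'   match rate over register vessels is attached as `attr(, "match_rate")`.
#' @export
link_register <- function(register, ais, threshold = 0.85,
                          exact_first = TRUE) {
  if (!nrow(register) || !nrow(ais))
    stop("register and AIS vessel tables must be non-empty")
  reg <- data.frame(register_id = register$register_id,
                    cs = normalize_id(register$callsign),
                    nm = normalize_id(register$name),
                    stringsAsFactors = FALSE)
  av <- data.frame(ais_vessel_id = ais$ais_vessel_id,
                   cs = normalize_id(ais$callsign),
                   nm = normalize_id(ais$name),
                   stringsAsFactors = FALSE)
  matches <- data.frame(register_id = character(0),
                        ais_vessel_id = character(0),
                        method = character(0), similarity = numeric(0),
                        stringsAsFactors = FALSE)
  free_r <- rep(TRUE, nrow(reg)); free_a <- rep(TRUE, nrow(av))

  if (exact_first) {
    # exact join on callsigns that are non-empty and unique on both sides
    cs_r <- reg$cs; cs_a <- av$cs
    uniq_r <- names(which(table(cs_r[cs_r != ""]) == 1))
    uniq_a <- names(which(table(cs_a[cs_a != ""]) == 1))
    common <- intersect(uniq_r, uniq_a)
    if (length(common)) {
      ir <- match(common, cs_r); ia <- match(common, cs_a)
      matches <- rbind(matches, data.frame(
        register_id = reg$register_id[ir],
        ais_vessel_id = av$ais_vessel_id[ia],
        method = "exact", similarity = 1,
        stringsAsFactors = FALSE))
      free_r[ir] <- FALSE; free_a[ia] <- FALSE
    }
  }

  for (step in c("fuzzy-name", "fuzzy-callsign")) {
    fld <- if (step == "fuzzy-name") "nm" else "cs"
    ir <- which(free_r & reg[[fld]] != "")
    ia <- which(free_a & av[[fld]] != "")
    if (!length(ir) || !length(ia)) next
    S <- .sim_matrix(reg[[fld]][ir], av[[fld]][ia])
    acc <- .mutual_best(S, threshold)
    if (nrow(acc)) {
      matches <- rbind(matches, data.frame(
        register_id = reg$register_id[ir[acc$i]],
        ais_vessel_id = av$ais_vessel_id[ia[acc$j]],
        method = step, similarity = acc$s,
        stringsAsFactors = FALSE))
      free_r[ir[acc$i]] <- FALSE; free_a[ia[acc$j]] <- FALSE
    }
  }

  nr <- sum(free_r); na <- sum(free_a)
  out <- rbind(matches,
               data.frame(register_id = reg$register_id[free_r],
                          ais_vessel_id = rep(NA_character_, nr),
                          method = rep("unmatched", nr),
                          similarity = rep(NA_real_, nr),
                          stringsAsFactors = FALSE),
               data.frame(register_id = rep(NA_character_, na),
                          ais_vessel_id = av$ais_vessel_id[free_a],
                          method = rep("unmatched", na),
                          similarity = rep(NA_real_, na),
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "match_rate") <-
    100 * sum(out$method != "unmatched") / nrow(reg)
  out
}

.sim_matrix <- function(a, b) {
  S <- matrix(0, length(a), length(b))
  for (i in seq_along(a)) {
    lev <- 1 - utils::adist(a[i], b)[1, ] / pmax(nchar(a[i]), nchar(b))
    jar <- vapply(b, function(x) .jaro1(a[i], x), numeric(1))
    S[i, ] <- pmax(lev, jar)
  }
  S
}

# Accept (i, j) iff S[i, j] >= thr and the pair is the unique mutual best:
# strictly above every other entry of row i and of column j.
.mutual_best <- function(S, thr) {
  acc <- list()
  for (i in seq_len(nrow(S))) {
    j <- which.max(S[i, ])
    s <- S[i, j]
    if (s < thr) next
    if (ncol(S) > 1 && any(S[i, -j] >= s)) next          # row tie
    if (nrow(S) > 1 && any(S[-i, j] >= s)) next          # column tie/beat
    acc[[length(acc) + 1L]] <- data.frame(i = i, j = j, s = s)
  }
  if (!length(acc)) return(data.frame(i = integer(0), j = integer(0),
                                      s = numeric(0)))
  do.call(rbind, acc)
}

#' Uptake rates from stratum counts
#'
#' The uptake rate of a stratum is `100 * n_with_ais / n_registered`
#' percent. Strata with no registered vessels get an `NA` rate and are
#' flagged rather than erroring.
#'
#' @param counts data.frame with columns `stratum`, `n_registered`,
#'   `n_with_ais`.
#' @return the input with `rate` (percent) and `undefined` columns added.
#' @export
uptake_table <- function(counts) {
  stopifnot(all(c("stratum", "n_registered", "n_with_ais") %in%
                  names(counts)))
  if (any(counts$n_with_ais > counts$n_registered) ||
      any(counts$n_with_ais < 0))
    stop("n_with_ais must lie in [0, n_registered]")
  counts$undefined <- counts$n_registered == 0
  counts$rate <- ifelse(counts$undefined, NA_real_,
                        100 * counts$n_with_ais / counts$n_registered)
  counts
}

#' Vessel length classes
#'
#' The standard register length classes used for uptake reporting.
#'
#' @param length_m vessel length in metres.
#' @return factor with levels `<15`, `15-18`, `18-24`, `>24`.
#' @export
length_class <- function(length_m) {
  cut(length_m, breaks = c(-Inf, 15, 18, 24, Inf),
      labels = c("<15", "15-18", "18-24", ">24"), right = FALSE)
}

#' AIS uptake by stratum
#'
#' A registered vessel counts as "with AIS" iff it was matched to an AIS
#' vessel and at least one of its messages falls in the observation window.
#'
#' @param register fleet register (needs the stratum column).
#' @param matches output of [link_register()].
#' @param messages AIS message table.
#' @param stratum name of the register column to stratify by (default
#'   `"length_class"`, computed from `length` if absent).
#' @param window optional `c(start, end)` POSIXct observation window.
#' @return an uptake table (see [uptake_table()]).
#' @export
uptake <- function(register, matches, messages, stratum = "length_class",
                   window = NULL) {
  if (!stratum %in% names(register) && stratum == "length_class")
    register$length_class <- length_class(register$length)
  if (!stratum %in% names(register))
    stop("no such stratum column: ", stratum)
  msg <- messages
  if (!is.null(window))
    msg <- msg[msg$timestamp >= window[1] & msg$timestamp <= window[2], ,
               drop = FALSE]
  active <- unique(msg$vessel_id)
  m <- matches[matches$method != "unmatched" &
                 matches$ais_vessel_id %in% active, , drop = FALSE]
  with_ais <- register$register_id %in% m$register_id
  agg <- aggregate(cbind(n_registered = rep(1L, nrow(register)),
                         n_with_ais = as.integer(with_ais)),
                   by = list(stratum = register[[stratum]]), FUN = sum)
  uptake_table(agg)
}

#' Cumulative monthly AIS uptake
#'
#' A vessel counts as "with AIS" from the month of its first message onward,
#' so per-stratum rates are non-decreasing over months.
#'
#' @inheritParams uptake
#' @return uptake table with one row per (month, stratum), ordered by month.
#' @export
uptake_by_month <- function(register, matches, messages,
                            stratum = "length_class") {
  if (!stratum %in% names(register) && stratum == "length_class")
    register$length_class <- length_class(register$length)
  m <- matches[matches$method != "unmatched", , drop = FALSE]
  first_msg <- aggregate(timestamp ~ vessel_id, data = messages, FUN = min)
  m$first_month <- format(
    first_msg$timestamp[match(m$ais_vessel_id, first_msg$vessel_id)], "%Y-%m")
  m <- m[!is.na(m$first_month), , drop = FALSE]
  months <- sort(unique(format(messages$timestamp, "%Y-%m")))
  out <- do.call(rbind, lapply(months, function(mo) {
    got <- m$register_id[m$first_month <= mo]
    with_ais <- register$register_id %in% got
    agg <- aggregate(cbind(n_registered = rep(1L, nrow(register)),
                           n_with_ais = as.integer(with_ais)),
                     by = list(stratum = register[[stratum]]), FUN = sum)
    agg$month <- mo
    agg
  }))
  uptake_table(out)
}
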