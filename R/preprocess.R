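# The three cleaning filters, applied per vessel in a fixed order:
# (1) keep messages with speed > 0.5 kn (drops in-port loitering),
# (2) keep vessels with more than 300 remaining messages (EM needs a robust
#     sample to estimate the two Gaussian components),
# (3) per vessel, drop speeds above Q3 + 1.5 IQR (sensor spikes / errors).

#' Speed filter
#'
#' Keeps messages whose speed is strictly greater than `min_speed` knots.
#' Low-speed messages concentrate near ports and would add a third,
#' zero-speed component to the speed profile.
#'
#' @param messages message table with a `speed` column (knots).
#' @param min_speed threshold, knots; rows with `speed <= min_speed` drop.
#' @return filtered messages.
#' @export
filter_speed <- function(messages, min_speed = 0.5) {
  stopifnot("speed" %in% names(messages), all(messages$speed >= 0))
  messages[messages$speed > min_speed, , drop = FALSE]
}

#' Minimum-message filter
#'
#' Drops every vessel with `min_count` or fewer remaining messages
#' (strictly "more than" is required to keep a vessel): below that the EM
#' estimates of the two Gaussian components are not considered robust.
#'
#' @param messages message table with `vessel_id`.
#' @param min_count threshold; vessels with `<= min_count` messages drop.
#' @return filtered messages; removed vessel ids in `attr(, "dropped_vessels")`.
#' @export
filter_min_messages <- function(messages, min_count = 300) {
  cnt <- table(messages$vessel_id)
  keep_v <- names(cnt)[cnt > min_count]
  out <- messages[messages$vessel_id %in% keep_v, , drop = FALSE]
  attr(out, "dropped_vessels") <- setdiff(names(cnt), keep_v)
  out
}

#' Per-vessel speed outlier filter
#'
#' For each vessel, removes messages whose speed is strictly above that
#' vessel's `Q3 + 1.5 IQR` (quartiles by linear interpolation between order
#' statistics, the `stats::quantile()` type-7 default). Vessels with fewer
#' than 4 messages are passed through untouched (quartiles ill-defined) and
#' listed in `attr(, "skipped_vessels")`.
#'
#' @param messages message table with `vessel_id` and `speed`.
#' @return filtered messages.
#' @export
filter_speed_outliers <- function(messages) {
  skipped <- character(0)
  keep <- rep(TRUE, nrow(messages))
  for (v in unique(messages$vessel_id)) {
    idx <- which(messages$vessel_id == v)
    sp <- messages$speed[idx]
    if (length(sp) < 4) {
      skipped <- c(skipped, v)
      next
    }
    q <- stats::quantile(sp, c(0.25, 0.75), names = FALSE)
    cutoff <- q[2] + 1.5 * (q[2] - q[1])
    keep[idx[sp > cutoff]] <- FALSE
  }
  out <- messages[keep, , drop = FALSE]
  attr(out, "skipped_vessels") <- skipped
  out
}

#' Run the full cleaning chain
#'
#' Applies the three filters once, in order: speed, minimum message count,
#' per-vessel speed outliers. Each filter can be switched off. A ledger of
#' input/output row counts per filter is attached.
#'
#' @param messages message table.
#' @param min_speed,min_count see the individual filters.
#' @param speed,min_messages,outliers logical switches for each filter.
#' @return cleaned messages with `attr(, "ledger")`, a data.frame with
#'   columns `filter`, `n_in`, `n_out`.
#' @export
clean_messages <- function(messages, min_speed = 0.5, min_count = 300,
                           speed = TRUE, min_messages = TRUE,
                           outliers = TRUE) {
  ledger <- data.frame(filter = character(0), n_in = integer(0),
                       n_out = integer(0), stringsAsFactors = FALSE)
  step <- function(name, fn, x) {
    n_in <- nrow(x)
    x2 <- fn(x)
    ledger <<- rbind(ledger, data.frame(filter = name, n_in = n_in,
                                        n_out = nrow(x2)))
    x2
  }
  out <- messages
  if (speed)
    out <- step("speed", function(x) filter_speed(x, min_speed), out)
  if (min_messages)
    out <- step("min_messages",
                function(x) filter_min_messages(x, min_count), out)
  if (outliers)
    out <- step("speed_outliers", filter_speed_outliers, out)
  attr(out, "ledger") <- ledger
  out
}
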