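#' Run the full AIS fishing-effort pipeline on a simulated fleet
#'
#' Convenience wrapper chaining every stage on one simulated dataset:
#' simulate, validate/ingest, link to the register, clean, detect fishing,
#' validate against logbooks, grid AIS and logbook effort, and estimate
#' coverage. Useful for demonstrations and end-to-end checks; real data
#' would enter through [read_ais()] and friends instead.
#'
#' @param config a [sim_config()].
#' @param k_sd fishing-band SD multiplier.
#' @param min_count minimum messages per vessel for the cleaning chain
#'   (defaults to 300).
#' @return list with `sim`, `matches`, `cleaned`, `detect`, `validation`,
#'   `effort_grid`, `logbook_effort`, `comparison`, `coverage`.
#' @export
run_pipeline <- function(config = sim_config(), k_sd = 1.5,
                         min_count = 300) {
  sim <- simulate_fleet(config)
  msgs <- read_ais(sim$messages)
  matches <- link_register(sim$register, ais_vessels(msgs))
  cleaned <- clean_messages(msgs, min_count = min_count)
  det <- detect_fishing(cleaned, k_sd = k_sd, seed = config$seed)
  val <- if (!is.null(det$messages))
    validate_classification(det$messages, sim$logbook) else NULL
  grid <- if (!is.null(det$messages))
    ais_effort(det$messages, sim$register,
               interval = config$nominal_interval,
               region = config$region)
  else NULL
  lbe <- logbook_effort(sim$logbook, sim$register)
  cmp <- if (!is.null(grid)) compare_efforts(grid, lbe) else NULL
  traj <- build_trajectories(msgs)
  interp <- interpolate_trajectories(traj, step = config$nominal_interval)
  cov <- coverage_grid(msgs, interp)
  list(sim = sim, matches = matches, cleaned = cleaned, detect = det,
       validation = val, effort_grid = grid, logbook_effort = lbe,
       comparison = cmp, coverage = cov)
}
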