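# Fishing-activity detection from per-vessel speed profiles.
#
# A trawler's at-sea speed histogram is bimodal: a low mode while towing the
# gear and a high mode while steaming. We model the cleaned speeds as a
# two-component Gaussian mixture fitted by expectation-maximisation, take
# the low-speed component as the fishing mode, and classify every message
# whose speed falls within mu1 +/- k_sd * sigma1 (default k_sd = 1.5) as
# fishing.

#' Fit a two-component Gaussian mixture to a speed profile by EM
#'
#' Classic EM for a two-component univariate normal mixture. The E-step
#' computes each observation's responsibility (ownership probability) under
#' the current parameters; the M-step re-estimates mixing weight, means and
#' variances as responsibility-weighted moments. Iteration stops when the
#' log-likelihood changes by less than `tol` or after `max_iter` steps. The
#' fit is repeated from `n_restarts` starts (one deterministic start at the
#' 25th/75th speed percentiles, the rest from random responsibilities) and
#' the best log-likelihood wins. Components are ordered so that
#' `mu1 < mu2`, i.e. component 1 is the fishing (towing) mode. Variances
#' are floored at `sigma_floor^2` to keep the likelihood bounded.
#'
#' @param speeds numeric vector of speeds (knots), finite and positive.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations per start.
#' @param n_restarts number of starts.
#' @param seed optional integer seed for the random starts.
#' @param sigma_floor lower bound on each component SD, knots.
#' @param k_sd SD multiplier stored with the model for [fishing_interval()].
#' @return an object of class `speed_mixture`: list with `pi` (weight of
#'   component 1), `mu1`, `sd1`, `mu2`, `sd2`, `loglik`, `ll_path`
#'   (per-iteration log-likelihoods of the winning start), `n_obs`,
#'   `iterations`, `converged`, `overlap_flag` (TRUE when
#'   `|mu2 - mu1| < 2 max(sd1, sd2)`, i.e. the profile is not clearly
#'   bimodal and the fishing band is unreliable), and `k_sd`.
#' @export
#' @examples
#' set.seed(1)
#' sp <- c(rnorm(300, 3, 0.5), rnorm(200, 10, 1))
#' fit <- fit_speed_mixture(sp)
#' c(fit$mu1, fit$mu2)
fit_speed_mixture <- function(speeds, tol = 1e-8, max_iter = 1000,
                              n_restarts = 3, seed = NULL,
                              sigma_floor = 0.05, k_sd = 1.5) {
  speeds <- as.numeric(speeds)
  if (any(!is.finite(speeds)) || any(speeds <= 0))
    stop("speeds must be finite and positive")
  n <- length(speeds)
  if (n < 4) stop("insufficient data: need at least 4 speeds")
  if (length(unique(speeds)) < 2)
    stop("degenerate fit: all speeds identical")
  if (!is.null(seed)) set.seed(as.integer(seed))

  best <- NULL
  for (r in seq_len(n_restarts)) {
    if (r == 1L) {
      mu <- stats::quantile(speeds, c(0.25, 0.75), names = FALSE)
      if (mu[1] == mu[2]) mu <- range(speeds)
      sdev <- rep(max(stats::sd(speeds) / 2, sigma_floor), 2)
      p <- 0.5
      fit <- .em_run(speeds, p, mu, sdev, tol, max_iter, sigma_floor)
    } else {
      g <- stats::runif(n)
      fit <- .em_from_resp(speeds, cbind(g, 1 - g), tol, max_iter,
                           sigma_floor)
    }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # order components by mean: component 1 = fishing (low) mode
  if (best$mu[1] > best$mu[2]) {
    best$mu <- rev(best$mu); best$sd <- rev(best$sd)
    best$p <- 1 - best$p
  }
  out <- list(pi = best$p, mu1 = best$mu[1], sd1 = best$sd[1],
              mu2 = best$mu[2], sd2 = best$sd[2],
              loglik = best$loglik, ll_path = best$ll_path,
              n_obs = n, iterations = length(best$ll_path),
              converged = best$converged,
              overlap_flag = abs(best$mu[2] - best$mu[1]) <
                2 * max(best$sd), k_sd = k_sd)
  class(out) <- "speed_mixture"
  out
}

# One EM run from given parameters.
.em_run <- function(x, p, mu, sdev, tol, max_iter, sigma_floor) {
  ll_path <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step (log-space for numerical safety)
    l1 <- log(p) + stats::dnorm(x, mu[1], sdev[1], log = TRUE)
    l2 <- log1p(-p) + stats::dnorm(x, mu[2], sdev[2], log = TRUE)
    m <- pmax(l1, l2)
    ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
    ll_path <- c(ll_path, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    g1 <- 1 / (1 + exp(l2 - l1))
    # M-step
    w1 <- sum(g1); w2 <- length(x) - w1
    p <- w1 / length(x)
    mu[1] <- sum(g1 * x) / w1
    mu[2] <- sum((1 - g1) * x) / w2
    sdev[1] <- max(sqrt(sum(g1 * (x - mu[1])^2) / w1), sigma_floor)
    sdev[2] <- max(sqrt(sum((1 - g1) * (x - mu[2])^2) / w2), sigma_floor)
    if (!is.finite(p) || p <= 0 || p >= 1) {
      p <- min(max(p, 1e-6), 1 - 1e-6)
    }
  }
  list(p = p, mu = mu, sd = sdev, loglik = ll_path[length(ll_path)],
       ll_path = ll_path, converged = converged)
}

# Start EM from a responsibility matrix (random restart): one M-step to get
# parameters, then the standard loop.
.em_from_resp <- function(x, gamma, tol, max_iter, sigma_floor) {
  g1 <- gamma[, 1]
  w1 <- sum(g1); w2 <- length(x) - w1
  p <- w1 / length(x)
  mu <- c(sum(g1 * x) / w1, sum((1 - g1) * x) / w2)
  sdev <- pmax(c(sqrt(sum(g1 * (x - mu[1])^2) / w1),
                 sqrt(sum((1 - g1) * (x - mu[2])^2) / w2)), sigma_floor)
  .em_run(x, p, mu, sdev, tol, max_iter, sigma_floor)
}

#' @export
print.speed_mixture <- function(x, ...) {
  cat("Two-component Gaussian speed mixture (n =", x$n_obs, ")\n")
  cat(sprintf("  fishing mode : mu1 = %.3f kn, sd1 = %.3f kn (pi = %.3f)\n",
              x$mu1, x$sd1, x$pi))
  cat(sprintf("  steaming mode: mu2 = %.3f kn, sd2 = %.3f kn\n",
              x$mu2, x$sd2))
  iv <- fishing_interval(x)
  cat(sprintf("  fishing band (+/- %.1f sd): [%.3f, %.3f] kn\n",
              x$k_sd, iv[1], iv[2]))
  cat(sprintf("  loglik = %.3f after %d iterations (converged: %s%s)\n",
              x$loglik, x$iterations, x$converged,
              if (x$overlap_flag) "; WARNING: modes overlap" else ""))
  invisible(x)
}

#' Fishing-speed interval from a fitted mixture
#'
#' The per-vessel fishing band `[mu1 - k_sd * sd1, mu1 + k_sd * sd1]`,
#' floored at 0 kn. The default multiplier of 1.5 was found applicable
#' fleet-wide for trawl gear.
#'
#' @param model a `speed_mixture`.
#' @param k_sd SD multiplier (defaults to the one stored in the model).
#' @return numeric `c(lo, hi)`.
#' @export
fishing_interval <- function(model, k_sd = model$k_sd) {
  lo <- max(0, model$mu1 - k_sd * model$sd1)
  hi <- model$mu1 + k_sd * model$sd1
  c(lo, hi)
}

#' Classify messages as fishing / non-fishing
#'
#' A message is labelled `fishing` iff its speed lies inside the vessel's
#' fishing interval (closed on both ends), `non-fishing` otherwise.
#'
#' @param messages this vessel's cleaned message table (needs `speed`).
#' @param model the vessel's fitted `speed_mixture`; must have converged.
#' @param k_sd SD multiplier (defaults to the model's).
#' @return `messages` with a `label` column added.
#' @export
classify_messages <- function(messages, model, k_sd = model$k_sd) {
  if (!isTRUE(model$converged))
    stop("model did not converge; vessel is unclassifiable")
  iv <- fishing_interval(model, k_sd)
  messages$label <- ifelse(messages$speed >= iv[1] &
                             messages$speed <= iv[2],
                           "fishing", "non-fishing")
  messages
}

#' Fit and classify a whole fleet
#'
#' Fits a speed mixture per vessel and labels its messages. Vessels whose
#' fit fails or does not converge are left out of the labelled table and
#' reported.
#'
#' @param messages cleaned multi-vessel message table.
#' @param k_sd SD multiplier for the fishing band.
#' @param seed integer seed (per-vessel seeds are derived from it).
#' @param ... passed to [fit_speed_mixture()].
#' @return list with `messages` (labelled rows), `models` (per-vessel
#'   parameter data.frame), and `unclassifiable` (vessel ids).
#' @export
detect_fishing <- function(messages, k_sd = 1.5, seed = 1L, ...) {
  vessels <- unique(messages$vessel_id)
  labeled <- list(); rows <- list(); bad <- character(0)
  for (k in seq_along(vessels)) {
    v <- vessels[k]
    mv <- messages[messages$vessel_id == v, , drop = FALSE]
    fit <- tryCatch(
      fit_speed_mixture(mv$speed, seed = as.integer(seed) + k, k_sd = k_sd,
                        ...),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      bad <- c(bad, v)
      next
    }
    iv <- fishing_interval(fit, k_sd)
    labeled[[v]] <- classify_messages(mv, fit, k_sd)
    rows[[v]] <- data.frame(vessel_id = v, pi = fit$pi, mu1 = fit$mu1,
                            sd1 = fit$sd1, mu2 = fit$mu2, sd2 = fit$sd2,
                            lo = iv[1], hi = iv[2], n_obs = fit$n_obs,
                            loglik = fit$loglik,
                            overlap_flag = fit$overlap_flag,
                            stringsAsFactors = FALSE)
  }
  out_msg <- if (length(labeled))
    do.call(rbind, c(labeled, list(make.row.names = FALSE))) else NULL
  out_mod <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
  list(messages = out_msg, models = out_mod, unclassifiable = bad)
}
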