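test_that("EM recovers mixture parameters from a labelled sample", {
  set.seed(101)
  x <- c(rnorm(3000, 3, 0.5), rnorm(2000, 10, 1))
  fit <- fit_speed_mixture(x, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$pi - 0.6) / 0.6, 0.05)
  expect_lt(abs(fit$mu1 - 3) / 3, 0.05)
  expect_lt(abs(fit$sd1 - 0.5) / 0.5, 0.05)
  expect_lt(abs(fit$mu2 - 10) / 10, 0.05)
  expect_lt(abs(fit$sd2 - 1) / 1, 0.05)
  expect_false(fit$overlap_flag)
})

test_that("perfectly separated two-point data collapse to the points", {
  fit <- fit_speed_mixture(c(3, 3, 3, 10, 10), seed = 1)
  expect_equal(fit$mu1, 3, tolerance = 1e-6)
  expect_equal(fit$mu2, 10, tolerance = 1e-6)
  expect_equal(fit$pi, 0.6, tolerance = 1e-6)
  # responsibilities are effectively 0/1: SDs hit the floor
  expect_equal(fit$sd1, 0.05)
  expect_equal(fit$sd2, 0.05)
})

test_that("degenerate inputs raise the stated errors", {
  expect_error(fit_speed_mixture(rep(5, 10)), "identical")
  expect_error(fit_speed_mixture(c(3, 10, 5)), "insufficient")
  expect_error(fit_speed_mixture(c(3, -1, 5, 6)), "positive")
})

test_that("log-likelihood is monotone over EM iterations", {
  for (seed in 1:5) {
    sp <- simulate_speeds(500, seed = seed)
    fit <- fit_speed_mixture(sp$speed, seed = seed)
    expect_true(all(diff(fit$ll_path) >= -1e-8))
  }
})

test_that("EM matches or beats a brute-force grid search on tiny samples", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- c(rnorm(30, 3, 0.5), rnorm(20, 10, 1))
    fit <- fit_speed_mixture(x, seed = seed)
    oracle <- mixture_grid_search(x, 0.5, 1)
    expect_gte(fit$loglik, oracle - 1e-6)
  }
})

test_that("the fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  sp <- simulate_speeds(2000, seed = 77)
  fit <- fit_speed_mixture(sp$speed, seed = 1)
  mc <- mclust::Mclust(sp$speed, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-5)
  expect_equal(sort(c(fit$mu1, fit$mu2)), sort(as.numeric(mc$parameters$mean)),
               tolerance = 1e-3)
})

test_that("fitting is equivariant under rescaling of speeds", {
  sp <- simulate_speeds(1000, seed = 15)
  f1 <- fit_speed_mixture(sp$speed, seed = 9)
  f2 <- fit_speed_mixture(2 * sp$speed, seed = 9)
  expect_equal(f2$mu1, 2 * f1$mu1, tolerance = 1e-4)
  expect_equal(f2$mu2, 2 * f1$mu2, tolerance = 1e-4)
  expect_equal(f2$sd1, 2 * f1$sd1, tolerance = 1e-4)
  expect_equal(fishing_interval(f2), 2 * fishing_interval(f1),
               tolerance = 1e-4)
})

test_that("single-regime input is flagged as overlapping modes", {
  set.seed(3)
  x <- rnorm(1000, 5, 1)
  # overlapping components make the likelihood plateau shallow, so EM needs
  # far more iterations here than on bimodal data
  fit <- fit_speed_mixture(abs(x) + 0.01, seed = 2, max_iter = 20000,
                           n_restarts = 1)
  expect_true(fit$converged)
  expect_true(fit$overlap_flag)
})

test_that("fishing interval arithmetic, flooring and k = 0", {
  m <- structure(list(mu1 = 3, sd1 = 0.5, k_sd = 1.5),
                 class = "speed_mixture")
  expect_equal(fishing_interval(m), c(2.25, 3.75))
  m$mu1 <- 1; m$sd1 <- 1
  expect_equal(fishing_interval(m), c(0, 2.5))
  expect_equal(fishing_interval(m, k_sd = 0), c(1, 1))
})

test_that("classification is inclusive at the band edges", {
  m <- structure(list(mu1 = 3, sd1 = 0.5, mu2 = 10, sd2 = 1, k_sd = 1.5,
                      converged = TRUE), class = "speed_mixture")
  msgs <- make_messages("V1", speed = c(2.0, 2.25, 3.0, 3.75, 9.8))
  lab <- classify_messages(msgs, m)
  expect_identical(lab$label, c("non-fishing", "fishing", "fishing",
                                "fishing", "non-fishing"))
  expect_identical(nrow(classify_messages(msgs[0, ], m)), 0L)
  m$converged <- FALSE
  expect_error(classify_messages(msgs, m), "unclassifiable")
})

test_that("fishing-band capture approaches the 1.5-SD Gaussian mass", {
  sp <- simulate_speeds(10000, seed = 55)
  fit <- fit_speed_mixture(sp$speed, seed = 1)
  lab <- classify_messages(make_messages("V", speed = sp$speed), fit)
  truefish <- sp$state == "fishing"
  captured <- mean(lab$label[truefish] == "fishing")
  p <- pnorm(1.5) - pnorm(-1.5)  # 0.8664
  expect_lt(abs(captured - p), 3 * sqrt(p * (1 - p) / sum(truefish)))
})

test_that("median recovery error over seeded replicates is small", {
  err1 <- err2 <- numeric(20)
  for (r in 1:20) {
    sp <- simulate_speeds(2000, seed = 1000 + r)
    fit <- fit_speed_mixture(sp$speed, seed = r, n_restarts = 1)
    err1[r] <- abs(fit$mu1 - 3)
    err2[r] <- abs(fit$mu2 - 10)
  }
  expect_lt(median(err1), 0.1)
  expect_lt(median(err2), 0.2)
})

test_that("detect_fishing labels per vessel and reports failures", {
  sim <- simulate_fleet(sim_config(n_vessels = 3, trips_per_vessel = 4,
                                   seed = 23))
  cl <- clean_messages(sim$messages, min_count = 100)
  det <- detect_fishing(cl, seed = 1)
  expect_identical(sort(unique(det$messages$vessel_id)),
                   sort(unique(cl$vessel_id)))
  expect_true(all(det$models$mu1 < det$models$mu2))
  expect_true(all(det$models$lo < det$models$hi))
  # labels respect each vessel's own band
  for (v in det$models$vessel_id) {
    mv <- det$messages[det$messages$vessel_id == v, ]
    band <- det$models[det$models$vessel_id == v, ]
    expect_identical(mv$label == "fishing",
                     mv$speed >= band$lo & mv$speed <= band$hi)
  }
})
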