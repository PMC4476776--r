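reg1 <- data.frame(vessel_id = "V1", power = 100)

test_that("effort arithmetic: messages x power x interval in kW-days", {
  m <- make_messages("V1", speed = 3, label = "fishing")
  m <- m[rep(1, 12), ]; m$msg_id <- sprintf("M%02d", 1:12)
  g <- ais_effort(m, reg1)
  expect_equal(attr(g, "total"), 12 * 100 * 300 / 86400, tolerance = 1e-12)
  expect_equal(attr(g, "total"), 4 + 1 / 6)  # 4.1667 kW-days

  m24 <- m[rep(1, 288), ]; m24$msg_id <- sprintf("M%03d", 1:288)
  expect_equal(attr(ais_effort(m24, reg1), "total"), 100)

  none <- make_messages("V1", speed = 9, label = "non-fishing")
  g0 <- ais_effort(none, reg1)
  expect_identical(nrow(g0), 0L)
  expect_equal(attr(g0, "total"), 0)
})

test_that("grid total conserves the closed-form message sum", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 500
    m <- make_messages(sample(c("V1", "V2", "V3"), n, TRUE),
                       speed = runif(n, 1, 12),
                       lon = runif(n, 10, 12), lat = runif(n, 57, 58),
                       label = sample(c("fishing", "non-fishing"), n, TRUE))
    reg <- data.frame(vessel_id = c("V1", "V2", "V3"),
                      power = c(150, 600, 1100))
    g <- ais_effort(m, reg)
    fish <- m[m$label == "fishing", ]
    expected <- sum(reg$power[match(fish$vessel_id, reg$vessel_id)]) *
      300 / 86400
    expect_lt(abs(attr(g, "total") - expected) / expected, 1e-9)
    expect_equal(sum(g$kw_days), attr(g, "total"))
    expect_true(all(g$kw_days >= 0))
  }
})

test_that("vessels without register power are skipped and counted", {
  m <- make_messages(c("V1", "VX"), speed = 3, label = "fishing")
  g <- ais_effort(m, reg1)
  expect_identical(attr(g, "n_skipped"), 1L)
  expect_equal(attr(g, "total"), 100 * 300 / 86400)
})

test_that("trip duration is allocated to rectangles by catch weight", {
  lb <- data.frame(
    trip_id = "T1", vessel_id = "V1",
    departure = as.POSIXct("2024-02-01", tz = "UTC"),
    arrival = as.POSIXct("2024-02-03", tz = "UTC"),
    catch_kg = c(300, 100), ices_rect = c("44G1", "44G2"),
    stringsAsFactors = FALSE)
  out <- logbook_effort(lb, data.frame(vessel_id = "V1", power = 200))
  expect_equal(out$kw_days[out$ices_rect == "44G1"], 1.5 * 200)
  expect_equal(out$kw_days[out$ices_rect == "44G2"], 0.5 * 200)

  single <- lb[1, ]
  out1 <- logbook_effort(single, data.frame(vessel_id = "V1", power = 200))
  expect_equal(out1$kw_days, 2 * 200)

  zero <- lb; zero$catch_kg <- c(0, 0)
  out0 <- logbook_effort(zero, data.frame(vessel_id = "V1", power = 200))
  expect_identical(attr(out0, "zero_catch_trips"), "T1")
  expect_equal(out0$kw_days, c(200, 200))
})

test_that("allocated days sum to the trip duration for random catches", {
  set.seed(99)
  for (r in 1:200) {
    k <- sample(1:4, 1)
    dur <- runif(1, 0.25, 6)
    lb <- data.frame(
      trip_id = "T", vessel_id = "V1",
      departure = as.POSIXct("2024-02-01", tz = "UTC"),
      arrival = as.POSIXct("2024-02-01", tz = "UTC") + dur * 86400,
      catch_kg = round(runif(k, 0, 500)),
      ices_rect = sample(c("44G1", "44G2", "45G1", "45G2"), k),
      stringsAsFactors = FALSE)
    alloc <- attr(logbook_effort(
      lb, data.frame(vessel_id = "V1", power = 330)), "allocation")
    expect_equal(sum(alloc$days), dur, tolerance = 1e-9)
  }
})

test_that("ICES rectangle encoding matches the published scheme", {
  expect_identical(ices_encode(57.75, 11.5), "44G1")
  expect_identical(ices_encode(55.9, 12.7), "40G2")   # the Sound
  expect_identical(ices_encode(36.0, -44), "01A0")
  expect_identical(ices_encode(54.75, 1.5), "38F1")   # central North Sea
  # the letter I is skipped: 30E falls in J
  expect_identical(substr(ices_encode(57.75, 30.5), 3, 3), "J")
  expect_error(ices_encode(30, 11.5), "domain")
  expect_error(ices_encode(57.75, 70), "domain")
})

test_that("decode inverts encode over the valid domain", {
  set.seed(5)
  lat <- runif(1000, 36, 85.5 - 1e-9)
  lon <- runif(1000, -44, 68.5 - 1e-9)
  b <- ices_decode(ices_encode(lat, lon))
  expect_true(all(lat >= b$lat_min & lat < b$lat_max))
  expect_true(all(lon >= b$lon_min & lon < b$lon_max))
  # boundary points follow the half-open convention
  b2 <- ices_decode(ices_encode(57.5, 11))
  expect_equal(b2$lat_min, 57.5)
  expect_equal(b2$lon_min, 11)
  expect_error(ices_decode("44I1"))
})

test_that("aggregating the fine grid to rectangles matches direct gridding", {
  # messages placed away from cell edges so both routes bin identically
  set.seed(6)
  n <- 300
  lb <- ices_decode(c("44G1", "44G2", "45G1"))
  pick <- sample(3, n, TRUE)
  m <- make_messages("V1", speed = 3,
                     lon = lb$lon_min[pick] + runif(n, 0.2, 0.8),
                     lat = lb$lat_min[pick] + runif(n, 0.1, 0.4),
                     label = "fishing")
  g <- ais_effort(m, reg1, region = c(11, 13, 57.5, 58.5))
  cmp <- aggregate(list(kw = rep(100 * 300 / 86400, n)),
                   by = list(rect = ices_encode(m$lat, m$lon)), FUN = sum)
  fine <- aggregate(list(kw = g$kw_days),
                    by = list(rect = ices_encode(g$lat, g$lon)), FUN = sum)
  fine <- fine[order(fine$rect), ]; cmp <- cmp[order(cmp$rect), ]
  expect_equal(fine$rect, cmp$rect)
  expect_equal(fine$kw, cmp$kw, tolerance = 1e-9)
})

test_that("AIS effort is below logbook effort but spatially aligned", {
  sim <- simulate_fleet(sim_config(n_vessels = 6, trips_per_vessel = 5,
                                   seed = 47))
  cl <- clean_messages(sim$messages, min_count = 100)
  det <- detect_fishing(cl, seed = 3)
  g <- ais_effort(det$messages, sim$register, region = c(9.5, 13.5, 56.5, 58.5))
  lbe <- logbook_effort(sim$logbook, sim$register)
  cmp <- compare_efforts(g, lbe)
  # logbooks count the whole trip; AIS only the fishing part
  expect_gt(sum(cmp$logbook_kw_days), sum(cmp$ais_kw_days))
  expect_gt(attr(cmp, "rank_correlation"), 0)
})

test_that("a single-rectangle fleet compares in one row", {
  m <- make_messages("V1", speed = 3, lon = 11.5, lat = 57.75,
                     label = "fishing")
  g <- ais_effort(m, reg1, region = c(11, 12, 57.5, 58))
  lbe <- data.frame(ices_rect = "44G1", kw_days = 5)
  cmp <- compare_efforts(g, lbe)
  expect_identical(nrow(cmp), 1L)
  expect_identical(cmp$ices_rect, "44G1")
  expect_true(is.na(attr(cmp, "rank_correlation")))
})
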