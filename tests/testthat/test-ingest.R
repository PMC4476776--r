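test_that("read_ais validates, rejects and deduplicates rows", {
  msgs <- make_messages("V1", speed = runif(100, 1, 10))
  clean <- read_ais(msgs)
  expect_identical(nrow(clean), 100L)
  expect_identical(sum(attr(clean, "rejections")$n), 0L)

  bad <- msgs
  bad$lat[7] <- 95.0
  out <- read_ais(bad)
  expect_identical(nrow(out), 99L)
  rej <- attr(out, "rejections")
  expect_identical(rej$n[rej$reason == "bad_coordinates"], 1L)

  dup <- rbind(msgs, msgs[10, ])
  out <- read_ais(dup)
  expect_identical(nrow(out), 100L)
  rej <- attr(out, "rejections")
  expect_identical(rej$n[rej$reason == "duplicate"], 1L)

  # per-vessel timestamps strictly increasing after the stable sort + dedup
  expect_true(all(diff(as.numeric(out$timestamp)) > 0))
  expect_error(read_ais(msgs[, -3]), "missing required column")
})

test_that("read_ais round-trips the simulator's CSV output", {
  sim <- simulate_fleet(sim_config(n_vessels = 2, trips_per_vessel = 1,
                                   seed = 6))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  back <- read_ais(file.path(dir, "ais.csv"))
  expect_identical(nrow(back), nrow(sim$messages))
  expect_equal(as.numeric(back$timestamp),
               as.numeric(sim$messages$timestamp))
  expect_equal(back$speed, sim$messages$speed)
})

test_that("string similarities match hand-computed values", {
  # one substitution in a 7-character callsign: 1 - 1/7
  expect_equal(levenshtein_sim("SFB1234", "SFB123A"), 6 / 7)
  expect_equal(levenshtein_sim("ABC", "ABC"), 1)
  expect_equal(levenshtein_sim("", ""), 0)
  # classical Jaro examples, computed by hand from m and t:
  # MARTHA/MARHTA: m = 6, t = 1 -> (1 + 1 + 5/6)/3
  expect_equal(jaro_sim("MARTHA", "MARHTA"), (1 + 1 + 5 / 6) / 3)
  # DIXON/DICKSONX: m = 4, t = 0 -> (4/5 + 4/8 + 1)/3
  expect_equal(jaro_sim("DIXON", "DICKSONX"), (4 / 5 + 4 / 8 + 1) / 3)
  expect_equal(jaro_sim("A", "B"), 0)
})

test_that("exact callsign matches take similarity 1 via the exact step", {
  reg <- data.frame(register_id = "R1", callsign = "SFB1234",
                    name = "FV ALPHA", stringsAsFactors = FALSE)
  ais <- data.frame(ais_vessel_id = "A1", callsign = "SFB1234",
                    name = "FV ALPHA", stringsAsFactors = FALSE)
  m <- link_register(reg, ais)
  expect_identical(m$method[1], "exact")
  expect_identical(m$similarity[1], 1)
})

test_that("a single-edit callsign with no competitors matches fuzzily", {
  # names are dissimilar so only the callsign step can fire;
  # Levenshtein similarity 6/7 ~ 0.857 >= 0.85
  reg <- data.frame(register_id = c("R1", "R2"),
                    callsign = c("SFB1234", "XQZ9999"),
                    name = c("AAAA", "QQQQQ"), stringsAsFactors = FALSE)
  ais <- data.frame(ais_vessel_id = c("A1", "A2"),
                    callsign = c("SFB123A", "XQZ9999"),
                    name = c("ZZZZZZZ", "WWWW"), stringsAsFactors = FALSE)
  m <- link_register(reg, ais, threshold = 0.85)
  r1 <- m[!is.na(m$register_id) & m$register_id == "R1", ]
  expect_identical(r1$method, "fuzzy-callsign")
  expect_identical(r1$ais_vessel_id, "A1")
  # reported similarity is the larger of the two scores; the Jaro value
  # (m = 6, t = 0 over lengths 7/7) edges out the Levenshtein 6/7
  expect_equal(r1$similarity, (6 / 7 + 6 / 7 + 1) / 3)
  expect_gte(r1$similarity, 6 / 7)
})

test_that("exact similarity ties reject both candidates", {
  reg <- data.frame(register_id = c("R1", "R2"),
                    callsign = c("SFB1111", "SFB1112"),
                    name = c("AAAA", "BBBB"), stringsAsFactors = FALSE)
  # equidistant from both register callsigns (one substitution each)
  ais <- data.frame(ais_vessel_id = "A1", callsign = "SFB1113",
                    name = "CCCC", stringsAsFactors = FALSE)
  m <- link_register(reg, ais, threshold = 0.85)
  expect_true(all(m$method == "unmatched"))
})

test_that("linkage of a typo-free simulated fleet is exact and complete", {
  sim <- simulate_fleet(sim_config(n_vessels = 15, trips_per_vessel = 1,
                                   seed = 21))
  m <- link_register(sim$register, ais_vessels(sim$messages))
  hit <- m[m$method != "unmatched", ]
  expect_identical(nrow(hit), 15L)
  expect_true(all(hit$method == "exact"))
  expect_identical(sort(hit$register_id), sort(sim$register$register_id))
})

test_that("matches are one-to-one for corrupted registers", {
  for (seed in 1:5) {
    sim <- simulate_fleet(sim_config(n_vessels = 12, trips_per_vessel = 1,
                                     seed = seed))
    reg <- inject_typos(sim$register, 0.3, seed = seed)
    m <- link_register(reg, ais_vessels(sim$messages))
    hit <- m[m$method != "unmatched", ]
    expect_false(any(duplicated(hit$register_id)))
    expect_false(any(duplicated(hit$ais_vessel_id)))
  }
})

test_that("uptake arithmetic and edge cases behave", {
  counts <- data.frame(stratum = c("a", "b", "c"),
                       n_registered = c(10L, 5L, 0L),
                       n_with_ais = c(0L, 5L, 0L))
  tab <- uptake_table(counts)
  expect_equal(tab$rate, c(0, 100, NA_real_))
  expect_identical(tab$undefined, c(FALSE, FALSE, TRUE))
  counts$n_with_ais[1] <- 11L
  expect_error(uptake_table(counts), "n_with_ais")
})

test_that("every transmitting vessel yields 100% uptake in all strata", {
  sim <- simulate_fleet(sim_config(n_vessels = 10, trips_per_vessel = 1,
                                   seed = 13))
  m <- link_register(sim$register, ais_vessels(sim$messages))
  tab <- uptake(sim$register, m, sim$messages)
  expect_true(all(tab$rate[!tab$undefined] == 100))
})

test_that("cumulative monthly uptake is non-decreasing per stratum", {
  sim <- simulate_fleet(sim_config(n_vessels = 8, trips_per_vessel = 4,
                                   seed = 17))
  # push vessels' first messages into different months
  msgs <- sim$messages
  shift <- (as.integer(factor(msgs$vessel_id)) %% 3) * 32 * 86400
  msgs$timestamp <- msgs$timestamp + shift
  m <- link_register(sim$register, ais_vessels(msgs))
  tab <- uptake_by_month(sim$register, m, msgs)
  for (s in unique(tab$stratum)) {
    r <- tab$rate[tab$stratum == s & !tab$undefined]
    expect_true(all(diff(r) >= 0))
  }
  last <- tab[tab$month == max(tab$month) & !tab$undefined, ]
  expect_true(all(last$rate == 100))
})
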