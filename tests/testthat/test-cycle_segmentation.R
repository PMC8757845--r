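test_that("pressure rises are found within two samples of ground truth", {
  sc <- scenario_regular_breathing(duration = 42, seed = 2)
  sim <- simulate_psv(sc)
  st <- clean_settings()
  onsets <- detect_pressure_rises(sim$recording$channels$pressure, 64, st)
  expect_equal(length(onsets), nrow(sim$cycles))
  expect_lt(max(abs(onsets - sim$cycles$onset)), 2 / 64)
})

test_that("flat or noisy baseline pressure yields no rises", {
  st <- clean_settings()
  expect_equal(detect_pressure_rises(rep(4, 64 * 10), 64, st), numeric(0))
  set.seed(11)
  noisy <- 4 + rnorm(64 * 30, 0, 0.2)
  expect_equal(detect_pressure_rises(noisy, 64, st), numeric(0))
  expect_error(detect_pressure_rises(rep(4, 30), 64, st),
               "insufficient data")
})

test_that("adding one detectable rise increases the onset count by one", {
  st <- clean_settings()
  p <- rep(4, 64 * 20)
  add_rise <- function(p, at) {
    idx <- round(at * 64) + seq_len(64)
    p[idx] <- 4 + 12 * (1 - exp(-(seq_len(64) / 64) / 0.05))
    p
  }
  p1 <- add_rise(p, 5)
  p2 <- add_rise(p1, 12)
  expect_equal(length(detect_pressure_rises(p1, 64, st)), 1)
  expect_equal(length(detect_pressure_rises(p2, 64, st)), 2)
})

test_that("segment_cycles partitions the recording", {
  cyc <- segment_cycles(c(0, 4, 8), c(1, 5, 9), 12)
  expect_equal(cyc$onset, c(0, 4, 8))
  expect_equal(cyc$end, c(4, 8, 12))
  expect_equal(nrow(segment_cycles(numeric(), numeric(), 10)), 0)
  expect_error(segment_cycles(c(4, 0), c(5, 1), 12), "increasing")
  # no gaps, no overlaps
  expect_equal(cyc$onset[-1], cyc$end[-3])
})

test_that("a 20-min zero-effort scenario yields 240 backup cycles of 5 s", {
  sim <- simulate_psv(scenario_backup_only(duration = 1200))
  st <- clean_settings()
  onsets <- detect_pressure_rises(sim$recording$channels$pressure, 64, st)
  expect_equal(length(onsets), 240)
  expect_lt(max(abs(diff(onsets) - 5)), 2 / 64)
})

test_that("efforts are detected with correct supported/unsupported status", {
  st <- clean_settings()
  # all-triggering scenario: every effort supported
  sc <- scenario_regular_breathing(duration = 62, seed = 3)
  sim <- simulate_psv(sc)
  rec <- sim$recording
  onsets <- detect_pressure_rises(rec$channels$pressure, 64, st)
  cyc <- segment_cycles(onsets,
                        detect_insp_ends(rec$channels$pressure, 64, onsets, st),
                        rec_duration(rec))
  ef <- detect_efforts(rec$channels$flow, 64, cyc)
  expect_equal(sum(ef$supported), nrow(sc$efforts))
  expect_equal(sum(!ef$supported), 0)

  # pure backup ventilation: no efforts at all
  simb <- simulate_psv(scenario_backup_only(duration = 62))
  onb <- detect_pressure_rises(simb$recording$channels$pressure, 64, st)
  cycb <- segment_cycles(onb,
                         detect_insp_ends(simb$recording$channels$pressure,
                                          64, onb, st),
                         rec_duration(simb$recording))
  efb <- detect_efforts(simb$recording$channels$flow, 64, cycb)
  expect_equal(nrow(efb), 0)
})

test_that("sub-threshold efforts during expiration are recovered within 3 samples", {
  sc <- scenario_with_events(duration = 300, n_ie = 5, seed = 3)
  sim <- simulate_psv(sc)
  sco <- score_recording(sim$recording, sc$settings)
  truth_ie <- sim$truth$units$onset[sim$truth$units$label == "IE"]
  found_ie <- sco$units$onset[sco$units$label == "IE"]
  expect_equal(length(found_ie), 5)
  expect_lt(max(abs(found_ie - truth_ie)), 3 / 64)
})

test_that("breathing frequency counts efforts plus effort-free machine cycles", {
  eff <- data.frame(onset = seq_len(300), peak_time = seq_len(300) + 0.1,
                    amplitude = 5, supported = FALSE,
                    cycle_index = NA_integer_)
  expect_equal(breathing_frequency(eff, NULL, 1200), 15)
  cyc <- data.frame(index = 1:240)
  expect_equal(breathing_frequency(NULL, cyc, 1200), 12)
  expect_error(breathing_frequency(eff, cyc, 0), "duration")
  # simulator truth: 15 regular breaths/min plus 3 IEs over 4 min
  sc <- scenario_with_events(duration = 240, n_ie = 3, seed = 5)
  sim <- simulate_psv(sc)
  sco <- score_recording(sim$recording, sc$settings)
  truth_rate <- round((nrow(sc$efforts) +
                         sum(sim$cycles$cause != "triggered")) / 240 * 60)
  expect_lte(abs(sco$f_breath - truth_rate), 1)
})

test_that("detection is deterministic", {
  sc <- scenario_with_events(duration = 120, n_ie = 2, noise_flow = 2,
                             seed = 8)
  sim <- simulate_psv(sc)
  s1 <- score_recording(sim$recording, sc$settings)
  s2 <- score_recording(sim$recording, sc$settings)
  expect_identical(s1$units, s2$units)
})
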