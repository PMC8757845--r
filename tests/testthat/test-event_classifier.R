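test_that("asynchrony index follows the published per-patient arithmetic", {
  # per-patient automatic counts with printed AI values
  expect_equal(round(asynchrony_index(
    c(N_tot = 324, N_IE = 5, N_AT = 7, N_DT = 3)), 1), 4.6)
  expect_equal(round(asynchrony_index(
    c(N_tot = 498, N_IE = 69, N_AT = 147, N_DT = 6)), 1), 44.6)
  expect_equal(asynchrony_index(
    c(N_tot = 200, N_IE = 0, N_AT = 0, N_DT = 0)), 0)
  expect_true(is.na(asynchrony_index(
    c(N_tot = 0, N_IE = 0, N_AT = 0, N_DT = 0))))
  expect_error(asynchrony_index(
    c(N_tot = 5, N_IE = 4, N_AT = 4, N_DT = 0)), "exceed")
})

test_that("zero-effort backup ventilation scores all Bck with AI 0", {
  sim <- simulate_psv(scenario_backup_only(duration = 300))
  sco <- score_recording(sim$recording, clean_settings())
  expect_equal(unname(sco$counts[["N_Bck"]]), unname(sco$counts[["N_tot"]]))
  expect_equal(sco$ai, 0)
})

test_that("injected events are classified one for one on clean recordings", {
  sc <- scenario_with_events(duration = 600, n_ie = 5, n_at = 7, n_dt = 2,
                             seed = 12)
  sim <- simulate_psv(sc)
  sco <- score_recording(sim$recording, sc$settings)
  expect_equal(unname(sco$counts[["N_AT"]]), 7)
  expect_equal(unname(sco$counts[["N_IE"]]), 5)
  expect_equal(unname(sco$counts[["N_DT"]]), 2)
  # each IE unit extends N_tot beyond the machine-cycle count
  n_machine <- nrow(sim$cycles)
  expect_equal(unname(sco$counts[["N_tot"]]),
               n_machine - 2 + 5)  # DT pairs merge, IEs append
})

test_that("DT pairs and AT+N sequences are discriminated by flow amplitude", {
  # two rises with separate efforts are never a DT candidate
  sc <- scenario_regular_breathing(duration = 60, breath_period = 4)
  sim <- simulate_psv(sc)
  sco <- score_recording(sim$recording, sc$settings)
  expect_equal(unname(sco$counts[["N_DT"]]), 0)
  # dt_vs_atn on synthetic windows: second peak at half the first, spanning
  # effort present
  rate <- 64
  tt <- (0:(rate * 8 - 1)) / rate
  q <- numeric(length(tt))
  q[tt >= 1 & tt < 2] <- 60 * sin(pi * (tt[tt >= 1 & tt < 2] - 1))
  q[tt >= 2.2 & tt < 3] <- 18 * sin(pi * (tt[tt >= 2.2 & tt < 3] - 2.2) / 0.8)
  expect_equal(dt_vs_atn(1, 2.2, 2.0, 4, flow = q, rate = rate), "DT")
  q2 <- q
  q2[tt >= 2.2 & tt < 3] <- 40 * sin(pi * (tt[tt >= 2.2 & tt < 3] - 2.2) / 0.8)
  expect_equal(dt_vs_atn(1, 2.2, 2.0, 4, flow = q2, rate = rate), "AT+N")
})

test_that("seeded DT and AT+N instances are discriminated on >= 95 % of cases", {
  correct <- sapply(1:20, function(seed) {
    set.seed(seed + 500)
    scd <- scenario_regular_breathing(duration = 60, seed = seed,
             noise_sd = c(pressure = 0.1, flow = 0.5, belt = 0))
    scd$efforts$amplitude[8] <- runif(1, 13, 17)
    scd$efforts$duration[8] <- runif(1, 1.7, 2.1)
    simd <- simulate_psv(scd)
    scod <- score_recording(simd$recording, scd$settings)
    dt_ok <- sum(scod$units$label == "DT") ==
      sum(simd$truth$units$label == "DT")
    sca <- scenario_regular_breathing(duration = 60, seed = seed,
             noise_sd = c(pressure = 0.1, flow = 0.5, belt = 0))
    sca$auto_trigger_times <- 31.3 + runif(1, 0.1, 0.5)
    i <- which(sca$efforts$onset == 34)
    sca$efforts$onset[i] <- 35.3
    sima <- simulate_psv(sca)
    scoa <- score_recording(sima$recording, sca$settings)
    at_ok <- sum(scoa$units$label == "AT") == 1 &&
      sum(scoa$units$label == "DT") == 0
    c(dt_ok, at_ok)
  })
  expect_gte(mean(correct), 0.95)
})

test_that("count summary emits the standard row schema", {
  sco <- make_scored(c(rep("N", 5), "Bck", "AT", "AT", "IE", "DT", "X"))
  row <- summarize_counts(sco)
  expect_named(row, c("N_tot", "N_IE", "N_AT", "N_DT", "AI", "N_Bck",
                      "N_X", "f_breath"))
  expect_equal(row$N_tot, 11)
  expect_equal(row$AI, round(100 * 4 / 11, 1))
  empty <- scored_recording(data.frame(onset = numeric(), end = numeric(),
                                       label = character()), 10)
  expect_true(is.na(summarize_counts(empty)$AI))
})

test_that("labels partition N_tot and AI stays within [0, 100]", {
  for (seed in 1:3) {
    sc <- scenario_with_events(duration = 300, n_ie = 3, n_at = 2, n_dt = 1,
                               n_bck = 1, seed = seed)
    sim <- simulate_psv(sc)
    sco <- score_recording(sim$recording, sc$settings)
    cc <- sco$counts
    expect_equal(unname(cc[["N_N"]] + cc[["N_Bck"]] + cc[["N_DT"]] +
                        cc[["N_AT"]] + cc[["N_IE"]] + cc[["N_X"]]),
                 unname(cc[["N_tot"]]))
    expect_gte(sco$ai, 0)
    expect_lte(sco$ai, 100)
  }
})

test_that("adding an asynchrony unit strictly increases the index", {
  sco <- make_scored(c(rep("N", 20), "AT"))
  for (lbl in c("AT", "IE", "DT")) {
    bigger <- make_scored(c(rep("N", 20), "AT", lbl),
                          onsets = c(1:21, 22))
    expect_gt(bigger$ai, sco$ai)
  }
})

test_that("a breathing frequency above 24/min raises the AT over-detection warning", {
  sc <- scenario_with_events(duration = 240, n_ie = 0, breath_period = 2.3,
                             seed = 2)
  sim <- simulate_psv(sc)
  sco <- score_recording(sim$recording, sc$settings)
  expect_gt(sco$f_breath, 24)
  expect_true(any(grepl("over-detected", sco$warnings)))
})

test_that("scorings serialize to JSON and back", {
  sco <- make_scored(c("N", "Bck", "AT", "IE"))
  path <- tempfile(fileext = ".json")
  write_scoring(sco, path)
  back <- read_scoring(path)
  expect_equal(back$units, sco$units)
  expect_equal(back$counts, sco$counts)
  expect_equal(back$ai, sco$ai)
})
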