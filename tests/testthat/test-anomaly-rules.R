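cfg <- rule_config()

test_that("tachycardia fires strictly above the mean-rate threshold", {
  expect_true(tachycardia_rule(rep(350, 5), 1, 5, cfg))    # 171.4 bpm
  expect_false(tachycardia_rule(rep(1000, 5), 1, 5, cfg))  # 60 bpm
  expect_false(tachycardia_rule(rep(400, 5), 1, 5, cfg))   # exactly 150: strict
  expect_error(tachycardia_rule(rep(400, 4), 1, 5, cfg), "out of range")
})

test_that("tachycardia is monotone in the R-R intervals", {
  set.seed(10)
  fired <- 0L
  for (i in 1:100) {
    rr <- runif(5, 250, 600)
    if (tachycardia_rule(rr, 1, 5, cfg)) {
      fired <- fired + 1L
      shrunk <- rr * runif(5, 0.5, 1)
      expect_true(tachycardia_rule(shrunk, 1, 5, cfg))
    }
  }
  expect_gt(fired, 10)  # the property was actually exercised
})

test_that("SA block requires a pause that is a near-multiple", {
  expect_true(sa_block_rule(800, 1600, cfg))    # ratio 2, remainder 0
  expect_false(sa_block_rule(800, 800, cfg))    # no pause
  expect_false(sa_block_rule(800, 1500, cfg))   # remainder 100 >= e
})

test_that("sinus pause is the non-multiple complement", {
  expect_true(sinus_pause_rule(800, 1500, cfg))
  expect_false(sinus_pause_rule(800, 1600, cfg))  # multiple -> SA block instead
  expect_false(sinus_pause_rule(800, 900, cfg))   # ratio below 1.5
})

test_that("the symmetric remainder option counts near-multiples from below", {
  # 1570 = 2*800 - 30: plain remainder is 770, symmetric remainder is 30
  expect_true(sa_block_rule(800, 1570, cfg))
  asym <- rule_config(symmetric_remainder = FALSE)
  expect_false(sa_block_rule(800, 1570, asym))
  expect_true(sinus_pause_rule(800, 1570, asym))
})

test_that("SA block and sinus pause never fire on the same pair", {
  set.seed(11)
  for (i in 1:200) {
    prev <- runif(1, 400, 1200)
    curr <- runif(1, 400, 3000)
    expect_false(sa_block_rule(prev, curr, cfg) &&
                   sinus_pause_rule(prev, curr, cfg))
  }
})

test_that("sinus arrhythmia needs coherent respiratory-band modulation", {
  tt <- cumsum(rep(1000, 16)) / 1000
  expect_true(sinus_arrhythmia_rule(1000 * (1 + 0.15 * sin(2 * pi * 0.25 * tt)), cfg))
  expect_false(sinus_arrhythmia_rule(rep(1000, 16), cfg))
  expect_false(sinus_arrhythmia_rule(1000 * (1 + 0.02 * sin(2 * pi * 0.25 * tt)), cfg))
  # modulation outside the respiratory band does not qualify
  expect_false(sinus_arrhythmia_rule(1000 * (1 + 0.15 * sin(2 * pi * 0.5 * tt)), cfg))
  # incoherent jitter of the same spread does not qualify
  set.seed(12)
  fired <- vapply(1:50, function(i) {
    sinus_arrhythmia_rule(1000 * (1 + runif(16, -0.05, 0.05)), cfg)
  }, logical(1))
  expect_false(any(fired))
  expect_error(sinus_arrhythmia_rule(rep(1000, 7), cfg), ">= 8")
})

test_that("an injected tachycardia episode raises exactly one alert", {
  al <- ecg_alerts(ecg_script(duration_s = 40, rate_bpm = 70, rr_jitter = 0.02,
                              events = list(ecg_event_tachycardia(15, 25, bpm = 170)),
                              seed = 3))
  tachy <- al[al$type == "tachycardia", ]
  expect_equal(nrow(tachy), 1)
  expect_gte(tachy$time_ms, 15000)
  expect_lte(tachy$time_ms, 27000)
  expect_equal(sum(al$type == "sinus_arrhythmia"), 0)
})

test_that("a doubled P-P interval raises exactly one SA-block alert", {
  al <- ecg_alerts(ecg_script(duration_s = 30, rate_bpm = 60, rr_jitter = 0.02,
                              events = list(ecg_event_dropped_beat(15)),
                              seed = 4))
  expect_equal(al$type, "sa_block")
  expect_gte(al$time_ms, 15000)
})

test_that("a non-multiple pause raises exactly one sinus-pause alert", {
  al <- ecg_alerts(ecg_script(duration_s = 30, rate_bpm = 60, rr_jitter = 0.02,
                              events = list(ecg_event_pause(15, ratio = 1.8)),
                              seed = 5))
  expect_equal(al$type, "sinus_pause")
  expect_gte(al$time_ms, 15000)
})

test_that("respiratory R-R modulation raises exactly one arrhythmia alert", {
  al <- ecg_alerts(ecg_script(duration_s = 60, rate_bpm = 60, rr_jitter = 0.02,
                              events = list(ecg_event_resp_modulation(0.25, 0.15)),
                              seed = 6))
  expect_equal(al$type, "sinus_arrhythmia")
})

test_that("normal sinus rhythm with bounded jitter raises no alerts", {
  for (s in 1:6) {
    al <- ecg_alerts(ecg_script(duration_s = 40, rate_bpm = 60 + 5 * s,
                                rr_jitter = 0.05, seed = 100 + s))
    expect_equal(nrow(al), 0)
  }
})
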