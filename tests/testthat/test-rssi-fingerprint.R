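test_that("outlier fences drop extreme RSSI and keep the bulk", {
  # brute-force fence oracle with linear-interpolation quartiles
  fence_keep <- function(v) {
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    v[v > q[1] - 3 * (q[2] - q[1]) & v < q[2] + 3 * (q[2] - q[1])]
  }
  expect_equal(filter_outliers(c(-50, -51, -49, -50, -90)),
               fence_keep(c(-50, -51, -49, -50, -90)))
  expect_equal(filter_outliers(c(-50, -51, -49, -50, -90)),
               c(-50, -51, -49, -50))
  expect_equal(filter_outliers(c(-40, -42, -44, -46, -48, -100)),
               c(-40, -42, -44, -46, -48))
  # identical values: fences collapse, median fallback retains everything
  expect_equal(filter_outliers(rep(-60, 4)), rep(-60, 4))
  expect_error(filter_outliers(numeric(0)), "non-empty")
})

test_that("outlier filtering is idempotent", {
  set.seed(42)
  for (i in 1:40) {
    v <- round(rnorm(sample(4:30, 1), -60, sd = runif(1, 0.5, 10)), 1)
    once <- filter_outliers(v)
    expect_identical(filter_outliers(once), once)
  }
})

test_that("calibration summarises filtered readings and floors the sd", {
  f <- fingerprint("solo", list(rssi_scan(c(X = -60)), rssi_scan(c(X = -60)),
                                rssi_scan(c(X = -60))))
  m <- calibrate(list(f))
  row <- m$stats[m$stats$bssid == "X", ]
  expect_equal(row$mean, -60)
  expect_equal(row$sd, 0.5)   # sd floor replaces the zero variance
  expect_equal(row$n, 3L)
})

test_that("unobserved BSSIDs are imputed 20% beyond the observed minimum", {
  f1 <- fingerprint("one", list(rssi_scan(c(X = -90, Y = -50)),
                                rssi_scan(c(X = -90, Y = -50))))
  f2 <- fingerprint("two", list(rssi_scan(c(Y = -55)), rssi_scan(c(Y = -55))))
  m <- calibrate(list(f1, f2))
  expect_equal(m$floor, -108)  # -90 * 1.2
  imp <- m$stats[m$stats$fingerprint == "two" & m$stats$bssid == "X", ]
  expect_equal(imp$mean, -108)
  expect_equal(imp$sd, 0.5)
  expect_equal(imp$n, 2L)
  expect_true(imp$imputed)
  expect_true(m$floor < min(-90, -55, -50))
})

test_that("calibrated means are computed on the outlier-filtered set", {
  vals <- c(-50, -51, -49, -50, -90)
  scans <- lapply(vals, function(v) rssi_scan(c(X = v)))
  m <- calibrate(list(fingerprint("p", scans)))
  kept <- filter_outliers(vals)
  row <- m$stats[m$stats$bssid == "X", ]
  expect_equal(row$mean, mean(kept))
  expect_equal(row$n, length(kept))
  expect_error(calibrate(list()), "no fingerprints")
})

test_that("residual standardization follows (r - mean) / (sd / sqrt(n))", {
  expect_equal(standardize_residual(-55, -60, 5, 25), 5)
  expect_equal(standardize_residual(-65, -60, 5, 1), -1)
  expect_equal(standardize_residual(-60, -60, 5, 9), 0)
  expect_equal(standardize_residual(-55, -60, 5, 25, scale = "standard_deviation"), 1)
  expect_error(standardize_residual(-55, -60, 0, 25), "sd must be")
})

test_that("significance levels are two-sided with a normal branch for n > 30", {
  expect_equal(alpha_level(0, 10), 1)
  expect_equal(alpha_level(2, 10), 0.0766, tolerance = 1e-3)
  expect_equal(alpha_level(1.96, 1000), 0.050, tolerance = 1e-3)
  expect_equal(alpha_level(-2, 10), alpha_level(2, 10))
  # clamp keeps products away from zero
  expect_gte(alpha_level(1000, 10), 1e-300)
  expect_error(alpha_level(1, 1), "n must be")
})

test_that("probabilities normalize, respect symmetry and BSSID order", {
  solo <- calibrate(list(fingerprint("only", list(rssi_scan(c(X = -60)),
                                                  rssi_scan(c(X = -61))))))
  est <- fingerprint_probabilities(rssi_scan(c(X = -60.5)), solo)
  expect_equal(unname(est$probabilities), 1)

  # mirror-symmetric residuals -> 0.5 / 0.5
  fa <- fingerprint("a", list(rssi_scan(c(X = -49)), rssi_scan(c(X = -51))))
  fb <- fingerprint("b", list(rssi_scan(c(X = -69)), rssi_scan(c(X = -71))))
  m <- calibrate(list(fa, fb))
  est <- fingerprint_probabilities(rssi_scan(c(X = -60)), m)
  expect_equal(unname(est$probabilities), c(0.5, 0.5))
  expect_equal(est$winner, "a")  # lexicographic tie-break

  m2 <- calibrate(toy_calibration())
  s <- rssi_scan(c(X = -45, Y = -65))
  p1 <- fingerprint_probabilities(s, m2)$probabilities
  p2 <- fingerprint_probabilities(rssi_scan(c(Y = -65, X = -45)), m2)$probabilities
  expect_equal(p1, p2)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
})

test_that("log-domain product matches the direct product", {
  m <- calibrate(toy_calibration())
  scan <- rssi_scan(c(X = -44, Y = -66))
  est <- fingerprint_probabilities(scan, m, keep_alphas = TRUE)
  # direct (non-log) product oracle from the model statistics
  direct <- vapply(m$fingerprints, function(fid) {
    rows <- m$stats[m$stats$fingerprint == fid, ]
    rows <- rows[match(m$bssids, rows$bssid), ]
    obs <- c(X = -44, Y = -66)[m$bssids]
    tt <- (obs - rows$mean) / (rows$sd / sqrt(rows$n))
    prod(ifelse(rows$n > 30, 2 * pnorm(-abs(tt)), 2 * pt(-abs(tt), rows$n - 1)))
  }, numeric(1))
  expect_equal(unname(est$probabilities), unname(direct / sum(direct)),
               tolerance = 1e-12)
})

test_that("a scan at a fingerprint's means wins", {
  m <- calibrate(toy_calibration())
  amean <- m$stats[m$stats$fingerprint == "a", ]
  scan <- rssi_scan(setNames(amean$mean, amean$bssid))
  expect_equal(fingerprint_probabilities(scan, m)$winner, "a")
})

test_that("the tracker commits only after k consecutive wins", {
  st <- track_state(k = 1)
  st <- update_track(stub_estimate("A"), st)
  expect_equal(st$committed, "A")

  st <- track_state(k = 3)
  for (w in c("A", "A", "B", "B")) st <- update_track(stub_estimate(w), st)
  expect_true(is.na(st$committed))
  st <- update_track(stub_estimate("B"), st)
  expect_equal(st$committed, "B")

  st <- track_state(k = 2)
  for (w in rep(c("A", "B"), 4)) st <- update_track(stub_estimate(w), st)
  expect_true(is.na(st$committed))
  expect_lte(st$count, st$k)
})

test_that("locate propagates errors for unknown BSSIDs", {
  m <- calibrate(toy_calibration())
  expect_error(locate(rssi_scan(c(ZZZ = -50)), m, track_state()),
               "no BSSID")
})

test_that("the locator recovers the true room on synthetic environments", {
  sim <- simulate_rssi(rssi_environment(), scans_per_fp = 50L,
                       test_per_fp = 30L, seed = 11L)
  model <- calibrate(sim$calibration)
  pred <- vapply(sim$test_scans,
                 function(s) fingerprint_probabilities(s, model)$winner,
                 character(1))
  expect_gte(mean(pred == sim$test_labels), 0.95)
})
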