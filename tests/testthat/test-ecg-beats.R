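test_that("the wavelet pyramid reconstructs perfectly", {
  set.seed(1)
  for (n in c(64, 100, 257)) {
    x <- rnorm(n)
    w <- carewatch:::.dwt(x, levels = 3)
    expect_equal(carewatch:::.idwt(w), x, tolerance = 1e-10)
  }
})

test_that("soft-threshold denoising reduces noise on a smooth signal", {
  set.seed(2)
  t <- seq(0, 1, length.out = 512)
  clean <- sin(2 * pi * 3 * t)
  noisy <- clean + rnorm(512, 0, 0.2)
  den <- denoise_dwt(noisy, levels = 2)
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))
})

test_that("preprocessing maps zero and DC inputs to a null envelope", {
  z <- ecg_signal(rep(0, 1024), 256)
  expect_equal(max(abs(ecg_preprocess(z))), 0)
  dc <- ecg_signal(rep(0.7, 1024), 256)
  expect_lt(max(ecg_preprocess(dc)), 1e-12)
  short <- ecg_signal(rep(0, 10), 256)
  expect_error(ecg_preprocess(short), "shorter than one integration window")
})

test_that("envelope maxima sit on the QRS complexes", {
  sim <- simulate_ecg(ecg_script(duration_s = 10, rate_bpm = 60, seed = 1))
  env <- ecg_preprocess(sim$signal)
  tol <- round(0.050 * 256)
  for (r in sim$truth$r) {
    win <- env[(r - tol):(r + tol)]
    expect_gt(max(win), 0.5 * max(env))  # strong local energy at each beat
  }
})

test_that("the adaptive threshold update is exact", {
  expect_equal(update_threshold(0, 5, alpha = 1, gamma = 1), 5)
  expect_equal(update_threshold(7, 100, alpha = 0, gamma = 0.5), 7)
  expect_equal(update_threshold(10, 100, alpha = 0.5, gamma = 0.5), 30)
})

test_that("R detection hits every scripted beat on clean signals", {
  sim <- simulate_ecg(ecg_script(duration_s = 10, rate_bpm = 60, seed = 1))
  env <- ecg_preprocess(sim$signal)
  r <- detect_r_peaks(env, sim$signal)
  expect_length(r, 10)
  expect_true(all(abs(r - sim$truth$r) <= round(0.020 * 256)))

  flat <- ecg_signal(rep(0, 2560), 256)
  expect_length(detect_r_peaks(ecg_preprocess(flat), flat), 0)
})

test_that("detection is invariant under positive amplitude scaling", {
  sim <- simulate_ecg(ecg_script(duration_s = 20, rate_bpm = 72,
                                 rr_jitter = 0.03, noise_sd = 0.04, seed = 5))
  r1 <- detect_r_peaks(ecg_preprocess(sim$signal), sim$signal)
  for (k in c(0.5, 2, 10)) {
    sc <- ecg_signal(sim$signal$samples * k, sim$signal$rate)
    rk <- detect_r_peaks(ecg_preprocess(sc), sc)
    expect_equal(rk, r1)
  }
})

test_that("wave location recovers scripted P/Q/S/T positions", {
  sim <- simulate_ecg(ecg_script(duration_s = 12, rate_bpm = 65, seed = 4))
  env <- ecg_preprocess(sim$signal)
  r <- detect_r_peaks(env, sim$signal)
  ann <- locate_waves(sim$signal, r)
  # align each retained beat with its nearest scripted beat
  truth <- sim$truth[vapply(ann$r, function(x) which.min(abs(sim$truth$r - x)),
                            integer(1)), ]
  tol <- round(0.030 * 256)
  expect_true(all(abs(ann$q - truth$q) <= tol))
  expect_true(all(abs(ann$s - truth$s) <= tol))
  expect_true(all(abs(ann$p - truth$p) <= tol))
  expect_true(all(abs(ann$t - truth$t) <= tol))
  # ordering invariant
  expect_true(all(ann$p < ann$q & ann$q < ann$r & ann$r < ann$s & ann$s < ann$t))
})

test_that("a beat generated without a P bump is reported P-absent", {
  mor <- ecg_morphology()
  mor$amp[mor$wave == "p"] <- 0
  sim <- simulate_ecg(ecg_script(duration_s = 10, rate_bpm = 60,
                                 morphology = mor, seed = 6))
  env <- ecg_preprocess(sim$signal)
  ann <- locate_waves(sim$signal, detect_r_peaks(env, sim$signal))
  expect_true(all(is.na(ann$p)))
  expect_true(all(!is.na(ann$t)))
})

test_that("Q and S are the window minima around R on a clean beat", {
  sim <- simulate_ecg(ecg_script(duration_s = 6, rate_bpm = 60, seed = 2))
  raw <- sim$signal$samples
  r <- detect_r_peaks(ecg_preprocess(sim$signal), sim$signal)
  ann <- locate_waves(sim$signal, r)
  qs <- round(0.060 * 256)
  for (i in seq_len(nrow(ann))) {
    rr <- ann$r[i]
    expect_equal(ann$q[i], (rr - qs) + which.min(raw[(rr - qs):(rr - 1)]) - 1L)
    expect_equal(ann$s[i], rr + which.min(raw[(rr + 1):(rr + qs)]))
  }
})

test_that("beat features convert sample intervals to milliseconds", {
  ann <- data.frame(p = c(900, 1700), q = c(970, 1770), r = c(1000, 1800),
                    s = c(1030, 1830), t = c(1250, 2050))
  f <- beat_features(ann, rate = 1000)
  expect_equal(f$Ri, c(NA, 800))
  expect_equal(f$Pi, c(NA, 800))
  expect_equal(f$Dqr, c(30, 30))

  ann2 <- data.frame(p = NA_integer_, q = 250L, r = 256L, s = 262L,
                     t = NA_integer_)
  f2 <- beat_features(ann2, rate = 256)
  expect_equal(f2$Dqr, 6 * 1000 / 256)   # 23.4375 ms
  expect_true(all(is.na(f2[, c("Pi", "Qi", "Ri", "Si", "Ti")])))
  expect_true(is.na(f2$Dpq))
})

test_that("feature vectors survive a CSV round trip losslessly", {
  sim <- simulate_ecg(ecg_script(duration_s = 10, rate_bpm = 60, seed = 1))
  env <- ecg_preprocess(sim$signal)
  ann <- locate_waves(sim$signal, detect_r_peaks(env, sim$signal))
  f <- beat_features(ann, 256)
  path <- tempfile(fileext = ".csv")
  write_features_csv(f, path)
  f2 <- read_features_csv(path)
  expect_equal(as.data.frame(f2), as.data.frame(f))
})
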