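test_that("lead identities hold for arbitrary electrode traces", {
  tr <- random_traces(c("RA", "LA", "LL", paste0("V", 1:6)))
  ch <- derive_ecg_channels(tr)
  expect_equal(nrow(ch), 16L)
  expect_equal(rownames(ch), ecg_channel_order())
  # Einthoven: I + III = II
  expect_equal(ch["I", ] + ch["III", ], ch["II", ], tolerance = 1e-12)
  # Goldberger: aVR + aVL + aVF = 0
  expect_lt(max(abs(ch["aVR", ] + ch["aVL", ] + ch["aVF", ])), 1e-12)
})

test_that("constant electrode potentials give the documented channel arithmetic", {
  nm <- c("RA", "LA", "LL", paste0("V", 1:6))
  tr <- random_traces(nm, n_t = 4)
  tr["RA", ] <- 1; tr["LA", ] <- 3; tr["LL", ] <- 5
  ch <- derive_ecg_channels(tr)
  expect_equal(unique(ch["I", ]), 2)
  expect_equal(unique(ch["II", ]), 4)
  expect_equal(unique(ch["III", ]), 2)
  expect_equal(unique(ch["LL-RA-LA", ]), 1)
  expect_equal(unique(ch["avg(RA,LA,LL)", ]), 4.5)
  tr2 <- random_traces("RA")
  expect_error(derive_ecg_channels(tr2), "LA")
})

test_that("EGM vector set enumerates exactly 16 channels with antisymmetry", {
  nm <- c("RVtip", "RVring", "RVcoil", "SVC", "CAN", paste0("LVtip", 1:4))
  tr <- random_traces(nm)
  ch <- derive_egm_channels(tr)
  expect_equal(nrow(ch), 16L)
  expect_equal(rownames(ch), egm_channel_order())

  # all potentials equal -> all channels zero
  tr0 <- tr; tr0[] <- 2.5
  expect_true(all(derive_egm_channels(tr0) == 0))

  # swapping CAN and SVC negates the CAN-SVC channel
  trs <- tr
  trs["CAN", ] <- tr["SVC", ]; trs["SVC", ] <- tr["CAN", ]
  expect_equal(derive_egm_channels(trs)["CAN-SVC", ], -ch["CAN-SVC", ],
               tolerance = 1e-12)
})

test_that("QRS windowing follows max activation and is shared across channels", {
  nm <- c("RA", "LA", "LL", paste0("V", 1:6))
  tr <- random_traces(nm, n_t = 200)  # times 0..99.5
  ch <- derive_ecg_channels(tr)
  win <- extract_qrs(ch, max_tau = 80, upstroke = 1, margin = 0)
  times <- attr(win, "times")
  expect_equal(max(times), 81)           # window length 81 ms
  expect_equal(min(times), 0)
  # identical window for a different channel set of the same beat
  sub <- structure(ch[7:16, ], times = attr(ch, "times"), class = class(ch))
  win2 <- extract_qrs(sub, max_tau = 80, upstroke = 1, margin = 0)
  expect_equal(attr(win2, "times"), times)
  expect_error(extract_qrs(ch, max_tau = 120, upstroke = 1, margin = 0), "window")
})

test_that("signal energy after full activation is negligible within the QRS band", {
  mesh <- small_mesh(); lf <- small_lf(); cond <- small_cond()
  act <- solve_activation(cond, 321L)
  tmpl <- ap_template()
  # simulate well past the end of activation but before repolarization
  dur <- max(act$tau) + 10
  tr <- beat_traces(lf, act$tau, tmpl, duration = dur)
  times <- attr(tr, "times")
  outside <- times > max(act$tau) + tmpl$upstroke + 1e-9
  expect_true(any(outside))
  ratio <- sum(tr[, outside]^2) / sum(tr^2)
  expect_lt(ratio, 1e-9)
})

test_that("resampling to 16 points preserves constants, endpoints and fixed points", {
  mk <- function(vals) structure(matrix(vals, 1, length(vals), byrow = TRUE),
                                 times = seq(0, length.out = length(vals), by = 2),
                                 class = c("vt_channels", "matrix", "array"))
  const <- resample_16(mk(rep(3.3, 40)))
  expect_equal(as.numeric(const), rep(3.3, 16))

  ramp_vals <- seq(0, 7.8, by = 0.2)
  ramp <- resample_16(mk(ramp_vals))
  expect_equal(ramp[1, 1], 0); expect_equal(ramp[1, 16], 7.8)

  on_grid <- mk(sin(1:16))
  expect_equal(as.numeric(resample_16(on_grid)), sin(1:16), tolerance = 1e-12)
  expect_error(resample_16(mk(1)), "samples")
})

test_that("additive noise hits the requested SNR and is seed-reproducible", {
  set.seed(1)
  sig <- matrix(sin(seq(0, 400 * pi, length.out = 2e5)), nrow = 2, byrow = TRUE)
  noisy <- add_noise(sig, snr_db = 25, seed = 10)
  for (r in 1:2) {
    snr_emp <- 10 * log10(mean(sig[r, ]^2) / mean((noisy[r, ] - sig[r, ])^2))
    expect_lt(abs(snr_emp - 25), 0.5)
  }
  expect_identical(add_noise(sig, 25, seed = 10), noisy)
  expect_false(identical(add_noise(sig, 25, seed = 11), noisy))
  expect_identical(add_noise(sig, Inf, seed = 10), sig)
})

test_that("signal matrices are 16x16 with unit max-abs after normalization", {
  vals <- matrix(rnorm(256), 16, 16)
  sm <- signal_matrix(vals, "ecg")
  expect_equal(dim(sm$values), c(16L, 16L))
  expect_equal(max(abs(sm$values)), 1)
  expect_equal(sm$channel_order, ecg_channel_order())
  noisy <- add_noise(sm, 25, seed = 2)
  expect_equal(max(abs(noisy$values)), 1)   # noise added before normalization
  expect_equal(noisy$snr_db, 25)
  expect_error(signal_matrix(matrix(0, 16, 16), "ecg"), "zero")
  expect_error(signal_matrix(matrix(1, 8, 8), "ecg"), "16 x 16")
})

test_that("phi wedges tile [-pi, pi] in 68 equal 0.09-rad intervals", {
  d <- 2 * pi / 68
  expect_equal(round(d, 2), 0.09)
  expect_equal(phi_to_wedge(-pi), 1L)
  expect_equal(phi_to_wedge(pi), 68L)
  expect_equal(phi_to_wedge(-pi + d), 2L)      # left-closed intervals
  ks <- 1:68
  expect_equal(phi_to_wedge(wedge_to_phi(ks)), ks)
  expect_error(phi_to_wedge(3.2), "outside")
  expect_error(wedge_to_phi(0), "outside")
})
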