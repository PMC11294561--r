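# Limb-lead algebra, scaling and resampling.

test_that("limb-lead derivation matches the Einthoven-Goldberger identities", {
  out <- derive_limb_leads(rep(0.2, 5), rep(1.0, 5))
  expect_equal(unname(out["III", ]), rep(0.8, 5))
  expect_equal(unname(out["aVR", ]), rep(-0.6, 5))
  expect_equal(unname(out["aVL", ]), rep(-0.3, 5))
  expect_equal(unname(out["aVF", ]), rep(0.9, 5))

  # I = II forces III = 0
  x <- rnorm(50)
  expect_equal(max(abs(derive_limb_leads(x, x)["III", ])), 0)
})

test_that("augmented leads sum to zero and derived records are consistent", {
  set.seed(11)
  for (i in 1:20) {
    ll <- derive_limb_leads(rnorm(200), rnorm(200))
    expect_lt(max(abs(colSums(ll[c("aVR", "aVL", "aVF"), ]))), 1e-12)
    sig <- rbind(ll, matrix(rnorm(6 * 200), 6,
                            dimnames = list(precordial_leads(), NULL)))
    rec <- ecg_record(sig, 250)
    expect_true(check_limb_consistency(rec, tol = 1e-9)$pass)
  }
})

test_that("limb consistency flags a constructed violation", {
  ll <- derive_limb_leads(rnorm(100), rnorm(100))
  sig <- rbind(ll, matrix(0, 6, 100,
                          dimnames = list(precordial_leads(), NULL)))
  sig["aVF", 10] <- sig["aVF", 10] + 0.1
  chk <- check_limb_consistency(ecg_record(sig, 250), tol = 1e-3)
  expect_false(chk$pass)
  expect_equal(chk$residual, 0.1, tolerance = 1e-9)
})

test_that("derive_limb_leads rejects malformed input", {
  expect_error(derive_limb_leads(1:3, 1:4), "same length")
  expect_error(derive_limb_leads(c(1, NA), c(1, 2)), "finite")
})

test_that("unit scaling maps the +/-2.5 mV window to [0, 1] with clipping", {
  expect_equal(scale_to_unit(c(-2.5, 0, 2.5)), c(0, 0.5, 1))
  expect_equal(scale_to_unit(3.1), 1)     # clipped above
  expect_equal(scale_to_unit(-9), 0)      # clipped below
  expect_equal(unscale(c(0, 0.5, 1)), c(-2.5, 0, 2.5))
  # monotone non-decreasing
  v <- sort(runif(200, -4, 4))
  expect_true(all(diff(scale_to_unit(v)) >= 0))
})

test_that("scaling round-trips inside the window at machine precision", {
  set.seed(21)
  v <- runif(1000, -2.5, 2.5)
  expect_lt(max(abs(unscale(scale_to_unit(v)) - v)), 1e-12)
  u <- runif(1000)
  expect_lt(max(abs(scale_to_unit(unscale(u)) - u)), 1e-12)
})

test_that("resampling halves a 500 Hz record and preserves a 5 Hz sine", {
  x <- sin(2 * pi * 5 * (0:4999) / 500)
  y <- resample_signal(x, 500, 250)
  expect_length(y, 2500)
  expect_lt(abs(max(abs(y)) - 1), 0.01)
  # identity when rates agree
  expect_identical(resample_signal(x, 500, 500), x)
  # repeated application at the same rate changes nothing
  expect_identical(resample_signal(y, 250, 250), y)
  expect_error(resample_signal(numeric(0), 500, 250), "empty")
})

test_that("record resampling keeps limb-lead consistency", {
  m <- dipole_model()
  rec <- project_leads(simulate_dipole(m, 2, 500, seed = 5), m)
  rec250 <- relead:::resample_record(rec, 250)
  expect_equal(ncol(rec250$signals), 500)
  expect_true(check_limb_consistency(rec250, tol = 1e-9)$pass)
})
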