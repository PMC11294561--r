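# Dipole simulator, lead projection and the dataset generator.

test_that("zero wave amplitudes give an identically zero trajectory", {
  w <- default_amp0 <- lapply(relead:::default_waves(), function(x) {
    x$amp <- 0; x
  })
  m <- dipole_model(waves = w)
  tr <- simulate_dipole(m, 2, 250, seed = 1)
  expect_equal(max(abs(tr)), 0)
  rec <- project_leads(tr, m)
  expect_equal(max(abs(rec$signals)), 0)
})

test_that("simulation is reproducible bit-for-bit under a fixed seed", {
  m <- dipole_model()
  t1 <- simulate_dipole(m, 2, 250, seed = 9)
  t2 <- simulate_dipole(m, 2, 250, seed = 9)
  expect_identical(t1, t2)
  expect_false(identical(t1, simulate_dipole(m, 2, 250, seed = 10)))
})

test_that("a lone R wave reaches its nominal amplitude every beat", {
  w <- lapply(relead:::default_waves(), function(x) { x$amp <- 0; x })
  w$x$amp[w$x$wave == "R"] <- 1.2
  m <- dipole_model(waves = w, heart_rate = 60, rr_variability = 0)
  tr <- simulate_dipole(m, 4, 250, seed = 3)
  # closed form: peak of a Gaussian bump = its amplitude, once per beat
  for (b in 0:3) {
    seg <- tr[1, (b * 250 + 1):((b + 1) * 250)]
    expect_equal(max(seg), 1.2, tolerance = 0.01)
  }
  expect_equal(max(abs(tr[2:3, ])), 0)
})

test_that("invalid simulation inputs are rejected", {
  m <- dipole_model()
  expect_error(simulate_dipole(m, -1, 250), "positive")
  expect_error(simulate_dipole(m, 10, 300), "unsupported")
  expect_error(project_leads(matrix(0, 2, 10), m), "3 x N")
})

test_that("projection obeys the limb identities and rank-3 structure", {
  m <- dipole_model()
  tr <- simulate_dipole(m, 2, 250, seed = 31)
  rec <- project_leads(tr, m)
  s <- rec$signals
  expect_lt(max(abs(s["III", ] - (s["II", ] - s["I", ]))), 1e-10)
  expect_true(check_limb_consistency(rec, tol = 1e-9)$pass)
  # every precordial lead is a fixed linear combination of I, II, V3
  X <- t(s[c("I", "II", "V3"), ])
  for (l in precordial_leads()) {
    fit <- lm.fit(X, s[l, ])
    expect_lt(max(abs(fit$residuals)), 1e-10)
  }
})

test_that("ST displacement elevates the anterior leads only in the ST window", {
  m <- dipole_model()
  tr0 <- simulate_dipole(m, 2, 250, seed = 41)
  pat <- pathology_spec("stemi", st_offset = 0.3, territory = "anterior")
  tr1 <- relead:::apply_st_displacement(tr0, m, pat)
  d <- project_leads(tr1, m)$signals - project_leads(tr0, m)$signals
  win <- relead:::st_window(m)
  phase <- attr(tr0, "phase")
  outside <- phase < win[1] | phase > win[2]
  expect_equal(max(abs(d[, outside])), 0)
  # most affected territory lead is elevated by st_offset at the plateau
  expect_equal(max(d), 0.3, tolerance = 1e-6)
  expect_gt(max(d["V3", ]), 0.1)
})

test_that("pathology and noise specs validate their invariants", {
  expect_error(pathology_spec("normal", st_offset = 0.1), "must be 0")
  expect_silent(pathology_spec("stemi", st_offset = 0.2))
  expect_error(noise_spec(baseline_amp = -1), ">= 0")
  expect_error(noise_spec(powerline_freq = 55), "50 or 60")
})

test_that("the dataset generator hits the MI fraction and stays reproducible", {
  ds <- generate_ecg_dataset(50, 2, mi_fraction = 0.5, duration = 2,
                             seed = 77)
  expect_equal(sum(ds$manifest$mi_label), 50)
  expect_equal(nrow(ds$manifest), 100)
  expect_setequal(unique(ds$manifest$pathology[ds$manifest$mi_label]),
                  "stemi")
  ds0 <- generate_ecg_dataset(5, 1, mi_fraction = 0, duration = 2, seed = 3)
  expect_false(any(ds0$manifest$mi_label))
  expect_setequal(unique(ds0$manifest$pathology), "normal")
  expect_error(generate_ecg_dataset(5, 1, mi_fraction = 1.2), "\\[0, 1\\]")
  # reproducibility
  a <- generate_ecg_dataset(4, 1, duration = 2, seed = 5)
  b <- generate_ecg_dataset(4, 1, duration = 2, seed = 5)
  expect_identical(a$records[[3]]$signals, b$records[[3]]$signals)
})

test_that("dipole-level noise preserves the limb algebra; per-lead noise breaks it", {
  ds <- generate_ecg_dataset(4, 1, noise = noise_spec(), duration = 2,
                             seed = 12)
  for (r in ds$records)
    expect_true(check_limb_consistency(r, tol = 1e-9)$pass)
  dsl <- generate_ecg_dataset(4, 1, duration = 2, seed = 12,
                              noise = noise_spec(white_sd = 0.05,
                                                 per_lead = TRUE))
  res <- vapply(dsl$records, function(r)
    check_limb_consistency(r)$residual, numeric(1))
  expect_gt(min(res), 1e-3)
})

test_that("default-configuration voltages respect the 2.5 mV envelope", {
  ds <- generate_ecg_dataset(20, 1, duration = 2, seed = 55)
  v <- unlist(lapply(ds$records, function(r) r$signals))
  expect_gte(mean(abs(v) <= 2.5), 0.99)
})

test_that("noiseless records admit a near-perfect (I,II,V3) linear readout", {
  m <- dipole_model()
  r1 <- project_leads(simulate_dipole(m, 2, 250, seed = 61), m)
  r2 <- project_leads(simulate_dipole(m, 2, 250, seed = 62), m)
  X1 <- t(r1$signals[c("I", "II", "V3"), ])
  B <- solve(crossprod(X1), crossprod(X1, t(r1$signals[precordial_leads(), ])))
  pred <- t(t(r2$signals[c("I", "II", "V3"), ]) %*% B)
  expect_gt(ecg_r2(r2$signals[precordial_leads(), ], pred), 99.9)
})
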