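# Reconstruction network: construction, training mechanics, prediction.

test_that("architecture validation and section counts follow the config", {
  arch <- scaled_recon_arch()
  p <- relead:::recon_init_params(arch, seed = 1)
  expect_length(p$ext, 3L)              # one extractor per input lead
  expect_length(p$heads, 6L)            # always six precordial heads
  arch2 <- scaled_recon_arch(c("I", "II"))
  p2 <- relead:::recon_init_params(arch2, seed = 1)
  expect_length(p2$ext, 2L)
  expect_length(p2$heads, 6L)
  expect_error(recon_arch(character(0)), "not be empty")
  expect_error(recon_arch(c("I", "Vx")), "unknown lead")
  expect_error(recon_arch(kernel_size = 8), "odd")
})

test_that("full-size defaults carry the published architecture constants", {
  arch <- recon_arch()
  expect_equal(arch$samples_per_lead, 2500L)
  expect_equal(arch$feat_channels, 32L)
  expect_equal(arch$agg_channels, 192L)
  ca <- clf_arch()
  expect_equal(ca$samples_per_lead, 2500L)
  expect_equal(ca$embedding_dim, 128L)
  expect_length(ca$input_leads, 8L)
})

test_that("parameter initialization is reproducible under a seed", {
  arch <- scaled_recon_arch()
  p1 <- relead:::recon_init_params(arch, seed = 7)
  p2 <- relead:::recon_init_params(arch, seed = 7)
  expect_identical(relead:::flatten_params(p1),
                   relead:::flatten_params(p2))
  p3 <- relead:::recon_init_params(arch, seed = 8)
  expect_false(identical(relead:::flatten_params(p1),
                         relead:::flatten_params(p3)))
})

test_that("forward output has the contracted shape and time length", {
  arch <- scaled_recon_arch()
  p <- relead:::recon_init_params(arch, seed = 1)
  X <- lapply(1:3, function(i) array(rnorm(500 * 2), c(1, 500, 2)))
  fw <- relead:::recon_fwd(p, X, relead:::geom_cache(), need_cache = FALSE)
  expect_equal(dim(fw$yhat), c(6, 500, 2))
})

test_that("analytic gradients match finite differences", {
  # tiny configuration so central differences are cheap and stable
  arch <- recon_arch(c("I", "II"), samples_per_lead = 32L,
                     feat_channels = 2L, agg_channels = 3L,
                     blocks_per_section = 1L, kernel_size = 3L)
  p <- relead:::recon_init_params(arch, seed = 2)
  theta <- relead:::flatten_params(p)
  getg <- relead:::geom_cache()
  set.seed(3)
  X <- lapply(1:2, function(i) array(rnorm(32 * 2), c(1, 32, 2)))
  Y <- array(rnorm(6 * 32 * 2), c(6, 32, 2))
  loss_at <- function(th) {
    pp <- relead:::unflatten_params(th, p)
    fw <- relead:::recon_fwd(pp, X, getg, need_cache = FALSE)
    relead:::r2_loss_grad(fw$yhat, Y)$loss
  }
  fw <- relead:::recon_fwd(p, X, getg)
  lg <- relead:::r2_loss_grad(fw$yhat, Y)
  gr <- relead:::flatten_params(relead:::recon_bwd(p, fw$cache, lg$dyhat,
                                                   getg))
  idx <- sort(sample(length(theta), 25))
  h <- 1e-5
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    num <- (loss_at(tp) - loss_at(tm)) / (2 * h)
    expect_equal(gr[i], num, tolerance = 1e-4)
  }
})

test_that("training rejects degenerate inputs and zero-variance targets", {
  expect_error(fit_reconstructor(list()), "empty")
  ds <- noiseless_dataset()
  expect_error(
    fit_reconstructor(ds$records[1:4], scaled_recon_arch(),
                      train_control(loss = "cross_entropy")),
    "one_minus_r2")
  # constant-zero targets: every lead excluded -> error with guard message
  flat <- lapply(ds$records[1:4], function(r) {
    s <- r$signals
    s[precordial_leads(), ] <- 0
    ecg_record(s, r$fs, r$individual_id, r$mi_label)
  })
  expect_error(
    suppressWarnings(fit_reconstructor(
      flat, scaled_recon_arch(),
      train_control(epochs = 1, batch_size = 4, seed = 1))),
    "zero variance")
})

test_that("a short training run reduces the 1-R2 loss deterministically", {
  ds <- noiseless_dataset()
  recs <- ds$records[1:20]
  ctrl <- train_control(epochs = 3, batch_size = 8, learning_rate = 5e-3,
                        patience = 5, seed = 9)
  m1 <- fit_reconstructor(recs, scaled_recon_arch(), ctrl)
  expect_lt(tail(m1$history$val_loss, 1), m1$history$val_loss[1])
  m2 <- fit_reconstructor(recs, scaled_recon_arch(), ctrl)
  expect_identical(relead:::flatten_params(m1$params),
                   relead:::flatten_params(m2$params))
  expect_identical(m1$history, m2$history)
})

test_that("reconstruction passes through inputs and keeps exact limb algebra", {
  m <- trained_recon()
  ds <- noiseless_dataset()
  rec <- ds$records[[3]]
  out <- predict(m, rec)
  expect_s3_class(out, "ecg_record")
  expect_equal(dim(out$signals), c(12, 500))
  # limb leads are exact algebra on the input's I and II
  expect_true(check_limb_consistency(out, tol = 1e-9)$pass)
  expect_equal(out$signals["I", ], rec$signals["I", ])
  # the input precordial lead is passed through unchanged
  expect_identical(out$signals["V3", ], rec$signals["V3", ])
  expect_equal(out$meta$passthrough_leads, "V3")
  # a lead the model must synthesize differs from passthrough
  expect_gt(max(abs(out$signals["V1", ] - rec$signals["V1", ])), 0)
  expect_error(predict(m, ecg_record(matrix(0, 12, 40), 250)),
               "architecture expects")
})
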