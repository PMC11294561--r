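# MI classifier: construction, probability contract, training mechanics.

test_that("classifier outputs are probabilities strictly inside (0, 1)", {
  arch <- scaled_clf_arch()
  p <- relead:::clf_init_params(arch, seed = 1)
  X <- lapply(1:8, function(i) array(rnorm(500 * 3), c(1, 500, 3)))
  fw <- relead:::clf_fwd(p, X, arch, relead:::geom_cache(),
                         need_cache = FALSE)
  prob <- 1 / (1 + exp(-fw$logits))
  expect_length(prob, 3L)
  expect_true(all(prob > 0 & prob < 1))
})

test_that("untrained classifier sits near chance-level cross-entropy", {
  ds <- stemi_dataset()
  arch <- scaled_clf_arch()
  p <- relead:::clf_init_params(arch, seed = 4)
  recs <- ds$records[1:20]
  X <- relead:::clf_tensors(recs, arch)
  fw <- relead:::clf_fwd(p, X, arch, relead:::geom_cache(),
                         need_cache = FALSE)
  y <- vapply(recs, function(r) isTRUE(r$mi_label), NA)
  ce <- relead:::bce_loss_grad(fw$logits, y)$loss
  expect_lt(abs(ce - log(2)), 0.2)
})

test_that("classifier initialization is seed-reproducible", {
  arch <- scaled_clf_arch()
  expect_identical(
    relead:::flatten_params(relead:::clf_init_params(arch, seed = 3)),
    relead:::flatten_params(relead:::clf_init_params(arch, seed = 3)))
})

test_that("classifier gradients match finite differences", {
  arch <- clf_arch(samples_per_lead = 32L, feat_channels = 2L,
                   embedding_dim = 3L, fnn_widths = 3L,
                   blocks_per_section = 1L, reduce_steps = 1L,
                   kernel_size = 3L)
  p <- relead:::clf_init_params(arch, seed = 5)
  theta <- relead:::flatten_params(p)
  getg <- relead:::geom_cache()
  set.seed(6)
  X <- lapply(1:8, function(i) array(rnorm(32 * 2), c(1, 32, 2)))
  y <- c(TRUE, FALSE)
  loss_at <- function(th) {
    pp <- relead:::unflatten_params(th, p)
    fw <- relead:::clf_fwd(pp, X, arch, getg, need_cache = FALSE)
    relead:::bce_loss_grad(fw$logits, y)$loss
  }
  fw <- relead:::clf_fwd(p, X, arch, getg)
  lg <- relead:::bce_loss_grad(fw$logits, y)
  gr <- relead:::flatten_params(relead:::clf_bwd(p, fw$cache, lg$dz, arch,
                                                 getg))
  idx <- sort(sample(length(theta), 20))
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + 1e-5
    tm <- theta; tm[i] <- tm[i] - 1e-5
    expect_equal(gr[i], (loss_at(tp) - loss_at(tm)) / 2e-5,
                 tolerance = 1e-4)
  }
})

test_that("training requires binary labels of both classes", {
  ds <- stemi_dataset()
  pos <- ds$records[ds$manifest$mi_label][1:6]
  expect_error(fit_mi_classifier(pos), "single class")
  unl <- lapply(ds$records[1:4], function(r)
    ecg_record(r$signals, r$fs, r$individual_id, NA))
  expect_error(fit_mi_classifier(unl), "label")
  expect_error(fit_mi_classifier(ds$records[1:8],
                                 control = train_control()),
               "cross_entropy")
})

test_that("predictions are deterministic and ignore metadata", {
  m <- trained_classifier()
  ds <- stemi_dataset()
  rec <- ds$records[[5]]
  p1 <- predict(m, rec)
  p2 <- predict(m, rec)
  expect_identical(p1, p2)
  rec2 <- ecg_record(rec$signals, rec$fs, "someone-else", !rec$mi_label,
                     meta = list(note = "metadata must not matter"))
  expect_equal(unname(predict(m, rec2)), unname(p1))
})

test_that("trained classifier separates MI from non-MI on held-out data", {
  m <- trained_classifier()
  ds <- stemi_dataset(); sp <- stemi_split()
  te <- split_records(ds, sp, "test")
  y <- vapply(te, function(r) isTRUE(r$mi_label), NA)
  p <- predict(m, te)
  expect_gt(mean(p[y]), mean(p[!y]))
  # validation loss at the restored checkpoint is the history minimum
  expect_equal(m$val_loss, min(m$history$val_loss))
})

test_that("MI probability responds monotonically to the ST offset", {
  m <- trained_classifier()
  offsets <- c(0, 0.1, 0.2, 0.3)
  means <- vapply(offsets, function(o) {
    pat <- if (o == 0) pathology_spec("normal")
           else pathology_spec("stemi", st_offset = o)
    ds <- generate_ecg_dataset(8, 1, mi_fraction = if (o == 0) 0 else 1,
                               pathology = pat, duration = 2, seed = 500)
    mean(predict(m, ds))
  }, numeric(1))
  expect_gt(cor(offsets, means, method = "spearman"), 0)
})
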