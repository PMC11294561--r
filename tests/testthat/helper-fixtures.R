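# Shared fixtures, generated in code at test time.
#
# Heavy objects (datasets, trained models) are built once per test run
# and memoized in this environment so the per-file tests and the
# acceptance checks reuse the same artifacts.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Noiseless synthetic benchmark (rank-3 dipole data, per-individual
# jitter), 2-second records: the reconstruction test bed.
noiseless_dataset <- function() {
  fixture("noiseless_ds", function() {
    generate_ecg_dataset(40, 2, mi_fraction = 0.5, noise = noise_none(),
                         duration = 2, seed = 101)
  })
}

noiseless_split <- function() {
  fixture("noiseless_split", function() {
    grouped_stratified_split(noiseless_dataset(), seed = 102)
  })
}

split_records <- function(dataset, split, subset) {
  dataset$records[split$subset == subset]
}

# Noisy ST-elevation benchmark for the classifier.
stemi_dataset <- function() {
  fixture("stemi_ds", function() {
    generate_ecg_dataset(60, 2, mi_fraction = 0.5, noise = noise_spec(),
                         pathology = pathology_spec("stemi", st_offset = 0.3),
                         duration = 2, seed = 103)
  })
}

stemi_split <- function() {
  fixture("stemi_split", function() {
    grouped_stratified_split(stemi_dataset(), seed = 104)
  })
}

scaled_recon_arch <- function(leads = c("I", "II", "V3")) {
  recon_arch(leads, scaled_down = TRUE, samples_per_lead = 500L)
}

scaled_clf_arch <- function() {
  clf_arch(scaled_down = TRUE, samples_per_lead = 500L)
}

# Trained models, shared between the model unit tests, the attribution
# tests and the acceptance checks.
trained_recon <- function(leads = c("I", "II", "V3")) {
  key <- paste0("recon_", paste(leads, collapse = "_"))
  fixture(key, function() {
    ds <- noiseless_dataset(); sp <- noiseless_split()
    fit_reconstructor(
      split_records(ds, sp, "train"), scaled_recon_arch(leads),
      train_control(epochs = 70, batch_size = 16, learning_rate = 5e-3,
                    patience = 10, seed = 105),
      val_records = split_records(ds, sp, "validation"))
  })
}

# Balanced label permutation: exactly half of each true class relabeled
# positive, so the permuted labels are orthogonal to the pathology by
# construction (a restricted permutation, the standard variance-reduction
# device for permutation controls).
balanced_shuffle <- function(y, seed) {
  set.seed(seed)
  out <- logical(length(y))
  for (cl in c(TRUE, FALSE)) {
    idx <- which(y == cl)
    out[sample(idx, floor(length(idx) / 2))] <- TRUE
  }
  out
}

# One permutation-control classifier: same architecture and optimizer as
# the real classifier, trained on balanced-permuted labels (no early
# stopping - the control must actually fit the permuted labels rather
# than return a barely-trained model).
shuffled_label_control <- function(records, seed) {
  ytrue <- vapply(records, function(r) isTRUE(r$mi_label), NA)
  fit_mi_classifier(records, scaled_clf_arch(),
                    train_control(epochs = 40, batch_size = 16,
                                  learning_rate = 2e-3, patience = 40,
                                  seed = seed, loss = "cross_entropy"),
                    labels = balanced_shuffle(ytrue, seed))
}

trained_classifier <- function() {
  fixture("clf", function() {
    ds <- stemi_dataset(); sp <- stemi_split()
    fit_mi_classifier(
      split_records(ds, sp, "train"), scaled_clf_arch(),
      train_control(epochs = 30, batch_size = 16, learning_rate = 2e-3,
                    patience = 8, seed = 106, loss = "cross_entropy"),
      val_records = split_records(ds, sp, "validation"))
  })
}
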