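#' Pipeline configuration
#'
#' Assembles the full run configuration (dataset sizes, architecture and
#' training settings, output directory, seed) with desktop-scale
#' defaults.  The configuration round-trips losslessly through YAML
#' ([read_pipeline_config()] / the `config.yaml` written next to every
#' run's outputs).
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it, so a run is fully reproducible.
#' @param n_individuals,records_per_individual,mi_fraction,duration,fs
#'   Synthetic dataset parameters (see [generate_ecg_dataset()]).
#' @param st_offset ST elevation (mV) of MI-labeled records.
#' @param noise Noise profile: `"default"`, `"none"`, or a list of
#'   [noise_spec()] arguments.
#' @param epochs,batch_size,learning_rate,patience Training settings
#'   shared by the reconstruction and classification models.
#' @param recon Extra overrides for [recon_arch()] (list).
#' @param clf Extra overrides for [clf_arch()] (list).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "relead-run", seed = 1L,
                            n_individuals = 60L,
                            records_per_individual = 2L,
                            mi_fraction = 0.5, duration = 2, fs = 250,
                            st_offset = 0.3, noise = "default",
                            epochs = 40L, batch_size = 16L,
                            learning_rate = 2e-3, patience = 8L,
                            recon = list(), clf = list()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_individuals = as.integer(n_individuals),
                 records_per_individual = as.integer(records_per_individual),
                 mi_fraction = mi_fraction, duration = duration, fs = fs,
                 st_offset = st_offset, noise = noise,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 recon = recon, clf = clf),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [run_pipeline()] or by hand.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

config_noise <- function(noise) {
  if (is.character(noise)) {
    switch(noise, none = noise_none(), default = noise_spec(),
           stop("unknown noise profile: ", noise))
  } else {
    do.call(noise_spec, noise)
  }
}

#' Run the full reduced-lead reconstruction pipeline
#'
#' End-to-end, fully reproducible under the configuration seed:
#' simulate a labeled synthetic dataset; split it grouped-and-stratified
#' into train/validation/test; train two reconstruction models (inputs
#' I+II and I+II+V3); train the MI classifier on original records; score
#' the three ECG versions (Original, I+II, I+II+V3) with that one
#' classifier; write evaluation tables (reconstruction fidelity with 95%
#' CIs, one AUC row per version), the Shapley lead-attribution table, the
#' dataset manifest and split, and the resolved configuration.
#'
#' @param config A [pipeline_config()] (or path to its YAML form).
#' @param verbose Print stage progress (default `TRUE`).
#' @return Invisibly, a list with the fitted models and the evaluation
#'   tables; all artifacts are also written under `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[relead] ", ...)
  stage <- "setup"
  res <- tryCatch({
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))

    stage <- "simulate"
    say("simulating dataset (", config$n_individuals, " individuals)")
    dataset <- generate_ecg_dataset(
      n_individuals = config$n_individuals,
      records_per_individual = config$records_per_individual,
      mi_fraction = config$mi_fraction,
      noise = config_noise(config$noise),
      pathology = pathology_spec("stemi", st_offset = config$st_offset),
      fs = config$fs, duration = config$duration,
      seed = config$seed)
    utils::write.table(dataset$manifest,
                       file.path(config$out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "split"
    split <- grouped_stratified_split(dataset, seed = config$seed + 1L)
    utils::write.table(as.data.frame(split)[c("record_id", "subset")],
                       file.path(config$out_dir, "split.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    recs <- function(s) dataset$records[split$subset == s]

    n_samp <- as.integer(round(config$duration * config$fs))
    ctrl <- function(loss, seed_off) train_control(
      epochs = config$epochs, batch_size = config$batch_size,
      learning_rate = config$learning_rate, patience = config$patience,
      seed = config$seed + seed_off, loss = loss)

    stage <- "train-recon"
    recon_models <- list()
    for (leads in list(c("I", "II"), c("I", "II", "V3"))) {
      tag <- paste(leads, collapse = "+")
      say("training reconstructor (", tag, ")")
      arch <- do.call(recon_arch, c(
        list(input_leads = leads, scaled_down = TRUE,
             samples_per_lead = n_samp), config$recon))
      recon_models[[tag]] <- fit_reconstructor(
        recs("train"), arch, ctrl("one_minus_r2", 2L),
        val_records = recs("validation"))
    }

    stage <- "train-clf"
    say("training MI classifier")
    clf <- fit_mi_classifier(
      recs("train"),
      do.call(clf_arch, c(list(scaled_down = TRUE,
                               samples_per_lead = n_samp), config$clf)),
      ctrl("cross_entropy", 3L), val_records = recs("validation"))

    stage <- "evaluate"
    say("evaluating on the test subset")
    test <- recs("test")
    fid <- lapply(recon_models, evaluate_reconstruction, records = test)
    fid_tab <- do.call(rbind, lapply(names(fid), function(v) data.frame(
      version = v, n = fid[[v]]$n,
      r2_mean = fid[[v]]$r2_mean, r2_halfwidth = fid[[v]]$r2_halfwidth,
      mse_mean = fid[[v]]$mse_mean, mse_halfwidth = fid[[v]]$mse_halfwidth,
      stringsAsFactors = FALSE)))
    write_num_table(fid_tab, file.path(config$out_dir, "reconstruction.tsv"))
    auc_tab <- score_versions(clf, test, recon_models)
    write_num_table(auc_tab, file.path(config$out_dir, "auc.tsv"))

    stage <- "shap"
    say("computing Shapley lead attributions")
    m3 <- recon_models[["I+II+V3"]]
    sh <- lead_shap(shap_value_r2(m3, test[seq_len(min(8L, length(test)))]),
                    m3$arch$input_leads)
    shap_tab <- data.frame(lead = names(sh$phi), phi = as.numeric(sh$phi),
                           stringsAsFactors = FALSE)
    write_num_table(shap_tab, file.path(config$out_dir, "shap.tsv"))

    list(dataset = dataset, split = split, recon_models = recon_models,
         classifier = clf, reconstruction = fid_tab, auc = auc_tab,
         shap = shap_tab)
  }, error = function(e) {
    stop("pipeline stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
  say("done; artifacts in ", config$out_dir)
  invisible(res)
}

# Deterministic fixed-format table writer (byte-identical across runs
# with identical inputs).
write_num_table <- function(df, path) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.10g", df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
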