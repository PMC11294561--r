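#' Architecture of the precordial-lead reconstruction network
#'
#' The reconstruction network is organized into three sections: one
#' residual-CNN feature extractor per input lead (each emitting
#' `feat_channels` channels at full time resolution), a single aggregation
#' residual-CNN block operating on the concatenated per-lead features and
#' emitting `agg_channels` channels, and six independent residual-CNN
#' heads, one per precordial lead, each ending in a linear 1x1 convolution
#' whose output is unrestricted and directly in millivolts.  The full-size
#' defaults (2500 samples, 32 feature channels, 192 aggregate channels)
#' match the clinical-scale design; `scaled_down = TRUE` selects a small
#' configuration suitable for desktop-scale experiments.
#'
#' @param input_leads Ordered subset of canonical lead names used as input
#'   (default `c("I", "II", "V3")`).
#' @param samples_per_lead Samples per lead (2500 = 10 s at 250 Hz).
#' @param feat_channels Channels emitted by each per-lead extractor.
#' @param agg_channels Channels emitted by the aggregation block.
#' @param blocks_per_section Residual units per section.
#' @param kernel_size Odd convolution kernel length (samples).
#' @param scaled_down If `TRUE`, shrink samples/channels for fast
#'   experiments (500 samples, 6/12 channels, 1 unit, kernel 9).
#' @return Object of class `recon_arch`.
#' @export
recon_arch <- function(input_leads = c("I", "II", "V3"),
                       samples_per_lead = 2500L,
                       feat_channels = 32L,
                       agg_channels = 192L,
                       blocks_per_section = 2L,
                       kernel_size = 15L,
                       scaled_down = FALSE) {
  if (scaled_down) {
    if (missing(samples_per_lead)) samples_per_lead <- 500L
    if (missing(feat_channels)) feat_channels <- 6L
    if (missing(agg_channels)) agg_channels <- 12L
    if (missing(blocks_per_section)) blocks_per_section <- 1L
    if (missing(kernel_size)) kernel_size <- 9L
  }
  if (length(input_leads) < 1L) stop("`input_leads` must not be empty")
  bad <- setdiff(input_leads, canonical_leads())
  if (length(bad)) stop("unknown lead name(s): ", paste(bad, collapse = ", "))
  if (kernel_size %% 2L != 1L) stop("`kernel_size` must be odd")
  structure(list(input_leads = input_leads,
                 samples_per_lead = as.integer(samples_per_lead),
                 feat_channels = as.integer(feat_channels),
                 agg_channels = as.integer(agg_channels),
                 blocks_per_section = as.integer(blocks_per_section),
                 kernel_size = as.integer(kernel_size),
                 scaled_down = scaled_down),
            class = "recon_arch")
}

#' Training hyperparameters
#'
#' @param epochs Maximum number of epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience on validation loss, in epochs;
#'   the best-validation parameters are restored when training ends.
#' @param seed Integer seed fixing initialization and shuffling.
#' @param loss `"one_minus_r2"` (reconstruction) or `"cross_entropy"`
#'   (classification); [fit_reconstructor()] and [fit_mi_classifier()]
#'   each accept only their own loss.
#' @return Object of class `train_control`.
#' @export
train_control <- function(epochs = 60L, batch_size = 16L,
                          learning_rate = 1e-3, patience = 5L,
                          seed = 1L,
                          loss = c("one_minus_r2", "cross_entropy")) {
  if (epochs < 1L) stop("`epochs` must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 loss = match.arg(loss)),
            class = "train_control")
}

# --- parameter construction --------------------------------------------

recon_init_params <- function(arch, seed) {
  set.seed(seed)
  L <- length(arch$input_leads)
  k <- arch$kernel_size
  B <- arch$blocks_per_section
  list(
    ext = replicate(L, section_init(1L, arch$feat_channels, k, B),
                    simplify = FALSE),
    agg = section_init(L * arch$feat_channels, arch$agg_channels, k, B),
    heads = replicate(6L, c(
      section_init(arch$agg_channels, arch$agg_channels, k, B),
      list(final = conv_init(arch$agg_channels, 1L, 1L, gain = 0.3))),
      simplify = FALSE))
}

recon_fwd <- function(params, Xlist, getg, need_cache = TRUE) {
  L <- length(Xlist)
  N <- dim(Xlist[[1L]])[2L]
  nb <- dim(Xlist[[1L]])[3L]
  F <- dim(params$ext[[1L]][[1L]]$c1$W)[1L]
  Z <- array(0, c(L * F, N, nb))
  ext_caches <- vector("list", L)
  for (l in seq_len(L)) {
    r <- section_fwd(params$ext[[l]], Xlist[[l]], getg)
    Z[((l - 1L) * F + 1L):(l * F), , ] <- r$out
    ext_caches[[l]] <- r$caches
  }
  ra <- section_fwd(params$agg, Z, getg)
  A <- ra$out
  g1 <- getg(N, 1L, nb)
  yhat <- array(0, c(6L, N, nb))
  head_caches <- vector("list", 6L)
  for (h in seq_len(6L)) {
    ph <- params$heads[[h]]
    nu <- length(ph) - 1L
    rh <- section_fwd(ph[seq_len(nu)], A, getg)
    ff <- conv_fwd(ph$final, rh$out, g1)
    yhat[h, , ] <- ff$out[1L, , ]
    head_caches[[h]] <- list(sec = rh$caches, final_Xcol = ff$Xcol)
  }
  if (!need_cache) return(list(yhat = yhat))
  list(yhat = yhat,
       cache = list(ext = ext_caches, agg = ra$caches, heads = head_caches,
                    L = L, F = F, N = N, nb = nb))
}

recon_bwd <- function(params, cache, dyhat, getg) {
  N <- cache$N; nb <- cache$nb; L <- cache$L; F <- cache$F
  g1 <- getg(N, 1L, nb)
  dA <- NULL
  head_grads <- vector("list", 6L)
  for (h in seq_len(6L)) {
    ph <- params$heads[[h]]
    nu <- length(ph) - 1L
    dy <- array(dyhat[h, , ], c(1L, N, nb))
    bf <- conv_bwd(ph$final, list(Xcol = cache$heads[[h]]$final_Xcol),
                   dy, g1, need_dx = TRUE)
    bs <- section_bwd(ph[seq_len(nu)], cache$heads[[h]]$sec, bf$dX, getg,
                      need_dx = TRUE)
    head_grads[[h]] <- c(bs$grads, list(final = bf$grads))
    dA <- if (is.null(dA)) bs$dX else dA + bs$dX
  }
  ba <- section_bwd(params$agg, cache$agg, dA, getg, need_dx = TRUE)
  ext_grads <- vector("list", L)
  for (l in seq_len(L)) {
    dZl <- ba$dX[((l - 1L) * F + 1L):(l * F), , , drop = FALSE]
    be <- section_bwd(params$ext[[l]], cache$ext[[l]], dZl, getg,
                      need_dx = FALSE)
    ext_grads[[l]] <- be$grads
  }
  list(ext = ext_grads, agg = ba$grads, heads = head_grads)
}

# 1 - R2 loss over a (6, N, nb) prediction in mV.  R2 is computed per
# (record, lead) over time about the per-lead target mean; leads with
# (numerically) zero target variance are excluded from the loss.
r2_loss_grad <- function(yhat, y, eps = 1e-12) {
  d <- dim(y); N <- d[2L]; nb <- d[3L]
  mu <- apply(y, c(1L, 3L), mean)
  centered <- y - aperm(array(mu, c(6L, nb, N)), c(1L, 3L, 2L))
  sst <- apply(centered^2, c(1L, 3L), sum)
  valid <- sst > eps
  n_valid <- sum(valid)
  if (n_valid == 0L) stop("all target leads have zero variance")
  if (n_valid < length(valid))
    warning("excluding ", length(valid) - n_valid,
            " zero-variance target lead(s) from the loss")
  resid <- yhat - y
  ssr <- apply(resid^2, c(1L, 3L), sum)
  w <- ifelse(valid, 1 / pmax(sst, eps), 0)
  loss <- sum(ssr * w) / n_valid
  warr <- aperm(array(w, c(6L, nb, N)), c(1L, 3L, 2L))
  list(loss = loss, dyhat = 2 * resid * warr / n_valid)
}

# Assemble model inputs (list of (1, N, nb) unit-scaled arrays) and
# targets ((6, N, nb) in mV) from a list of records.
recon_tensors <- function(records, arch, v_min = -2.5, v_max = 2.5) {
  N <- arch$samples_per_lead
  nb <- length(records)
  Xlist <- lapply(arch$input_leads, function(l) array(0, c(1L, N, nb)))
  names(Xlist) <- arch$input_leads
  Y <- array(0, c(6L, N, nb))
  for (i in seq_len(nb)) {
    r <- records[[i]]
    if (ncol(r$signals) != N)
      stop("record has ", ncol(r$signals), " samples; architecture expects ",
           N, " (resample/trim first)")
    for (l in arch$input_leads)
      Xlist[[l]][1L, , i] <-
        2 * (scale_to_unit(r$signals[l, ], v_min, v_max) - 0.5)
    Y[, , i] <- r$signals[precordial_leads(), ]
  }
  list(X = Xlist, Y = Y)
}

#' Fit the reduced-lead reconstruction network
#'
#' Trains the three-section residual CNN that maps a reduced set of
#' unit-scaled input leads to the six precordial leads in mV, minimizing
#' the mean over records and leads of `1 - R2`.  Training uses Adam with
#' minibatches, tracks train/validation loss per epoch, and restores the
#' best-validation parameters (early stopping).
#'
#' @param records Training records: an [ecg_dataset()] or list of
#'   [ecg_record()]s, all with `samples_per_lead` samples.
#' @param arch A [recon_arch()].
#' @param control A [train_control()] with `loss = "one_minus_r2"`.
#' @param val_records Validation records; if `NULL`, a random 20% of
#'   `records` is held out (seeded).
#' @return Object of class `ecg_recon` with the fitted parameters, the
#'   architecture, and a per-epoch loss `history` data frame.
#' @export
fit_reconstructor <- function(records, arch = recon_arch(scaled_down = TRUE),
                              control = train_control(),
                              val_records = NULL) {
  if (inherits(records, "ecg_dataset")) records <- records$records
  if (length(records) == 0L) stop("empty training set")
  if (control$loss != "one_minus_r2")
    stop("fit_reconstructor() requires loss = \"one_minus_r2\"")
  if (!is.null(val_records) && inherits(val_records, "ecg_dataset"))
    val_records <- val_records$records
  set.seed(control$seed)
  if (is.null(val_records)) {
    n_val <- max(1L, round(0.2 * length(records)))
    vi <- sample.int(length(records), n_val)
    val_records <- records[vi]
    records <- records[-vi]
    if (length(records) == 0L) stop("empty training set after validation split")
  }
  params <- recon_init_params(arch, seed = control$seed)
  theta <- flatten_params(params)
  state <- adam_init(length(theta))
  getg <- geom_cache()
  tr <- recon_tensors(records, arch)
  va <- recon_tensors(val_records, arch)
  n <- length(records)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(control$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
    tl <- 0
    for (b in batches) {
      Xb <- lapply(tr$X, function(a) a[, , b, drop = FALSE])
      Yb <- tr$Y[, , b, drop = FALSE]
      fw <- recon_fwd(params, Xb, getg)
      lg <- r2_loss_grad(fw$yhat, Yb)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch,
             "; reduce the learning rate")
      gr <- recon_bwd(params, fw$cache, lg$dyhat, getg)
      st <- adam_step(theta, flatten_params(gr), state,
                      control$learning_rate)
      theta <- st$theta; state <- st$state
      params <- unflatten_params(theta, params)
      tl <- tl + lg$loss * length(b)
    }
    fv <- recon_fwd(params, va$X, getg, need_cache = FALSE)
    vl <- r2_loss_grad(fv$yhat, va$Y)$loss
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tl / n, val_loss = vl))
    if (vl < best$loss) {
      best <- list(loss = vl, theta = theta, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= control$patience) break
    }
  }
  params <- unflatten_params(best$theta, params)
  structure(list(arch = arch, control = control, params = params,
                 history = history, best_epoch = best$epoch,
                 val_loss = best$loss, scaler = c(v_min = -2.5, v_max = 2.5)),
            class = "ecg_recon")
}

#' @export
print.ecg_recon <- function(x, ...) {
  cat(sprintf(
    "reduced-lead ECG reconstructor (input: %s)\n",
    paste(x$arch$input_leads, collapse = "+")))
  cat(sprintf("  %d samples/lead, %d feature / %d aggregate channels, %d unit(s)/section\n",
              x$arch$samples_per_lead, x$arch$feat_channels,
              x$arch$agg_channels, x$arch$blocks_per_section))
  cat(sprintf("  trained %d epoch(s); best validation 1-R2 = %.4f (epoch %d)\n",
              nrow(x$history), x$val_loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.ecg_recon <- function(object, ...) {
  print(object)
  cat(sprintf("  parameters: %d\n", length(flatten_params(object$params))))
  cat(sprintf("  held-out R2 at best epoch: %.2f%%\n",
              100 * (1 - object$val_loss)))
  invisible(object)
}

#' Plot the training history of a fitted model
#' @param x An `ecg_recon` or `mi_clf` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ecg_recon <- function(x, ...) {
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_loss, x$history$val_loss),
                    type = "l", lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"),
                   lty = 1, col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Reconstruct full 12-lead ECGs from a fitted model
#'
#' The four dependent limb leads are derived exactly from the input's
#' leads I and II (the exact-algebra module); the six precordial leads are
#' the network's mV predictions, except that any precordial lead supplied
#' as input is passed through unchanged (recorded in the output metadata).
#'
#' @param object A fitted `ecg_recon`.
#' @param newdata An [ecg_record()], a list of them, or an
#'   [ecg_dataset()].
#' @param ... Unused.
#' @return Reconstructed record(s), same shape as `newdata`.
#' @export
predict.ecg_recon <- function(object, newdata, ...) {
  single <- inherits(newdata, "ecg_record")
  was_dataset <- inherits(newdata, "ecg_dataset")
  records <- if (single) list(newdata)
             else if (was_dataset) newdata$records else newdata
  arch <- object$arch
  te <- recon_tensors(records, arch)
  getg <- geom_cache()
  fw <- recon_fwd(object$params, te$X, getg, need_cache = FALSE)
  pre_in <- intersect(arch$input_leads, precordial_leads())
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    limb <- derive_limb_leads(r$signals["I", ], r$signals["II", ])
    pre <- fw$yhat[, , i]
    rownames(pre) <- precordial_leads()
    for (l in pre_in) pre[l, ] <- r$signals[l, ]
    meta <- r$meta
    meta$reconstructed_from <- paste(arch$input_leads, collapse = "+")
    meta$passthrough_leads <- pre_in
    out[[i]] <- ecg_record(rbind(limb, pre), r$fs, r$individual_id,
                           r$mi_label, meta)
  }
  names(out) <- names(records)
  if (single) out[[1L]] else if (was_dataset) ecg_dataset(out) else out
}

#' Reconstruct a 12-lead ECG (alias for the predict method)
#' @inheritParams predict.ecg_recon
#' @param record Input record(s).
#' @export
reconstruct <- function(object, record) predict(object, record)

#' Evaluate reconstruction fidelity on a set of records
#'
#' Computes per-record MSE (mV^2) and R2 (%) over the six precordial
#' leads between original records and their reconstructions, with 95%
#' normal-approximation confidence halfwidths.
#'
#' @param object A fitted `ecg_recon`.
#' @param records Original records ([ecg_dataset()] or list).
#' @param level Confidence level (default 0.95).
#' @return A list of class `recon_eval`: per-record values plus
#'   `r2_mean`, `r2_halfwidth`, `mse_mean`, `mse_halfwidth`, `n`.
#' @export
evaluate_reconstruction <- function(object, records, level = 0.95) {
  if (inherits(records, "ecg_dataset")) records <- records$records
  recon <- predict(object, records)
  pre <- precordial_leads()
  r2v <- numeric(length(records))
  msev <- numeric(length(records))
  for (i in seq_along(records)) {
    y <- records[[i]]$signals[pre, ]
    yh <- recon[[i]]$signals[pre, ]
    r2v[i] <- ecg_r2(y, yh)
    msev[i] <- ecg_mse(y, yh)
  }
  r2ci <- aggregate_with_ci(r2v, level)
  mseci <- aggregate_with_ci(msev, level)
  structure(list(r2 = r2v, mse = msev,
                 r2_mean = r2ci$mean, r2_halfwidth = r2ci$halfwidth,
                 mse_mean = mseci$mean, mse_halfwidth = mseci$halfwidth,
                 n = length(records), level = level),
            class = "recon_eval")
}

#' @export
print.recon_eval <- function(x, ...) {
  cat(sprintf("reconstruction fidelity over %d records:\n", x$n))
  cat(sprintf("  R2  = %.2f +/- %.2f %%\n", x$r2_mean, x$r2_halfwidth))
  cat(sprintf("  MSE = %.5f +/- %.5f mV^2\n", x$mse_mean, x$mse_halfwidth))
  invisible(x)
}
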