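#' Architecture of the acute-MI detection classifier
#'
#' The classifier receives the eight informative leads (I, II, V1-V6; the
#' four remaining limb leads are algebraically redundant) as unit-scaled
#' signals.  Per-lead residual-CNN extractors emit `feat_channels`
#' channels at full time resolution; the concatenated features pass
#' through residual units interleaved with average pooling that halves
#' the time length, then a global average pool collapses time into a
#' single `embedding_dim`-value vector; a small feed-forward section and
#' a sigmoid return the probability of acute MI.  Full-size defaults are
#' 2500 samples, 32 feature channels and a 128-value embedding.
#'
#' @param samples_per_lead Samples per lead.
#' @param feat_channels Channels per per-lead extractor.
#' @param embedding_dim Length of the pooled embedding vector.
#' @param fnn_widths Hidden widths of the feed-forward section.
#' @param blocks_per_section Residual units per extractor section.
#' @param reduce_steps Number of pool-by-2 reduction stages.
#' @param kernel_size Odd convolution kernel length.
#' @param scaled_down If `TRUE`, shrink to a desktop-scale configuration.
#' @return Object of class `clf_arch`.  The input lead set is fixed to
#'   the eight leads I, II, V1-V6.
#' @export
clf_arch <- function(samples_per_lead = 2500L,
                     feat_channels = 32L,
                     embedding_dim = 128L,
                     fnn_widths = 64L,
                     blocks_per_section = 2L,
                     reduce_steps = 3L,
                     kernel_size = 15L,
                     scaled_down = FALSE) {
  if (scaled_down) {
    if (missing(samples_per_lead)) samples_per_lead <- 500L
    if (missing(feat_channels)) feat_channels <- 4L
    if (missing(embedding_dim)) embedding_dim <- 16L
    if (missing(fnn_widths)) fnn_widths <- 8L
    if (missing(blocks_per_section)) blocks_per_section <- 1L
    if (missing(reduce_steps)) reduce_steps <- 2L
    if (missing(kernel_size)) kernel_size <- 9L
  }
  if (kernel_size %% 2L != 1L) stop("`kernel_size` must be odd")
  structure(list(input_leads = c("I", "II", precordial_leads()),
                 samples_per_lead = as.integer(samples_per_lead),
                 feat_channels = as.integer(feat_channels),
                 embedding_dim = as.integer(embedding_dim),
                 fnn_widths = as.integer(fnn_widths),
                 blocks_per_section = as.integer(blocks_per_section),
                 reduce_steps = as.integer(reduce_steps),
                 kernel_size = as.integer(kernel_size),
                 scaled_down = scaled_down),
            class = "clf_arch")
}

clf_init_params <- function(arch, seed) {
  set.seed(seed)
  k <- arch$kernel_size
  B <- arch$blocks_per_section
  E <- arch$embedding_dim
  red <- vector("list", max(1L, arch$reduce_steps))
  cin <- 8L * arch$feat_channels
  for (i in seq_along(red)) {
    red[[i]] <- section_init(cin, E, k, 1L)
    cin <- E
  }
  widths <- c(E, arch$fnn_widths, 1L)
  fnn <- vector("list", length(widths) - 1L)
  for (i in seq_along(fnn))
    fnn[[i]] <- dense_init(widths[i], widths[i + 1L])
  list(ext = replicate(8L, section_init(1L, arch$feat_channels, k, B),
                       simplify = FALSE),
       red = red, fnn = fnn)
}

clf_fwd <- function(params, Xlist, arch, getg, need_cache = TRUE) {
  N <- dim(Xlist[[1L]])[2L]
  nb <- dim(Xlist[[1L]])[3L]
  F <- arch$feat_channels
  Z <- array(0, c(8L * F, N, nb))
  ext_caches <- vector("list", 8L)
  for (l in 1:8) {
    r <- section_fwd(params$ext[[l]], Xlist[[l]], getg)
    Z[((l - 1L) * F + 1L):(l * F), , ] <- r$out
    ext_caches[[l]] <- r$caches
  }
  red_caches <- vector("list", length(params$red))
  lens <- integer(length(params$red))
  A <- Z
  for (i in seq_along(params$red)) {
    r <- section_fwd(params$red[[i]], A, getg)
    lens[i] <- dim(r$out)[2L]
    A <- if (arch$reduce_steps > 0L) pool2_fwd(r$out) else r$out
    red_caches[[i]] <- r$caches
  }
  # global average pool over time -> embedding x batch
  emb <- apply(A, c(1L, 3L), mean)
  if (nb == 1L) emb <- matrix(emb, ncol = 1L)
  H <- emb
  fnn_caches <- vector("list", length(params$fnn))
  for (i in seq_along(params$fnn)) {
    f <- dense_fwd(params$fnn[[i]], H)
    fnn_caches[[i]] <- list(X = f$X, a = f$out)
    H <- if (i < length(params$fnn)) lrelu(f$out) else f$out
  }
  z <- as.vector(H)
  if (!need_cache) return(list(logits = z))
  list(logits = z,
       cache = list(ext = ext_caches, red = red_caches, lens = lens,
                    fnn = fnn_caches, emb_dim = dim(A), N = N, nb = nb,
                    F = F))
}

clf_bwd <- function(params, cache, dz, arch, getg) {
  nb <- cache$nb
  dH <- matrix(dz, 1L, nb)
  fnn_grads <- vector("list", length(params$fnn))
  for (i in rev(seq_along(params$fnn))) {
    if (i < length(params$fnn))
      dH <- dH * lrelu_grad(cache$fnn[[i]]$a)
    b <- dense_bwd(params$fnn[[i]], list(X = cache$fnn[[i]]$X), dH)
    fnn_grads[[i]] <- b$grads
    dH <- b$dX
  }
  # undo global average pool
  ed <- cache$emb_dim
  dA <- array(rep(dH / ed[2L], each = 1L), c(ed[1L], nb, ed[2L]))
  dA <- aperm(dA, c(1L, 3L, 2L))
  red_grads <- vector("list", length(params$red))
  for (i in rev(seq_along(params$red))) {
    if (arch$reduce_steps > 0L) dA <- pool2_bwd(dA, cache$lens[i])
    b <- section_bwd(params$red[[i]], cache$red[[i]], dA, getg,
                     need_dx = TRUE)
    red_grads[[i]] <- b$grads
    dA <- b$dX
  }
  F <- cache$F
  ext_grads <- vector("list", 8L)
  for (l in 1:8) {
    dZl <- dA[((l - 1L) * F + 1L):(l * F), , , drop = FALSE]
    b <- section_bwd(params$ext[[l]], cache$ext[[l]], dZl, getg,
                     need_dx = FALSE)
    ext_grads[[l]] <- b$grads
  }
  list(ext = ext_grads, red = red_grads, fnn = fnn_grads)
}

# numerically stable binary cross-entropy on logits
bce_loss_grad <- function(z, y) {
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  p <- 1 / (1 + exp(-z))
  list(loss = loss, dz = (p - y) / length(z), p = p)
}

clf_tensors <- function(records, arch, v_min = -2.5, v_max = 2.5) {
  N <- arch$samples_per_lead
  nb <- length(records)
  Xlist <- lapply(arch$input_leads, function(l) array(0, c(1L, N, nb)))
  names(Xlist) <- arch$input_leads
  for (i in seq_len(nb)) {
    r <- records[[i]]
    if (ncol(r$signals) != N)
      stop("record has ", ncol(r$signals), " samples; architecture expects ", N)
    for (l in arch$input_leads)
      Xlist[[l]][1L, , i] <-
        2 * (scale_to_unit(r$signals[l, ], v_min, v_max) - 0.5)
  }
  Xlist
}

#' Fit the acute-MI detection classifier
#'
#' Trains the eight-lead residual-CNN classifier by minimizing binary
#' cross-entropy between the MI labels and the predicted probabilities.
#' The best-validation parameters are kept (early stopping).
#'
#' @param records Labeled records ([ecg_dataset()] or list); every record
#'   must carry a non-missing `mi_label`.
#' @param arch A [clf_arch()].
#' @param control A [train_control()] with `loss = "cross_entropy"`.
#' @param val_records Validation records; if `NULL`, a random 20% of
#'   `records` is held out (seeded).
#' @param labels Optional logical vector overriding the records' labels
#'   (e.g. for permutation controls).
#' @return Object of class `mi_clf`.
#' @export
fit_mi_classifier <- function(records,
                              arch = clf_arch(scaled_down = TRUE),
                              control = train_control(loss = "cross_entropy"),
                              val_records = NULL, labels = NULL) {
  if (inherits(records, "ecg_dataset")) records <- records$records
  if (length(records) == 0L) stop("empty training set")
  if (control$loss != "cross_entropy")
    stop("fit_mi_classifier() requires loss = \"cross_entropy\"")
  y <- if (is.null(labels))
    vapply(records, function(r) as.logical(r$mi_label)[1L], NA)
  else as.logical(labels)
  if (anyNA(y)) stop("all training records need a binary MI label")
  if (length(unique(y)) < 2L)
    stop("training set contains a single class; need both MI and non-MI")
  if (!is.null(val_records) && inherits(val_records, "ecg_dataset"))
    val_records <- val_records$records
  set.seed(control$seed)
  if (is.null(val_records)) {
    n_val <- max(2L, round(0.2 * length(records)))
    vi <- sample.int(length(records), n_val)
    val_records <- records[vi]
    yv <- y[vi]
    records <- records[-vi]; y <- y[-vi]
  } else {
    yv <- vapply(val_records, function(r) isTRUE(r$mi_label), NA)
  }
  params <- clf_init_params(arch, seed = control$seed)
  theta <- flatten_params(params)
  state <- adam_init(length(theta))
  getg <- geom_cache()
  Xtr <- clf_tensors(records, arch)
  Xva <- clf_tensors(val_records, arch)
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
      Xb <- lapply(Xtr, function(a) a[, , b, drop = FALSE])
      fw <- clf_fwd(params, Xb, arch, getg)
      lg <- bce_loss_grad(fw$logits, y[b])
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", epoch)
      gr <- clf_bwd(params, fw$cache, lg$dz, arch, getg)
      st <- adam_step(theta, flatten_params(gr), state,
                      control$learning_rate)
      theta <- st$theta; state <- st$state
      params <- unflatten_params(theta, params)
      tl <- tl + lg$loss * length(b)
    }
    fv <- clf_fwd(params, Xva, arch, getg, need_cache = FALSE)
    vl <- bce_loss_grad(fv$logits, yv)$loss
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
                 val_loss = best$loss),
            class = "mi_clf")
}

#' @export
print.mi_clf <- function(x, ...) {
  cat("acute-MI detection classifier (8 leads: I, II, V1-V6)\n")
  cat(sprintf("  %d samples/lead, %d feature channels, %d-value embedding\n",
              x$arch$samples_per_lead, x$arch$feat_channels,
              x$arch$embedding_dim))
  cat(sprintf("  trained %d epoch(s); best validation CE = %.4f (epoch %d)\n",
              nrow(x$history), x$val_loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.mi_clf <- function(object, ...) {
  print(object)
  cat(sprintf("  parameters: %d\n", length(flatten_params(object$params))))
  invisible(object)
}

#' @rdname plot.ecg_recon
#' @export
plot.mi_clf <- function(x, ...) plot.ecg_recon(x, ...)

#' Predict acute-MI probability
#'
#' Deterministic given the fitted model and input: the same record always
#' yields the same probability, strictly inside (0, 1).  Works on
#' original or reconstructed records (any record carrying the eight
#' required leads).
#'
#' @param object A fitted `mi_clf`.
#' @param newdata An [ecg_record()], list of records, or [ecg_dataset()].
#' @param type `"response"` for probabilities (default) or `"link"` for
#'   logits.
#' @param ... Unused.
#' @return Numeric vector of probabilities (named by record id when
#'   available).
#' @export
predict.mi_clf <- function(object, newdata, type = c("response", "link"),
                           ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ecg_record")) newdata <- list(newdata)
  if (inherits(newdata, "ecg_dataset")) newdata <- newdata$records
  X <- clf_tensors(newdata, object$arch)
  fw <- clf_fwd(object$params, X, object$arch, geom_cache(),
                need_cache = FALSE)
  out <- if (type == "response") 1 / (1 + exp(-fw$logits)) else fw$logits
  names(out) <- names(newdata)
  out
}
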