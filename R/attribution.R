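#' Exact Shapley attribution over input leads
#'
#' Quantifies each input lead's contribution to a model score (e.g. mean
#' precordial R2 of the reconstruction, or MI probability) by exact
#' Shapley-value enumeration over all `2^n` lead coalitions - feasible
#' because the player set is at most twelve leads.  Leads outside a
#' coalition are masked by the caller's baseline inside `value_fn`; the
#' package helpers ([shap_value_r2()], [shap_value_proba()]) mask to the
#' per-lead mean waveform by default, with a constant-voltage baseline
#' selectable.
#'
#' The returned attributions satisfy the efficiency axiom
#' (`sum(phi) = v(all) - v(empty)`) to numerical precision, and inherit
#' the symmetry and dummy axioms from exact enumeration.
#'
#' @param value_fn Function taking a character vector of present leads (a
#'   coalition, possibly empty) and returning a single numeric score.
#'   Must be deterministic; this is verified by evaluating the full
#'   coalition twice.
#' @param leads Character vector of player leads (length <= 12).
#' @param check_deterministic Verify determinism of `value_fn` (default
#'   `TRUE`).
#' @return Object of class `shap_attribution`: per-lead `phi` (units of
#'   the value function), `v_empty`, `v_full`, `efficiency_residual`.
#' @export
#' @examples
#' bonus <- c(I = 1, II = 2, V3 = 4)
#' v <- function(coal) sum(bonus[coal])
#' lead_shap(v, c("I", "II", "V3"))$phi
lead_shap <- function(value_fn, leads, check_deterministic = TRUE) {
  n <- length(leads)
  if (n < 1L) stop("`leads` must contain at least one lead")
  if (n > 12L)
    stop("exact enumeration supports at most 12 leads (2^12 coalitions)")
  if (anyDuplicated(leads)) stop("duplicate lead names")
  if (check_deterministic) {
    v1 <- value_fn(leads)
    v2 <- value_fn(leads)
    if (!isTRUE(all.equal(v1, v2, tolerance = 0)))
      stop("`value_fn` is not deterministic: two evaluations of the full ",
           "coalition differ")
  }
  masks <- seq_len(2^n) - 1L
  vals <- vapply(masks, function(m) {
    coal <- leads[bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
    as.numeric(value_fn(coal))
  }, numeric(1))
  # factorial weights |S|! (n-|S|-1)! / n!
  sizes <- vapply(masks, function(m) sum(bitwAnd(
    m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L), numeric(1))
  # weight of the full coalition is never used (no marginal from it)
  wt <- ifelse(sizes < n,
               factorial(sizes) * factorial(pmax(n - sizes - 1, 0)) /
                 factorial(n),
               0)
  phi <- stats::setNames(numeric(n), leads)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- masks[bitwAnd(masks, bit) == 0L]
    gain <- vals[match(bitwOr(without, bit), masks)] -
      vals[match(without, masks)]
    phi[i] <- sum(wt[match(without, masks)] * gain)
  }
  v_empty <- vals[1L]
  v_full <- vals[length(vals)]
  structure(list(phi = phi, v_empty = v_empty, v_full = v_full,
                 efficiency_residual = sum(phi) - (v_full - v_empty)),
            class = "shap_attribution")
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat("Shapley lead attribution:\n")
  for (l in names(x$phi))
    cat(sprintf("  %-4s %+ .4f\n", l, x$phi[l]))
  cat(sprintf("  v(empty) = %.4f, v(all) = %.4f, efficiency residual %.2e\n",
              x$v_empty, x$v_full, x$efficiency_residual))
  invisible(x)
}

# Per-lead baseline signals used to mask absent leads: either the
# lead-wise mean waveform across the evaluation records (keeps masked
# inputs ECG-shaped, so coalition scores degrade gracefully) or a
# constant voltage.
masking_baseline <- function(records, leads, baseline) {
  n <- ncol(records[[1L]]$signals)
  if (is.numeric(baseline)) {
    out <- matrix(baseline, length(leads), n,
                  dimnames = list(leads, NULL))
    return(out)
  }
  out <- matrix(0, length(leads), n, dimnames = list(leads, NULL))
  for (l in leads) {
    out[l, ] <- rowMeans(vapply(records, function(r) r$signals[l, ],
                                numeric(n)))
  }
  out
}

mask_records <- function(records, input_leads, coalition, base) {
  lapply(records, function(r) {
    s <- r$signals
    for (l in setdiff(input_leads, coalition)) s[l, ] <- base[l, ]
    ecg_record(s, r$fs, r$individual_id, r$mi_label, r$meta)
  })
}

#' Value function: mean precordial R2 of a reconstruction model
#'
#' Builds a coalition value function for [lead_shap()]: leads absent from
#' the coalition are replaced by a masking baseline before running the
#' reconstruction, and the score is the mean R2 (%) over the six
#' precordial leads and all supplied records.
#'
#' The default baseline is the per-lead mean waveform across `records`,
#' which keeps masked inputs inside the space of plausible ECGs; a
#' constant-voltage baseline (e.g. `0` for a flat 0 mV line) is
#' available but pushes the network far off its training distribution
#' when most leads are masked, making coalition scores erratic.
#'
#' @param model A fitted `ecg_recon`.
#' @param records Records to evaluate on ([ecg_dataset()] or list).
#' @param baseline `"mean"` (default) for the per-lead mean waveform, or
#'   a single voltage in mV (e.g. `0`).
#' @return A function `coalition -> mean R2 (%)`.
#' @export
shap_value_r2 <- function(model, records, baseline = "mean") {
  if (inherits(records, "ecg_dataset")) records <- records$records
  pre <- precordial_leads()
  base <- masking_baseline(records, model$arch$input_leads, baseline)
  function(coalition) {
    masked <- mask_records(records, model$arch$input_leads, coalition,
                           base)
    rec <- predict(model, masked)
    mean(vapply(seq_along(records), function(i)
      ecg_r2(records[[i]]$signals[pre, ], rec[[i]]$signals[pre, ]),
      numeric(1)))
  }
}

#' Value function: MI probability of a classifier
#'
#' Coalition value function for [lead_shap()] on the classifier: absent
#' leads are masked to the baseline voltage and the value is the mean
#' predicted MI probability over the records.
#'
#' @param clf A fitted `mi_clf`.
#' @inheritParams shap_value_r2
#' @return A function `coalition -> mean probability`.
#' @export
shap_value_proba <- function(clf, records, baseline = "mean") {
  if (inherits(records, "ecg_dataset")) records <- records$records
  base <- masking_baseline(records, clf$arch$input_leads, baseline)
  function(coalition) {
    masked <- mask_records(records, clf$arch$input_leads, coalition, base)
    mean(predict(clf, masked))
  }
}
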