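#' Grouped, label-stratified train/validation/test split
#'
#' Assigns every record to one of three mutually exclusive subsets such
#' that (a) all records of one individual share a subset (no
#' individual-level leakage), (b) the MI label proportion in each subset
#' stays within a tolerance of the global proportion, and (c) subset
#' sizes approximate the requested fractions.  Individuals are visited in
#' seeded random order and each is assigned greedily to the subset that
#' best balances fill level and label proportion.
#'
#' @param manifest Data frame with columns `record_id`, `individual_id`,
#'   `mi_label`, or an [ecg_dataset()] (its manifest is used).
#' @param fractions Named numeric vector summing to 1 (default
#'   `c(train = 0.70, validation = 0.15, test = 0.15)`).
#' @param seed Integer seed; the assignment is deterministic under it.
#' @param label_tol Warning threshold for per-subset label deviation
#'   (default 0.02).
#' @return A `split_assignment`: the manifest with an added `subset`
#'   column, carrying the fractions as an attribute.
#' @export
grouped_stratified_split <- function(manifest,
                                     fractions = c(train = 0.70,
                                                   validation = 0.15,
                                                   test = 0.15),
                                     seed = 1L, label_tol = 0.02) {
  if (inherits(manifest, "ecg_dataset")) manifest <- manifest$manifest
  stopifnot(all(c("record_id", "individual_id", "mi_label") %in%
                  names(manifest)))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must sum to 1")
  if (is.null(names(fractions)))
    names(fractions) <- c("train", "validation", "test")
  set.seed(seed)
  inds <- split(seq_len(nrow(manifest)), manifest$individual_id)
  ord <- sample(length(inds))
  p_global <- mean(manifest$mi_label)
  N <- nrow(manifest)
  ns <- stats::setNames(numeric(3), names(fractions))
  nmi <- ns
  assign_ind <- character(length(inds))
  names(assign_ind) <- names(inds)
  for (ii in ord) {
    rows <- inds[[ii]]
    r_n <- length(rows)
    r_mi <- sum(manifest$mi_label[rows])
    score <- vapply(names(fractions), function(s) {
      fill <- (ns[s] + r_n) / (N * fractions[s])
      lab <- abs((nmi[s] + r_mi) / (ns[s] + r_n) - p_global)
      fill + 2 * lab
    }, numeric(1))
    s <- names(fractions)[which.min(score)]
    ns[s] <- ns[s] + r_n
    nmi[s] <- nmi[s] + r_mi
    assign_ind[names(inds)[ii]] <- s
  }
  out <- manifest
  out$subset <- assign_ind[manifest$individual_id]
  dev <- abs(nmi / pmax(ns, 1) - p_global)
  if (any(dev > label_tol))
    warning("label proportion deviates by more than ", label_tol,
            " in subset(s): ",
            paste(names(fractions)[dev > label_tol], collapse = ", "))
  attr(out, "fractions") <- fractions
  class(out) <- c("split_assignment", class(out))
  out
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("grouped stratified split:\n")
  for (s in names(attr(x, "fractions"))) {
    rows <- x$subset == s
    cat(sprintf("  %-10s %5d records (%.1f%%), MI share %.1f%%\n",
                s, sum(rows), 100 * mean(rows),
                if (any(rows)) 100 * mean(x$mi_label[rows]) else 0))
  }
  invisible(x)
}

#' Mean squared reconstruction error
#'
#' Mean over samples (and leads) of the squared voltage difference, in
#' mV^2; 0 for a perfect reconstruction.
#'
#' @param y,yhat Numeric vectors or matrices of matching shape (mV).
#' @return MSE in mV^2.
#' @export
#' @examples
#' ecg_mse(c(0, 1, 2, 3), c(0, 1, 2, 2))
ecg_mse <- function(y, yhat) {
  if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat))
    stop("`y` and `yhat` must have matching shapes")
  mean((y - yhat)^2)
}

#' Coefficient of determination of a reconstruction
#'
#' `R2 = 100 * (1 - SS_res / SS_tot)` with `SS_tot` about the per-lead
#' mean of the target: the percentage of target-signal variance captured
#' by the reconstruction (100% when perfect, 0% for the mean predictor).
#' For matrix inputs (leads x samples) the per-lead values are averaged;
#' zero-variance target leads are undefined and are excluded with a
#' warning.
#'
#' @inheritParams ecg_mse
#' @return R2 as a percentage.
#' @export
#' @examples
#' ecg_r2(c(0, 1, 2, 3), c(0, 1, 2, 2))
ecg_r2 <- function(y, yhat) {
  if (!identical(dim(y), dim(yhat)) || length(y) != length(yhat))
    stop("`y` and `yhat` must have matching shapes")
  if (is.null(dim(y))) {
    y <- matrix(y, nrow = 1)
    yhat <- matrix(yhat, nrow = 1)
  }
  vals <- numeric(0)
  skipped <- 0L
  for (l in seq_len(nrow(y))) {
    sst <- sum((y[l, ] - mean(y[l, ]))^2)
    if (sst <= 1e-300) {
      skipped <- skipped + 1L
      next
    }
    ssr <- sum((y[l, ] - yhat[l, ])^2)
    vals <- c(vals, 100 * (1 - ssr / sst))
  }
  if (skipped > 0L)
    warning("excluded ", skipped, " zero-variance target lead(s); R2 undefined")
  if (length(vals) == 0L) stop("no lead with nonzero target variance")
  mean(vals)
}

#' Mean with a normal-approximation confidence halfwidth
#'
#' `mean +/- z * sd / sqrt(n)` at the requested confidence level (default
#' 95%, z = 1.96).
#'
#' @param x Numeric vector of per-record values (n >= 2).
#' @param level Confidence level in (0, 1).
#' @return List with `mean`, `halfwidth`, `n`, `level`.
#' @export
aggregate_with_ci <- function(x, level = 0.95) {
  if (length(x) < 2L) stop("need at least two values for a confidence interval")
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(mean = mean(x), halfwidth = z * stats::sd(x) / sqrt(length(x)),
       n = length(x), level = level)
}

#' ROC curve and AUC
#'
#' Builds the ROC curve by sweeping the decision threshold over the
#' sorted unique scores and integrates it by the trapezoidal rule, which
#' equals the Mann-Whitney pair statistic with ties counted 1/2.
#'
#' @param labels Binary ground truth (logical or 0/1); both classes must
#'   be present.
#' @param scores Numeric scores (higher = more likely positive).
#' @return Object of class `roc_result` with `fpr`, `tpr`, `thresholds`,
#'   and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  if (anyNA(labels) || anyNA(scores)) stop("NA in labels or scores")
  if (length(labels) != length(scores)) stop("length mismatch")
  P <- sum(labels); Ng <- sum(!labels)
  if (P == 0L || Ng == 0L)
    stop("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied scores into single threshold steps
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / Ng)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[last]), auc = auc,
                 n_pos = P, n_neg = Ng),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "1 - specificity",
                 ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Clinical reader metrics
#'
#' Sensitivity (TP/P), specificity (TN/N) and accuracy (correct/total)
#' of categorical reader calls against binary truth, with 95%
#' normal-approximation halfwidths (Wilson intervals optional).
#' Indeterminate ("unable to determine") calls are counted as incorrect -
#' never as true positives or true negatives.
#'
#' @param truth Logical vector (TRUE = condition present).
#' @param calls Character vector in `{"positive", "negative",
#'   "indeterminate"}`, same length as `truth`.
#' @param level Confidence level.
#' @param method `"normal"` (default) or `"wilson"` interval.
#' @return Object of class `clinical_metrics`.
#' @export
clinical_metrics <- function(truth, calls, level = 0.95,
                             method = c("normal", "wilson")) {
  method <- match.arg(method)
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(calls)) stop("length mismatch")
  calls <- match.arg(calls, c("positive", "negative", "indeterminate"),
                     several.ok = TRUE)
  truth <- as.logical(truth)
  TP <- sum(truth & calls == "positive")
  TN <- sum(!truth & calls == "negative")
  P <- sum(truth); Ng <- sum(!truth)
  n <- length(truth)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- function(p, m) {
    if (m == 0L) return(c(NA_real_, NA_real_))
    if (method == "normal") {
      c(p, z * sqrt(p * (1 - p) / m))
    } else {
      center <- (p + z^2 / (2 * m)) / (1 + z^2 / m)
      hw <- z * sqrt(p * (1 - p) / m + z^2 / (4 * m^2)) / (1 + z^2 / m)
      c(center, hw)
    }
  }
  sens <- ci(if (P > 0) TP / P else NA_real_, P)
  spec <- ci(if (Ng > 0) TN / Ng else NA_real_, Ng)
  acc <- ci((TP + TN) / n, n)
  structure(list(sensitivity = sens[1], sensitivity_halfwidth = sens[2],
                 specificity = spec[1], specificity_halfwidth = spec[2],
                 accuracy = acc[1], accuracy_halfwidth = acc[2],
                 n_total = n, n_positive = P, method = method,
                 level = level),
            class = "clinical_metrics")
}

#' @export
print.clinical_metrics <- function(x, ...) {
  cat(sprintf("clinical metrics (n = %d, %d positive):\n",
              x$n_total, x$n_positive))
  cat(sprintf("  sensitivity %.1f +/- %.1f %%\n",
              100 * x$sensitivity, 100 * x$sensitivity_halfwidth))
  cat(sprintf("  specificity %.1f +/- %.1f %%\n",
              100 * x$specificity, 100 * x$specificity_halfwidth))
  cat(sprintf("  accuracy    %.1f +/- %.1f %%\n",
              100 * x$accuracy, 100 * x$accuracy_halfwidth))
  invisible(x)
}

#' One-sided non-inferiority z-test for two proportions
#'
#' Tests whether a new method's accuracy is not worse than a reference by
#' more than a prespecified margin.  The null hypothesis is that the new
#' proportion is more than `margin` below the reference; it is rejected
#' (non-inferiority demonstrated) when the one-sided p-value falls below
#' `alpha`.  The statistic uses unpooled variance estimates:
#' `z = (p_new - p_ref + margin) / sqrt(p_ref (1 - p_ref) / n_ref +
#' p_new (1 - p_new) / n_new)`.
#'
#' @param p_ref,p_new Observed proportions in `[0, 1]`.
#' @param n_ref,n_new Sample sizes (>= 1).
#' @param margin Non-inferiority margin (proportion, default 0.10).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `noninf_test` with `z`, `one_sided_p`,
#'   `margin`, `alpha` and `decision`.
#' @export
#' @examples
#' noninferiority_z(0.846, 238, 0.814, 238)
noninferiority_z <- function(p_ref, n_ref, p_new, n_new, margin = 0.10,
                             alpha = 0.05) {
  if (p_ref < 0 || p_ref > 1 || p_new < 0 || p_new > 1)
    stop("proportions must be in [0, 1]")
  if (n_ref < 1L || n_new < 1L) stop("sample sizes must be >= 1")
  if (margin < 0) stop("`margin` must be >= 0")
  v <- p_ref * (1 - p_ref) / n_ref + p_new * (1 - p_new) / n_new
  if (v <= 0)
    stop("degenerate proportions give zero variance; cannot form the statistic")
  z <- (p_new - p_ref + margin) / sqrt(v)
  p <- 1 - stats::pnorm(z)
  structure(list(z = z, one_sided_p = p, margin = margin, alpha = alpha,
                 p_ref = p_ref, n_ref = n_ref, p_new = p_new, n_new = n_new,
                 decision = if (p < alpha) "non-inferior"
                            else "not demonstrated"),
            class = "noninf_test")
}

#' @export
print.noninf_test <- function(x, ...) {
  cat(sprintf("non-inferiority z-test (margin %.0f%%, alpha %.2f):\n",
              100 * x$margin, x$alpha))
  cat(sprintf("  reference %.3f (n = %d) vs new %.3f (n = %d)\n",
              x$p_ref, x$n_ref, x$p_new, x$n_new))
  cat(sprintf("  z = %.3f, one-sided p = %.4f -> %s\n",
              x$z, x$one_sided_p, x$decision))
  invisible(x)
}

#' Score the three ECG versions with one classifier
#'
#' Runs the same fitted classifier on the original records and on each
#' reconstructed version, returning one AUC row per version.
#'
#' @param clf A fitted [fit_mi_classifier()] model.
#' @param records Labeled original records ([ecg_dataset()] or list).
#' @param recon_models Named list of fitted `ecg_recon` models, e.g.
#'   `list("I+II" = m2, "I+II+V3" = m3)`; the original version is always
#'   scored first.
#' @return Data frame with columns `version`, `n`, `auc`.
#' @export
score_versions <- function(clf, records, recon_models = list()) {
  if (inherits(records, "ecg_dataset")) records <- records$records
  y <- vapply(records, function(r) isTRUE(r$mi_label), NA)
  rows <- list()
  score_one <- function(version, recs) {
    p <- predict(clf, recs)
    data.frame(version = version, n = length(recs),
               auc = roc_auc(y, p)$auc, stringsAsFactors = FALSE)
  }
  rows[["Original"]] <- score_one("Original", records)
  for (v in names(recon_models)) {
    rec <- predict(recon_models[[v]], records)
    rows[[v]] <- score_one(v, rec)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
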