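#' Canonical 12-lead order
#'
#' The fixed lead order used everywhere in this package: the six limb leads
#' (I, II, III, aVR, aVL, aVF) followed by the six precordial leads (V1-V6).
#'
#' @return Character vector of the twelve lead names.
#' @export
#' @examples
#' canonical_leads()
canonical_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Precordial (chest) lead names
#' @return Character vector V1..V6.
#' @export
precordial_leads <- function() paste0("V", 1:6)

# limb leads derivable from I and II
limb_leads <- function() c("I", "II", "III", "aVR", "aVL", "aVF")

#' Construct a 12-lead ECG record
#'
#' The universal unit of exchange: a `12 x N` voltage matrix in millivolts,
#' rows in canonical lead order, with a sampling rate and optional
#' individual identifier and acute-MI label.
#'
#' @param signals Numeric `12 x N` matrix of voltages in mV.  Rows may be
#'   named with lead names (any order, case-insensitive); unnamed rows are
#'   assumed to already be in canonical order.
#' @param fs Sampling frequency in Hz.
#' @param individual_id Opaque identifier of the person the record belongs
#'   to; used by the grouped train/validation/test split.
#' @param mi_label Logical acute-MI label, or `NA` when unlabeled.
#' @param meta Free-form list of tags (pathology kind, provenance, ...).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signals, fs, individual_id = NA_character_,
                       mi_label = NA, meta = list()) {
  if (!is.matrix(signals) || nrow(signals) != 12L)
    stop("`signals` must be a 12 x N matrix (one row per lead)")
  if (!all(is.finite(signals)))
    stop("`signals` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  signals <- normalize_lead_rows(signals)
  structure(
    list(signals = signals, fs = fs,
         individual_id = as.character(individual_id),
         mi_label = as.logical(mi_label), meta = meta),
    class = "ecg_record")
}

# Reorder/validate rows into canonical lead order using rownames if present.
normalize_lead_rows <- function(signals) {
  leads <- canonical_leads()
  rn <- rownames(signals)
  if (is.null(rn)) {
    rownames(signals) <- leads
    return(signals)
  }
  idx <- match(toupper(leads), toupper(trimws(rn)))
  if (anyNA(idx)) {
    missing <- leads[is.na(idx)]
    stop("missing required leads: ", paste(missing, collapse = ", "))
  }
  out <- signals[idx, , drop = FALSE]
  rownames(out) <- leads
  out
}

#' @export
print.ecg_record <- function(x, ...) {
  n <- ncol(x$signals)
  cat(sprintf("12-lead ECG record: %d samples at %g Hz (%.2f s)\n",
              n, x$fs, n / x$fs))
  cat(sprintf("  individual: %s   MI label: %s\n",
              x$individual_id,
              ifelse(is.na(x$mi_label), "<none>", x$mi_label)))
  rng <- range(x$signals)
  cat(sprintf("  voltage range: [%.3f, %.3f] mV\n", rng[1], rng[2]))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.ecg_record <- function(x, ...) x$signals

#' Plot a 12-lead ECG record
#'
#' One panel per lead, time in seconds, voltage in mV.
#'
#' @param x An `ecg_record`.
#' @param leads Leads to draw (default all twelve).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ecg_record <- function(x, leads = canonical_leads(), ...) {
  tt <- seq_len(ncol(x$signals)) / x$fs
  old <- graphics::par(mfrow = c(ceiling(length(leads) / 2), 2),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (l in leads) {
    graphics::plot(tt, x$signals[l, ], type = "l", xlab = "",
                   ylab = paste0(l, " [mV]"), ...)
  }
  invisible(x)
}

# Extract a leads x N matrix for a subset of leads
lead_matrix <- function(record, leads) {
  record$signals[leads, , drop = FALSE]
}

#' Assemble a dataset of ECG records with a manifest
#'
#' @param records List of [ecg_record()] objects.
#' @return An `ecg_dataset`: the record list plus a manifest data frame
#'   (record_id, individual_id, mi_label, pathology).
#' @export
ecg_dataset <- function(records) {
  stopifnot(length(records) >= 1L)
  ids <- names(records)
  if (is.null(ids)) {
    ids <- sprintf("rec%05d", seq_along(records))
    names(records) <- ids
  }
  manifest <- data.frame(
    record_id = ids,
    individual_id = vapply(records, function(r) r$individual_id, ""),
    mi_label = vapply(records, function(r) isTRUE(r$mi_label), NA),
    pathology = vapply(records, function(r)
      if (is.null(r$meta$pathology)) NA_character_ else r$meta$pathology, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(records = records, manifest = manifest),
            class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("ECG dataset: %d records, %d individuals, %d MI-labeled\n",
              nrow(m), length(unique(m$individual_id)),
              sum(m$mi_label, na.rm = TRUE)))
  invisible(x)
}

#' @export
`[.ecg_dataset` <- function(x, i) {
  ecg_dataset(x$records[i])
}

#' @export
length.ecg_dataset <- function(x) length(x$records)
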