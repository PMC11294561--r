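# Reading and writing ECG records.
#
# Two on-disk formats are supported:
#   * delimited text: one column per lead, header row of lead names,
#     voltages in mV at full precision - the lossless interchange format;
#   * a minimal WFDB-compatible format: text header (<name>.hea) plus a
#     little-endian int32 signal file (<name>.dat, format 32), one gain/
#     baseline per signal.  This writer/reader covers only what this
#     package emits (12 signals, shared fs, mV units).

#' Write an ECG record to disk
#'
#' @param record An [ecg_record()].
#' @param path Output path; for `format = "wfdb"` the record name (paths
#'   `<path>.hea` and `<path>.dat` are written).
#' @param format `"delimited"` (tab-separated text, lossless) or
#'   `"wfdb"` (minimal WFDB format-32 pair).
#' @param gain Integer WFDB gain in adu/mV (default `2e6`, quantization
#'   5e-7 mV).
#' @return `path`, invisibly.
#' @export
write_ecg <- function(record, path, format = c("delimited", "wfdb"),
                      gain = 2e6) {
  format <- match.arg(format)
  if (format == "delimited") {
    df <- as.data.frame(t(record$signals))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# fs_hz=", format(record$fs, digits = 15),
                      " individual_id=", record$individual_id,
                      " mi_label=", record$mi_label), con)
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    name <- basename(path)
    n <- ncol(record$signals)
    adc <- round(record$signals * gain)
    if (any(abs(adc) >= 2^31))
      stop("signal exceeds the int32 range at this gain")
    hea <- c(sprintf("%s 12 %s %d", name, format(record$fs, digits = 15), n),
             sprintf("%s.dat 32 %d(0)/mV 32 0 %d 0 0 %s",
                     name, as.integer(gain), as.integer(adc[, 1]),
                     rownames(record$signals)),
             sprintf("# individual_id=%s mi_label=%s",
                     record$individual_id, record$mi_label))
    writeLines(hea, paste0(path, ".hea"))
    con <- file(paste0(path, ".dat"), "wb")
    on.exit(close(con))
    writeBin(as.integer(adc), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read an ECG record from disk
#'
#' Lead columns are matched by name case-insensitively (`AVR` is `aVR`)
#' and reordered into canonical order; unknown or missing lead names are
#' rejected with a message naming them.
#'
#' @param path Path written by [write_ecg()] (for WFDB, the record name
#'   without extension).
#' @param format `"delimited"` or `"wfdb"`.
#' @return An [ecg_record()].
#' @export
read_ecg <- function(path, format = c("delimited", "wfdb")) {
  format <- match.arg(format)
  if (format == "delimited") {
    header <- readLines(path, n = 1L)
    if (!startsWith(header, "#"))
      stop("missing metadata header line in ", path)
    fs <- as.numeric(sub(".*fs_hz=([^ ]+).*", "\\1", header))
    iid <- sub(".*individual_id=([^ ]+).*", "\\1", header)
    mi <- sub(".*mi_label=([^ ]+).*", "\\1", header)
    df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                            check.names = FALSE)
    known <- match(toupper(names(df)), toupper(canonical_leads()))
    if (anyNA(known))
      stop("unknown lead name(s): ",
           paste(names(df)[is.na(known)], collapse = ", "))
    sig <- t(as.matrix(df))
    rownames(sig) <- canonical_leads()[known]
    ecg_record(sig, fs, iid, as.logical(mi))
  } else {
    hea <- readLines(paste0(path, ".hea"))
    top <- strsplit(hea[1L], " +")[[1L]]
    nsig <- as.integer(top[2L]); fs <- as.numeric(top[3L])
    n <- as.integer(top[4L])
    sig_lines <- hea[2:(1L + nsig)]
    parts <- strsplit(sig_lines, " +")
    gains <- vapply(parts, function(p)
      as.numeric(sub("\\(.*", "", p[3L])), numeric(1))
    leads <- vapply(parts, function(p) p[length(p)], "")
    meta_line <- grep("^# individual_id=", hea, value = TRUE)
    iid <- NA_character_; mi <- NA
    if (length(meta_line)) {
      iid <- sub(".*individual_id=([^ ]+).*", "\\1", meta_line[1L])
      mi <- as.logical(sub(".*mi_label=([^ ]+).*", "\\1", meta_line[1L]))
    }
    con <- file(paste0(path, ".dat"), "rb")
    on.exit(close(con))
    adc <- readBin(con, "integer", n = nsig * n, size = 4L,
                   endian = "little")
    sig <- matrix(adc, nrow = nsig) / gains
    known <- match(toupper(leads), toupper(canonical_leads()))
    if (anyNA(known))
      stop("unknown lead name(s): ", paste(leads[is.na(known)], collapse = ", "))
    rownames(sig) <- canonical_leads()[known]
    ecg_record(sig, fs, iid, mi)
  }
}

#' Write an ECG dataset (records plus manifest) to a directory
#'
#' One file (or WFDB pair) per record plus a tab-separated
#' `manifest.tsv` (record id, individual id, MI label, pathology kind).
#'
#' @param dataset An [ecg_dataset()].
#' @param dir Output directory (created if needed).
#' @param format Passed to [write_ecg()].
#' @return `dir`, invisibly.
#' @export
write_ecg_dataset <- function(dataset, dir,
                              format = c("delimited", "wfdb")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "delimited") ".tsv" else ""
  for (id in names(dataset$records))
    write_ecg(dataset$records[[id]], file.path(dir, paste0(id, ext)),
              format = format)
  utils::write.table(dataset$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an ECG dataset written by [write_ecg_dataset()]
#'
#' @param dir Dataset directory containing `manifest.tsv`.
#' @param format Storage format used when writing.
#' @return An [ecg_dataset()].
#' @export
read_ecg_dataset <- function(dir, format = c("delimited", "wfdb")) {
  format <- match.arg(format)
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  ext <- if (format == "delimited") ".tsv" else ""
  records <- lapply(manifest$record_id, function(id)
    read_ecg(file.path(dir, paste0(id, ext)), format = format))
  names(records) <- manifest$record_id
  ecg_dataset(records)
}
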