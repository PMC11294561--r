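#' Derive the six limb leads from leads I and II
#'
#' The limb leads are linearly dependent: Einthoven's relation gives
#' III = II - I, and the Goldberger augmented leads follow as
#' aVR = -(I + II)/2, aVL = (I - III)/2, aVF = (II + III)/2.  Measuring
#' leads I and II therefore determines all six limb leads exactly.
#'
#' @param lead_I,lead_II Numeric vectors of equal length, voltages in mV.
#' @return A `6 x N` matrix with rows I, II, III, aVR, aVL, aVF.
#' @export
#' @examples
#' derive_limb_leads(rep(0.2, 4), rep(1.0, 4))[, 1]
derive_limb_leads <- function(lead_I, lead_II) {
  if (length(lead_I) != length(lead_II))
    stop("lead I and lead II must have the same length")
  if (!all(is.finite(lead_I)) || !all(is.finite(lead_II)))
    stop("lead signals must be finite")
  III <- lead_II - lead_I
  out <- rbind(I = lead_I, II = lead_II, III = III,
               aVR = -(lead_I + lead_II) / 2,
               aVL = (lead_I - III) / 2,
               aVF = (lead_II + III) / 2)
  out
}

#' Check the limb-lead consistency of a record
#'
#' Computes the maximum absolute deviation from the four limb-lead
#' identities (III = II - I and the three augmented-lead relations) and
#' compares it against a tolerance.  The residual is the maximum (not RMS)
#' deviation, in mV - the strictest interpretable bound.
#'
#' @param record An [ecg_record()].
#' @param tol Tolerance in mV (default `1e-9`).
#' @return List with elements `pass` (logical) and `residual` (mV), class
#'   `limb_consistency`.
#' @export
check_limb_consistency <- function(record, tol = 1e-9) {
  s <- record$signals
  III <- s["II", ] - s["I", ]
  res <- max(
    max(abs(s["III", ] - III)),
    max(abs(s["aVR", ] + (s["I", ] + s["II", ]) / 2)),
    max(abs(s["aVL", ] - (s["I", ] - III) / 2)),
    max(abs(s["aVF", ] - (s["II", ] + III) / 2)))
  structure(list(pass = res <= tol, residual = res, tol = tol),
            class = "limb_consistency")
}

#' @export
print.limb_consistency <- function(x, ...) {
  cat(sprintf("limb-lead consistency: %s (residual %.3g mV, tol %.3g mV)\n",
              if (x$pass) "PASS" else "FAIL", x$residual, x$tol))
  invisible(x)
}

#' Band-limited resampling of a signal
#'
#' Resamples a finite record from `fs_in` to `fs_out` Hz by Fourier
#' interpolation: the discrete spectrum is truncated (downsampling) or
#' zero-padded (upsampling) at the output Nyquist frequency, which
#' preserves all content below `fs_out / 2` and is anti-aliasing by
#' construction.
#'
#' @param x Numeric vector, the signal in mV.
#' @param fs_in,fs_out Input and output sampling frequencies in Hz.
#' @return Numeric vector of length `round(length(x) * fs_out / fs_in)`.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  if (length(x) < 1L) stop("cannot resample an empty signal")
  if (fs_in <= 0 || fs_out <= 0) stop("sampling frequencies must be positive")
  n <- length(x)
  m <- as.integer(round(n * fs_out / fs_in))
  if (m == n && isTRUE(all.equal(fs_in, fs_out))) return(x)
  if (m < 1L) stop("output would be empty; fs_out too small")
  X <- stats::fft(x)
  Y <- complex(m)
  keep <- min(n, m)
  h <- keep %/% 2L
  # positive frequencies (incl. DC)
  Y[seq_len(h + 1L)] <- X[seq_len(h + 1L)]
  # negative frequencies
  if (h > 0L) {
    neg <- seq_len(h - as.integer(keep %% 2L == 0L))
    if (length(neg) > 0L)
      Y[m + 1L - neg] <- X[n + 1L - neg]
  }
  # shared Nyquist bin when downsampling to an even length
  if (m < n && m %% 2L == 0L) {
    Y[h + 1L] <- (X[h + 1L] + X[n - h + 1L]) / 2
  }
  Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
}

# Resample all 12 leads of a record; returns a new ecg_record.
resample_record <- function(record, fs_out) {
  if (isTRUE(all.equal(record$fs, fs_out))) return(record)
  sig <- t(apply(record$signals, 1L, resample_signal,
                 fs_in = record$fs, fs_out = fs_out))
  rownames(sig) <- rownames(record$signals)
  ecg_record(sig, fs_out, record$individual_id, record$mi_label, record$meta)
}

#' Map voltages to the unit interval
#'
#' Affine feature scaling of a lead: `v_min` maps to 0 and `v_max` to 1,
#' with clipping outside the range (values above `v_max` become 1, values
#' below `v_min` become 0).  Defaults follow the +/-2.5 mV physiological
#' window used by the reconstruction and classification networks.
#'
#' @param x Voltages in mV.
#' @param v_min,v_max Scaling window in mV (defaults -2.5 and 2.5).
#' @return Values in `[0, 1]`, same shape as `x`.
#' @export
#' @examples
#' scale_to_unit(c(-2.5, 0, 2.5, 3.1))
scale_to_unit <- function(x, v_min = -2.5, v_max = 2.5) {
  if (!(v_min < v_max)) stop("v_min must be below v_max")
  u <- (x - v_min) / (v_max - v_min)
  u[u > 1] <- 1
  u[u < 0] <- 0
  u
}

#' Invert the unit scaling back to millivolts
#'
#' Inverse of [scale_to_unit()]; `unscale(scale_to_unit(v))` is the
#' identity for `v` inside `[v_min, v_max]`.
#'
#' @param u Values in `[0, 1]`.
#' @inheritParams scale_to_unit
#' @return Voltages in mV.
#' @export
unscale <- function(u, v_min = -2.5, v_max = 2.5) {
  if (!(v_min < v_max)) stop("v_min must be below v_max")
  u * (v_max - v_min) + v_min
}
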