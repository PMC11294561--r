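# Synthetic 12-lead ECG generation from a rotating heart-vector (dipole)
# source.  The cardiac electrical activity is modeled as a 3-dimensional
# time-varying dipole; each surface lead is the projection of that vector
# onto a fixed direction.  Because leads I and II span the frontal plane
# and the derived limb leads are built from them by construction, every
# generated record satisfies the Einthoven-Goldberger identities exactly,
# while the precordial leads carry an out-of-plane component that leads
# I+II alone cannot determine - the structure that makes reduced-lead
# reconstruction a meaningful learning problem.

# Default Gaussian wave table for one dipole axis: amplitude (mV), phase
# center mu (rad, R peak at 0), phase width sigma (rad).  The anterior
# (z) axis has its own wave timing and morphology - delayed R peak,
# deeper S, prominent T - so the anterior component is only weakly
# predictable from the frontal axes, as in real ECGs: the frontal leads
# alone then explain only about half of the precordial variance and the
# chest-lead input carries decisive information.
default_waves <- function() {
  mk <- function(amp, mu = c(-2.0, -0.35, 0.0, 0.35, 2.0),
                 sigma = c(0.25, 0.10, 0.10, 0.10, 0.35)) {
    data.frame(wave = c("P", "Q", "R", "S", "T"), amp = amp, mu = mu,
               sigma = sigma, stringsAsFactors = FALSE)
  }
  list(x = mk(c(0.10, -0.10, 1.20, -0.25, 0.35)),
       y = mk(c(0.08, -0.06, 0.90, -0.15, 0.20)),
       z = mk(c(0.03, -0.06, 1.10, -0.50, 0.35),
              mu = c(-2.1, -0.45, 0.15, 0.55, 2.25),
              sigma = c(0.25, 0.10, 0.12, 0.12, 0.40)))
}

# Default lead direction vectors.  I and II lie in the frontal (x, y)
# plane; the four dependent limb leads are derived from them so the limb
# identities hold by construction.  The precordial directions sweep the
# horizontal plane with a nonzero anterior (z) component, largest at V3.
default_lead_vectors <- function() {
  vI  <- c(1, 0, 0)
  vII <- c(cos(pi / 3), sin(pi / 3), 0)
  vIII <- vII - vI
  pre <- rbind(
    V1 = c(-0.40, 0.15, 0.55),
    V2 = c(-0.15, 0.20, 0.75),
    V3 = c( 0.15, 0.25, 0.90),
    V4 = c( 0.45, 0.30, 0.70),
    V5 = c( 0.70, 0.25, 0.45),
    V6 = c( 0.90, 0.20, 0.20))
  lv <- rbind(I = vI, II = vII, III = vIII,
              aVR = -(vI + vII) / 2,
              aVL = (vI - vIII) / 2,
              aVF = (vII + vIII) / 2,
              pre)
  colnames(lv) <- c("x", "y", "z")
  lv
}

#' Dipole source model for synthetic 12-lead ECGs
#'
#' Defines the time-varying heart vector (a sum of Gaussian bumps on a
#' circular cardiac phase, one parameter set per spatial axis) and the
#' twelve lead direction vectors onto which it is projected.
#'
#' The four dependent limb-lead directions are always recomputed from the
#' supplied I and II directions, so the limb-lead identities hold for
#' every projected record by construction; I and II must lie in the
#' frontal plane (zero third component).
#'
#' @param lead_vectors `12 x 3` matrix of direction vectors (rows in
#'   canonical lead order).  Only rows I, II and V1-V6 are free; III, aVR,
#'   aVL, aVF are overwritten with their derived values.
#' @param waves List with components `x`, `y`, `z`, each a data frame with
#'   columns `wave`, `amp` (mV), `mu` (rad), `sigma` (rad) describing the
#'   P, Q, R, S, T Gaussian bumps on that axis.
#' @param heart_rate Mean heart rate in beats/min.
#' @param rr_variability Fractional standard deviation of the beat-to-beat
#'   interval (0 = perfectly regular rhythm).
#' @return Object of class `dipole_model`.
#' @export
#' @examples
#' m <- dipole_model()
#' round(m$lead_vectors["V3", ], 2)
dipole_model <- function(lead_vectors = default_lead_vectors(),
                         waves = default_waves(),
                         heart_rate = 70,
                         rr_variability = 0.03) {
  if (!is.matrix(lead_vectors) || any(dim(lead_vectors) != c(12L, 3L)))
    stop("`lead_vectors` must be a 12 x 3 matrix")
  rownames(lead_vectors) <- canonical_leads()
  if (any(lead_vectors[c("I", "II"), 3] != 0))
    stop("lead vectors I and II must lie in the frontal plane (z = 0)")
  # enforce the limb-lead identities on the direction vectors
  vI <- lead_vectors["I", ]; vII <- lead_vectors["II", ]
  lead_vectors["III", ] <- vII - vI
  lead_vectors["aVR", ] <- -(vI + vII) / 2
  lead_vectors["aVL", ] <- (vI - (vII - vI)) / 2
  lead_vectors["aVF", ] <- (vII + (vII - vI)) / 2
  if (all(abs(lead_vectors[precordial_leads(), 3]) < 1e-12))
    stop("at least one precordial lead vector must leave the frontal plane")
  stopifnot(is.list(waves), all(c("x", "y", "z") %in% names(waves)))
  if (heart_rate <= 0) stop("`heart_rate` must be positive")
  if (rr_variability < 0) stop("`rr_variability` must be >= 0")
  structure(list(lead_vectors = lead_vectors, waves = waves,
                 heart_rate = heart_rate, rr_variability = rr_variability),
            class = "dipole_model")
}

#' @export
print.dipole_model <- function(x, ...) {
  cat(sprintf("dipole ECG model: %g bpm (rr variability %.1f%%)\n",
              x$heart_rate, 100 * x$rr_variability))
  cat(sprintf("  R-wave amplitudes (x/y/z): %.2f / %.2f / %.2f mV\n",
              x$waves$x$amp[x$waves$x$wave == "R"],
              x$waves$y$amp[x$waves$y$wave == "R"],
              x$waves$z$amp[x$waves$z$wave == "R"]))
  invisible(x)
}

# wrap phase differences into (-pi, pi]
wrap_phase <- function(d) {
  d - 2 * pi * round(d / (2 * pi))
}

#' Simulate the heart-vector trajectory
#'
#' Advances a circular cardiac phase at the (optionally jittered) heart
#' rate and evaluates the per-axis sums of Gaussian bumps, giving a
#' `3 x N` dipole trajectory in mV.  The phase is attached as an
#' attribute so downstream pathology shaping (ST displacement) can locate
#' the ST window.
#'
#' @param model A [dipole_model()].
#' @param duration Record length in seconds (> 0).
#' @param fs Sampling frequency in Hz; 250 or 500.
#' @param seed Integer seed; identical inputs and seed reproduce the
#'   trajectory bit-for-bit.
#' @return `3 x N` numeric matrix (rows x, y, z) with attributes `fs` and
#'   `phase`.
#' @export
simulate_dipole <- function(model, duration, fs = 250, seed = 1L) {
  stopifnot(inherits(model, "dipole_model"))
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be a positive number of seconds")
  if (!fs %in% c(250, 500))
    stop("unsupported sampling frequency: ", fs, " Hz (use 250 or 500)")
  n <- as.integer(round(duration * fs))
  set.seed(seed)
  # beat-to-beat intervals with multiplicative jitter
  rr0 <- 60 / model$heart_rate
  n_beats <- ceiling(duration / rr0) + 3L
  rr <- rr0 * (1 + model$rr_variability * stats::rnorm(n_beats))
  rr <- pmax(rr, 0.2 * rr0)
  onsets <- c(0, cumsum(rr))
  tt <- (seq_len(n) - 1L) / fs
  beat <- findInterval(tt, onsets)
  phase <- -pi + 2 * pi * (tt - onsets[beat]) / rr[beat]
  traj <- matrix(0, 3L, n, dimnames = list(c("x", "y", "z"), NULL))
  for (a in 1:3) {
    w <- model$waves[[a]]
    for (i in seq_len(nrow(w))) {
      d <- wrap_phase(phase - w$mu[i])
      traj[a, ] <- traj[a, ] + w$amp[i] * exp(-d^2 / (2 * w$sigma[i]^2))
    }
  }
  attr(traj, "fs") <- fs
  attr(traj, "phase") <- phase
  traj
}

#' Project a dipole trajectory onto the twelve leads
#'
#' Lead `k` at time `t` is the inner product of the lead direction vector
#' with the heart vector at `t`.  Because the dependent limb-lead
#' directions are derived from I and II inside [dipole_model()], the
#' projected record satisfies the limb-lead identities to machine
#' precision.
#'
#' @param trajectory `3 x N` matrix from [simulate_dipole()] (or any
#'   matrix with an `fs` attribute).
#' @param model A [dipole_model()].
#' @param individual_id,mi_label,meta Passed to [ecg_record()].
#' @return An [ecg_record()].
#' @export
project_leads <- function(trajectory, model, individual_id = NA_character_,
                          mi_label = NA, meta = list()) {
  stopifnot(inherits(model, "dipole_model"))
  if (!is.matrix(trajectory) || nrow(trajectory) != 3L)
    stop("`trajectory` must be a 3 x N matrix")
  fs <- attr(trajectory, "fs")
  if (is.null(fs)) stop("`trajectory` must carry an `fs` attribute")
  sig <- model$lead_vectors %*% trajectory
  ecg_record(sig, fs, individual_id = individual_id,
             mi_label = mi_label, meta = meta)
}

#' Pathology specification for synthetic records
#'
#' Describes how a record deviates from normal morphology.  ST-elevation
#' (STEMI-like) records receive a constant dipole displacement active
#' during the ST phase window (between the end of the S wave and the onset
#' of the T wave), directed so that the selected territory's leads show
#' the elevation.
#'
#' @param kind One of `"normal"`, `"stemi"`, `"other_abnormal"`.
#' @param st_offset ST elevation in mV seen in the most affected territory
#'   lead; must be 0 for `kind = "normal"`.
#' @param territory `"anterior"` (V1-V4), `"lateral"` (I, aVL, V5, V6) or
#'   `"inferior"` (II, III, aVF).
#' @return Object of class `pathology_spec`.
#' @export
pathology_spec <- function(kind = c("normal", "stemi", "other_abnormal"),
                           st_offset = if (kind[1] == "stemi") 0.3 else 0,
                           territory = "anterior") {
  kind <- match.arg(kind)
  if (kind == "normal" && st_offset != 0)
    stop("`st_offset` must be 0 for normal records")
  if (st_offset < 0) stop("`st_offset` must be >= 0")
  territory <- match.arg(territory, c("anterior", "lateral", "inferior"))
  structure(list(kind = kind, st_offset = st_offset, territory = territory),
            class = "pathology_spec")
}

territory_leads <- function(territory) {
  switch(territory,
         anterior = c("V1", "V2", "V3", "V4"),
         lateral  = c("I", "aVL", "V5", "V6"),
         inferior = c("II", "III", "aVF"))
}

# ST phase window [after S, before T] from the wave table (x axis is the
# reference for wave timing; all axes share mu/sigma by default).
st_window <- function(model) {
  w <- model$waves$x
  s <- w[w$wave == "S", ]; t <- w[w$wave == "T", ]
  c(s$mu + 2 * s$sigma, t$mu - 2 * t$sigma)
}

# Apply the ST displacement to a trajectory (in place, returns trajectory).
# The displacement direction is the normalized mean of the territory lead
# vectors, scaled so the most affected territory lead is elevated by
# exactly `st_offset` mV at the window plateau; cosine ramps of width
# `ramp` keep the support inside the window.
apply_st_displacement <- function(trajectory, model, pathology,
                                  ramp = 0.08) {
  if (pathology$kind != "stemi" || pathology$st_offset == 0)
    return(trajectory)
  win <- st_window(model)
  phase <- attr(trajectory, "phase")
  leads <- territory_leads(pathology$territory)
  v <- model$lead_vectors[leads, , drop = FALSE]
  u <- colMeans(v); u <- u / sqrt(sum(u^2))
  proj <- as.vector(v %*% u)
  d <- pathology$st_offset * u / max(proj)
  # smooth plateau supported inside [win[1], win[2]]
  w <- rep(0, length(phase))
  inside <- phase >= win[1] & phase <= win[2]
  ww <- rep(1, sum(inside))
  ph <- phase[inside]
  lo <- ph < win[1] + ramp
  hi <- ph > win[2] - ramp
  ww[lo] <- 0.5 * (1 - cos(pi * (ph[lo] - win[1]) / ramp))
  ww[hi] <- 0.5 * (1 - cos(pi * (win[2] - ph[hi]) / ramp))
  w[inside] <- ww
  out <- trajectory + outer(d, w)
  attributes(out) <- attributes(trajectory)
  out
}

#' Noise specification for synthetic records
#'
#' Additive noise applied, by default, to the dipole trajectory *before*
#' projection, which preserves the limb-lead identities exactly.  Setting
#' `per_lead = TRUE` instead adds independent sensor noise to each of the
#' twelve leads after projection, deliberately breaking the exact algebra
#' (for robustness experiments).
#'
#' @param baseline_amp Baseline-wander amplitude in mV.
#' @param baseline_freq Baseline-wander frequency in Hz.
#' @param white_sd Broadband (white) noise standard deviation in mV.
#' @param powerline_amp Powerline interference amplitude in mV.
#' @param powerline_freq Powerline frequency, 50 or 60 Hz.
#' @param per_lead Add noise per lead after projection instead of to the
#'   dipole (default `FALSE`).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_amp = 0.05, baseline_freq = 0.33,
                       white_sd = 0.02, powerline_amp = 0.02,
                       powerline_freq = 60, per_lead = FALSE) {
  if (baseline_amp < 0 || white_sd < 0 || powerline_amp < 0)
    stop("noise amplitudes must be >= 0")
  if (!powerline_freq %in% c(50, 60))
    stop("`powerline_freq` must be 50 or 60 Hz")
  structure(list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 white_sd = white_sd, powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq, per_lead = per_lead),
            class = "noise_spec")
}

#' Zero-noise specification
#' @return A [noise_spec()] with all amplitudes 0.
#' @export
noise_none <- function() {
  noise_spec(baseline_amp = 0, white_sd = 0, powerline_amp = 0)
}

# Additive noise matrix for `rows` channels over `n` samples at `fs`.
noise_matrix <- function(noise, rows, n, fs) {
  tt <- (seq_len(n) - 1L) / fs
  out <- matrix(0, rows, n)
  for (r in seq_len(rows)) {
    if (noise$baseline_amp > 0)
      out[r, ] <- out[r, ] + noise$baseline_amp *
        sin(2 * pi * noise$baseline_freq * tt + stats::runif(1, 0, 2 * pi))
    if (noise$powerline_amp > 0)
      out[r, ] <- out[r, ] + noise$powerline_amp *
        sin(2 * pi * noise$powerline_freq * tt + stats::runif(1, 0, 2 * pi))
    if (noise$white_sd > 0)
      out[r, ] <- out[r, ] + stats::rnorm(n, sd = noise$white_sd)
  }
  out
}

# Per-individual jitter: multiplicative perturbation of the free lead
# vectors (I, II, V1-V6; dependent limb leads re-derived) and of the wave
# amplitudes, drawn once per individual.
jitter_model <- function(model, amount = 0.10) {
  lv <- model$lead_vectors
  for (l in c("I", "II", precordial_leads())) {
    lv[l, ] <- lv[l, ] * (1 + stats::runif(3, -amount, amount))
  }
  lv[c("I", "II"), 3] <- 0
  waves <- lapply(model$waves, function(w) {
    w$amp <- w$amp * (1 + stats::runif(nrow(w), -amount, amount))
    w
  })
  hr <- model$heart_rate * (1 + stats::runif(1, -amount, amount))
  dipole_model(lv, waves, hr, model$rr_variability)
}

#' Generate a labeled synthetic 12-lead ECG dataset
#'
#' Draws one perturbed dipole model per individual (multiplicative jitter
#' on the free lead vectors and wave amplitudes, so the inter-lead
#' dependency varies from individual to individual), simulates the
#' requested number of records per individual, applies ST-elevation
#' pathology to the MI-labeled fraction, adds noise, and projects onto the
#' twelve leads.
#'
#' @param n_individuals Number of individuals (>= 1).
#' @param records_per_individual Records per individual (>= 1).
#' @param mi_fraction Fraction of records labeled acute MI, in `[0, 1]`;
#'   realized count is `round(mi_fraction * n)`.
#' @param model Base [dipole_model()].
#' @param noise [noise_spec()]; use [noise_none()] for noiseless data.
#' @param pathology [pathology_spec()] applied to MI-labeled records
#'   (default STEMI with 0.3 mV anterior ST elevation).
#' @param fs Sampling frequency (250 or 500 Hz).
#' @param duration Record length in seconds (default 10).
#' @param individual_jitter Fractional per-individual perturbation
#'   (default 0.10).
#' @param anterior_variability Per-record morphology variability of the
#'   anterior (z) dipole axis: each record draws fresh multiplicative
#'   amplitude jitter (fraction, default 0.30) and phase-timing jitter
#'   (0.4 x this value, in radians) for the z-axis waves.  This emulates
#'   the beat-to-beat and posture/respiration variation of the anterior
#'   component that the frontal leads cannot observe - the reason a
#'   chest lead is genuinely required for precordial reconstruction.
#'   Set to 0 for a fully stereotyped anterior axis.
#' @param seed Integer seed; the full dataset is reproducible under it.
#' @return An [ecg_dataset()].
#' @export
generate_ecg_dataset <- function(n_individuals, records_per_individual = 1L,
                                 mi_fraction = 0.5,
                                 model = dipole_model(),
                                 noise = noise_spec(),
                                 pathology = pathology_spec("stemi"),
                                 fs = 250, duration = 10,
                                 individual_jitter = 0.10,
                                 anterior_variability = 0.30,
                                 seed = 1L) {
  if (mi_fraction < 0 || mi_fraction > 1)
    stop("`mi_fraction` must be in [0, 1]")
  if (n_individuals < 1L || records_per_individual < 1L)
    stop("counts must be >= 1")
  stopifnot(inherits(noise, "noise_spec"), inherits(model, "dipole_model"))
  set.seed(seed)
  n <- n_individuals * records_per_individual
  n_mi <- round(mi_fraction * n)
  mi <- rep(FALSE, n)
  mi[sample.int(n, n_mi)] <- TRUE
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ind_models <- replicate(
    n_individuals,
    if (individual_jitter > 0) jitter_model(model, individual_jitter)
    else model,
    simplify = FALSE)
  noise_seeds <- sample.int(.Machine$integer.max - 1L, n)
  morph_seeds <- sample.int(.Machine$integer.max - 1L, n)
  records <- vector("list", n)
  k <- 0L
  for (i in seq_len(n_individuals)) {
    mi_ind <- ind_models[[i]]
    for (j in seq_len(records_per_individual)) {
      k <- k + 1L
      rec_model <- mi_ind
      if (anterior_variability > 0) {
        set.seed(morph_seeds[k])
        zw <- rec_model$waves$z
        zw$amp <- zw$amp *
          (1 + stats::runif(nrow(zw), -anterior_variability,
                            anterior_variability))
        zw$mu <- zw$mu + stats::runif(nrow(zw),
                                      -0.4 * anterior_variability,
                                      0.4 * anterior_variability)
        rec_model$waves$z <- zw
      }
      traj <- simulate_dipole(rec_model, duration, fs, seed = rec_seeds[k])
      pat <- if (mi[k]) pathology else pathology_spec("normal")
      traj <- apply_st_displacement(traj, mi_ind, pat)
      set.seed(noise_seeds[k])
      if (!noise$per_lead) {
        ph <- attr(traj, "phase")
        traj <- traj + noise_matrix(noise, 3L, ncol(traj), fs)
        attr(traj, "fs") <- fs
        attr(traj, "phase") <- ph
      }
      rec <- project_leads(traj, mi_ind,
                           individual_id = sprintf("ind%04d", i),
                           mi_label = mi[k],
                           meta = list(pathology = pat$kind,
                                       seed = rec_seeds[k]))
      if (noise$per_lead) {
        rec$signals <- rec$signals + noise_matrix(noise, 12L, ncol(traj), fs)
      }
      records[[k]] <- rec
    }
  }
  names(records) <- sprintf("rec%05d", seq_len(n))
  ecg_dataset(records)
}
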