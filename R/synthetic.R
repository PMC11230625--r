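#' Synthetic modular connectome
#'
#' Generates a directed, non-negative, log-normally weighted connectome with
#' modular structure (denser within modules than between), labeled with
#' atlas-like region names including the designated `V1` (primary visual
#' cortex) and `S1BF` (barrel field) regions. A pure function of
#' `(parameters, seed)`.
#'
#' @param n_regions number of regions (>= 2); the study's atlas has 496
#' @param n_modules number of modules
#' @param weight_lognorm `c(meanlog, sdlog)` of the edge-weight distribution
#' @param density overall edge density in `(0, 1]`; within-module density is
#'   1.5x the between-module density (both capped at 1, so `density = 1`
#'   yields the complete off-diagonal graph)
#' @param seed RNG seed
#' @return a [connectome()] object
#' @export
make_connectome <- function(n_regions = 496, n_modules = 8,
                            weight_lognorm = c(0, 1), density = 0.1,
                            seed = 1) {
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  if (n_modules > n_regions)
    stop("density/module layout incompatible: more modules than regions")
  set.seed(seed)
  module <- rep(seq_len(n_modules), length.out = n_regions)
  p_within <- min(1, 1.5 * density)
  p_between <- density
  same <- outer(module, module, `==`)
  p <- ifelse(same, p_within, p_between)
  diag(p) <- 0
  edges <- matrix(runif(n_regions^2) < p, n_regions)
  w <- matrix(0, n_regions, n_regions)
  w[edges] <- rlnorm(sum(edges), weight_lognorm[1], weight_lognorm[2])
  named <- c("V1", "S1BF", "M1", "A1", "RSC", "CG1", "LGN", "VPM", "SC",
             "MD", "CPu", "PrL")
  labels <- c(named[seq_len(min(length(named), n_regions))],
              sprintf("R%03d", seq_len(max(0, n_regions - length(named)))))
  connectome(w, labels[seq_len(n_regions)])
}

#' Synthetic SWD-laden EEG with ground truth
#'
#' Background is `1/f^exponent` noise; each scheduled seizure epoch carries a
#' harmonic spike-and-wave waveform (fundamental plus two phase-aligned
#' harmonics, producing a sharp spike and a slow wave per cycle) scaled to
#' `amp_ratio` times the background RMS amplitude. Construction is checked at
#' generation time: each epoch must dominate the 7-12 Hz band and reach its
#' amplitude ratio.
#'
#' @param duration trace length (s)
#' @param fs sampling rate (Hz)
#' @param seizure_schedule data frame of intended intervals (`start`, `end`)
#' @param swd_freq fundamental SWD frequency (Hz), inside `(1, fs / 4)`
#' @param amp_ratio SWD amplitude over background RMS
#' @param noise_exponent spectral exponent of the background
#' @param seed RNG seed
#' @return list with `trace` (an [eeg_trace()]) and `truth` (generator echo
#'   including the exact intervals)
#' @export
make_eeg <- function(duration = 120, fs = 1024,
                     seizure_schedule = data.frame(start = numeric(0),
                                                   end = numeric(0)),
                     swd_freq = 8, amp_ratio = 3, noise_exponent = 1,
                     seed = 1) {
  if (swd_freq <= 1 || swd_freq >= fs / 4)
    stop("swd_freq must lie in (1, fs/4)")
  set.seed(seed)
  n <- round(duration * fs)
  bg <- powerlaw_noise(n, fs, noise_exponent)
  bg <- bg / sqrt(mean(bg^2)) * 10         # background RMS 10 microvolts
  x <- bg
  t <- (seq_len(n) - 1) / fs
  bg_rms <- sqrt(mean(bg^2))
  for (k in seq_len(nrow(seizure_schedule))) {
    s0 <- seizure_schedule$start[k]
    s1 <- seizure_schedule$end[k]
    sel <- t >= s0 & t < s1
    tt <- t[sel] - s0
    wave <- cos(2 * pi * swd_freq * tt) +
      0.5 * cos(4 * pi * swd_freq * tt) +
      0.25 * cos(6 * pi * swd_freq * tt)
    wave <- wave / sqrt(mean(wave^2))
    ramp <- pmin(1, pmin(tt, (s1 - s0) - tt) / 0.1)
    x[sel] <- x[sel] + amp_ratio * bg_rms * wave * ramp
  }
  trace <- eeg_trace(x, fs)
  # generation-time construction checks
  for (k in seq_len(nrow(seizure_schedule))) {
    sel <- t >= seizure_schedule$start[k] & t < seizure_schedule$end[k]
    psd <- welch_psd(x[sel], fs, seg_len_s = 1)
    bp <- band_power(psd, 7, 12) / band_power(psd, 1, 90)
    ratio <- sqrt(mean(x[sel]^2)) / bg_rms
    if (amp_ratio >= 2 && (bp < 0.2 || ratio < sqrt(1 + amp_ratio^2) * 0.7))
      warning("generated epoch ", k, " misses its construction targets")
  }
  list(trace = trace,
       truth = list(intervals = seizure_schedule, swd_freq = swd_freq,
                    amp_ratio = amp_ratio, noise_exponent = noise_exponent,
                    fs = fs, duration = duration, seed = seed))
}

# FFT-shaped 1/f^alpha noise, band-limited to the EEG band of interest so
# that amplitude ratios mean the same thing to the generator and detector
powerlaw_noise <- function(n, fs, alpha, band = c(1, 90)) {
  nf <- n %/% 2
  f <- seq_len(nf) * fs / n
  amp <- f^(-alpha / 2)
  amp[f < band[1] | f > band[2]] <- 0
  phase <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- c(0, spec, if (n %% 2 == 0) Conj(rev(spec[-nf])) else Conj(rev(spec)))
  Re(fft(full, inverse = TRUE)) / n
}

#' Synthetic stimulation schedule targeting ictal and interictal periods
#'
#' Lays out stimulation blocks separated by at least `min_gap` seconds,
#' alternating between onsets inside scheduled seizures (ictal targets) and
#' onsets at least 5 s away from any seizure (interictal targets), emulating
#' the study's manually balanced sampling of both states.
#'
#' @param duration recording length (s)
#' @param seizure_intervals data frame (`start`, `end`)
#' @param block_duration stimulation block length (s)
#' @param min_gap minimum gap between consecutive blocks (s)
#' @param policy `"alternate"` (ictal/interictal) or `"interictal_only"`
#' @param seed RNG seed (jitters onsets within feasible windows)
#' @return list with `blocks` (data frame `onset`, `duration`,
#'   `intended_state`) and `truth` echo
#' @export
make_stim_schedule <- function(duration, seizure_intervals,
                               block_duration = 6, min_gap = 20,
                               policy = c("alternate", "interictal_only"),
                               seed = 1) {
  policy <- match.arg(policy)
  set.seed(seed)
  sz <- seizure_intervals
  interictal_ok <- function(onset) {
    if (!nrow(sz)) return(TRUE)
    all(onset + block_duration + 5 <= sz$start | onset >= sz$end + 5)
  }
  ictal_onset_after <- function(tmin) {
    cand <- sz[sz$end > tmin, , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      o <- max(tmin, cand$start[j] + 0.2)
      if (o < cand$end[j]) return(o)
    }
    NA_real_
  }
  interictal_onset_after <- function(tmin) {
    o <- tmin
    while (o + block_duration <= duration) {
      if (interictal_ok(o)) return(o)
      o <- o + 0.5
    }
    NA_real_
  }
  onsets <- numeric(0)
  states <- character(0)
  want <- "interictal"
  tmin <- 1
  while (tmin + block_duration <= duration) {
    if (policy == "interictal_only") want <- "interictal"
    o <- if (want == "ictal") ictal_onset_after(tmin) else
      interictal_onset_after(tmin)
    if (is.na(o) || o + block_duration > duration) {
      alt <- if (want == "ictal") interictal_onset_after(tmin) else
        ictal_onset_after(tmin)
      if (is.na(alt) || alt + block_duration > duration) break
      o <- alt
      want <- setdiff(c("ictal", "interictal"), want)
    }
    onsets <- c(onsets, o)
    states <- c(states, want)
    tmin <- o + block_duration + min_gap
    want <- if (policy == "alternate")
      setdiff(c("ictal", "interictal"), want) else "interictal"
  }
  if (length(onsets) < 2)
    stop("infeasible constraints: duration too short for 2 blocks with ",
         "min_gap = ", min_gap, " s")
  blocks <- data.frame(onset = onsets, duration = block_duration,
                       intended_state = states)
  list(blocks = blocks,
       truth = list(seizure_intervals = sz, block_duration = block_duration,
                    min_gap = min_gap, policy = policy, seed = seed))
}

#' Synthetic 4D fMRI with known effects
#'
#' Voxel time series are built as the sum over conditions of
#' `beta * (boxcar * basis_k)` inside each condition's ROI, plus AR(1) noise
#' and optional motion spikes (simultaneous jumps of the motion parameters
#' and global intensity artifacts). The defaults mirror the study's
#' acquisition: ~2 s volume time, 45 min, i.e. 1350 volumes, on a desk-scale
#' 20 x 20 x 12 grid.
#'
#' @param dims 3D grid dimensions
#' @param TR volume acquisition time (s)
#' @param n_volumes number of volumes (default `45 * 60 / TR`)
#' @param design_events data frame `onset`, `duration`, `condition`
#' @param roi_beta_maps named list (by condition) of lists with `roi` (3D
#'   logical array) and `betas` (length-3 weights of the basis functions)
#' @param basis an [gamma_basis()] object
#' @param noise list: `sd` (innovation SD), `ar` (AR(1) coefficient)
#' @param motion_spikes frame indices receiving a motion spike
#' @param spike_mm spike amplitude (mm)
#' @param seed RNG seed
#' @return list with `vol4d`, `motion` (6-column data frame), `frame_times`,
#'   and `truth` (ROIs, betas, events, parameters)
#' @export
make_fmri <- function(dims = c(20, 20, 12), TR = 2,
                      n_volumes = round(45 * 60 / TR),
                      design_events = data.frame(onset = numeric(0),
                                                 duration = numeric(0),
                                                 condition = character(0)),
                      roi_beta_maps = list(), basis = gamma_basis(TR = TR),
                      noise = list(sd = 1, ar = 0.3),
                      motion_spikes = integer(0), spike_mm = 0.1, seed = 1) {
  set.seed(seed)
  frame_times <- (seq_len(n_volumes) - 1) * TR
  nvox <- prod(dims)
  data <- matrix(0, n_volumes, nvox)
  for (cond in names(roi_beta_maps)) {
    spec <- roi_beta_maps[[cond]]
    if (!all(dim(spec$roi) == dims)) stop("ROI outside volume dimensions")
    ev <- design_events[design_events$condition == cond, , drop = FALSE]
    if (!nrow(ev)) next
    reg <- convolve_events(ev$onset, ev$duration, basis, frame_times)
    ts <- drop(reg %*% spec$betas)
    vox <- which(as.vector(spec$roi))
    data[, vox] <- data[, vox] + ts
  }
  if (noise$sd > 0) {
    innov <- matrix(rnorm(n_volumes * nvox, sd = noise$sd), n_volumes, nvox)
    ar_noise <- innov
    for (k in 2:n_volumes)
      ar_noise[k, ] <- noise$ar * ar_noise[k - 1, ] + innov[k, ]
    data <- data + ar_noise
  }
  motion <- matrix(rnorm(n_volumes * 6, sd = 1e-4), n_volumes, 6)
  motion <- apply(motion, 2, cumsum)
  if (length(motion_spikes)) {
    for (f in motion_spikes) {
      motion[f, 1:3] <- motion[f, 1:3] + spike_mm
      data[f, ] <- data[f, ] + 5 * noise$sd
    }
  }
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  vol4d <- array(t(data), c(dims, n_volumes))
  list(vol4d = vol4d, motion = as.data.frame(motion),
       frame_times = frame_times,
       truth = list(dims = dims, TR = TR, n_volumes = n_volumes,
                    events = design_events, roi_beta_maps = roi_beta_maps,
                    basis = basis, noise = noise,
                    motion_spikes = motion_spikes, seed = seed))
}
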