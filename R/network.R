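#' Sensory stimulation protocol
#'
#' A periodic square-pulse stimulus delivered in blocks to target regions,
#' modeled as an increase in the excitatory drive to those nodes. The study's
#' two protocols are available as presets: visual (3 Hz pulses of 166 ms) and
#' whisker (2 Hz pulses of 250 ms), both in 6 s blocks.
#'
#' @param target_regions character vector of stimulated region labels
#' @param amplitude added excitatory drive during a pulse (Hz)
#' @param pulse_freq pulse repetition frequency (Hz)
#' @param pulse_width pulse width (ms); must be shorter than one cycle
#' @param block_duration block length (s)
#' @param onsets block onset times (s), sorted, non-overlapping
#' @return an object of class `stimulus_protocol`
#' @export
stimulus_protocol <- function(target_regions, amplitude = 20,
                              pulse_freq = 3, pulse_width = 166,
                              block_duration = 6, onsets = numeric(0)) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (pulse_width * 1e-3 >= 1 / pulse_freq)
    stop("pulse_width must be shorter than one pulse cycle")
  if (is.unsorted(onsets)) stop("onsets must be sorted")
  if (length(onsets) > 1 &&
      any(diff(onsets) < block_duration))
    stop("stimulation blocks must not overlap")
  structure(list(target_regions = as.character(target_regions),
                 amplitude = amplitude, pulse_freq = pulse_freq,
                 pulse_width = pulse_width, block_duration = block_duration,
                 onsets = onsets),
            class = "stimulus_protocol")
}

#' @rdname stimulus_protocol
#' @param type preset name
#' @param ... overrides
#' @export
preset_protocol <- function(type = c("visual", "whisker"), ...) {
  type <- match.arg(type)
  args <- if (type == "visual")
    list(pulse_freq = 3, pulse_width = 166, block_duration = 6)
  else
    list(pulse_freq = 2, pulse_width = 250, block_duration = 6)
  do.call(stimulus_protocol, utils::modifyList(args, list(...)))
}

# shared pulse-train waveform of a protocol sampled on a time grid (s)
protocol_wave <- function(protocol, time) {
  on <- rep(FALSE, length(time))
  cycle <- 1 / protocol$pulse_freq
  width_s <- protocol$pulse_width * 1e-3
  for (o in protocol$onsets) {
    inblock <- time >= o & time < o + protocol$block_duration
    phase <- (time[inblock] - o) %% cycle
    on[inblock] <- phase < width_s
  }
  ifelse(on, protocol$amplitude, 0)
}

#' Build per-region stimulus input series
#'
#' Samples the protocol's square-pulse waveform on a uniform time grid and
#' places it on the target regions; all other regions receive zero.
#'
#' @param protocol a [stimulus_protocol()]
#' @param time uniform time grid (s)
#' @param labels region labels of the simulated network
#' @return matrix (regions x time points) of added excitatory drive (Hz)
#' @export
build_stimulus <- function(protocol, time, labels) {
  if (length(time) > 1) {
    dts <- diff(time)
    if (max(abs(dts - dts[1])) > 1e-9) stop("time grid must be uniform")
  }
  if (length(protocol$onsets) &&
      max(protocol$onsets) + protocol$block_duration > max(time) + 1e-9)
    stop("stimulation block extends past the end of the time grid")
  missing <- setdiff(protocol$target_regions, labels)
  if (length(missing))
    stop("target regions not in labels: ", paste(missing, collapse = ", "))
  wave <- protocol_wave(protocol, time)
  out <- matrix(0, length(labels), length(time),
                dimnames = list(labels, NULL))
  out[labels %in% protocol$target_regions, ] <-
    rep(wave, each = sum(labels %in% protocol$target_regions))
  out
}

#' Whole-brain simulation configuration
#'
#' @param dt integration step (ms)
#' @param duration simulated time (s)
#' @param transient_discard initial transient excluded from statistics (s)
#' @param coupling_scale global coupling gain `S` applied to the
#'   row-normalized connectome
#' @param noise_std excitatory rate-noise standard deviation (Hz)
#' @param seed RNG seed
#' @param state `"ictal"` or `"interictal"` (selects the adaptation default)
#' @param record_dt_ms sampling interval of stored series (ms)
#' @return an object of class `sim_config`
#' @export
sim_config <- function(dt = 0.1, duration = 11, transient_discard = 1,
                       coupling_scale = 0.05, noise_std = 0.02, seed = 1,
                       state = c("interictal", "ictal"), record_dt_ms = 1) {
  state <- match.arg(state)
  if (dt <= 0 || dt > 0.5) stop("dt must lie in (0, 0.5] ms")
  if (duration <= transient_discard)
    stop("duration must exceed transient_discard")
  if (coupling_scale < 0) stop("coupling_scale must be >= 0")
  structure(list(dt = dt, duration = duration,
                 transient_discard = transient_discard,
                 coupling_scale = coupling_scale, noise_std = noise_std,
                 seed = seed, state = state, record_dt_ms = record_dt_ms),
            class = "sim_config")
}

# row-normalize incoming weights to unit sum (zero rows stay zero)
normalize_weights <- function(w) {
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  w / rs
}

#' Simulate the whole-brain network
#'
#' Integrates one mean-field node per region, coupled through the
#' row-normalized connectome scaled by `coupling_scale`. The long-range
#' coupling and the stimulus enter the excitatory afferent of both
#' populations of the target node. Bit-reproducible given the seed.
#'
#' @param conn a [connectome()] object
#' @param params a [node_params()] object; when `NULL`, taken from
#'   `config$state` via [default_params()]
#' @param protocol a [stimulus_protocol()] (possibly with no onsets)
#' @param config a [sim_config()]
#' @param coeffs transfer coefficients
#' @return a `simulation_result` list: `time` (s), matrices `nu_e`, `nu_i`,
#'   `W`, `mu_V` (regions x time points, Hz / pA / mV), `labels`, `config`
#' @export
simulate_network <- function(conn, params = NULL, protocol, config,
                             coeffs = default_coefficients()) {
  if (is.null(params)) params <- default_params(config$state)
  missing <- setdiff(protocol$target_regions, conn$labels)
  if (length(missing))
    stop("protocol targets not in connectome: ",
         paste(missing, collapse = ", "))
  n_steps <- round(config$duration * 1e3 / config$dt)
  record_every <- max(1, round(config$record_dt_ms / config$dt))
  tgrid <- (seq_len(n_steps) - 1) * config$dt * 1e-3
  wave <- protocol_wave(protocol, tgrid)
  target <- as.numeric(conn$labels %in% protocol$target_regions)
  Wc <- config$coupling_scale * normalize_weights(conn$weights)
  dl <- if (is.null(conn$delays)) matrix(0L, conn$n, conn$n) else
    matrix(as.integer(round(conn$delays / config$dt)), conn$n, conn$n)
  # settle a single uncoupled node deterministically and start every region
  # there: keeps the coupled baseline inside the basin of the resting state
  init <- settle_state(params, coeffs, dt = config$dt)
  out <- mf_network_cpp(Wc, dl, wave, target, config$dt, n_steps,
                        record_every, config$noise_std, unclass(params),
                        coeffs_list(coeffs), init$nu_e, init$nu_i, init$W,
                        config$seed, 0)
  res <- list(time = as.numeric(out$time), nu_e = out$nu_e, nu_i = out$nu_i,
              W = out$W, mu_V = out$mu_V, labels = conn$labels,
              fs = 1e3 / config$record_dt_ms, config = config,
              params = params)
  class(res) <- "simulation_result"
  res
}

#' Per-region stimulus responsiveness statistics
#'
#' Runs a multi-trial stimulation simulation and tests, per region, the
#' paired difference between the mean excitatory rate in each stimulation
#' block and in the equally long pre-block baseline, across trials
#' (paired t-test, Benjamini-Hochberg corrected). A region is called
#' significant only when, in addition, its mean rate change stands out
#' against the ongoing dynamics: the absolute effect must reach
#' `effect_floor_sd` times the region's ongoing temporal fluctuation
#' (median within-baseline standard deviation). During spike-and-wave
#' oscillations the ongoing fluctuation is large, so stimulus-locked
#' entrainment shifts that do not exceed the ongoing rhythm are not counted
#' as responses.
#'
#' @param conn a [connectome()] object
#' @param params node parameters (or `NULL` to use `config$state` defaults)
#' @param protocol a [stimulus_protocol()]; when it carries fewer than
#'   `n_trials` onsets, onsets are laid out internally with `trial_gap`
#'   seconds between blocks
#' @param config a [sim_config()]; its `duration` is extended to cover all
#'   trials when needed
#' @param n_trials number of stimulation blocks (>= 10)
#' @param alpha corrected significance level
#' @param trial_gap minimum gap between consecutive blocks (s)
#' @param trial_jitter uniform random extension of each gap (s); irregular
#'   spacing prevents phase-locking of the trial sequence to slow network
#'   modes (drawn deterministically from `config$seed`)
#' @param effect_floor_sd minimum absolute effect, in units of the region's
#'   ongoing (within-baseline) temporal standard deviation, for a
#'   statistically significant region to be counted as responsive
#' @param coeffs transfer coefficients
#' @return a `region_stats` data frame: `region`, `effect_hz` (mean rate
#'   change), `stat` (paired t), `p`, `p_adj`, `ongoing_sd` (Hz),
#'   `significant`, `degenerate` (zero-variance flag), `n_trials`
#' @export
responsiveness_map <- function(conn, params = NULL, protocol, config,
                               n_trials = 10, alpha = 0.05, trial_gap = 20,
                               trial_jitter = 6, effect_floor_sd = 1,
                               coeffs = default_coefficients()) {
  if (n_trials < 10) stop("n_trials must be >= 10")
  bd <- protocol$block_duration
  if (length(protocol$onsets) < n_trials) {
    first <- config$transient_discard + bd + 1
    set.seed(config$seed + 211)
    gaps <- trial_gap + runif(n_trials, 0, trial_jitter)
    protocol$onsets <- first + cumsum(c(0, (bd + gaps)[-n_trials]))
  }
  onsets <- protocol$onsets[seq_len(n_trials)]
  needed <- max(onsets) + bd + 1
  if (config$duration < needed) config$duration <- needed
  sim <- simulate_network(conn, params, protocol, config, coeffs)
  n <- conn$n
  block_mean <- baseline_mean <- ongoing <- matrix(NA_real_, n, n_trials)
  for (k in seq_len(n_trials)) {
    blk <- sim$time >= onsets[k] & sim$time < onsets[k] + bd
    bas <- sim$time >= onsets[k] - bd & sim$time < onsets[k]
    block_mean[, k] <- rowMeans(sim$nu_e[, blk, drop = FALSE])
    baseline_mean[, k] <- rowMeans(sim$nu_e[, bas, drop = FALSE])
    ongoing[, k] <- apply(sim$nu_e[, bas, drop = FALSE], 1, sd)
  }
  d <- block_mean - baseline_mean
  effect <- rowMeans(d)
  sd_d <- apply(d, 1, sd)
  ongoing_sd <- apply(ongoing, 1, median)
  degenerate <- sd_d < .Machine$double.eps^0.5
  stat <- ifelse(degenerate, 0, effect / (sd_d / sqrt(n_trials)))
  p <- ifelse(degenerate, 1, 2 * pt(-abs(stat), df = n_trials - 1))
  if (any(degenerate))
    warning(sum(degenerate), " region(s) had zero-variance differences; p set to 1")
  p_adj <- p.adjust(p, method = "BH")
  out <- data.frame(region = conn$labels, effect_hz = effect, stat = stat,
                    p = p, p_adj = p_adj, ongoing_sd = ongoing_sd,
                    significant = p_adj < alpha &
                      abs(effect) >= effect_floor_sd * ongoing_sd,
                    degenerate = degenerate, n_trials = n_trials,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_stats", "data.frame")
  out
}

#' Count significant regions
#'
#' @param stats a `region_stats` data frame from [responsiveness_map()]
#' @return number of regions with a significant (corrected) response
#' @export
count_significant <- function(stats) {
  if (is.null(stats$significant)) stop("stats must carry a significant flag")
  sum(stats$significant)
}
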