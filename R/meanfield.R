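#' One stochastic-Heun step of a single mean-field node
#'
#' Advances the node state `(nu_e, nu_i, W)` by `dt` under the rate dynamics
#' `T dnu_e/dt = F_e(nu_e_tot, nu_i, W) - nu_e + noise`,
#' `T dnu_i/dt = F_i(nu_e_tot, nu_i, 0) - nu_i`,
#' `dW/dt = -W/tau_w + b nu_e + a (mu_V - E_L_e)/tau_w`,
#' where `nu_e_tot` is the node's own excitatory rate plus the afferent
#' excitatory drive and the ambient external drive. Deterministic given
#' `(state, afferent, noise_draw)`.
#'
#' @param state list with `nu_e`, `nu_i` (Hz), `W` (pA)
#' @param afferent length-2 numeric: additional excitatory and inhibitory
#'   drive (Hz), e.g. long-range coupling plus stimulus
#' @param dt time step (ms); must be <= 0.5 ms
#' @param noise_draw rate-noise realization (Hz) added to the excitatory
#'   equation
#' @param params a [node_params()] object
#' @param coeffs a [transfer_coefficients()] object
#' @return updated state list, including the derived `mu_V` (mV)
#' @export
step_node <- function(state, afferent = c(0, 0), dt = 0.1, noise_draw = 0,
                      params = default_params(), coeffs = default_coefficients()) {
  if (dt > 0.5) stop("dt must be <= 0.5 ms (stability guard)")
  deriv <- function(ne, ni, W) {
    drive_e <- max(0, ne + afferent[1] + params$nu_ext)
    drive_i <- max(0, ni + afferent[2])
    Fe <- transfer_rate(drive_e, drive_i, W, params, coeffs, "e")
    Fi <- transfer_rate(drive_e, drive_i, 0, params, coeffs, "i")
    mu <- conductance_stats(drive_e, drive_i, W, params, "e")$mu_V
    list(de = (Fe - ne) / params$T, di = (Fi - ni) / params$T,
         dw = -W / params$tau_w + params$b * ne * 1e-3 +
           params$a * (mu - params$E_L_e) / params$tau_w,
         mu_V = mu)
  }
  k1 <- deriv(state$nu_e, state$nu_i, state$W)
  e1 <- clip_rate(state$nu_e + dt * k1$de, params)
  i1 <- clip_rate(state$nu_i + dt * k1$di, params)
  w1 <- state$W + dt * k1$dw
  k2 <- deriv(e1, i1, w1)
  out <- list(
    nu_e = clip_rate(state$nu_e + dt * (k1$de + k2$de) / 2 +
                       noise_draw * sqrt(dt / params$T), params),
    nu_i = clip_rate(state$nu_i + dt * (k1$di + k2$di) / 2, params),
    W = state$W + dt * (k1$dw + k2$dw) / 2)
  out$mu_V <- k1$mu_V
  if (any(!vapply(out, is.finite, logical(1))))
    stop("integration error: non-finite state after step")
  out
}

clip_rate <- function(x, params) pmin(pmax(x, 0), params$rate_cap)

#' Simulate a single uncoupled mean-field node
#'
#' Convenience wrapper over the network integrator with one region and zero
#' coupling.
#'
#' @param params a [node_params()] object
#' @param coeffs transfer coefficients
#' @param duration_s simulated time (s)
#' @param dt time step (ms)
#' @param seed RNG seed
#' @param record_dt_ms sampling interval of the returned series (ms)
#' @param noise_std overrides `params$noise_std` when not `NULL`
#' @param stream_offset noise-stream index of the node; a whole-brain
#'   simulation at zero coupling reproduces region `r` exactly with
#'   `stream_offset = r - 1`
#' @param init optional initial state list (`nu_e`, `nu_i`, `W`)
#' @return list with `time` (s) and `nu_e`, `nu_i`, `W`, `mu_V` series
#' @export
simulate_node <- function(params = default_params(), coeffs = default_coefficients(),
                          duration_s = 11, dt = 0.1, seed = 1,
                          record_dt_ms = 1, noise_std = NULL,
                          stream_offset = 0, init = NULL) {
  if (!is.null(noise_std)) params$noise_std <- noise_std
  if (is.null(init)) init <- list(nu_e = 2, nu_i = 10, W = 0)
  n_steps <- round(duration_s * 1e3 / dt)
  record_every <- max(1, round(record_dt_ms / dt))
  fp <- mf_network_cpp(matrix(0, 1, 1), matrix(0L, 1, 1),
                       numeric(n_steps), 0, dt, n_steps, record_every,
                       params$noise_std, unclass(params), coeffs_list(coeffs),
                       init$nu_e, init$nu_i, init$W, seed, stream_offset)
  list(time = as.numeric(fp$time), nu_e = as.numeric(fp$nu_e),
       nu_i = as.numeric(fp$nu_i), W = as.numeric(fp$W),
       mu_V = as.numeric(fp$mu_V), fs = 1e3 / record_dt_ms)
}

coeffs_list <- function(coeffs) {
  list(P_e = coeffs$P_e, P_i = coeffs$P_i, norm = coeffs$norm)
}

# deterministic 3 s settle of one uncoupled node; returns its final state
settle_state <- function(params, coeffs, dt = 0.1, settle_s = 3) {
  params$noise_std <- 0
  n_steps <- round(settle_s * 1e3 / dt)
  out <- mf_network_cpp(matrix(0, 1, 1), matrix(0L, 1, 1), numeric(n_steps),
                        0, dt, n_steps, n_steps, 0, unclass(params),
                        coeffs_list(coeffs), 2, 10, 0, 1, 0)
  list(nu_e = out$nu_e[1, 1], nu_i = out$nu_i[1, 1], W = out$W[1, 1])
}

#' Locate a deterministic fixed point of a single node
#'
#' Integrates the noise-free node to (near) stationarity and polishes the
#' final state by damped fixed-point iteration on the rate equations.
#'
#' @inheritParams simulate_node
#' @param settle_s integration time used to approach the attractor (s)
#' @return state list (`nu_e`, `nu_i`, `W`, `mu_V`), or `NULL` when the
#'   trajectory does not converge to a stationary point (e.g. a limit cycle)
#' @export
find_fixed_point <- function(params = default_params(),
                             coeffs = default_coefficients(),
                             settle_s = 4, dt = 0.1) {
  sim <- simulate_node(params, coeffs, duration_s = settle_s, dt = dt,
                       seed = 1, noise_std = 0)
  n <- length(sim$nu_e)
  st <- list(nu_e = sim$nu_e[n], nu_i = sim$nu_i[n], W = sim$W[n])
  for (k in 1:2000) {
    drive_e <- max(0, st$nu_e + params$nu_ext)
    Fe <- transfer_rate(drive_e, st$nu_i, st$W, params, coeffs, "e")
    Fi <- transfer_rate(drive_e, st$nu_i, 0, params, coeffs, "i")
    Ws <- params$tau_w * params$b * st$nu_e * 1e-3 +
      params$a * (conductance_stats(drive_e, st$nu_i, st$W, params, "e")$mu_V -
                    params$E_L_e)
    lam <- 0.2
    new <- list(nu_e = (1 - lam) * st$nu_e + lam * Fe,
                nu_i = (1 - lam) * st$nu_i + lam * Fi,
                W = (1 - lam) * st$W + lam * Ws)
    delta <- abs(new$nu_e - st$nu_e) + abs(new$nu_i - st$nu_i) +
      abs(new$W - st$W)
    st <- new
    if (delta < 1e-12) break
  }
  if (delta >= 1e-8) return(NULL)
  st$mu_V <- conductance_stats(max(0, st$nu_e + params$nu_ext), st$nu_i,
                               st$W, params, "e")$mu_V
  st
}

#' Classify a rate trace as asynchronous-irregular or spike-and-wave
#'
#' Labels the regime from the Welch spectrum of the (transient-trimmed)
#' excitatory rate: the trace is called SWD when the oscillation index (the
#' spectral power fraction within +/-1.5 Hz of the 1-20 Hz peak, relative to
#' total 1-20 Hz power) exceeds `osc_threshold` and the peak-to-trough rate
#' excursion exceeds `excursion_floor`; otherwise AI.
#'
#' @param trace excitatory rate series (Hz)
#' @param fs sampling rate of the trace (Hz)
#' @param transient_s initial transient discarded before analysis (s)
#' @param osc_threshold oscillation-index threshold
#' @param excursion_floor minimum peak-to-trough excursion (Hz)
#' @return list with `label` (`"AI"` or `"SWD"`), `peak_hz`, `osc_index`,
#'   `excursion_hz`
#' @export
classify_regime <- function(trace, fs, transient_s = 1, osc_threshold = 0.4,
                            excursion_floor = 5) {
  trace <- trace[-seq_len(min(length(trace) - 1, round(transient_s * fs)))]
  if (length(trace) < 5 * fs)
    stop("trace too short: need >= 5 s after the discarded transient")
  psd <- welch_psd(trace, fs, seg_len_s = 2)
  peak <- spectral_peak(psd, 1, 20)
  total <- band_power(psd, 1, 20)
  inband <- band_power(psd, max(1, peak - 1.5), min(20, peak + 1.5))
  oi <- if (total > 0) inband / total else 0
  excursion <- diff(range(trace))
  label <- if (oi > osc_threshold && excursion > excursion_floor) "SWD" else "AI"
  list(label = label, peak_hz = peak, osc_index = oi,
       excursion_hz = excursion)
}

#' Scan the adaptation strength for the AI-to-SWD transition
#'
#' Simulates a single node for each adaptation increment `b` in the grid and
#' classifies the resulting regime. Used once to calibrate the shipped
#' interictal/ictal defaults.
#'
#' @param b_grid ascending adaptation increments (pA)
#' @param params base parameters (the scan overrides `b`)
#' @param coeffs transfer coefficients
#' @param duration_s,dt,seed simulation settings shared by all grid points
#' @return data frame with columns `b_pA`, `regime`, `peak_hz`, `amplitude_hz`
#' @export
scan_adaptation <- function(b_grid, params = default_params("interictal"),
                            coeffs = default_coefficients(),
                            duration_s = 11, dt = 0.1, seed = 1) {
  if (is.unsorted(b_grid, strictly = TRUE)) stop("grid must be sorted ascending")
  rows <- lapply(b_grid, function(b) {
    p <- params
    p$b <- b
    sim <- tryCatch(simulate_node(p, coeffs, duration_s, dt, seed),
                    error = function(e)
                      stop("simulation failed at b = ", b, ": ",
                           conditionMessage(e)))
    cls <- classify_regime(sim$nu_e, sim$fs)
    data.frame(b_pA = b, regime = cls$label, peak_hz = cls$peak_hz,
               amplitude_hz = cls$excursion_hz)
  })
  do.call(rbind, rows)
}
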