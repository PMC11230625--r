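#' Monte-Carlo single-neuron oracles
#'
#' Independent brute-force references for the mean-field transfer machinery:
#' `mc_membrane_stats()` simulates a passive conductance membrane (no spike
#' mechanism) under Poisson bombardment and returns the empirical mean and
#' standard deviation of the membrane potential; `mc_neuron_rate()` simulates
#' a full spiking AdEx neuron and returns its firing rate.
#'
#' @param nu_e,nu_i presynaptic rates per synapse (Hz)
#' @param params a [node_params()] object (supplies synaptic counts and
#'   passive constants)
#' @param population `"e"` (regular spiking) or `"i"` (fast spiking)
#' @param duration_s simulated time (s)
#' @param dt integration step (ms)
#' @param transient_s discarded initial transient (s)
#' @param neuron optional override of [adex_neuron_params()]
#' @return `mc_membrane_stats()`: list with `mu_V` and `sigma_V` (mV);
#'   `mc_neuron_rate()`: firing rate (Hz)
#' @export
mc_membrane_stats <- function(nu_e, nu_i, params = node_params(),
                              population = "e", duration_s = 5, dt = 0.05,
                              transient_s = 0.5, neuron = NULL) {
  if (is.null(neuron)) neuron <- adex_neuron_params(population, params)
  K_e <- params$p_conn * params$frac_exc * params$N_tot
  K_i <- params$p_conn * (1 - params$frac_exc) * params$N_tot
  out <- adex_neuron_mc(duration_s * 1e3, dt, nu_e, nu_i, K_e, K_i,
                        neuron, TRUE, transient_s * 1e3)
  list(mu_V = out$mu_V, sigma_V = out$sigma_V)
}

#' @rdname mc_membrane_stats
#' @param W constant adaptation current (pA) injected as an offset; emulated
#'   by shifting the leak reversal by `-W / g_L`
#' @export
mc_neuron_rate <- function(nu_e, nu_i, W = 0, params = node_params(),
                           population = "e", duration_s = 10, dt = 0.05,
                           transient_s = 0.5, neuron = NULL) {
  if (is.null(neuron)) neuron <- adex_neuron_params(population, params)
  if (W != 0) neuron$E_L <- neuron$E_L - W / neuron$g_L
  K_e <- params$p_conn * params$frac_exc * params$N_tot
  K_i <- params$p_conn * (1 - params$frac_exc) * params$N_tot
  out <- adex_neuron_mc(duration_s * 1e3, dt, nu_e, nu_i, K_e, K_i,
                        neuron, FALSE, transient_s * 1e3)
  out$rate_hz
}

#' Simulate an oracle rate grid for transfer-function fitting
#'
#' Runs the spiking Monte-Carlo neuron over a grid of presynaptic rates and
#' returns the grid in the shape expected by [fit_transfer_coefficients()].
#' Multiple seeds are averaged per point.
#'
#' @param nu_e_grid,nu_i_grid rate grids (Hz); ignored when `points` is given
#' @param points optional data frame with columns `nu_e`, `nu_i` and
#'   optionally `W` (pA) giving the sampled input states directly
#' @param n_seeds independent repetitions averaged per grid point
#' @param seed base RNG seed
#' @inheritParams mc_membrane_stats
#' @return data frame with columns `nu_e`, `nu_i`, `W`, `rate`
#' @export
mc_rate_grid <- function(nu_e_grid = NULL, nu_i_grid = NULL, points = NULL,
                         params = node_params(), population = "e",
                         duration_s = 5, n_seeds = 2, seed = 42, dt = 0.05,
                         neuron = NULL) {
  pts <- if (is.null(points)) expand.grid(nu_e = nu_e_grid, nu_i = nu_i_grid)
  else as.data.frame(points)
  if (is.null(pts$W)) pts$W <- 0
  pts$rate <- vapply(seq_len(nrow(pts)), function(k) {
    rates <- vapply(seq_len(n_seeds), function(s) {
      set.seed(seed + 1000 * s + k)
      mc_neuron_rate(pts$nu_e[k], pts$nu_i[k], pts$W[k], params, population,
                     duration_s, dt, neuron = neuron)
    }, 0)
    mean(rates)
  }, 0)
  pts[, c("nu_e", "nu_i", "W", "rate")]
}

#' Default oracle sampling points for transfer-function fitting
#'
#' Input states covering the fluctuation-driven regime (inhibition scaled as
#' a multiple of excitation) up to high-rate states, plus hyperpolarized
#' states with a nonzero adaptation current for the excitatory population.
#'
#' @param population `"e"` or `"i"`
#' @return data frame with columns `nu_e`, `nu_i`, `W`
#' @export
default_fit_points <- function(population = c("e", "i")) {
  population <- match.arg(population)
  ratios <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4.5)
  nu_e <- c(1, 2, 3, 4, 6, 8, 10, 14, 18, 24, 32, 45, 60, 80, 100)
  base <- expand.grid(nu_e = nu_e, ratio = ratios)
  pts <- data.frame(nu_e = base$nu_e, nu_i = base$nu_e * base$ratio, W = 0)
  if (population == "e") {
    extra <- expand.grid(nu_e = c(6, 10, 14, 18, 24, 32, 45, 60),
                         ratio = c(0.25, 0.5, 0.75, 1.5, 3), W = c(250, 600))
    pts <- rbind(pts, data.frame(nu_e = extra$nu_e,
                                 nu_i = extra$nu_e * extra$ratio,
                                 W = extra$W))
  }
  pts
}
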