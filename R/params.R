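#' Mean-field node parameters
#'
#' Biophysical parameters of one brain region modeled as coupled excitatory
#' (RS) and inhibitory (FS) AdEx populations with spike-frequency adaptation.
#' Units follow the conductance-based convention: conductances in nS,
#' capacitance in pF, potentials in mV, time constants in ms, rates in Hz.
#'
#' @param g_L leak conductance (nS)
#' @param C_m membrane capacitance (pF)
#' @param E_L_e,E_L_i leak reversal potential of the excitatory / inhibitory
#'   population (mV)
#' @param E_e,E_i excitatory / inhibitory synaptic reversal potentials (mV)
#' @param Q_e,Q_i quantal synaptic conductances (nS)
#' @param tau_e,tau_i synaptic decay time constants (ms)
#' @param N_tot number of neurons in the population
#' @param p_conn connection probability
#' @param frac_exc excitatory fraction of the population
#' @param T population rate relaxation time constant (ms)
#' @param tau_w adaptation time constant (ms)
#' @param b spike-triggered adaptation increment (pA per Hz of excitatory rate)
#' @param a subthreshold adaptation conductance (nS)
#' @param nu_ext ambient external excitatory drive (Hz)
#' @param noise_std standard deviation of the Gaussian rate noise (Hz), applied
#'   to the excitatory population only
#' @param ceiling_e,ceiling_i refractory ceilings of the population transfer
#'   functions (Hz): the output rate cannot exceed the single-cell limit set
#'   by the absolute refractory period (regular-spiking cells are slower
#'   than fast-spiking cells)
#' @param rate_cap numerical upper bound on population rates (Hz)
#' @param sigma_eps membrane-fluctuation floor (mV) below which the transfer
#'   function degenerates to a hard threshold
#' @return an object of class `node_params` (a validated named list)
#' @export
node_params <- function(g_L = 10, C_m = 200, E_L_e = -64, E_L_i = -65,
                        E_e = 0, E_i = -80, Q_e = 1.5, Q_i = 5,
                        tau_e = 5, tau_i = 5, N_tot = 1e4, p_conn = 0.05,
                        frac_exc = 0.8, T = 5, tau_w = 50, b = 0, a = 0,
                        nu_ext = 0.5, noise_std = 0.02, ceiling_e = 100,
                        ceiling_i = 400, rate_cap = 200, sigma_eps = 1e-6) {
  p <- list(g_L = g_L, C_m = C_m, E_L_e = E_L_e, E_L_i = E_L_i,
            E_e = E_e, E_i = E_i, Q_e = Q_e, Q_i = Q_i,
            tau_e = tau_e, tau_i = tau_i, N_tot = N_tot, p_conn = p_conn,
            frac_exc = frac_exc, T = T, tau_w = tau_w, b = b, a = a,
            nu_ext = nu_ext, noise_std = noise_std, ceiling_e = ceiling_e,
            ceiling_i = ceiling_i, rate_cap = rate_cap,
            sigma_eps = sigma_eps)
  validate_node_params(p)
  class(p) <- "node_params"
  p
}

validate_node_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num))
    stop("non-finite or non-scalar parameter: ",
         paste(names(p)[!num], collapse = ", "))
  pos <- c("g_L", "C_m", "Q_e", "Q_i", "tau_e", "tau_i", "T", "tau_w",
           "N_tot", "rate_cap")
  bad <- pos[vapply(pos, function(f) p[[f]] <= 0, logical(1))]
  if (length(bad))
    stop("parameters must be > 0: ", paste(bad, collapse = ", "))
  if (p$frac_exc <= 0 || p$frac_exc >= 1) stop("frac_exc must lie in (0, 1)")
  if (p$p_conn < 0 || p$p_conn > 1) stop("p_conn must lie in [0, 1]")
  if (!(p$E_i < p$E_L_e && p$E_L_e < p$E_e))
    stop("reversal potentials must satisfy E_i < E_L_e < E_e")
  invisible(p)
}

#' Shipped default parameter sets for the two brain states
#'
#' Returns the calibrated parameter set for the interictal
#' (asynchronous-irregular) or ictal (spike-and-wave) regime. The two differ
#' only in the spike-triggered adaptation strength `b`: the values were fixed
#' once by an adaptation scan ([scan_adaptation()]) as the largest `b` still
#' yielding AI dynamics and the smallest `b` whose oscillation peak falls in
#' the 7-12 Hz SWD band of the GAERS rat.
#'
#' @param state `"interictal"` or `"ictal"`
#' @param ... overrides passed to [node_params()]
#' @return a `node_params` object
#' @export
default_params <- function(state = c("interictal", "ictal"), ...) {
  state <- match.arg(state)
  b <- if (state == "ictal") .gaersim_defaults$b_ictal else
    .gaersim_defaults$b_interictal
  node_params(b = b, ...)
}

# calibrated regime constants (see the adaptation-scan analysis script)
.gaersim_defaults <- new.env(parent = emptyenv())
.gaersim_defaults$b_interictal <- 300
.gaersim_defaults$b_ictal <- 400

#' Transfer-function coefficients for both populations
#'
#' Houses the semi-analytic transfer function's effective-threshold
#' polynomial: 11 coefficients (mV) per population (second-order polynomial
#' in the three normalized membrane statistics, plus one trilinear cross
#' term) and the six normalization constants.
#'
#' @param P_e,P_i numeric vectors of 11 polynomial coefficients (mV) for the
#'   excitatory (RS) and inhibitory (FS) population
#' @param norm normalization constants
#'   `c(muV0, dmuV0, sigmaV0, dsigmaV0, tauVN0, dtauVN0)`; deltas must be
#'   nonzero
#' @return an object of class `transfer_coefficients`
#' @export
transfer_coefficients <- function(P_e, P_i,
                                  norm = c(muV0 = -60, dmuV0 = 10,
                                           sigmaV0 = 4, dsigmaV0 = 6,
                                           tauVN0 = 0.5, dtauVN0 = 1)) {
  if (length(P_e) != 11 || length(P_i) != 11)
    stop("exactly 11 coefficients are required per population")
  if (length(norm) != 6 || any(!is.finite(norm)))
    stop("norm must be 6 finite normalization constants")
  if (any(norm[c(2, 4, 6)] == 0))
    stop("normalization deltas must be nonzero")
  obj <- list(P_e = as.numeric(P_e), P_i = as.numeric(P_i),
              norm = as.numeric(norm))
  class(obj) <- "transfer_coefficients"
  obj
}

#' Read / write transfer coefficients as TSV
#'
#' The shipped coefficient table is plain text: one row per coefficient with
#' columns `population` (`e`, `i`, or `norm`), `name` and `value`.
#'
#' @param path file path
#' @return for the reader, a `transfer_coefficients` object
#' @export
read_transfer_coefficients <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  pe <- tab$value[tab$population == "e"]
  pi_ <- tab$value[tab$population == "i"]
  nm <- tab$value[tab$population == "norm"]
  transfer_coefficients(pe, pi_, nm)
}

#' @rdname read_transfer_coefficients
#' @param coeffs a `transfer_coefficients` object
#' @export
write_transfer_coefficients <- function(coeffs, path) {
  tab <- data.frame(
    population = c(rep("e", 11), rep("i", 11), rep("norm", 6)),
    name = c(paste0("P", 0:10), paste0("P", 0:10),
             c("muV0", "dmuV0", "sigmaV0", "dsigmaV0", "tauVN0", "dtauVN0")),
    value = c(coeffs$P_e, coeffs$P_i, coeffs$norm))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default (shipped) transfer coefficients
#'
#' Loads the coefficient table shipped with the package, produced by
#' [fit_transfer_coefficients()] against the in-repo single-neuron
#' Monte-Carlo oracle (see the transfer-fit analysis script).
#'
#' @return a `transfer_coefficients` object
#' @export
default_coefficients <- function() {
  path <- system.file("extdata", "transfer_coefficients.tsv",
                      package = "gaersim")
  if (!nzchar(path)) stop("shipped coefficient table not found")
  read_transfer_coefficients(path)
}

#' Single-neuron AdEx parameters for the Monte-Carlo oracle
#'
#' Parameters of the spiking AdEx neuron used to fit and validate the
#' mean-field transfer function. `population = "e"` gives a regular-spiking
#' cell; `"i"` a fast-spiking cell with smaller spike sharpness, a shorter
#' refractory period (so inhibition outpaces excitation at sustained high
#' rates) and a raised spike threshold (-49 mV), encoding the depressed
#' cortical inhibition hypothesized in the GAERS model of absence epilepsy.
#'
#' @param population `"e"` or `"i"`
#' @param params the matching `node_params` (shares the passive membrane and
#'   synaptic constants)
#' @return a named list of single-neuron parameters
#' @export
adex_neuron_params <- function(population = c("e", "i"),
                               params = node_params()) {
  population <- match.arg(population)
  list(C_m = params$C_m, g_L = params$g_L,
       E_L = if (population == "e") params$E_L_e else params$E_L_i,
       E_e = params$E_e, E_i = params$E_i,
       Q_e = params$Q_e, Q_i = params$Q_i,
       tau_e = params$tau_e, tau_i = params$tau_i,
       V_T = if (population == "e") -50 else -49,
       Delta_T = if (population == "e") 2 else 0.5,
       V_reset = if (population == "e") params$E_L_e else params$E_L_i,
       t_ref = if (population == "e") 10 else 2.5, a = 0, b = 0, tau_w = params$tau_w, V_spike = -30)
}
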