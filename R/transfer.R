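#' Membrane-potential statistics under synaptic bombardment
#'
#' Computes the mean, standard deviation and autocorrelation time of the
#' membrane potential of a conductance-based neuron receiving Poissonian
#' excitatory and inhibitory input at the given presynaptic rates, plus the
#' effective membrane time constant. This is the first stage of the
#' semi-analytic mean-field transfer function.
#'
#' With `K_e = p_conn * frac_exc * N_tot` and
#' `K_i = p_conn * (1 - frac_exc) * N_tot`:
#' `mu_Gs = K_s nu_s tau_s Q_s`, `mu_G = g_L + mu_Ge + mu_Gi`,
#' `tau_m = C_m / mu_G`,
#' `mu_V = (mu_Ge E_e + mu_Gi E_i + g_L E_L - W) / mu_G`,
#' `U_s = (Q_s / mu_G)(E_s - mu_V)`,
#' `sigma_V = sqrt(sum_s K_s nu_s (U_s tau_s)^2 / (2 (tau_m + tau_s)))`, and
#' `tau_V` is the ratio of the corresponding weighted sums (equal to `tau_m`
#' in the zero-input limit).
#'
#' @param nu_e_in,nu_i_in presynaptic excitatory / inhibitory rates (Hz)
#' @param W adaptation current (pA)
#' @param params a [node_params()] object
#' @param population which population receives the input (`"e"` or `"i"`);
#'   selects the leak reversal
#' @return a named list with `mu_V` (mV), `sigma_V` (mV), `tau_V` (ms) and
#'   `tau_m_eff` (ms)
#' @export
conductance_stats <- function(nu_e_in, nu_i_in, W, params,
                              population = c("e", "i")) {
  population <- match.arg(population)
  for (nm in c("nu_e_in", "nu_i_in", "W")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("non-finite input: ", nm)
  }
  if (nu_e_in < 0 || nu_i_in < 0) stop("input rates must be >= 0")
  E_L <- if (population == "e") params$E_L_e else params$E_L_i
  K_e <- params$p_conn * params$frac_exc * params$N_tot
  K_i <- params$p_conn * (1 - params$frac_exc) * params$N_tot
  nu_e <- nu_e_in * 1e-3   # kHz so that nu * tau is dimensionless
  nu_i <- nu_i_in * 1e-3
  mu_Ge <- K_e * nu_e * params$tau_e * params$Q_e
  mu_Gi <- K_i * nu_i * params$tau_i * params$Q_i
  mu_G <- params$g_L + mu_Ge + mu_Gi
  tau_m <- params$C_m / mu_G
  mu_V <- (mu_Ge * params$E_e + mu_Gi * params$E_i + params$g_L * E_L - W) / mu_G
  U_e <- (params$Q_e / mu_G) * (params$E_e - mu_V)
  U_i <- (params$Q_i / mu_G) * (params$E_i - mu_V)
  s_e <- K_e * nu_e * (U_e * params$tau_e)^2
  s_i <- K_i * nu_i * (U_i * params$tau_i)^2
  d_e <- s_e / (tau_m + params$tau_e)
  d_i <- s_i / (tau_m + params$tau_i)
  sigma_V <- sqrt(max(0, (d_e + d_i) / 2))
  tau_V <- if ((d_e + d_i) > 0) (s_e + s_i) / (d_e + d_i) else tau_m
  list(mu_V = mu_V, sigma_V = sigma_V, tau_V = tau_V, tau_m_eff = tau_m,
       mu_G = mu_G)
}

# polynomial basis of the effective threshold: second order in the three
# normalized membrane statistics plus one trilinear term (11 terms)
threshold_basis <- function(mu_V, sigma_V, tau_VN, norm) {
  x1 <- (mu_V - norm[1]) / norm[2]
  x2 <- (sigma_V - norm[3]) / norm[4]
  x3 <- (tau_VN - norm[5]) / norm[6]
  cbind(1, x1, x2, x3, x1^2, x2^2, x3^2, x1 * x2, x1 * x3, x2 * x3,
        x1 * x2 * x3)
}

#' Effective firing threshold (mV)
#'
#' Evaluates the fitted threshold polynomial for one population at the given
#' input statistics.
#'
#' @inheritParams conductance_stats
#' @param coeffs a [transfer_coefficients()] object
#' @return effective threshold (mV)
#' @export
effective_threshold <- function(nu_e_in, nu_i_in, W, params, coeffs,
                                population = c("e", "i")) {
  population <- match.arg(population)
  st <- conductance_stats(nu_e_in, nu_i_in, W, params, population)
  P <- if (population == "e") coeffs$P_e else coeffs$P_i
  tau_VN <- st$tau_V * st$mu_G / params$C_m
  drop(threshold_basis(st$mu_V, st$sigma_V, tau_VN, coeffs$norm) %*% P)
}

#' Semi-analytic population transfer function
#'
#' Output firing rate of one population given its presynaptic rates and
#' adaptation current:
#' `rate = erfc((V_thr_eff - mu_V) / (sqrt(2) sigma_V)) / (2 tau_V)`,
#' where `V_thr_eff` is the fitted effective-threshold polynomial. In the
#' fluctuation-free limit (`sigma_V` below `params$sigma_eps`) the transfer
#' degenerates to a hard threshold: 0 below `V_thr_eff`, `1 / tau_V` above.
#'
#' @inheritParams effective_threshold
#' @return firing rate (Hz), bounded by `1000 / tau_V` and by the
#'   population's refractory ceiling
#' @export
transfer_rate <- function(nu_e_in, nu_i_in, W, params, coeffs,
                          population = c("e", "i")) {
  population <- match.arg(population)
  if (!inherits(coeffs, "transfer_coefficients"))
    stop("missing or invalid transfer coefficients")
  st <- conductance_stats(nu_e_in, nu_i_in, W, params, population)
  P <- if (population == "e") coeffs$P_e else coeffs$P_i
  tau_VN <- st$tau_V * st$mu_G / params$C_m
  V_thr <- drop(threshold_basis(st$mu_V, st$sigma_V, tau_VN, coeffs$norm) %*% P)
  if (st$sigma_V < params$sigma_eps) {
    rate_khz <- if (st$mu_V < V_thr) 0 else 1 / st$tau_V
  } else {
    z <- (V_thr - st$mu_V) / (sqrt(2) * st$sigma_V)
    rate_khz <- 0.5 * erfc(z) / st$tau_V
  }
  ceiling_hz <- if (population == "e") params$ceiling_e else params$ceiling_i
  min(rate_khz * 1e3, ceiling_hz)
}

erfc <- function(x) 2 * pnorm(-x * sqrt(2))
erfcinv <- function(y) -qnorm(y / 2) / sqrt(2)

#' Fit transfer-function coefficients to an oracle rate grid
#'
#' Reproduces the published fitting recipe: at each grid point the measured
#' rate is inverted through the erfc relation to an empirical effective
#' threshold, which is then least-squares fitted by the threshold polynomial.
#'
#' @param grid data frame with columns `nu_e`, `nu_i` (Hz), optionally `W`
#'   (pA, default 0), and `rate` (Hz) from a single-neuron simulation
#' @param params a [node_params()] object
#' @param population which population the grid describes
#' @param norm normalization constants (see [transfer_coefficients()])
#' @param rms_tol warn if the refitted transfer function misses the oracle
#'   rates by more than this RMS error (Hz)
#' @return list with the 11 fitted coefficients `P`, the achieved `rms` (Hz,
#'   over the invertible sub-saturation grid points the erfc form can
#'   represent) and the empirical thresholds used
#' @export
fit_transfer_coefficients <- function(grid, params, population = c("e", "i"),
                                      norm = c(-60, 10, 4, 6, 0.5, 1),
                                      rms_tol = 5) {
  population <- match.arg(population)
  if (!all(c("nu_e", "nu_i", "rate") %in% names(grid)))
    stop("grid must have columns nu_e, nu_i, rate")
  if (is.null(grid$W)) grid$W <- 0
  keep <- grid$rate > 0
  if (sum(keep) < 30)
    stop("fitting error: grid must cover >= 30 points with nonzero rates")
  g <- grid[keep, ]
  stats_list <- lapply(seq_len(nrow(g)), function(k)
    conductance_stats(g$nu_e[k], g$nu_i[k], g$W[k], params, population))
  mu_V <- vapply(stats_list, `[[`, 0, "mu_V")
  sigma_V <- vapply(stats_list, `[[`, 0, "sigma_V")
  tau_V <- vapply(stats_list, `[[`, 0, "tau_V")
  mu_G <- vapply(stats_list, `[[`, 0, "mu_G")
  # invert erfc relation; points at/above half saturation cannot be inverted
  arg <- 2 * (g$rate * 1e-3) * tau_V
  ok <- arg > 0 & arg < 2 & sigma_V > 0
  if (sum(ok) < 30)
    stop("fitting error: fewer than 30 invertible grid points")
  V_emp <- mu_V[ok] + sqrt(2) * sigma_V[ok] * erfcinv(arg[ok])
  X <- threshold_basis(mu_V[ok], sigma_V[ok], tau_V[ok] * mu_G[ok] / params$C_m,
                       norm)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("fitting error: degenerate/collinear grid (rank ",
         qx$rank, " < ", ncol(X), ")")
  P <- qr.coef(qx, V_emp)
  co <- transfer_coefficients(P, P, norm)
  gf <- g[ok, ]
  pred <- vapply(seq_len(nrow(gf)), function(k)
    transfer_rate(gf$nu_e[k], gf$nu_i[k], gf$W[k], params, co, population), 0)
  rms <- sqrt(mean((pred - gf$rate)^2))
  if (rms > rms_tol)
    warning(sprintf("transfer fit RMS error %.2f Hz exceeds tolerance %.2f Hz",
                    rms, rms_tol))
  list(P = as.numeric(P), rms = rms, norm = norm, n_used = sum(ok),
       thresholds = data.frame(mu_V = mu_V[ok], sigma_V = sigma_V[ok],
                               V_thr = V_emp))
}
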