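#' LFP kernel parameters
#'
#' Parameters of the kernel-method LFP proxy: the LFP is modeled as the sum
#' of the excitatory and inhibitory population rates convolved with unit-area
#' Gaussian kernels, each with its own amplitude, width and delay. The
#' inhibitory amplitude is typically negative and larger in magnitude, which
#' yields the sharp negative deflection of the spike-and-wave pattern.
#'
#' @param A_e,A_i kernel amplitudes (arbitrary units)
#' @param sigma_e,sigma_i Gaussian kernel widths (ms)
#' @param d_e,d_i kernel delays (ms)
#' @return an object of class `lfp_kernel_params`
#' @export
lfp_kernel_params <- function(A_e = 1, A_i = -1.6, sigma_e = 2.1,
                              sigma_i = 2.1, d_e = 1.5, d_i = 0.5) {
  if (sigma_e <= 0 || sigma_i <= 0) stop("kernel widths must be > 0")
  if (d_e < 0 || d_i < 0) stop("kernel delays must be >= 0")
  structure(list(A_e = A_e, A_i = A_i, sigma_e = sigma_e, sigma_i = sigma_i,
                 d_e = d_e, d_i = d_i), class = "lfp_kernel_params")
}

# discrete unit-area Gaussian kernel centered at `delay` (ms)
gauss_kernel <- function(sigma_ms, delay_ms, fs) {
  dt_ms <- 1e3 / fs
  half <- ceiling((4 * sigma_ms + delay_ms) / dt_ms)
  t <- (-half:half) * dt_ms
  k <- exp(-(t - delay_ms)^2 / (2 * sigma_ms^2))
  k / sum(k)
}

#' Kernel-method LFP from population rates
#'
#' `LFP(t) = A_e (G_e * nu_e)(t - d_e) + A_i (G_i * nu_i)(t - d_i)` with
#' unit-area Gaussian kernels `G`. Linear in each rate input and zero-phase
#' apart from the stated delays.
#'
#' @param nu_e,nu_i excitatory / inhibitory rate series (Hz), equal length
#' @param fs sampling rate (Hz)
#' @param params an [lfp_kernel_params()] object
#' @return LFP series (same length as the inputs, arbitrary units)
#' @export
compute_lfp <- function(nu_e, nu_i, fs, params = lfp_kernel_params()) {
  if (length(nu_e) != length(nu_i)) stop("rate series must have equal length")
  if (min(params$sigma_e, params$sigma_i) < 2e3 / fs)
    stop("sampling rate too low to resolve the kernels (sigma < 2 samples)")
  conv_same <- function(x, k) {
    half <- (length(k) - 1) / 2
    out <- stats::convolve(c(rep(0, half), x, rep(0, half)), rev(k),
                           type = "filter")
    out
  }
  params$A_e * conv_same(nu_e, gauss_kernel(params$sigma_e, params$d_e, fs)) +
    params$A_i * conv_same(nu_i, gauss_kernel(params$sigma_i, params$d_i, fs))
}

#' Third-order gamma basis for the hemodynamic response
#'
#' Builds the three unit-peak gamma-shaped basis functions used to model the
#' HRF: column `k` is the gamma density with the given `(shape, scale)`,
#' normalized to unit peak height, sampled every `TR` seconds. Each column
#' peaks at `(shape - 1) * scale` seconds.
#'
#' @param TR sampling interval (s)
#' @param duration basis support (s); must cover the slowest peak plus
#'   three scales
#' @param shapes list of three `c(shape, scale)` pairs (shape > 1)
#' @return an object of class `hrf_basis` with elements `TR`, `duration`,
#'   `shapes`, `time` and `matrix` (samples x 3)
#' @export
gamma_basis <- function(TR = 2, duration = 20,
                        shapes = list(c(3, 1), c(5, 1), c(7, 1))) {
  if (length(shapes) != 3) stop("exactly 3 gamma basis functions are required")
  for (s in shapes) {
    if (s[1] <= 1) stop("gamma shape must be > 1 for an interior peak")
    if (duration < (s[1] - 1) * s[2] + 3 * s[2])
      stop("duration must cover the latest peak plus 3 scales")
  }
  time <- seq(0, duration, by = TR)
  mat <- vapply(shapes, function(s) gamma_unit_peak(time, s[1], s[2]),
                numeric(length(time)))
  structure(list(TR = TR, duration = duration, shapes = shapes,
                 time = time, matrix = mat), class = "hrf_basis")
}

# gamma density normalized to unit peak height
gamma_unit_peak <- function(t, shape, scale) {
  peak <- dgamma((shape - 1) * scale, shape = shape, scale = scale)
  dgamma(t, shape = shape, scale = scale) / peak
}

#' Reconstruct an HRF from basis betas
#'
#' The HRF estimate is the beta-weighted sum of the three gamma basis
#' functions, on the basis sampling grid.
#'
#' @param betas numeric vector of 3 regression coefficients
#' @param basis an [gamma_basis()] object
#' @return data frame with columns `time` (s) and `hrf`
#' @export
hrf_from_betas <- function(betas, basis) {
  if (length(betas) != 3 || any(!is.finite(betas)))
    stop("betas must be 3 finite values")
  data.frame(time = basis$time, hrf = drop(basis$matrix %*% betas))
}

#' Extreme (maximum-magnitude) value with sign preserved
#'
#' Returns the element of largest absolute magnitude, keeping its sign; exact
#' ties between a negative and a positive value of equal magnitude resolve to
#' the positive one.
#'
#' @param x numeric vector (e.g. an HRF curve or ROI beta values)
#' @return signed extreme value
#' @export
extreme_beta <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("input must be non-empty")
  m <- max(abs(x))
  if (m %in% x) m else -m
}
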