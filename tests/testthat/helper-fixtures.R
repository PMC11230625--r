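# shared fixtures; everything is generated in code, nothing on disk

fix_params <- gaersim::node_params()
fix_coeffs <- gaersim::default_coefficients()
fix_basis <- gaersim::gamma_basis(TR = 2)

empty_intervals <- data.frame(start = numeric(0), end = numeric(0))

# small modular connectome used across network tests
small_connectome <- function(n = 12, seed = 5) {
  gaersim::make_connectome(n, n_modules = 3, density = 0.25, seed = seed)
}

# classified blocks for a simple interictal-only session
plain_blocks <- function(onsets, duration = 6) {
  gaersim::classify_stimulations(
    data.frame(onset = onsets, duration = duration), empty_intervals)
}

# synthetic fMRI with one active ROI, returning everything needed for a fit
roi_fmri <- function(dims = c(10, 10, 6), n_volumes = 120, betas = c(2, 1, -0.5),
                     noise = list(sd = 0, ar = 0), seed = 3,
                     onsets = seq(20, 200, by = 30)) {
  roi <- array(FALSE, dims)
  roi[3:5, 3:5, 2:4] <- TRUE
  ev <- data.frame(onset = onsets, duration = 6, condition = "interictal_stim")
  fm <- gaersim::make_fmri(dims, TR = 2, n_volumes = n_volumes,
                           design_events = ev,
                           roi_beta_maps = list(interictal_stim =
                                                  list(roi = roi, betas = betas)),
                           basis = fix_basis, noise = noise, seed = seed)
  dsn <- gaersim::build_design(plain_blocks(ev$onset), empty_intervals,
                               NULL, fix_basis, fm$frame_times)
  list(fm = fm, roi = roi, design = dsn, events = ev)
}
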