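test_that("membrane statistics have the correct quiescent and adaptation limits", {
  st0 <- conductance_stats(0, 0, 0, fix_params, "e")
  expect_equal(st0$mu_V, fix_params$E_L_e)
  expect_equal(st0$sigma_V, 0)
  expect_equal(st0$tau_V, st0$tau_m_eff)

  st0i <- conductance_stats(0, 0, 0, fix_params, "i")
  expect_equal(st0i$mu_V, fix_params$E_L_i)

  # adaptation current hyperpolarizes
  stW <- conductance_stats(5, 5, 100, fix_params, "e")
  st <- conductance_stats(5, 5, 0, fix_params, "e")
  expect_lt(stW$mu_V, st$mu_V)

  # bounds over a grid
  for (ne in c(0, 1, 10, 50)) for (ni in c(0, 1, 10, 50)) {
    s <- conductance_stats(ne, ni, 0, fix_params, "e")
    expect_gte(s$mu_V, fix_params$E_i)
    expect_lte(s$mu_V, fix_params$E_e)
    expect_gte(s$sigma_V, 0)
    expect_gt(s$tau_V, 0)
    expect_gt(s$tau_m_eff, 0)
  }
})

test_that("non-finite membrane inputs are rejected by name", {
  expect_error(conductance_stats(NaN, 0, 0, fix_params), "nu_e_in")
  expect_error(conductance_stats(0, Inf, 0, fix_params), "nu_i_in")
  expect_error(conductance_stats(0, 0, NA_real_, fix_params), "W")
})

test_that("analytic membrane statistics match a Monte-Carlo membrane", {
  # brute-force single-compartment conductance simulation as the oracle
  grid <- expand.grid(nu_e = c(1, 5, 10), nu_i = c(1, 5, 10))
  for (k in seq_len(nrow(grid))) {
    set.seed(400 + k)
    mc <- mc_membrane_stats(grid$nu_e[k], grid$nu_i[k], fix_params,
                            duration_s = 8)
    an <- conductance_stats(grid$nu_e[k], grid$nu_i[k], 0, fix_params, "e")
    expect_lt(abs(mc$mu_V - an$mu_V), 1)                      # 1 mV
    expect_lt(abs(mc$sigma_V - an$sigma_V) / an$sigma_V, 0.15) # 15%
  }
})

test_that("transfer rate halves exactly at the effective threshold", {
  # constant-threshold coefficient set: V_thr == P0 everywhere
  st <- conductance_stats(5, 5, 0, fix_params, "e")
  co <- transfer_coefficients(c(st$mu_V, rep(0, 10)), c(st$mu_V, rep(0, 10)))
  r <- transfer_rate(5, 5, 0, fix_params, co, "e")
  expect_equal(r, 1e3 / (2 * st$tau_V), tolerance = 1e-10)
})

test_that("transfer rate is monotone over the default input box", {
  # excitation: strictly non-decreasing everywhere on the 5^3 grid;
  # inhibition and adaptation: non-increasing up to the polynomial's fit
  # noise (RMS a few Hz) inside the calibrated inhibition/excitation cone
  ne_grid <- c(1, 3, 6, 10, 16)
  ni_grid <- c(1, 3, 6, 10, 16)
  W_grid <- c(0, 60, 150, 300, 600)
  in_cone <- function(ne, ni) ni / ne >= 0.25 & ni / ne <= 4.5
  tol <- 2.5
  rate <- function(ne, ni, W)
    transfer_rate(ne, ni, W, fix_params, fix_coeffs, "e")
  for (ni in ni_grid) for (W in W_grid) {
    r <- vapply(ne_grid, rate, 0, ni = ni, W = W)
    expect_true(all(diff(r) >= -1e-9))
  }
  for (ne in ne_grid) for (W in W_grid) {
    keep <- in_cone(ne, ni_grid)
    r <- vapply(ni_grid[keep], function(ni) rate(ne, ni, W), 0)
    if (length(r) > 1) expect_true(all(diff(r) <= tol))
  }
  for (ne in ne_grid) for (ni in ni_grid[in_cone(ne, ni_grid)]) {
    r <- vapply(W_grid, function(W) rate(ne, ni, W), 0)
    expect_true(all(diff(r) <= tol))
  }
})

test_that("fluctuation-free limit degenerates to a hard threshold", {
  # constructed constant thresholds above / below the resting potential
  co_high <- transfer_coefficients(c(-10, rep(0, 10)), c(-10, rep(0, 10)))
  expect_equal(transfer_rate(0, 0, 0, fix_params, co_high, "e"), 0)
  co_low <- transfer_coefficients(c(-80, rep(0, 10)), c(-80, rep(0, 10)))
  st <- conductance_stats(0, 0, 0, fix_params, "e")
  expect_equal(transfer_rate(0, 0, 0, fix_params, co_low, "e"),
               min(1e3 / st$tau_V, fix_params$ceiling_e), tolerance = 1e-10)
})

test_that("transfer rate never exceeds its saturation bound", {
  for (ne in c(1, 5, 20, 60)) for (ni in c(1, 5, 20)) {
    st <- conductance_stats(ne, ni, 0, fix_params, "e")
    r <- transfer_rate(ne, ni, 0, fix_params, fix_coeffs, "e")
    expect_gte(r, 0)
    expect_lte(r, 1e3 / st$tau_V + 1e-9)
  }
})

test_that("coefficient fitting round-trips a known threshold surface", {
  # oracle generated from an existing coefficient set, fit recovers it
  pts <- default_fit_points("e")
  pts <- pts[pts$W == 0, ]
  pts$rate <- vapply(seq_len(nrow(pts)), function(k)
    transfer_rate(pts$nu_e[k], pts$nu_i[k], 0, fix_params, fix_coeffs, "e"), 0)
  fit <- fit_transfer_coefficients(pts, fix_params, "e")
  co2 <- transfer_coefficients(fit$P, fit$P)
  for (k in seq(1, nrow(pts), by = 7)) {
    v1 <- effective_threshold(pts$nu_e[k], pts$nu_i[k], 0, fix_params,
                              fix_coeffs, "e")
    v2 <- effective_threshold(pts$nu_e[k], pts$nu_i[k], 0, fix_params,
                              co2, "e")
    expect_lt(abs(v1 - v2), 0.5)
  }
  expect_lt(fit$rms, 1)
})

test_that("degenerate fitting grids are rejected", {
  pts <- data.frame(nu_e = rep(5, 40), nu_i = rep(5, 40), rate = rep(10, 40))
  expect_error(fit_transfer_coefficients(pts, fix_params, "e"),
               "degenerate|collinear")
  zero <- data.frame(nu_e = 1:40, nu_i = 1:40, rate = 0)
  expect_error(fit_transfer_coefficients(zero, fix_params, "e"),
               "fitting error")
})

test_that("R and compiled transfer evaluations agree", {
  for (ne in c(0.5, 4, 15)) for (ni in c(1, 8)) for (W in c(0, 120)) {
    r_r <- transfer_rate(ne, ni, W, fix_params, fix_coeffs, "e")
    r_c <- mf_transfer_cpp(ne, ni, W, "e", unclass(fix_params),
                           gaersim:::coeffs_list(fix_coeffs))
    expect_equal(r_r, unname(r_c["rate_hz"]), tolerance = 1e-10)
  }
})
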