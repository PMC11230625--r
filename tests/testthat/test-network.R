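test_that("pulse trains have the printed counts and duty cycles", {
  tg <- seq(0, 10, by = 1e-3)
  # visual protocol: 3 Hz, 166 ms pulses, 6 s blocks -> 18 pulses
  vis <- preset_protocol("visual", target_regions = "A", amplitude = 10,
                         onsets = 1)
  s <- build_stimulus(vis, tg, c("A", "B"))
  expect_true(all(s %in% c(0, 10)))
  expect_true(all(s["B", ] == 0))
  on <- s["A", ] > 0
  expect_equal(sum(diff(on) == 1) + on[1], 18)
  # whisker protocol: 2 Hz, 250 ms -> 12 pulses, integral 12 * 0.25 * amp
  whi <- preset_protocol("whisker", target_regions = "A", amplitude = 8,
                         onsets = 1)
  sw <- build_stimulus(whi, tg, c("A", "B"))
  onw <- sw["A", ] > 0
  expect_equal(sum(diff(onw) == 1) + onw[1], 12)
  expect_equal(sum(sw["A", ]) * 1e-3, 12 * 0.25 * 8, tolerance = 0.01)

  # amplitude zero is identically zero
  z <- build_stimulus(preset_protocol("visual", target_regions = "A",
                                      amplitude = 0, onsets = 1), tg, c("A", "B"))
  expect_true(all(z == 0))
  # block past the grid end errors
  expect_error(build_stimulus(preset_protocol("visual", target_regions = "A",
                                              onsets = 6), tg, c("A", "B")),
               "past")
  expect_error(build_stimulus(vis, tg, c("B", "C")), "target")
})

test_that("zero coupling reproduces independent single-node simulations exactly", {
  cn <- small_connectome(4)
  prot <- preset_protocol("visual", target_regions = cn$labels[1],
                          amplitude = 0)
  p <- default_params("interictal")
  cfg <- sim_config(duration = 3, seed = 17, coupling_scale = 0)
  net <- simulate_network(cn, p, prot, cfg)
  init <- gaersim:::settle_state(p, fix_coeffs, dt = cfg$dt)
  for (r in c(1, 3)) {
    node <- simulate_node(p, fix_coeffs, duration_s = 3, dt = cfg$dt,
                          seed = 17, stream_offset = r - 1, init = init)
    expect_identical(net$nu_e[r, ], node$nu_e)
    expect_identical(net$W[r, ], node$W)
  }
  # weights are irrelevant at S = 0
  cn2 <- connectome(matrix(5, 4, 4) - diag(5, 4), cn$labels)
  net2 <- simulate_network(cn2, p, prot, cfg)
  expect_identical(net$nu_e, net2$nu_e)
})

test_that("a localized stimulus only affects the target at zero coupling", {
  cn <- small_connectome(4)
  p <- default_params("interictal")
  cfg <- sim_config(duration = 4, seed = 8, coupling_scale = 0)
  off <- simulate_network(cn, p, preset_protocol("visual",
                                                 target_regions = cn$labels[2],
                                                 amplitude = 0), cfg)
  on <- simulate_network(cn, p, preset_protocol("visual",
                                                target_regions = cn$labels[2],
                                                amplitude = 20, onsets = 1.5),
                         cfg)
  expect_false(identical(on$nu_e[2, ], off$nu_e[2, ]))
  for (r in c(1, 3, 4)) expect_identical(on$nu_e[r, ], off$nu_e[r, ])
})

test_that("a zero-weight region never alters the others", {
  cn <- small_connectome(5)
  w6 <- rbind(cbind(cn$weights, 0), 0)
  cn6 <- connectome(w6, c(cn$labels, "ISOLATE"))
  prot <- preset_protocol("visual", target_regions = cn$labels[1],
                          amplitude = 20, onsets = 1.5)
  cfg <- sim_config(duration = 4, seed = 21)
  a <- simulate_network(cn, NULL, prot, cfg)
  b <- simulate_network(cn6, NULL, prot, cfg)
  expect_identical(a$nu_e, b$nu_e[1:5, ])
})

test_that("stimulus response propagates down an excitatory chain", {
  # mild adaptation keeps the relay in its linear regime: with the strong
  # calibrated interictal adaptation, pulsed relayed input is net-suppressive
  w <- matrix(0, 3, 3)
  w[2, 1] <- 1   # A -> B
  w[3, 2] <- 1   # B -> C
  cn <- connectome(w, c("A", "B", "C"))
  ons <- seq(8, by = 26, length.out = 8)
  prot <- stimulus_protocol("A", amplitude = 30, pulse_freq = 1,
                            pulse_width = 950, block_duration = 6,
                            onsets = ons)
  cfg <- sim_config(duration = max(ons) + 10, seed = 5, coupling_scale = 0.3)
  sim <- simulate_network(cn, node_params(b = 100), prot, cfg)
  inblock <- rowSums(sapply(ons, function(o)
    sim$time >= o & sim$time < o + 6)) > 0
  base <- rowMeans(sim$nu_e[, !inblock & sim$time > 1])
  stim <- rowMeans(sim$nu_e[, inblock])
  delta <- stim - base
  expect_gt(delta[1], delta[2])
  expect_gt(delta[2], delta[3])
  expect_gt(delta[3], 0)
})

test_that("responsiveness statistics are exchangeable under a null protocol", {
  cn <- small_connectome(12)
  prot <- preset_protocol("visual", target_regions = "V1", amplitude = 0,
                          block_duration = 3)
  cfg <- sim_config(seed = 7, state = "interictal")
  rs <- responsiveness_map(cn, NULL, prot, cfg, n_trials = 20, trial_gap = 4,
                           trial_jitter = 2)
  # corrected false positives under the null
  expect_equal(count_significant(rs), 0)
  expect_true(all(rs$p >= 0 & rs$p <= 1))
  # uncorrected p-values roughly uniform: fraction below 0.2 bounded
  expect_lt(mean(rs$p < 0.2), 0.2 + 2 * sqrt(0.2 * 0.8 / nrow(rs)) + 0.25)
})

test_that("count_significant equals the brute-force flag sum", {
  df <- data.frame(significant = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(count_significant(df), 3)
  expect_equal(count_significant(data.frame(significant = logical(0))), 0)
  expect_error(count_significant(data.frame(x = 1)), "flag")
})

test_that("grid layout is a deterministic near-square injection", {
  g4 <- grid_layout(letters[1:4])
  expect_equal(max(g4$row), 2)
  expect_equal(max(g4$col), 2)
  labs <- sprintf("r%03d", 1:496)
  g <- grid_layout(labs)
  expect_equal(nrow(g), 496)
  expect_false(any(duplicated(g[, c("row", "col")])))
  expect_lte(max(g$row) * max(g$col), ceiling(sqrt(496))^2)
  expect_identical(g, grid_layout(labs))
  expect_error(grid_layout(c("a", "a")), "unique")
})

test_that("delayed coupling shifts the arrival of a propagated response", {
  w <- matrix(0, 2, 2)
  w[2, 1] <- 1
  delays <- matrix(0, 2, 2)
  delays[2, 1] <- 50   # ms
  cn0 <- connectome(w, c("SRC", "DST"))
  cnD <- connectome(w, c("SRC", "DST"), delays = delays)
  prot <- preset_protocol("visual", target_regions = "SRC", amplitude = 60,
                          onsets = 2)
  cfg <- sim_config(duration = 9, seed = 4, state = "interictal",
                    coupling_scale = 0.3)
  s0 <- simulate_network(cn0, NULL, prot, cfg)
  sD <- simulate_network(cnD, NULL, prot, cfg)
  # cross-correlation peak of DST responses shifted by the delay
  r0 <- s0$nu_e[2, ] - mean(s0$nu_e[2, ])
  rD <- sD$nu_e[2, ] - mean(sD$nu_e[2, ])
  cc <- stats::ccf(rD, r0, lag.max = 100, plot = FALSE)
  shift_ms <- cc$lag[which.max(cc$acf)] * 1000 / s0$fs
  expect_equal(shift_ms, 50, tolerance = 15)
})
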