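test_that("simulators are deterministic given seed and config", {
  cfg <- stack_sim_config(n_stacks = 1, cells_per_stack = 4,
                          foci_per_cell = 2, frame_size = 48, z_planes = 7,
                          seed = 42)
  a <- simulate_focus_stacks(cfg)
  b <- simulate_focus_stacks(cfg)
  expect_identical(a$stacks[[1]]$voxels, b$stacks[[1]]$voxels)
  expect_identical(a$ground_truth, b$ground_truth)

  fc <- frap_sim_config(n_traces = 3, seed = 42)
  expect_identical(simulate_frap_traces(fc)$traces,
                   simulate_frap_traces(fc)$traces)

  tc <- traj_sim_config(n_molecules = 20, seed = 42)
  expect_identical(simulate_trajectories(tc)$localizations,
                   simulate_trajectories(tc)$localizations)
})

test_that("rendered foci conserve photons inside a +/-4 sigma box", {
  vox <- array(0, dim = c(15, 41, 41))
  vox <- render_focus(vox, center = c(8, 21, 21), sigma = c(2, 1, 1),
                      photons = 22 * 400)
  expect_lt(abs(sum(vox) - 22 * 400) / (22 * 400), 0.01)

  # full stack-level conservation with noise disabled and centred z
  cfg <- stack_sim_config(n_stacks = 1, cells_per_stack = 5,
                          foci_per_cell = 1, copies_per_focus = 22,
                          unit_intensity = 400, frame_size = 64,
                          z_planes = 15, cytosolic_background = 50,
                          read_noise_sd = 0, shot_noise = FALSE,
                          z_placement = "center", seed = 2)
  sim <- simulate_focus_stacks(cfg)
  signal <- sum(sim$stacks[[1]]$voxels) - 50 * length(sim$stacks[[1]]$voxels)
  expect_lt(abs(signal - 5 * 22 * 400) / (5 * 22 * 400), 0.01)
})

test_that("zero-copy stacks contain background only and yield no foci", {
  cfg <- stack_sim_config(n_stacks = 1, cells_per_stack = 5,
                          foci_per_cell = 2, copies_per_focus = 0,
                          frame_size = 64, z_planes = 7, seed = 3)
  sim <- simulate_focus_stacks(cfg)
  expect_equal(nrow(sim$ground_truth), 0)
  expect_equal(nrow(detect_foci(sim$stacks[[1]])), 0)
})

test_that("mean rendered focus intensity scales as the copy-number ratio", {
  # direct averaging of rendered integrals (no detection pipeline): with
  # identical unit intensity and z-placement statistics, the mean integrated
  # signal per focus must be proportional to the copy number
  base <- list(n_stacks = 8, cells_per_stack = 25, foci_per_cell = 5,
               unit_intensity = 400, frame_size = 200, z_planes = 10,
               cytosolic_background = 0, read_noise_sd = 0,
               shot_noise = FALSE)
  mean_integral <- function(copies, seed) {
    cfg <- do.call(stack_sim_config,
                   c(base, list(copies_per_focus = copies, seed = seed)))
    sim <- simulate_focus_stacks(cfg)
    tot <- sum(vapply(sim$stacks, function(s) sum(s$voxels), 0))
    tot / nrow(sim$ground_truth)
  }
  ratio <- mean_integral(22, seed = 5) / mean_integral(24, seed = 6)
  expect_lt(abs(ratio - 22 / 24) / (22 / 24), 0.02)
})

test_that("focus placement failure is an error, never a silent drop", {
  cfg <- stack_sim_config(n_stacks = 1, cells_per_stack = 50,
                          foci_per_cell = 10, frame_size = 24,
                          min_separation_px = 8, seed = 1)
  expect_error(simulate_focus_stacks(cfg), "could not place")
})

test_that("noiseless FRAP traces obey the recovery limits", {
  ratio_of <- function(tr) spot_ratio(tr$I_spot, tr$I_cell, tr$I_bg)

  # full recovery: mobile fraction 1, long times return to pre-bleach level
  cfg <- frap_sim_config(n_traces = 1, true_t_half = 10, mobile_fraction = 1,
                         bleach_depth = 0.9, noise_sd = 0,
                         frame_schedule = list(c(50, 10)), seed = 1)
  tr <- simulate_frap_traces(cfg)$traces[[1]]
  r <- ratio_of(tr)
  expect_equal(tail(r, 1), 1, tolerance = 1e-9)

  # immobile limit: post-bleach ratio constant
  cfg0 <- frap_sim_config(n_traces = 1, true_t_half = 10,
                          mobile_fraction = 0, bleach_depth = 0.9,
                          noise_sd = 0, frame_schedule = list(c(30, 5)),
                          seed = 1)
  tr0 <- simulate_frap_traces(cfg0)$traces[[1]]
  r0 <- ratio_of(tr0)
  post <- r0[(attr(tr0, "bleach_index") + 1):length(r0)]
  expect_equal(post, rep(1 - 0.9, length(post)), tolerance = 1e-12)

  # at t = t_half exactly half of the mobile amplitude has recovered
  cfg_h <- frap_sim_config(n_traces = 1, true_t_half = 40.4,
                           mobile_fraction = 0.8, bleach_depth = 0.9,
                           noise_sd = 0, ref_interval = 0.04,
                           frame_schedule = list(c(20, 4)), seed = 1)
  tr_h <- simulate_frap_traces(cfg_h)$traces[[1]]
  r_h <- ratio_of(tr_h)
  bi <- attr(tr_h, "bleach_index")
  t_post <- tr_h$time_s - tr_h$time_s[bi]
  i_half <- which(abs(t_post - 40.4) < 1e-9)
  expect_length(i_half, 1)
  recovered <- (r_h[i_half] - (1 - 0.9)) / 0.9
  expect_equal(recovered, 0.8 / 2, tolerance = 1e-12)
})

test_that("FRAP config rejects invalid mobile fractions and schedules", {
  expect_error(frap_sim_config(mobile_fraction = 1.2))
  expect_error(frap_sim_config(mobile_fraction = -0.1))
  expect_error(frap_sim_config(true_t_half = 0))
  expect_error(frap_sim_config(frame_schedule = list(c(0, 2))))
})

test_that("trajectory steps obey Brownian scaling with localization error", {
  # MSD identity: per-step squared displacement has mean 4 D dt (+ 4 sigma^2)
  cfg <- traj_sim_config(populations = data.frame(fraction = 1, D = 0.5),
                         loc_error_sd = 0, mean_track_length = 60,
                         n_molecules = 300, cell_bounds = c(50, 50),
                         seed = 8)
  sim <- simulate_trajectories(cfg)
  steps <- do.call(rbind, lapply(split(sim$localizations,
                                       sim$localizations$molecule_id),
                                 function(m) {
    m <- m[order(m$frame), ]
    if (nrow(m) < 2) return(NULL)
    cbind(diff(m$x_um), diff(m$y_um))
  }))
  expect_gt(nrow(steps), 1e4)
  d_hat <- mean(steps[, 1]^2 + steps[, 2]^2) / (4 * cfg$frame_interval)
  expect_lt(abs(d_hat - 0.5) / 0.5, 0.03)

  # with localization error the mean squared step gains 4 sigma^2
  cfg_e <- traj_sim_config(populations = data.frame(fraction = 1, D = 0.2),
                           loc_error_sd = 0.04, mean_track_length = 60,
                           n_molecules = 300, cell_bounds = c(50, 50),
                           seed = 9)
  sim_e <- simulate_trajectories(cfg_e)
  steps_e <- do.call(rbind, lapply(split(sim_e$localizations,
                                         sim_e$localizations$molecule_id),
                                   function(m) {
    m <- m[order(m$frame), ]
    if (nrow(m) < 2) return(NULL)
    cbind(diff(m$x_um), diff(m$y_um))
  }))
  ms <- mean(steps_e[, 1]^2 + steps_e[, 2]^2)
  expected <- 4 * 0.2 * cfg_e$frame_interval + 4 * 0.04^2
  expect_lt(abs(ms - expected) / expected, 0.03)
})

test_that("immobile noiseless molecules localize identically in every frame", {
  cfg <- traj_sim_config(populations = data.frame(fraction = 1, D = 0),
                         loc_error_sd = 0, mean_track_length = 20,
                         n_molecules = 10, seed = 4)
  sim <- simulate_trajectories(cfg)
  for (m in split(sim$localizations, sim$localizations$molecule_id)) {
    expect_equal(diff(range(m$x_um)), 0)
    expect_equal(diff(range(m$y_um)), 0)
  }
})

test_that("trajectory config validates populations", {
  expect_error(traj_sim_config(populations = data.frame(fraction = numeric(0),
                                                        D = numeric(0))))
  expect_error(traj_sim_config(
    populations = data.frame(fraction = c(0.5, 0.4), D = c(0.1, 0.2))))
  expect_error(traj_sim_config(
    populations = data.frame(fraction = 1, D = -0.1)))
})
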