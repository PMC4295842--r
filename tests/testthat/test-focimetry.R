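test_that("background statistics are exact on constant stacks and robust to outliers", {
  const <- image_stack(array(7, dim = c(3, 8, 8)), 100, 150)
  expect_equal(estimate_background(const), c(mean = 7, sd = 0))

  # N(100, 5^2) voxels with 1% bright outliers: clipped statistics must match
  # the outlier-free truth
  set.seed(10)
  n <- 30000
  clean <- rnorm(n, 100, 5)
  vox <- clean
  hot <- sample(n, n / 100)
  vox[hot] <- vox[hot] + 200
  st <- image_stack(array(vox, dim = c(10, 50, 60)), 100, 150)
  bg <- estimate_background(st)
  expect_lt(abs(bg[["mean"]] - 100), 0.5)
  expect_lt(abs(bg[["sd"]] - 5), 0.5)
})

test_that("pure background produces at most Gaussian-tail false positives", {
  set.seed(11)
  st <- image_stack(array(rnorm(32^3, 100, 5), dim = c(32, 32, 32)), 100, 150)
  bg <- estimate_background(st)
  n_above <- sum(st$voxels > bg[["mean"]] + 5 * bg[["sd"]])
  # expected Gaussian exceedances: 32^3 * P(Z > 5) ~ 0.0094
  expect_lte(n_above, 3)
  expect_equal(nrow(detect_foci(st)), 0)
})

test_that("detection finds a single rendered focus at its true position", {
  st <- make_test_stack(dims = c(7, 32, 32), foci = data.frame(z = 4, y = 16,
                                                               x = 20),
                        photons = 3000, seed = 12)
  bg <- estimate_background(st)
  # peak must be comfortably above the 5 SD threshold for this fixture
  expect_gt(max(st$voxels), bg[["mean"]] + 10 * bg[["sd"]])
  foci <- detect_foci(st)
  expect_equal(nrow(foci), 1)
  expect_lte(abs(foci$y - 16), 1)
  expect_lte(abs(foci$x - 20), 1)
  # brute-force voxel scan agrees
  orc <- oracle_detect_foci(st)
  expect_equal(foci[c("z", "y", "x")], orc[c("z", "y", "x")])
})

test_that("uniform stacks yield no foci", {
  st <- image_stack(array(50, dim = c(5, 16, 16)), 100, 150)
  expect_equal(nrow(detect_foci(st)), 0)
})

test_that("two point sources closer than the minimum separation merge", {
  vox <- array(0, dim = c(5, 20, 20))
  vox[3, 10, 10] <- 100
  vox[3, 10, 12] <- 100
  st <- image_stack(vox, 100, 150)
  foci <- detect_foci(st, min_separation_px = 3)
  expect_equal(nrow(foci), 1)
  # 3 px apart they are kept separate
  vox2 <- array(0, dim = c(5, 20, 20))
  vox2[3, 10, 10] <- 100
  vox2[3, 10, 13] <- 100
  st2 <- image_stack(vox2, 100, 150)
  expect_equal(nrow(detect_foci(st2, min_separation_px = 3)), 2)
})

test_that("detection matches the brute-force oracle on random small stacks", {
  for (seed in 1:5) {
    set.seed(seed)
    n_foci <- sample(2:5, 1)
    foci <- data.frame(z = runif(n_foci, 2, 6),
                       y = runif(n_foci, 5, 28),
                       x = runif(n_foci, 5, 28))
    st <- make_test_stack(dims = c(7, 32, 32), foci = foci,
                          photons = 3000, seed = seed + 100)
    a <- detect_foci(st)
    b <- oracle_detect_foci(st)
    expect_equal(a[c("z", "y", "x", "peak_intensity")],
                 b[c("z", "y", "x", "peak_intensity")])
  }
})

test_that("detection is gain invariant and translation equivariant", {
  foci <- data.frame(z = c(4, 3), y = c(10, 22), x = c(12, 20))
  st <- make_test_stack(dims = c(7, 32, 32), foci = foci, photons = 3000,
                        seed = 21)
  base <- detect_foci(st)
  # gain: positions unchanged, corrected intensity scales
  g <- 3.7
  st_g <- image_stack(st$voxels * g, st$pixel_size, st$z_spacing)
  gained <- detect_foci(st_g)
  expect_equal(base[c("z", "y", "x")], gained[c("z", "y", "x")])
  m <- measure_focus_intensity(st, base[1, ], 100, 0)
  m_g <- measure_focus_intensity(st_g, base[1, ], 100 * g, 0)
  expect_equal(m_g$corrected_intensity, g * m$corrected_intensity,
               tolerance = 1e-10)
  # cyclic lateral shift moves every detected position by the same offset
  sh <- 3
  shifted_vox <- st$voxels[, c((32 - sh + 1):32, 1:(32 - sh)), , drop = FALSE]
  st_s <- image_stack(shifted_vox, st$pixel_size, st$z_spacing)
  shifted <- detect_foci(st_s)
  expect_equal(shifted$y, ((base$y + sh - 1) %% 32) + 1)
  expect_equal(shifted$x, base$x)
})

test_that("focus intensity measurement recovers the integrated signal", {
  # noiseless focus of known integral on a flat background
  vox <- array(100, dim = c(9, 31, 31))
  vox <- render_focus(vox, c(5, 16, 16), c(1.5, 1, 1), 5000)
  st <- image_stack(vox, 100, 150)
  m <- measure_focus_intensity(st, list(z = 5, y = 16, x = 16),
                               outside_background = 100,
                               autofluorescence = 0)
  expect_false(m$edge)
  # cylinder of radius 3 px captures all but the far Gaussian tails
  expect_lt(abs(m$corrected_intensity - 5000) / 5000, 0.02)
  # analytic Gaussian integral over the discrete cylindrical ROI
  off <- expand.grid(dy = -3:3, dx = -3:3)
  off <- off[off$dy^2 + off$dx^2 <= 9, ]
  px_mass <- function(c0, i) pnorm(i + 0.5, c0, 1) - pnorm(i - 0.5, c0, 1)
  lat_mass <- sum(px_mass(16, 16 + off$dy) * px_mass(16, 16 + off$dx))
  z_mass <- pnorm(9.5, 5, 1.5) - pnorm(0.5, 5, 1.5)
  expect_equal(m$corrected_intensity, 5000 * lat_mass * z_mass,
               tolerance = 1e-6)

  # zero-signal ROI on a flat background equal to the corrections
  m0 <- measure_focus_intensity(st, list(z = 5, y = 5, x = 25),
                                outside_background = 60,
                                autofluorescence = 40)
  expect_equal(m0$corrected_intensity, 0, tolerance = 1e-9)

  # corner focus is edge-flagged
  mc <- measure_focus_intensity(st, list(z = 1, y = 1, x = 1),
                                outside_background = 100)
  expect_true(mc$edge)
})

test_that("relative stoichiometry reproduces closed-form ratios", {
  mk <- function(stack_means, per_stack = 120, noise = 0) {
    do.call(rbind, lapply(seq_along(stack_means), function(i)
      data.frame(stack_id = sprintf("s%d", i),
                 corrected_intensity = stack_means[i] + noise *
                   rnorm(per_stack))))
  }
  # identical distributions give exactly the reference copy number
  set.seed(30)
  same <- mk(c(100, 105, 95), noise = 1)
  est <- relative_stoichiometry(same, same)
  expect_equal(est$mean_copies, 24)

  # per-stack means 110 vs 120 give 24 * 110/120 = 22
  est2 <- relative_stoichiometry(mk(rep(110, 3)), mk(rep(120, 3)))
  expect_equal(est2$mean_copies, 22)
  expect_equal(est2$sd_copies, 0)

  # error paths: too few stacks, non-positive reference
  expect_error(relative_stoichiometry(mk(110), mk(rep(120, 2))),
               "at least 2 stacks")
  expect_error(relative_stoichiometry(mk(rep(110, 2)), mk(rep(-5, 2))),
               "positive")
  w <- capture_warnings(relative_stoichiometry(mk(rep(110, 2),
                                                  per_stack = 10),
                                               mk(rep(120, 2),
                                                  per_stack = 10)))
  expect_match(w, "< 100 foci", all = TRUE)
  expect_length(w, 2)
})

test_that("stoichiometry recovers simulated copy numbers across a range", {
  # parameter recovery for several true copy numbers against a 24-copy
  # reference, >= 1000 foci per group; photon budget high enough that even
  # 6-copy foci clear the 5 SD threshold at every axial offset
  base <- list(n_stacks = 10, cells_per_stack = 20, foci_per_cell = 5,
               unit_intensity = 1000, frame_size = 200, z_planes = 10)
  cohort <- function(copies, seed) {
    cfg <- do.call(stack_sim_config,
                   c(base, list(copies_per_focus = copies, seed = seed)))
    simulate_focus_stacks(cfg)$stacks
  }
  ref <- cohort(24, seed = 900)
  for (c_true in c(6, 12, 22, 48)) {
    est <- estimate_stoichiometry(cohort(c_true, seed = c_true), ref)
    expect_gt(est$n_foci_target, 900)
    expect_lt(abs(est$mean_copies - c_true) / c_true, 0.05)
  }
})

test_that("intensity distributions are scale equivariant with stable width", {
  expect_equal(sum(intensity_distribution(c(5), n_bins = 5)$counts), 1)
  set.seed(31)
  v <- rnorm(500, 100, 15)
  d1 <- intensity_distribution(v, n_bins = 20)
  d2 <- intensity_distribution(2 * v, n_bins = 20)
  expect_equal(d2$sd, 2 * d1$sd, tolerance = 0.1)
  expect_equal(d2$iqr, 2 * d1$iqr, tolerance = 0.1)

  # equal generative variance gives equal relative spread for 22- and
  # 24-copy cohorts (the spread comes from axial offsets, not copy number)
  cfg22 <- stack_sim_config(n_stacks = 2, cells_per_stack = 25,
                            foci_per_cell = 4, copies_per_focus = 22,
                            frame_size = 200, seed = 61)
  cfg24 <- stack_sim_config(n_stacks = 2, cells_per_stack = 25,
                            foci_per_cell = 4, copies_per_focus = 24,
                            frame_size = 200, seed = 62)
  q22 <- do.call(rbind, lapply(simulate_focus_stacks(cfg22)$stacks,
                               quantify_stack))
  q24 <- do.call(rbind, lapply(simulate_focus_stacks(cfg24)$stacks,
                               quantify_stack))
  rel22 <- sd(q22$corrected_intensity) / mean(q22$corrected_intensity)
  rel24 <- sd(q24$corrected_intensity) / mean(q24$corrected_intensity)
  expect_lt(abs(rel22 - rel24) / rel24, 0.10)
})

test_that("stoichiometry is invariant to a common gain", {
  set.seed(33)
  mk <- function(mu) do.call(rbind, lapply(1:3, function(i)
    data.frame(stack_id = sprintf("s%d", i),
               corrected_intensity = rnorm(120, mu, 10))))
  tgt <- mk(110); ref <- mk(120)
  g <- 2.5
  tgt_g <- transform(tgt, corrected_intensity = corrected_intensity * g)
  ref_g <- transform(ref, corrected_intensity = corrected_intensity * g)
  expect_equal(relative_stoichiometry(tgt_g, ref_g)$mean_copies,
               relative_stoichiometry(tgt, ref)$mean_copies,
               tolerance = 1e-12)
})
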