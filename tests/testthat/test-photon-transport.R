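test_that("finger phantom rasterizes to labelled regions with correct volumes", {
  spec <- finger_geometry()
  lab <- build_geometry(spec)
  expect_equal(dim(lab), c(50L, 100L, 100L))
  labs <- finger_labels()
  counts <- table(factor(lab, levels = labs, labels = names(labs)))
  expect_true(all(counts[c("epidermis", "dermis", "muscle", "bone", "artery")] > 0))
  # labelled volume matches the analytic cylinder volume within a voxel shell
  vox_vol <- spec$voxel^3
  vol <- sum(lab > 0L) * vox_vol
  cyl <- pi * (spec$diameter / 2)^2 * spec$length
  shell <- 2 * pi * (spec$diameter / 2) * spec$length * spec$voxel
  expect_lt(abs(vol - cyl), shell)
  # two vessels, each of the configured mean diameter (from per-slice area)
  sect <- lab[25, , ] == labs[["artery"]]
  area <- sum(sect) * spec$voxel^2
  d_eff <- sqrt(4 * area / pi / spec$vessel_count)
  expect_equal(d_eff, spec$vessel_diameter_mean, tolerance = 0.15)
  # degenerate geometry: no vessels
  lab0 <- build_geometry(finger_geometry(vessel_count = 0))
  expect_equal(sum(lab0 == labs[["artery"]]), 0L)
  # impossible layering is rejected
  expect_error(finger_geometry(epidermis = 0.8), "tile")
})

test_that("pulsation scaling acts linearly on mu_a and mu_s only", {
  blood <- finger_optics()$artery
  expect_equal(pulsation_scale(blood, 1), blood)
  scaled <- pulsation_scale(blood, 1.1)
  expect_equal(scaled$mu_a, 0.33)
  expect_equal(scaled$mu_s, 247.5)
  expect_equal(scaled$g_anis, blood$g_anis)
  # cosine volume waveform at 60 BPM repeats with a 1 s period
  relvol <- function(t_s) 1 + 0.05 * cos(2 * pi * t_s)
  expect_equal(pulsation_scale(blood, relvol(0.3)),
               pulsation_scale(blood, relvol(1.3)))
  expect_error(pulsation_scale(blood, 0), "relative_volume")
})

test_that("Monte Carlo conserves energy, is seed-deterministic, and handles vacuum", {
  lab <- homog_block(c(20L, 20L, 20L), h = 0.05)
  props <- list(epidermis = optical_properties(5, 20, 0.9))
  phi1 <- run_mc(lab, props, n_photons = 2e4, seed = 42)
  phi2 <- run_mc(lab, props, n_photons = 2e4, seed = 42)
  expect_identical(as.numeric(phi1), as.numeric(phi2))
  phi3 <- run_mc(lab, props, n_photons = 2e4, seed = 43)
  expect_false(identical(as.numeric(phi1), as.numeric(phi3)))
  expect_true(all(phi1 >= 0))
  expect_lte(attr(phi1, "absorbed"), 1)
  expect_lte(attr(phi1, "absorbed") + attr(phi1, "escaped"), 1 + 1e-9)
  # purely absorbing medium still conserves energy
  phi_a <- run_mc(lab, list(epidermis = optical_properties(10, 0, 0.9)),
                  n_photons = 1e4, seed = 1)
  expect_lte(attr(phi_a, "absorbed"), 1)
  # vacuum: ballistic cone, zero deposition, fluence only along the beam
  phi_v <- run_mc(lab, list(epidermis = optical_properties(0, 0, 0.9)),
                  n_photons = 5e3, seed = 1,
                  source = list(center = c(0.5, 0.5, 0.975), side = 0.02,
                                half_angle = 0))
  expect_equal(attr(phi_v, "absorbed"), 0)
  expect_gt(phi_v[10, 10, 5] + phi_v[11, 11, 5], 0)  # beam column lit
  expect_equal(sum(phi_v[1:5, 1:5, ]), 0)            # off-cone corner dark
  # undefined label properties are rejected
  lab_bad <- homog_block(c(8L, 8L, 8L), label = 3L)
  expect_error(run_mc(lab_bad, list(epidermis = optical_properties(1, 1)),
                      n_photons = 10, seed = 1), "label")
})

test_that("fluence variance shrinks like 1/n_photons", {
  lab <- homog_block(c(16L, 16L, 16L), h = 0.05)
  props <- list(epidermis = optical_properties(1, 20, 0.9))
  roi <- function(phi) mean(phi[6:11, 6:11, 8:11])
  est <- function(n, seeds) vapply(seeds, function(s)
    roi(run_mc(lab, props, n_photons = n, seed = s)), 0)
  v_small <- stats::var(est(2e3, 1:8))
  v_big <- stats::var(est(8e3, 11:18))
  ratio <- v_small / v_big
  expect_gt(ratio, 4 / 3)    # clearly shrinking
  expect_lt(ratio, 12)       # and compatible with 1/n (factor 4)
})

test_that("deep fluence in a homogeneous block follows diffusion theory", {
  lab <- homog_block(c(50L, 50L, 50L), h = 0.04)
  mua <- 0.05; mus <- 50; g <- 0.9
  phi <- run_mc(lab, list(epidermis = optical_properties(mua, mus, g)),
                n_photons = 2.5e5, seed = 7,
                source = list(center = c(1, 1, 2 - 0.02), side = 0.02,
                              half_angle = 0))
  musp <- mus * (1 - g); mutp <- mua + musp
  D <- 1 / (3 * mutp); mueff <- sqrt(mua / D); z0 <- 1 / mutp; zb <- 2 * D
  depth <- (2 - 0.02) - ((seq_len(50) - 0.5) * 0.04)
  onax <- vapply(seq_len(50), function(k) mean(phi[23:28, 23:28, k]), 0)
  pred <- (exp(-mueff * pmax(abs(depth - z0), 1e-6)) /
             pmax(abs(depth - z0), 1e-6) -
             exp(-mueff * (depth + z0 + 2 * zb)) / (depth + z0 + 2 * zb)) /
    (4 * pi * D)
  sel <- depth > 3 / mutp & depth < 0.9     # 3+ transport MFPs, away from far wall
  expect_gt(sum(sel), 4)
  expect_lt(max(abs(onax[sel] / pred[sel] - 1)), 0.15)
})

test_that("adjoint Jacobian is the fluence product with disjoint ROI masks", {
  spec <- finger_geometry(grid = c(20L, 40L, 40L), voxel = 0.05)
  lab <- build_geometry(spec)
  phi <- run_mc(lab, finger_optics(), n_photons = 5e4, seed = 5)
  jac <- make_jacobian(phi, lab)
  expect_true(all(jac$weights >= 0) && all(is.finite(jac$weights)))
  expect_equal(sum(jac$artery & jac$tissue), 0L)
  # identity factor: all-ones detection profile returns the excitation map
  ones <- array(1, dim = dim(phi))
  jac1 <- make_jacobian(phi, lab, phi_em = ones)
  expect_equal(as.numeric(jac1$weights), as.numeric(phi))
  # partition: artery + tissue sums equal the finger sum
  w <- sens_weights(jac)
  expect_equal(sum(w), sum(jac$weights[lab > 0]))
  expect_error(make_jacobian(phi, lab, phi_em = array(1, c(2, 2, 2))), "shape")
  # detector-side fluence re-simulated explicitly (launch into the rotated
  # geometry, rotate the result back) matches the rotated-profile shortcut
  phi_det <- rotate_y180(run_mc(rotate_y180(lab), finger_optics(),
                                n_photons = 5e4, seed = 6))
  jac2 <- make_jacobian(phi, lab, phi_em = phi_det)
  w2 <- sens_weights(jac2)
  expect_equal(w2[["tissue"]] / w[["tissue"]], 1, tolerance = 0.2)
  expect_equal(w2[["artery"]] / w[["artery"]], 1, tolerance = 0.5)
})
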