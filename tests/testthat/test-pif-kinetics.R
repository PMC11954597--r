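test_that("bi-exponential plasma curves evaluate to their closed form", {
  aby <- pif_aby029()
  ird <- pif_irdye680lt()
  expect_equal(eval_pif(aby, 0), 0.95 + 0.48)
  expect_equal(eval_pif(ird, 0), 5.2 + 0.35)
  # direct scalar evaluation as oracle
  expect_equal(eval_pif(aby, 10), 0.95 * exp(-2.3) + 0.48 * exp(-0.026))
  ts <- eval_pif(aby, seq(0, 100, by = 0.5))
  expect_s3_class(ts, "pdd_ts")
  expect_equal(ts$dt, 0.5)
  expect_true(all(diff(ts$values) < 0))        # monotone decay
  expect_error(eval_pif(aby, c(-1, 0)), "t >= 0")
  expect_error(biexp_pif(1, 0.01, 1, 0.2), "fast component")
  expect_error(biexp_pif(-1, 0.2, 1, 0.01), "positive")
})

test_that("cardiac modulation has the analytic amplitude and mean", {
  cfg <- pulsatile_config(heart_rate = 60, alpha = 0.2, dt = 0.05, duration = 1)
  const <- pdd_ts(rep(3, 1201), dt = 0.05, unit = "s")
  mod <- modulate_pif(const, cfg)
  # peak-to-trough excursion of a constant input is c * alpha
  expect_equal(max(mod$values) - min(mod$values), 3 * 0.2, tolerance = 1e-6)
  # sinusoid integrates to zero over whole cardiac periods (exclude endpoint)
  expect_equal(mean(mod$values[1:1200]), 3, tolerance = 1e-9)
  # alpha = 0 is the identity
  cfg0 <- pulsatile_config(alpha = 0, dt = 0.05, duration = 1)
  expect_identical(modulate_pif(const, cfg0)$values, const$values)
  # mismatched grids are rejected
  wrong <- pdd_ts(rep(3, 100), dt = 0.1, unit = "s")
  expect_error(modulate_pif(wrong, cfg), "not sampled")
  expect_error(pulsatile_config(heart_rate = 60, dt = 1),
               "Nyquist")
})

test_that("one-compartment closed form matches independent ODE integration", {
  kp <- kinetic_params(K1 = 0.1, k2 = 0.08)
  tt <- seq(0, 300, by = 1)
  cf <- one_compartment(pif_aby029(), kp, tt)
  expect_equal(cf$values[1], 0)
  expect_true(all(cf$values >= 0))
  # stiff ODE solver as the independent oracle
  p <- pif_aby029()
  sol <- deSolve::ode(c(C = 0), tt,
                      function(t, y, parms)
                        list(kp$K1 * (p$amp1 * exp(-p$rate1 * t) +
                                      p$amp2 * exp(-p$rate2 * t)) - kp$k2 * y),
                      NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(cf$values[-1] - sol[-1, "C"]) / sol[-1, "C"]), 1e-3)
})

test_that("one-compartment limiting cases and sampled-input path", {
  tt <- seq(0, 200, by = 0.5)
  zero <- one_compartment(pif_aby029(), kinetic_params(K1 = 0), tt)
  expect_true(all(zero$values == 0))
  # constant plasma level approaches the K1 c / k2 steady state
  const <- pdd_ts(rep(2, 4001), dt = 0.25, unit = "min")
  kp <- kinetic_params(K1 = 0.3, k2 = 0.2)
  cf <- one_compartment(const, kp)
  expect_equal(tail(cf$values, 1), kp$K1 * 2 / kp$k2, tolerance = 1e-3)
  # sampled path agrees with closed form on a bi-exponential input
  cf_d <- one_compartment(eval_pif(pif_aby029(), tt), kinetic_params())
  cf_a <- one_compartment(pif_aby029(), kinetic_params(), tt)
  expect_equal(cf_d$values[-1], cf_a$values[-1], tolerance = 2e-3)
  expect_error(one_compartment(pif_aby029(), kinetic_params(), c(0, 1, 3)),
               "uniform")
})

test_that("tumor model reduces, saturates, and matches a fixed-step RK4 oracle", {
  kp <- kinetic_params(K1 = 0.1, k2 = 0.08, kon = 0.05, koff = 0.12, Bmax = 10)
  tt <- seq(0, 300, by = 1)
  tm <- tumor_model(pif_aby029(), kp, tt)
  expect_equal(tm$Cf$values[1], 0)
  expect_equal(tm$Cb$values[1], 0)
  expect_true(all(tm$Cb$values <= kp$Bmax + 1e-9))
  expect_true(all(tm$Cf$values >= 0) && all(tm$Cb$values >= 0))

  # reduction: kon = 0 collapses to the one-compartment model
  tm0 <- tumor_model(pif_aby029(), kinetic_params(kon = 0), tt)
  expect_true(all(tm0$Cb$values == 0))
  cf1 <- one_compartment(pif_aby029(), kinetic_params(), tt)
  expect_equal(tm0$Cf$values, cf1$values, tolerance = 1e-6)

  # independent fixed-step RK4 oracle at dt = 0.01 min
  p <- pif_aby029()
  cp <- function(t) p$amp1 * exp(-p$rate1 * t) + p$amp2 * exp(-p$rate2 * t)
  f <- function(t, y) c(kp$K1 * cp(t) - kp$k2 * y[1] -
                          kp$kon * (kp$Bmax - y[2]) * y[1] + kp$koff * y[2],
                        kp$kon * (kp$Bmax - y[2]) * y[1] - kp$koff * y[2])
  hh <- 0.01
  y <- c(0, 0); keep <- matrix(0, length(tt), 2); keep[1, ] <- y; ti <- 0
  for (i in seq_len(300 / hh)) {
    k1 <- f(ti, y); k2_ <- f(ti + hh / 2, y + hh / 2 * k1)
    k3 <- f(ti + hh / 2, y + hh / 2 * k2_); k4 <- f(ti + hh, y + hh * k3)
    y <- y + hh / 6 * (k1 + 2 * k2_ + 2 * k3 + k4); ti <- ti + hh
    if (i %% 100 == 0) keep[i / 100 + 1, ] <- y
  }
  tot_oracle <- rowSums(keep)
  expect_lt(max(abs(tm$total$values[-1] - tot_oracle[-1]) / tot_oracle[-1]),
            1e-3)
})

test_that("one-compartment is linear in the input; saturable binding is not", {
  tt <- seq(0, 120, by = 1)
  p1 <- pif_aby029()
  p2 <- biexp_pif(2 * p1$amp1, p1$rate1, 2 * p1$amp2, p1$rate2)
  kp <- kinetic_params()
  expect_equal(one_compartment(p2, kp, tt)$values,
               2 * one_compartment(p1, kp, tt)$values, tolerance = 1e-12)
  tot1 <- tumor_model(p1, kp, tt)$total$values
  tot2 <- tumor_model(p2, kp, tt)$total$values
  # doubling the input progressively less-than-doubles the signal as the
  # bound pool saturates
  ratio <- tot2[-1] / tot1[-1]
  expect_true(all(diff(ratio[tt[-1] >= 5]) < 0))
  expect_lt(ratio[length(ratio)], 1.9)
})
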