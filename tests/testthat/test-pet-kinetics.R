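random_kinetic_truth <- function() {
  kinetic_params(K1 = exp(stats::rnorm(1, log(0.15), 0.4)),
                 k2 = exp(stats::rnorm(1, log(0.5), 0.4)),
                 k3 = exp(stats::rnorm(1, log(0.08), 0.4)),
                 k4 = exp(stats::rnorm(1, log(0.01), 0.4)),
                 vb = stats::runif(1, 0.03, 0.12),
                 Tc = stats::runif(1, 4, 10))
}

test_that("eigenvalues collapse correctly in the irreversible limit", {
  ev <- sabresponse:::two_tissue_eigen(k2 = 0.4, k3 = 0.1, k4 = 0)
  expect_equal(ev$alpha1, 0)
  expect_equal(ev$alpha2, 0.5)
})

test_that("impulse response matches the ODE matrix-exponential oracle", {
  set.seed(11)
  t_grid <- seq(0, 3600, length.out = 241)
  for (i in 1:10) {
    p <- random_kinetic_truth()
    expect_lt(max(abs(impulse_response(p, t_grid) -
                        ode_impulse_oracle(p, t_grid))), 1e-8)
  }
})

test_that("impulse response decays to zero and is monotone when k3 = 0", {
  p <- kinetic_params(0.2, 0.5, 0.1, 0.02, Tc = 6)
  expect_lt(impulse_response(p, 86400), 1e-7)
  q <- kinetic_params(0.2, 0.5, k3 = 0, k4 = 0.01, Tc = 6)
  h <- impulse_response(q, seq(6, 3600, by = 1))
  expect_true(all(diff(h) <= 1e-12))
  # plateau height equals K1 and continues continuously past Tc
  expect_equal(impulse_response(q, c(0, 3, 5.999)), rep(0.2, 3))
  expect_equal(impulse_response(q, 6), 0.2)
})

test_that("forward TAC is linear in the input and zero for zero input", {
  p <- kinetic_params(0.15, 0.4, 0.06, 0.01, vb = 0.05, Tc = 6)
  zero <- forward_tac(p, aif_gamma_variate(amplitude = 0),
                      pet_frame_schedule())
  expect_true(all(zero$values == 0))
  a1 <- forward_tac(p, aif_feng())
  a2 <- forward_tac(p, aif_feng(A = 2 * c(851.1, 21.9, 20.8)))
  expect_equal(a2$values, 2 * a1$values, tolerance = 1e-10)
})

test_that("a blood-only ROI reproduces the frame-averaged input", {
  # vb -> 1 limit: compare at vb close to its upper admissible value
  p <- kinetic_params(K1 = 0, k2 = 0.3, vb = 0.999)
  tac <- forward_tac(p, aif_feng())
  sched <- tac$schedule
  caf <- vapply(seq_len(nrow(sched)), function(i) {
    a <- sched$frame_start[i]
    b <- a + sched$frame_duration[i]
    stats::integrate(function(u) evaluate_aif(aif_feng(), sort(u))[order(order(u))],
                     a, b, rel.tol = 1e-9)$value / (b - a)
  }, numeric(1))
  expect_equal(tac$values, 0.999 * caf, tolerance = 1e-4)
})

test_that("frame-averaged forward model agrees with nested quadrature", {
  p <- kinetic_params(0.15, 0.4, 0.06, 0.01, vb = 0.05, Tc = 6)
  tac <- forward_tac(p, aif_feng(), dt = 0.25)
  oracle <- quadrature_tac_oracle(p, aif_feng(), tac$schedule)
  rel <- abs(tac$values - oracle) / pmax(abs(oracle), 1e-6)
  expect_lt(max(rel), 0.005)
})

test_that("macro parameters follow the printed formulas exactly", {
  p <- kinetic_params(0.1, 0.2, 0.05, 0.01)
  m <- macro_parameters(p)
  expect_equal(m$Ki, 0.1 * 0.05 / 0.26)
  expect_equal(m$Ki, 0.019231, tolerance = 1e-4)
  expect_equal(m$DV, (0.1 / 0.2) * (1 + 0.05 / 0.01))
  expect_equal(m$DV, 3.0)
  # k3 = 0 kills net uptake regardless of K1
  expect_equal(macro_parameters(kinetic_params(1.5, 0.3, 0))$Ki, 0)
  # irreversible limit: Ki defined, DV undefined
  m0 <- macro_parameters(kinetic_params(0.1, 0.2, 0.05, 0))
  expect_equal(m0$Ki, 0.1 * 0.05 / 0.25)
  expect_true(is.na(m0$DV))
  broken <- kinetic_params(0.1, 0.2, 0.05)
  broken$k2 <- 0
  expect_error(macro_parameters(broken), "k2")
})

test_that("Ki never exceeds K1 across random admissible parameters", {
  set.seed(21)
  for (i in 1:50) {
    p <- random_kinetic_truth()
    expect_lte(macro_parameters(p)$Ki, p$K1)
  }
})

test_that("SUV conversion follows dose-per-weight unit arithmetic", {
  sched <- pet_frame_schedule()
  flat <- function(v) time_curve(sched, rep(v, 39))
  # 10 kBq/mL at dose/weight 5 MBq/kg = 5 kBq/g -> SUV 2 g/mL
  s <- suv_from_frames(flat(10), dose_MBq = 350, weight_kg = 70)
  expect_equal(s$suv_max, 2.0)
  expect_equal(s$suv_mean, 2.0)
  expect_equal(s$window_start, 1800)
  expect_equal(s$window_end, 3600)
  expect_equal(suv_from_frames(flat(0), dose_MBq = 350,
                               weight_kg = 70)$suv_max, 0)
  # late frames 1..6 kBq/mL at dose/weight 1 kBq/g -> mean SUV 3.5
  vals <- rep(0, 39)
  vals[34:39] <- 1:6
  s2 <- suv_from_frames(time_curve(sched, vals), dose_MBq = 70,
                        weight_kg = 70)
  expect_equal(s2$suv_mean, 3.5)
  expect_error(suv_from_frames(flat(1), dose_MBq = 0, weight_kg = 70),
               "positive")
  # schedule without the late static window is rejected
  short <- time_curve(frame_schedule(seq(0, 45, 5), rep(5, 10)), rep(1, 10))
  expect_error(suv_from_frames(short, dose_MBq = 350, weight_kg = 70),
               "300 s frames")
})

test_that("percent change handles sign, identity and the -48.9 boundary", {
  expect_equal(percent_change(10, 5), -50)
  expect_equal(percent_change(7, 7), 0)
  expect_equal(percent_change(10, 5.11), -48.9)
  expect_error(percent_change(0, 5), "positive")
})

test_that("noise-free fits recover the generating parameters within 1%", {
  set.seed(31)
  for (i in 1:3) {
    truth <- random_kinetic_truth()
    tac <- forward_tac(truth, aif_feng(), dt = 0.5)
    fit <- suppressWarnings(fit_tac(tac, aif_feng(), dt = 0.5))
    for (nm in c("K1", "k2", "k3", "k4")) {
      expect_lt(abs(fit$params[[nm]] - truth[[nm]]) / truth[[nm]], 0.01)
    }
  }
})

test_that("an all-zero TAC yields a flagged degenerate fit with K1 at zero", {
  tac <- time_curve(pet_frame_schedule(), rep(0, 39))
  fit <- fit_tac(tac, aif_feng())
  expect_equal(fit$params$K1, 0)
  expect_true(fit$diagnostics$degenerate)
})
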