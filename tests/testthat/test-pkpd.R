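test_that("parameter constructors enforce positivity and ranges", {
  expect_error(pk_parameters(V1 = 0), "positive")
  expect_error(pk_parameters(Qb = -1), "positive")
  expect_error(pd_parameters(Emax = 1.2), "\\[0, 1\\]")
  expect_error(pd_parameters(E50 = 0), "positive")
  expect_error(dose_events(c(0, 14), c(60, -1)), ">= 0")
  expect_error(simulate_pkpd(h = 0), "positive")
  expect_error(simulate_pkpd(t_end = -1), "positive")
})

test_that("MAdCAM-1 suppression follows the Hill relationship", {
  pd <- pd_parameters()
  expect_equal(madcam(0, pd), 2.23e-2)
  # at the half-maximum concentration exactly half of Emax is realised
  expect_equal(madcam(0.093, pd), 2.23e-2 * (1 - 0.956 / 2))
  expect_equal(madcam(0.093, pd), 1.16406e-2, tolerance = 1e-6)
  # saturating drug approaches the floor M0 * (1 - Emax)
  expect_equal(madcam(1e15, pd), 9.812e-4, tolerance = 1e-4)
  # monotone non-increasing in c2
  c2 <- seq(0, 2, by = 0.01)
  expect_true(all(diff(madcam(c2, pd)) <= 0))
  expect_error(madcam(-0.1, pd), ">= 0")
})

test_that("drug is conserved under exchange without elimination", {
  pk0 <- pk_parameters(K = 0)
  traj <- simulate_pkpd(pk0, pd_parameters(), dose_events(0, 60),
                        t_end = 100, h = 0.01)
  total <- pk0$V1 * traj$C1 + pk0$V2 * traj$C2
  expect_equal(total, rep(pk0$V1 * 60, length(total)), tolerance = 1e-12)
  # closed form reaches the well-mixed equilibrium
  eq <- closed_form_two_compartment(pk0, 60, 1e5)
  expect_equal(eq$C1, 60 * pk0$V1 / (pk0$V1 + pk0$V2), tolerance = 1e-9)
  expect_equal(eq$C2, eq$C1, tolerance = 1e-9)
})

test_that("closed form satisfies the initial condition and matches RK4", {
  pk <- pk_parameters()
  t0 <- closed_form_two_compartment(pk, 60, 0)
  expect_equal(t0$C1, 60)
  expect_equal(t0$C2, 0)
  # independent brute-force RK4 at h = 1e-4 agrees to 6 significant digits
  rk <- rk4_two_compartment(pk$Qb, pk$V1, pk$V2, pk$K, 60, 14, 1e-4)
  cf <- closed_form_two_compartment(pk, 60, 14)
  expect_equal(cf$C1, rk[1], tolerance = 1e-6)
  expect_equal(cf$C2, rk[2], tolerance = 1e-6)
})

test_that("closed form handles a repeated-eigenvalue system", {
  # a = Qb/V1, b = Qb/V2; choosing V1 = V2 = 1, K = 0 gives eigenvalues
  # {0, -2a}; perturb to force near-coincident roots via tiny Qb and K
  pk <- pk_parameters(Qb = 1, V1 = 1, V2 = 1, K = 1e-14)
  out <- closed_form_two_compartment(pk, 10, c(0, 0.5, 1))
  expect_true(all(is.finite(out$C1)) && all(is.finite(out$C2)))
  rk <- rk4_two_compartment(1, 1, 1, 1e-14, 10, 1, 1e-4)
  expect_equal(out$C1[3], rk[1], tolerance = 1e-6)
})

test_that("Euler trajectory tracks the exact solution and converges at first order", {
  pk <- pk_parameters()
  sched <- dose_events(0, 60)
  traj <- simulate_pkpd(pk, pd_parameters(), sched, t_end = 364, h = 0.01)
  cf <- closed_form_two_compartment(pk, 60, traj$time)
  rel1 <- abs(traj$C1 - cf$C1) / cf$C1
  expect_lt(max(rel1), 1e-3)
  idx <- traj$time >= 1 # C2 starts at 0; compare where it is appreciable
  expect_lt(max(abs(traj$C2 - cf$C2)[idx] / cf$C2[idx]), 1e-3)
  # spot check at t = 42 days
  i42 <- which(traj$time == 42)
  expect_equal(traj$C1[i42], cf$C1[i42], tolerance = 1e-3)

  # halving the step at least halves the maximum deviation
  err_of <- function(h) {
    tr <- simulate_pkpd(pk, pd_parameters(), sched, t_end = 100, h = h)
    ex <- closed_form_two_compartment(pk, 60, tr$time)
    max(abs(tr$C1 - ex$C1))
  }
  expect_lt(err_of(0.01), err_of(0.02) / 1.9)
})

test_that("multi-dose schedule produces peaks at dose times and bounded M", {
  pk <- pk_parameters(); pd <- pd_parameters()
  sched <- standard_schedule(pk)
  expect_equal(sched$time_day, c(0, 2, 6, 14, 22, 30, 38, 46) * 7)
  expect_equal(sched$increment[1], 60)
  expect_equal(sched$increment[2], 300 / pk$V1)
  traj <- simulate_pkpd(pk, pd, sched, t_end = 364, h = 0.01)
  # local maximum of C1 at each dose instant, decay between doses
  for (td in sched$time_day[-1]) {
    i <- which(traj$time == td)
    expect_gt(traj$C1[i], traj$C1[i - 1])
    expect_gt(traj$C1[i], traj$C1[i + 10])
  }
  # between-dose decay: strictly decreasing inside the day 98-154 interval
  mid <- traj$time > 100 & traj$time < 150
  expect_true(all(diff(traj$C1[mid]) < 0))
  # M stays within its algebraic bounds and moves opposite to C2
  expect_true(all(traj$M <= pd$M0 + 1e-15))
  expect_true(all(traj$M >= pd$M0 * (1 - pd$Emax) - 1e-15))
  expect_true(all(traj$C1 >= 0) && all(traj$C2 >= 0))
  expect_error(simulate_pkpd(pk, pd, dose_events(400, 60), t_end = 364),
               "after 't_end'")
})

test_that("elimination constant is recoverable from noisy decay data", {
  pk <- pk_parameters()
  set.seed(20240712)
  times <- seq(0, 364, by = 7)
  truth <- closed_form_two_compartment(pk, 60, times)$C1
  obs <- truth * (1 + 0.05 * rnorm(length(times)))
  fit <- fit_elimination(times, obs, pk, c1_0 = 60)
  expect_lt(abs(fit$K - pk$K) / pk$K, 0.10)
})
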