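test_that("psi is the back-extrapolated piecewise-linear interpolation", {
  expect_equal(psi(-0.5), 1)
  expect_equal(psi(0), 1)
  expect_equal(psi(0.5), 0.5)
  expect_equal(psi(1), 0)
  # non-increasing over the whole domain
  tt <- seq(-2, 1, by = 0.01)
  expect_true(all(diff(psi(tt)) <= 0))
  expect_equal(phi(tt), 1 - psi(tt))
  expect_error(psi(1.2), "\\[-2, 1\\]")
  expect_error(psi(-2.5), "\\[-2, 1\\]")
  expect_error(psi(NaN), "finite")
})

test_that("derived task quantities obey their identities exactly", {
  set.seed(7)
  cond <- task_conditions(E = runif(50, -45, 45), H = runif(50, -45, 45),
                          T = runif(50, -45, 45))
  expect_identical(cond$TE, cond$T - cond$E)
  expect_identical(cond$HE, cond$H - cond$E)
  expect_identical(cond$TH, cond$TE - cond$HE)
  expect_identical(displacement_vector(cond), cond$T - cond$H)
  expect_error(task_conditions(Inf, 0, 0), "finite")
})

test_that("displacement vector is eye-invariant", {
  a <- task_conditions(E = 0, H = -10, T = 20)
  b <- task_conditions(E = -10, H = -10, T = 20)
  expect_equal(displacement_vector(a), 30)
  expect_equal(displacement_vector(b), 30)
  expect_equal(displacement_vector(task_conditions(5, 12, 12)), 0)
})

test_that("desired trajectory interpolates from HE to TE", {
  cond <- task_conditions(E = 0, H = -10, T = 20)
  expect_equal(desired_trajectory(cond, -0.2), cond$HE)  # delay: he = HE
  expect_equal(desired_trajectory(cond, -1.7), cond$HE)  # pre-target too
  expect_equal(desired_trajectory(cond, 1), cond$TE)
  expect_equal(desired_trajectory(cond, 0.5), 5)
  # monotone non-decreasing for T > H
  he <- vapply(seq(0, 1, 0.05), desired_trajectory, numeric(1), cond = cond)
  expect_true(all(diff(he) >= 0))
})

test_that("internal and extrinsic trajectories agree up to eye position", {
  set.seed(11)
  cond <- task_conditions(E = runif(20, -15, 15), H = runif(20, -30, 30),
                          T = runif(20, -30, 30))
  expect_equal(hand_position(cond, 0), cond$H)
  expect_equal(hand_position(cond, 1), cond$T)
  for (t in seq(0, 1, 0.25)) {
    expect_equal(hand_position(cond, t) - cond$E, desired_trajectory(cond, t))
  }
  expect_error(hand_position(cond, -0.1), "movement epoch")
})
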