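test_that("semilinear gain rectifies at zero", {
  expect_equal(semilinear_gain(c(-2, 0, 0.5)), c(0, 0, 0.5))
})

test_that("main-network node responses match their closed forms", {
  # eye node at its tuning/modulation onset: Gaussian term 1, gain f(1) = 1
  u_eye <- one_unit("eye", u = 0, v = 0, gain_sign = 1L)
  cond <- task_conditions(E = 0, H = 15, T = 0)  # TE = 0, HE = 15
  expect_equal(unname(unit_response(u_eye, cond, -0.5)[1, 1]), 30)

  # dynamic hand node at movement offset: psi = 0, so response hits the
  # onset regardless of the condition
  u_hand <- one_unit("hand_dyn", u = 0)
  conds <- task_conditions(E = c(0, 5, -10), H = c(-10, 12, 0),
                           T = c(20, 12, 15))
  expect_equal(unname(unit_response(u_hand, conds, 1)[1, ]), rep(30, 3))

  # pre-target regime: target-related factors are unity
  expect_equal(unname(unit_response(u_hand, conds, -1.5)[1, ]), rep(30, 3))
  u_eh <- one_unit("eye_hand", u = 3, v = -4)
  expect_equal(unname(unit_response(u_eh, conds, -1.5)[1, ]), rep(30, 3))
  u_eye2 <- one_unit("eye", u = 3, v = 0, gain_sign = 1L)
  expect_equal(unname(unit_response(u_eye2, conds, -1.5)[1, ]),
               semilinear_gain(conds$HE / 15) * 30)
})

test_that("alternative-network node responses match their closed forms", {
  # static displacement node at its onset
  u_static <- one_unit("hand_static", u = 0)
  expect_equal(unname(unit_response(u_static, task_conditions(5, 10, 10), 0.3)[1, 1]),
               30)
  # static displacement node off-peak at movement offset
  cond <- task_conditions(E = 0, H = -10, T = 20)  # TH = 30
  expect_equal(unname(unit_response(u_static, cond, 1)[1, 1]), 30 * exp(-2))
  # mixed node during the delay: rising factor at its onset, falling gain at 1
  u_mix <- one_unit("te_he_mixed", u = 0, v = 0, gain_sign = 1L)
  cond2 <- task_conditions(E = 0, H = 15, T = 10)  # TE = 10, HE = 15
  expect_equal(unname(unit_response(u_mix, cond2, -0.5)[1, 1]), 30)
  expect_error(unit_response(u_mix, cond2, -1.5), "pre-target")
})

test_that("noiseless responses are non-negative and reduce during delay", {
  set.seed(3)
  units <- small_main_population()
  cond <- task_conditions(E = runif(10, -15, 15), H = runif(10, -15, 15),
                          T = runif(10, -30, 30))
  for (t in c(-1.8, -0.7, 0, 0.4, 1)) {
    expect_true(all(unit_response(units, cond, t) >= 0))
  }
  # psi = 1 anywhere in the delay period: responses equal the t = 0 state
  expect_equal(unit_response(units, cond, -0.99), unit_response(units, cond, 0))
  # end-of-movement degeneracy: the dynamic hand node stops co-varying
  r1 <- unit_response(units[units$node == "hand_dyn", ], cond, 1)
  expect_equal(max(apply(r1, 1, var)), 0)
})

test_that("gain-sign symmetry holds for the eye node", {
  up <- one_unit("eye", u = 5, v = 7, gain_sign = 1L)
  um <- one_unit("eye", u = 5, v = -7, gain_sign = -1L)
  cond_p <- task_conditions(E = 0, H = c(-12, 0, 9), T = 4)
  cond_m <- task_conditions(E = 0, H = -c(-12, 0, 9), T = 4)
  # same TE in both condition sets, HE negated along with v and the slope
  expect_equal(unname(unit_response(up, cond_p, 0)[1, ]),
               unname(unit_response(um, cond_m, 0)[1, ]))
})

test_that("noise injection is additive, seeded and unbiased", {
  x <- matrix(10, 100, 100)
  expect_identical(add_noise(x, 0), x)
  set.seed(5); y1 <- add_noise(x, 5)
  set.seed(5); y2 <- add_noise(x, 5)
  expect_identical(y1, y2)
  # CLT bound on the mean perturbation of 1e4 entries
  expect_lt(abs(mean(y1 - x)), 4 * 5 / 100)
  expect_error(add_noise(x, -1))
})
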