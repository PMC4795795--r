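test_that("activity matrices respect the task geometry", {
  hand <- one_unit("hand_dyn", u = 0)
  m <- activity_matrix(hand, "T-H", t = -0.5)
  # response depends on T - H only: constant along diagonals
  for (i in 1:4) expect_equal(m[i, 1:4], m[i + 1, 2:5])
  # pre-target: the dynamic hand node is flat at its amplitude
  expect_true(all(activity_matrix(hand, "T-H", t = -1.5) == 30))
  # eye node varies along both axes of the H-E plane (tuning via TE = -E,
  # gain via HE = H - E)
  eye <- one_unit("eye", u = 0, v = -35)
  me <- activity_matrix(eye, "H-E", t = 0)
  expect_gt(max(apply(me, 1, var)), 0)
  expect_gt(max(apply(me, 2, var)), 0)
  expect_error(activity_matrix(eye, "T-X", t = 0), "invalid")
})

test_that("doubled-angle resultants behave on analytic matrices", {
  expect_equal(unit_gradient_resultant(matrix(5, 5, 5)), c(x = 0, y = 0))
  # pure dependence on the column parameter: all gradients share one angle,
  # the doubled resultant is nonzero and its halved angle is the column axis
  x <- seq(-20, 20, 10)
  m_col <- matrix(rep(x, each = 5), 5, 5)
  r <- unit_gradient_resultant(m_col)
  expect_equal(unname(r[1]) < 0, TRUE)  # doubled 2*90 = 180 degrees
  expect_equal(unname(r[2]), 0)
  expect_equal(unname(axial_distance(atan2(r[2], r[1]) * 90 / pi, 90)), 0)
  # dependence on T - H: the halved resultant angle sits on the -45 axis,
  # and doubling prevents the cancellation a naive sum suffers
  hand <- one_unit("hand_dyn", u = 0)
  m <- activity_matrix(hand, "T-H", t = 0)
  r2 <- unit_gradient_resultant(m)
  expect_lt(axial_distance(atan2(r2[2], r2[1]) * 90 / pi, -45), 5)
  g <- reachframes:::.grad_components(array(m, c(1, 5, 5)), 10)
  naive <- c(sum(g$d1), sum(g$d2))
  expect_gt(sqrt(sum(r2^2)), sqrt(sum(naive^2)))
})

test_that("population resultants sum and weight correctly", {
  ur <- rbind(c(1, 0), c(0, 1), c(2, 2))
  nodes <- c("eye", "eye", "hand_dyn")
  expect_equal(population_resultant(ur, nodes), c(3, 3))
  hy <- population_resultant(ur, nodes, c(eye = 0.5, hand_dyn = 0.5))
  expect_equal(unname(hy), c(0.5 * 0.5 + 0.5 * 2, 0.5 * 0.5 + 0.5 * 2))
  expect_equal(unname(population_resultant(ur * 0, nodes,
                                           c(eye = 0.25, hand_dyn = 0.75))),
               c(0, 0))
  expect_error(population_resultant(ur, nodes, c(eye = 0.5, hand_dyn = 0.2)),
               "sum to 1")
})

test_that("epoch samples are unit length and cover the asked epochs", {
  units <- build_population("hand_dyn", N = 8)
  series <- gradient_series(units, time_points = seq(-2, 1, 0.5),
                            pairs = "T-H")
  ep <- epoch_samples(series, epochs = c(pre_target = -1.5, go = 0,
                                         offset = 1))
  expect_equal(nrow(ep), 3)
  len <- sqrt(ep$x^2 + ep$y^2)
  expect_true(all(abs(len[ep$magnitude > 0] - 1) < 1e-9))
  expect_true(all(len[ep$magnitude == 0] == 0))
  expect_error(epoch_samples(series, epochs = c(go = 0.25)), "not covered")
})

test_that("the pure dynamic-hand population degenerates during movement", {
  units <- build_population("hand_dyn", N = 10)
  series <- gradient_series(units, time_points = c(-1.5, 0, 1),
                            pairs = "T-H")
  pre <- series$magnitude[series$t == -1.5]
  expect_equal(pre, 0)
  off <- series$magnitude[series$t == 1]
  delay <- series$magnitude[series$t == 0]
  expect_lt(off, 0.01 * delay)
})
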