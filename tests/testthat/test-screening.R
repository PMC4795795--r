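test_that("noiseless Gaussian tuning is recovered near-exactly", {
  unit <- one_unit("hand_dyn", u = 0)
  cond <- screening_task_conditions(15)
  y <- unit_response(unit, cond, 0)[1, ]
  fit <- fit_tuning_curve(y, cond$T)
  expect_equal(fit$a, 30, tolerance = 1e-4)
  expect_equal(fit$mu, 0, tolerance = 1e-4)
  expect_equal(fit$s, 15, tolerance = 1e-4)
  expect_equal(fit$c, 0, tolerance = 1e-3)
  expect_equal(fit$sve, 30, tolerance = 1e-3)
  expect_false(fit$degenerate)

  # off-grid peak: polish refines beyond the multistart grid
  unit2 <- one_unit("hand_dyn", u = 3.3)
  y2 <- unit_response(unit2, cond, 0)[1, ]
  fit2 <- fit_tuning_curve(y2, cond$T)
  expect_equal(fit2$mu, 3.3, tolerance = 1e-3)
})

test_that("constant responses give the degenerate zero-SVE fit", {
  fit <- fit_tuning_curve(rep(10, 9), seq(-30, 30, 7.5))
  expect_true(fit$degenerate)
  expect_equal(fit$r2, 0)
  expect_equal(fit$sve, 0)
  expect_equal(fit$a, 0)
})

test_that("SVE is the product of fit quality and amplitude", {
  set.seed(21)
  cond <- screening_task_conditions(15)
  units <- small_main_population()
  rates <- add_noise(unit_response(units, cond, 0), 5)
  rep <- screen_population(units, rates, cond$T)
  expect_equal(rep$sve, rep$r2 * rep$a)
})

test_that("the acceptance rule applies the peak and SVE criteria", {
  fit <- data.frame(mu = 0, s = 15, sve = 30, degenerate = FALSE)
  expect_true(screen_unit(fit, c(-30, 30)))
  expect_false(screen_unit(transform(fit, mu = 25), c(-30, 30)))
  expect_false(screen_unit(transform(fit, sve = 9.9), c(-30, 30)))
  expect_true(screen_unit(transform(fit, sve = 10), c(-30, 30)))  # boundary
  expect_error(screen_unit(fit, c(30, -30)), "lo < hi")
})

test_that("acceptance is monotone in SVE", {
  set.seed(8)
  for (i in 1:50) {
    fit <- data.frame(mu = runif(1, -45, 45), s = runif(1, 10, 30),
                      sve = runif(1, 0, 40), degenerate = FALSE)
    lo <- screen_unit(fit, c(-30, 30))
    hi <- screen_unit(transform(fit, sve = sve + 5), c(-30, 30))
    expect_true(!lo || hi)
  }
})
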