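delay_cond <- delay_task_conditions(15)

test_that("noiseless pure-frame units recover their true weights", {
  # eye unit with v = -20: the gain stays un-clipped over the task, so the
  # model represents the response exactly with w = 1, g = -1/v
  eye <- toy_units()[1, ]
  y_eye <- unit_response(eye, delay_cond, 0)[1, ]
  f_eye <- fit_reference_frame(y_eye, delay_cond)
  expect_lt(abs(f_eye$par[["w"]] - 1), 0.05)
  expect_lt(f_eye$rss, 1e-6)

  hand <- toy_units()[2, ]
  y_hand <- unit_response(hand, delay_cond, 0)[1, ]
  f_hand <- fit_reference_frame(y_hand, delay_cond)
  expect_lt(abs(f_hand$par[["w"]]), 0.05)
  expect_equal(f_hand$par[["mu"]], 5, tolerance = 1e-3)
})

test_that("submodels are nested in the full model", {
  set.seed(33)
  units <- toy_units()
  rates <- add_noise(unit_response(units, delay_cond, 0), 5)
  for (i in seq_len(nrow(units))) {
    y <- rates[i, ]
    se <- fit_reference_frame(y, delay_cond, w_fixed = 1)
    sh <- fit_reference_frame(y, delay_cond, w_fixed = 0)
    fu <- fit_reference_frame(y, delay_cond,
                              extra_starts = list(se$par, sh$par))
    expect_lte(fu$rss, se$rss + 1e-8 * (1 + se$rss))
    expect_lte(fu$rss, sh$rss + 1e-8 * (1 + sh$rss))
  }
  # misspecified frame fits worse: eye unit under the hand submodel
  y <- unit_response(units[1, ], delay_cond, 0)[1, ]
  expect_gt(fit_reference_frame(y, delay_cond, w_fixed = 0)$rss,
            fit_reference_frame(y, delay_cond, w_fixed = 1)$rss + 1)
  expect_error(fit_reference_frame(y, delay_cond, w_fixed = 0.5), "0 or 1")
})

test_that("nested F-test matches an independent t-distribution oracle", {
  expect_equal(nested_f_test(10, 10, 45), 1)
  expect_equal(nested_f_test(0, 0, 45), 1)
  expect_equal(nested_f_test(0, 5, 45), 0)
  # RSSsub = 2 RSSfull at n = 45: F = 39 on (1, 39) df; the F(1, d) tail
  # equals the two-sided tail of t(d) at sqrt(F)
  p <- nested_f_test(1, 2, 45)
  expect_equal(p, 2 * stats::pt(sqrt(39), 39, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(p, 0.01)
  expect_error(nested_f_test(2, 1, 45), "optimizer")
})

test_that("the stepwise decision table covers all four outcomes", {
  expect_equal(classify_unit(0.5, 0.001), "eye")
  expect_equal(classify_unit(0.001, 0.5), "hand")
  expect_equal(classify_unit(0.001, 0.002), "intermediate")
  expect_equal(classify_unit(0.5, 0.6), "indeterminate")
  expect_equal(classify_unit(c(0.5, 0.001), c(0.001, 0.5)),
               c("eye", "hand"))
})

test_that("noiseless toy units classify to their generating frames", {
  units <- toy_units()
  rates <- unit_response(units, delay_cond, 0)
  fits <- classify_reference_frames(units, rates, delay_cond)
  expect_equal(fits$class[1], "eye")
  expect_equal(fits$class[2], "hand")
  expect_true(fits$w[3] > 0 && fits$w[3] < 1)
})

test_that("distribution summaries count classes per node", {
  units <- toy_units()
  rates <- unit_response(units, delay_cond, 0)
  fits <- classify_reference_frames(units, rates, delay_cond)
  dist <- reference_frame_distribution(fits)
  expect_equal(dist$included, 3)
  expect_true(all(dist$units$class != "indeterminate"))
  expect_equal(sum(dist$class_counts), 3)
  expect_warning(reference_frame_distribution(fits[0, ]), "empty")
})
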