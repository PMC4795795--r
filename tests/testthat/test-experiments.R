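test_that("experiments are reproducible from name, config and seed", {
  cfg <- experiment_config(N = 6, seed = 99)
  r1 <- run_experiment("delay_noisy", cfg)
  r2 <- run_experiment("delay_noisy", cfg)
  expect_identical(r1$fits, r2$fits)
  expect_identical(jsonlite::toJSON(r1$summary, auto_unbox = TRUE),
                   jsonlite::toJSON(r2$summary, auto_unbox = TRUE))
  # summary schema: per-node class counts and percentages
  expect_true(all(c("included_total", "per_node") %in% names(r1$summary)))
  nd <- r1$summary$per_node[[1]]
  expect_setequal(names(nd), c("included", "counts", "percent"))
  expect_error(run_experiment("no_such_experiment", cfg))
})

test_that("experiment bundles are written to disk", {
  cfg <- experiment_config(N = 6, seed = 5)
  dir <- file.path(tempdir(), "rf-bundle")
  run_experiment("delay_noisy", cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "population.csv")))
  expect_true(file.exists(file.path(dir, "screening.csv")))
  expect_true(file.exists(file.path(dir, "fits.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_true("per_node" %in% names(js))
  unlink(dir, recursive = TRUE)
})

test_that("the hybrid gradient series covers pairs x time steps", {
  cfg <- experiment_config(N = 6, seed = 2)
  res <- run_experiment("gradient_hybrid", cfg)
  expect_equal(nrow(res$series), 3 * 31)
  expect_setequal(unique(res$series$pair), c("T-H", "T-E", "H-E"))
})

test_that("rate tables round-trip through CSV", {
  units <- toy_units()
  cond <- delay_task_conditions(15)
  rates <- unit_response(units, cond, 0)
  tbl <- rate_table(units, cond, 0, rates)
  path <- tempfile(fileext = ".csv")
  write_rate_table(tbl, path)
  back <- load_rate_table(path)
  expect_equal(back, tbl)
  mats <- rate_table_matrices(back)
  expect_equal(unname(mats$rates), unname(rates))
  expect_equal(mats$cond$TH, cond$TH)
  file.remove(path)
})

test_that("rate table schema violations are reported by name", {
  units <- toy_units()
  cond <- screening_task_conditions(15)
  tbl <- rate_table(units, cond, 0, unit_response(units, cond, 0))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(tbl[, setdiff(names(tbl), "rate")], path,
                   row.names = FALSE)
  expect_error(load_rate_table(path), "rate")
  tbl$extra <- 1
  utils::write.csv(tbl, path, row.names = FALSE)
  expect_warning(ok <- load_rate_table(path), "extra")
  expect_false("extra" %in% names(ok))
  file.remove(path)
})
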