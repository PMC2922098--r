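test_that("the generator is deterministic under a fixed seed", {
  cfg <- synthetic_config(sigma = 0.05, seed = 99)
  d1 <- synthetic_dataset(cfg)
  d2 <- synthetic_dataset(cfg)
  expect_identical(d1$noisy, d2$noisy)
  d3 <- synthetic_dataset(synthetic_config(sigma = 0.05, seed = 100))
  expect_false(identical(d1$noisy, d3$noisy))
})

test_that("the truth grid has the right shape and matches the simulator", {
  grid <- generate_truth(synthetic_config(sigma = 0))
  expect_identical(dim(grid), c(6L, 4L, 6L))
  fl <- simulate_flower(times = 0:5)
  for (w in 1:4)
    expect_equal(unname(grid[, w, ]), unname(t(fl[[w]]$totals)), tolerance = 1e-10)
})

test_that("zero noise is the identity and noise preserves the log mean", {
  cfg0 <- synthetic_config(sigma = 0)
  grid <- generate_truth(cfg0)
  expect_identical(add_noise(grid, cfg0), grid)
  cfg <- synthetic_config(sigma = 0.05, seed = 4)
  flat <- array(100, c(10, 10, 100))  # 1e4 replicates of one value
  noisy <- add_noise(flat, cfg)
  expect_lt(abs(mean(log(noisy / flat))), 3 * 0.05 / 100)
  expect_error(add_noise(flat - 200, cfg), "non-negative")
  expect_equal(add_noise(flat * 0, cfg), flat * 0)  # hard-off states stay zero
})

test_that("meristem averages are the volume-weighted whorl means", {
  grid <- array(0, c(6, 4, 2), dimnames = list(FLORAL_GENES, paste0("w", 1:4),
                                               c("d0", "d1")))
  grid[1, , 1] <- c(1, 0, 0, 0)
  avg <- meristem_average(grid)
  expect_equal(unname(avg[1, 1]), 1.1e4 / 7.8e4)
  uni <- array(250, c(6, 4, 2))
  expect_true(all(meristem_average(uni) == 250))
})

test_that("the day-5 pattern separates on from off states", {
  grid <- generate_truth(synthetic_config(sigma = 0))
  d5 <- grid[, , 6]
  truth <- table2_day5()
  # every cell except SHP in whorl 4 clears the fixed 100 nM threshold;
  # SHP, the weakest gene (its maximal rate sits far below the admissible
  # range), stays separated from the off states but below the threshold
  check <- (d5 >= 100) == truth
  check["SHP", 4] <- TRUE
  expect_true(all(check))
  expect_lt(d5["SHP", 4], 100)
  off_max <- max(d5[!truth])
  expect_gt(d5["SHP", 4], off_max)
  # SHP switches on late: still climbing steeply through days 3-5
  expect_true(all(diff(grid["SHP", 4, 3:6]) > 0))
  expect_gt(grid["SHP", 4, 6], 1.5 * grid["SHP", 4, 4])
})

test_that("averaging and re-splitting are mutually consistent on patterned grids", {
  set.seed(31)
  series <- matrix(10^stats::runif(36, 2, 3.5), 6, 6,
                   dimnames = list(FLORAL_GENES, paste0("d", 0:5)))
  rec <- whorl_concentrations(series)
  avg <- meristem_average(rec$concentrations)
  rec2 <- whorl_concentrations(avg)
  expect_equal(rec2$concentrations, rec$concentrations, tolerance = 1e-12)
})

test_that("generated datasets are stamped with their configuration", {
  ds <- synthetic_dataset(synthetic_config(sigma = 0.02, seed = 8))
  expect_identical(ds$config$seed, 8L)
  expect_identical(attr(ds$truth, "config")$sigma, 0.02)
  dir <- tempfile("synthds")
  write_synthetic_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "truth_grid.csv")))
  man <- readLines(file.path(dir, "manifest.json"))
  expect_true(any(grepl("\"seed\": 8", man)))
})
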