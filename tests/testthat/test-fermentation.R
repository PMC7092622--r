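test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_fermentation(growth_params("CO", seed = 5))
  b <- simulate_fermentation(growth_params("CO", seed = 5))
  expect_identical(a, b)
  c <- simulate_fermentation(growth_params("CO", seed = 6))
  expect_false(identical(a$od600, c$od600))
})

test_that("the noiseless limit reaches the caps up to the logistic tail", {
  for (cond in c("CO", "H2_CO2")) {
    p <- growth_params(cond)
    p$noise_sd[] <- 0
    p$od_noise_sd <- 0
    tc <- simulate_fermentation(p)
    expect_lt(abs(tc$od600[length(tc$times)] - p$od_max) / p$od_max, 0.001)
    for (prod in names(p$product_caps)) {
      cap <- p$product_caps[[prod]]
      final <- tc$products[[prod]][length(tc$times)]
      expect_lt(abs(final - cap) / cap, 0.001)
    }
    # monotone accumulation in the noiseless limit
    for (prod in names(p$product_caps))
      expect_true(all(diff(tc$products[[prod]]) >= 0))
  }
})

test_that("default CO simulation lands near the reported endpoints", {
  p <- growth_params("CO", seed = 2)
  tc <- simulate_fermentation(p)
  gs <- growth_summary(tc)
  expect_lt(abs(gs$peak_od - 8.4), 3 * 0.4 + 8.4 * 0.001)
  last <- length(tc$times)
  expect_lt(abs(tc$products$ethanol[last] - 713), 3 * 21 + 713 * 0.001)
  expect_lt(abs(tc$products$acetate[last] - 185), 3 * 7 + 185 * 0.001)
  # H2/CO2: acetate dominates the endpoint
  tc2 <- simulate_fermentation(growth_params("H2_CO2", seed = 2))
  last2 <- length(tc2$times)
  expect_gt(tc2$products$acetate[last2], tc2$products$ethanol[last2])
})

test_that("end-product ratios on the reported CO titers round to 1:1:4", {
  tc <- timecourse("CO", times = c(0, 120),
                   od600 = c(0, 8.4),
                   products = list(acetate = c(0, 185),
                                   butanediol = c(0, 188),
                                   ethanol = c(0, 713)))
  r <- end_product_ratios(tc, "acetate")
  expect_equal(unname(r$ratios["acetate"]), 1)
  expect_equal(unname(r$ratios["butanediol"]), 188 / 185)  # ~1.016
  expect_equal(unname(r$ratios["ethanol"]), 713 / 185)     # ~3.854
  expect_identical(unname(r$rounded[c("acetate", "butanediol", "ethanol")]),
                   c(1, 1, 4))
})

test_that("ratio extraction is scale-invariant and guards its reference", {
  tc <- timecourse("CO", times = c(0, 12), od600 = c(0, 1),
                   products = list(acetate = c(0, 50), ethanol = c(0, 200)))
  r1 <- end_product_ratios(tc, "acetate")
  tc$products <- lapply(tc$products, function(x) x * 7.5)
  r2 <- end_product_ratios(tc, "acetate")
  expect_equal(r1$ratios, r2$ratios)
  tc$products$acetate[] <- 0
  expect_error(end_product_ratios(tc, "acetate"), "zero final")
  expect_error(end_product_ratios(tc, "lactate"), "not in time course")
  # equal products give all-1 ratios
  tc3 <- timecourse("CO", c(0, 12), c(0, 1),
                    list(a = c(0, 5), b = c(0, 5)))
  expect_true(all(end_product_ratios(tc3, "a")$ratios == 1))
})

test_that("ratio estimates recover the generator cap ratios within 5%", {
  p0 <- growth_params("CO")
  p0$product_caps <- c(acetate = 185, butanediol = 185, ethanol = 740)  # 1:1:4
  est <- sapply(1:20, function(s) {
    p <- p0; p$seed <- s
    r <- end_product_ratios(simulate_fermentation(p), "acetate")
    r$ratios[c("butanediol", "ethanol")]
  })
  means <- rowMeans(est)
  expect_lt(abs(means[1] - 1) / 1, 0.05)
  expect_lt(abs(means[2] - 4) / 4, 0.05)
})

test_that("growth summary reports the first attainment of the peak", {
  up <- timecourse("CO", 1:5, c(1, 2, 3, 4, 5), list())
  expect_equal(growth_summary(up)$time_of_peak, 5)
  flat <- timecourse("CO", 1:4, c(2, 2, 2, 2), list())
  expect_equal(growth_summary(flat)$time_of_peak, 1)
  peaky <- timecourse("CO", 1:5, c(1, 9, 9, 3, 2), list())
  expect_equal(growth_summary(peaky)$time_of_peak, 2)
})

test_that("time-course CSV round trip and error reporting", {
  tc <- simulate_fermentation(growth_params("CO", seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse(tc, path)
  tc2 <- read_timecourse(path)
  expect_equal(tc$times, tc2$times)
  expect_equal(tc$od600, tc2$od600, tolerance = 1e-8)
  expect_equal(tc$products, tc2$products, tolerance = 1e-8)
  expect_identical(tc2$condition, "CO")

  # missing column
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_h,ethanol_mM", "0,0", "12,5"), bad)
  expect_error(read_timecourse(bad), "od600")
  # malformed row
  writeLines(c("time_h,od600", "0,0", "12"), bad)
  expect_error(read_timecourse(bad), "malformed row")
  # unsorted times violate the invariant
  writeLines(c("time_h,od600", "12,1", "0,0"), bad)
  expect_error(read_timecourse(bad), "strictly increasing")
})

test_that("parameter validation rejects impossible settings", {
  expect_error(growth_params("CO", od_max = -1), "od_max")
  expect_error(growth_params("CO", growth_rate = 0), "growth_rate")
  p <- growth_params("CO")
  expect_error(simulate_fermentation(p, horizon_h = -5), "positive")
  expect_error(timecourse("CO", c(0, 0), c(1, 1), list()), "strictly increasing")
  expect_error(timecourse("CO", c(0, 1), c(1, -1), list()), "non-negative")
})
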