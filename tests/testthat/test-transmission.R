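test_that("closed-form density ratios follow the residency bookkeeping", {
  fl <- expected_density_ratio("female_limited")
  expect_equal(fl[["X_A"]], 4 / 3)
  expect_identical(fl[["Y_A"]], 0)
  expect_equal(round(fl[["X_A"]], 2), 1.33)
  expect_equal(expected_density_ratio("unbiased"), c(X_A = 1, Y_A = 1))
  # X spends 1/3 of generations in males, autosomes 1/2, Y all of them
  ml <- expected_density_ratio("male_limited")
  expect_equal(ml[["X_A"]], (1 / 3) / (1 / 2))
  expect_equal(ml[["Y_A"]], 2)
  expect_error(expected_density_ratio("silent"), "undefined")
})

test_that("residency fractions are 1/2, 2/3, 0 at even sex ratio", {
  r <- simulate_transmission(4, 25, "unbiased", activity = 0.02, seed = 2)
  expect_equal(r$residency[["autosome"]], 1 / 2)
  expect_equal(r$residency[["X"]], 2 / 3)
  expect_identical(r$residency[["Y"]], 0)
})

test_that("zero activity leaves copy counts at their initial state", {
  r <- simulate_transmission(5, 40, "female_limited", activity = 0,
                             initial_per_autosome = 3, seed = 3)
  expect_identical(r$total_copies, r$initial_copies)
  expect_identical(r$mean_copies[["X"]], 0)
  expect_identical(r$mean_copies[["Y"]], 0)
})

test_that("copies never decrease and Y stays male-confined", {
  # monotone accumulation across a range of configurations
  for (mode in c("female_limited", "male_limited", "unbiased")) {
    r <- simulate_transmission(4, 60, mode, activity = 0.05, seed = 4)
    expect_gte(r$total_copies, r$initial_copies)
    if (mode == "female_limited") {
      # female-limited insertions can never touch a Y chromosome
      expect_identical(r$mean_copies[["Y"]], 0)
      expect_identical(r$density_ratio[["Y_A"]], 0)
    }
  }
})

test_that("the simulator converges to the closed forms (Monte Carlo)", {
  ratios <- vapply(1:12, function(s)
    simulate_transmission(8, 150, "female_limited", activity = 0.06,
                          seed = s)$density_ratio[["X_A"]], 0)
  m <- mean(ratios); se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(m - 4 / 3), 3 * se + 0.04)

  ratios_u <- vapply(1:8, function(s)
    simulate_transmission(8, 100, "unbiased", activity = 0.05,
                          seed = s)$density_ratio, c(X_A = 0, Y_A = 0))
  expect_lt(abs(mean(ratios_u["X_A", ]) - 1), 0.1)
  expect_lt(abs(mean(ratios_u["Y_A", ]) - 1), 0.1)
})
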