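test_that("pg to bp conversion uses 0.978e9 bp per pg", {
  expect_identical(pg_to_bp(1), 978000000)
  expect_identical(pg_to_bp(0), 0)
  expect_identical(pg_to_bp(2), 1956000000)
  expect_error(pg_to_bp(-0.1), "non-negative")
})

test_that("sex size difference reproduces the printed example values", {
  expect_identical(sex_size_difference(6.09, 6.09), 0)
  # largest-genome ecotype: printed male 6.31, female 6.09 pg/2C
  expect_equal(round(100 * sex_size_difference(6.31, 6.09), 2), 3.61)
  # nonlinearity: +d and -d are not symmetric except in the limit
  expect_equal(sex_size_difference(6.2, 6.0), 1 / 30)
  expect_false(isTRUE(all.equal(sex_size_difference(6.0, 6.2), -1 / 30)))
})

test_that("x_density matches its formula and flags Y-accumulating cases", {
  expect_identical(x_density(1000, 1000), 0)
  expect_equal(x_density(1000, 887.5, 0.15), 1.5)
  # ratio form: invariant to common rescaling of both copy numbers
  expect_equal(x_density(7 * 1000, 7 * 887.5), x_density(1000, 887.5))
  expect_error(x_density(0, 10), "F_copies")
  expect_warning(out <- x_density(1000, 800, y_accumulating = TRUE),
                 "not applicable")
  expect_true(is.na(out))
})

test_that("fold variation covers the printed genome-size extremes", {
  expect_equal(round(fold_variation(c(5.69, 6.09)), 2), 1.07)
  expect_identical(fold_variation(c(2, 2, 2)), 1)
  expect_identical(fold_variation(c(1, 2, 4)), 4)
  expect_error(fold_variation(c(1, -1)), "positive")
  expect_error(fold_variation(3), "at least 2")
})

test_that("pearson_with_p agrees with the definitional oracle to 1e-12", {
  expect_equal(pearson_with_p(1:5, 2 * (1:5) + 1)$r, 1)
  x <- c(5.69, 5.76, 5.84, 5.90, 5.97, 6.02, 6.09)
  y <- c(14.2, 15.1, 14.8, 16.0, 16.4, 15.9, 17.1)
  got <- pearson_with_p(x, y)
  expect_identical(got$n, 7L)
  expect_identical(got$df, 5L)          # df = n - 2
  want <- oracle_pearson(x, y)
  expect_lt(abs(got$r - want$r), 1e-12)
  expect_lt(abs(got$p - want$p), 1e-12)
  # a clearly non-significant pair, p still in (0, 1]
  got2 <- pearson_with_p(x, c(1, 9, 2, 8, 3, 7, 4))
  expect_true(got2$p > 0 && got2$p <= 1)
  expect_lte(abs(got2$r), 1)
  expect_error(pearson_with_p(1:5, rep(2, 5)), "variance")
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
})

test_that("copy-number variability separates Y-polymorphic families", {
  ecos <- paste0("e", 1:5)
  base <- c(100, 104, 98, 102, 101)
  tab <- rbind(
    data.frame(ecotype = ecos, sex = "female", family = "stableF",
               copies = 50),
    data.frame(ecotype = ecos, sex = "male", family = "stableF",
               copies = 50),
    data.frame(ecotype = ecos, sex = "female", family = "shifted",
               copies = base),
    data.frame(ecotype = ecos, sex = "male", family = "shifted",
               copies = base + 7),
    data.frame(ecotype = ecos, sex = "female", family = "ypoly",
               copies = 60),
    data.frame(ecotype = ecos, sex = "male", family = "ypoly",
               copies = 60 + c(4, 12, 0, 9, 17)))
  v <- copy_number_variability(tab)
  st <- v$stats
  expect_identical(st$sd_male[st$family == "stableF"], 0)
  # male = female + constant: equal SDs, constant difference vector
  expect_equal(st$sd_male[st$family == "shifted"],
               st$sd_female[st$family == "shifted"])
  expect_true(all(v$difference["shifted", ] == 7))
  # Y-linked variation shows up only in males
  expect_identical(st$sd_female[st$family == "ypoly"], 0)
  expect_gt(st$sd_male[st$family == "ypoly"], 0)
  expect_true(st$male_ge_female[st$family == "ypoly"])
  expect_false(st$male_ge_female[st$family == "shifted"])
})

test_that("ecotypes missing one sex are excluded with a warning", {
  tab <- data.frame(
    ecotype = c("e1", "e1", "e2", "e2", "e3"),
    sex = c("female", "male", "female", "male", "female"),
    family = "f", copies = c(10, 11, 12, 13, 99))
  expect_warning(v <- copy_number_variability(tab), "lack one sex")
  expect_identical(v$stats$n_ecotypes, 2L)
  expect_true(is.na(v$difference["f", "e3"]))
})
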