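test_that("degenerate distributions collapse to constants", {
  expect_equal(sample_fitness_field(fitness_uniform(1.5, 0), 441), rep(1.5, 441))
  expect_equal(sample_fitness_field(fitness_constant(0.7), 10), rep(0.7, 10))
  lat <- build_lattice(4, 4)
  expect_equal(checkerboard_field(1, 1, lat), rep(1, 16))
})

test_that("bimodal fields carry an exact round-half-up count of advantaged sites", {
  set.seed(3)
  f <- sample_fitness_field(fitness_bimodal(0.5, 1.5, 0.5), 441)
  expect_equal(sum(f == 1.5), 221L)  # round(0.5 * 441) = round(220.5), half up
  expect_equal(sum(f == 0.5), 220L)

  for (x in c(0, 0.1, 0.37, 1)) {
    f <- sample_fitness_field(fitness_bimodal(0.2, 2.8, x), 100)
    expect_equal(sum(f == 2.8), floor(x * 100 + 0.5))
  }
})

test_that("uniform samples have the stated support and mean", {
  set.seed(10)
  n <- 1e5
  f <- sample_fitness_field(fitness_uniform(1.0, 0.3), n)
  expect_gte(min(f), 0.7)
  expect_lte(max(f), 1.3)
  se <- 0.3 / sqrt(3) / sqrt(n)
  expect_lt(abs(mean(f) - 1.0), 3 * se)
})

test_that("triangular samples match the stated density (support, mean, skew)", {
  set.seed(11)
  n <- 1e5
  a <- 0.90; c <- 1.0; b <- 1.25
  f <- sample_fitness_field(fitness_triangular(a, b, mode = c), n)
  expect_gte(min(f), a)
  expect_lte(max(f), b)
  mu <- (a + b + c) / 3
  sdev <- sqrt((a^2 + b^2 + c^2 - a * b - a * c - b * c) / 18)
  expect_lt(abs(mean(f) - mu), 3 * sdev / sqrt(n))
  # upper support longer than lower: median above the mode side, mean above 1
  expect_gt(mean(f), 1)
})

test_that("checkerboard assigns the high value to even (row+col) parity", {
  lat <- build_lattice(2, 2)
  expect_equal(matrix(checkerboard_field(0.5, 1.5, lat), 2, byrow = TRUE),
               matrix(c(1.5, 0.5, 0.5, 1.5), 2, byrow = TRUE))
  lat21 <- build_lattice(21, 21)
  cb <- checkerboard_field(0.5, 1.5, lat21)
  expect_equal(sum(cb == 1.5), 221L)
  expect_equal(sum(cb == 0.5), 220L)
})

test_that("identical seeds reproduce identical quenched fields", {
  spec <- fitness_uniform(1.5, 1.5)
  set.seed(77); f1 <- sample_fitness_field(spec, 441)
  set.seed(77); f2 <- sample_fitness_field(spec, 441)
  expect_identical(f1, f2)
})

test_that("negative or inconsistent fitness specifications are rejected", {
  expect_error(fitness_uniform(1, 1.5), "below zero")
  expect_error(fitness_uniform(-1, 0), "non-negative")
  expect_error(fitness_constant(-0.1), "non-negative")
  expect_error(fitness_bimodal(0.5, 1.5, 1.2), "fraction")
  expect_error(fitness_bimodal(-0.5, 1.5, 0.5), "non-negative")
  expect_error(fitness_triangular(1.2, 1.5, mode = 1.0), "lower <= mode <= upper")
  expect_error(fitness_field(c(1, 1), c(1, -2)), "non-negative")
  expect_error(fitness_field(c(1, 1), c(1, 1, 1)), "equal length")
  # zero fitness is allowed: such a cell can die but never reproduce
  expect_silent(fitness_field(c(0, 0), c(1, 1)))
})
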