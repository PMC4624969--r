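test_that("degenerate fitness fields pin the fixation fraction", {
  lat <- build_lattice(3, 3)
  set.seed(1)
  # mutants that can never reproduce never fix
  dead <- fitness_field(rep(1, 9), rep(0, 9))
  expect_equal(as.numeric(
    estimate_fixation_single_config(dead, motility_params(), lat, 200)), 0)
})

test_that("identical master seeds give bit-identical estimates", {
  lat <- build_lattice(4, 4)
  args <- list(fitness_uniform(1.5, 1), fitness_constant(1), motility_params(),
               lat, n_configs = 3, n_iters = 100)
  e1 <- do.call(estimate_fixation, c(args, seed = 42))
  e2 <- do.call(estimate_fixation, c(args, seed = 42))
  expect_identical(tidy(e1), tidy(e2))
  expect_identical(e1$rho, e2$rho)
  e3 <- do.call(estimate_fixation, c(args, seed = 43))
  expect_false(identical(tidy(e3)$fraction, tidy(e1)$fraction))
})

test_that("pooled estimate is the mean of per-config fractions, each a count over n_iters", {
  lat <- build_lattice(4, 4)
  est <- estimate_fixation(fitness_uniform(1.5, 0.5), fitness_constant(1),
                           motility_params(), lat,
                           n_configs = 4, n_iters = 150, seed = 8)
  pc <- tidy(est)
  expect_equal(nrow(pc), 4L)
  expect_equal(est$rho, mean(pc$fraction))
  expect_equal(pc$fraction, pc$n_fixed / 150)
  expect_true(all(pc$n_fixed == round(pc$n_fixed)))
  expect_gte(est$rho, 0); expect_lte(est$rho, 1); expect_gte(est$spread, 0)
  g <- glance(est)
  expect_equal(g$rho, est$rho)
  expect_gt(g$se_combined, 0)
})

test_that("zero-width specs make configurations i.i.d. replicates of one process", {
  lat <- build_lattice(5, 5)
  est <- estimate_fixation(fitness_uniform(2, 0), fitness_constant(1),
                           motility_params(), lat,
                           n_configs = 4, n_iters = 400, seed = 12)
  set.seed(999)
  single <- as.numeric(estimate_fixation_single_config(
    homogeneous_field(25, 1, 2), motility_params(), lat, 1600))
  se <- sqrt(single * (1 - single) / 1600) + sqrt(est$rho * (1 - est$rho) / 1600)
  expect_lt(abs(est$rho - single), 4 * se)
})

test_that("a spatially constant advantageous mutant stays near (below) the well-mixed value", {
  lat <- build_lattice(21, 21)
  set.seed(13)
  n <- 2000
  fr <- as.numeric(estimate_fixation_single_config(
    homogeneous_field(441, 1, 1.5), motility_params(), lat, n))
  wm <- moran_fixation(1.5, 441)
  expect_lt(fr, wm + 3 * sqrt(wm * (1 - wm) / n))
  expect_gt(fr, 0.8 * wm)  # spatial structure reduces it only somewhat
})

test_that("sweeps order rows by the grid and validate their inputs", {
  lat <- build_lattice(4, 4)
  sw <- sweep_fixation("delta", c(0, 0.5, 1), lat,
                       spec_B = fitness_uniform(1.5, 0),
                       n_configs = 2, n_iters = 50, seed = 3)
  expect_s3_class(sw, "fixation_sweep")
  expect_equal(sw$value, c(0, 0.5, 1))
  expect_equal(sw$variable, rep("delta", 3))
  expect_true(all(c("rho", "spread", "se_combined", "per_config") %in% names(sw)))

  expect_error(sweep_fixation("delta", numeric(0), lat,
                              spec_B = fitness_uniform(1.5, 0)),
               "non-empty")
  expect_error(sweep_fixation("x", c(0.5), lat,
                              spec_B = fitness_uniform(1.5, 0)),
               "bimodal")
  expect_error(sweep_fixation("delta", c(0, 1), lat,
                              spec_B = fitness_bimodal(0.5, 1.5, 0.5)),
               "uniform")
})

test_that("sweep results plot as point ranges", {
  lat <- build_lattice(4, 4)
  sw <- sweep_fixation("delta", c(0, 1), lat, spec_B = fitness_uniform(1.5, 0),
                       n_configs = 2, n_iters = 50, seed = 4)
  p <- autoplot(sw)
  expect_s3_class(p, "ggplot")
})
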