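test_that("event distribution matches hand-computed cases", {
  lat <- build_lattice(3, 3)
  vac <- 5L  # interior site, neighbours (in list order): 2, 8, 4, 6

  # four identical resident neighbours, no motility: 1/4 each
  occ <- rep(0L, 9); occ[vac] <- NA
  d <- event_distribution(occ, homogeneous_field(9), motility_params(), lat, vac)
  expect_equal(d$prob[d$event == "divide"], rep(0.25, 4))
  expect_equal(d$prob[d$event == "migrate"], rep(0, 4))

  # neighbours A(1), A(1), B(2), B(0.5): total B-divide 2.5/4.5, A-divide 2/4.5
  occ <- rep(0L, 9); occ[vac] <- NA; occ[c(2L, 8L)] <- 1L
  rB <- rep(1, 9); rB[2L] <- 2; rB[8L] <- 0.5
  d <- event_distribution(occ, fitness_field(rep(1, 9), rB), motility_params(), lat, vac)
  expect_equal(sum(d$prob[d$type == "B" & d$event == "divide"]), 2.5 / 4.5)
  expect_equal(sum(d$prob[d$type == "A" & d$event == "divide"]), 2 / 4.5)

  # four A(1) neighbours with m_A = 3: divide 1/16, migrate 3/16 each
  occ <- rep(0L, 9); occ[vac] <- NA
  d <- event_distribution(occ, homogeneous_field(9), motility_params(m_A = 3), lat, vac)
  expect_equal(d$prob[d$event == "divide"], rep(1 / 16, 4))
  expect_equal(d$prob[d$event == "migrate"], rep(3 / 16, 4))
})

test_that("event probabilities normalise to one over random configurations", {
  set.seed(21)
  for (k in 1:20) {
    lat <- build_lattice(sample(2:5, 1), sample(2:5, 1))
    n <- lat$n_sites
    field <- sample_field_pair(lat, fitness_uniform(1, 0.9), fitness_uniform(1.5, 1.5))
    mot <- motility_params(runif(1, 0, 4), runif(1, 0, 4))
    occ <- sample(0:1, n, replace = TRUE)
    vac <- sample.int(n, 1)
    occ[vac] <- NA
    d <- event_distribution(occ, field, mot, lat, vac)
    expect_lt(abs(sum(d$prob) - 1), 1e-12)
    expect_true(all(d$prob >= 0))
    # entries exist only for occupied neighbours, typed by their occupant
    expect_true(all(!is.na(occ[d$site])))
    expect_equal(d$type, ifelse(occ[d$site] == 1L, "B", "A"))
  }
})

test_that("event distribution rejects ill-posed vacancies", {
  lat <- build_lattice(2, 2)
  field <- homogeneous_field(4)
  occ <- c(0L, 1L, 0L, 1L)
  expect_error(event_distribution(occ, field, motility_params(), lat, 1L),
               class = "moranfield_logic_error")  # vacancy occupied
  occ_all_vac <- c(NA, NA, NA, 0L)
  expect_error(event_distribution(occ_all_vac, field, motility_params(), lat, 1L),
               class = "moranfield_logic_error")  # every neighbour vacant
  occ <- c(NA, 0L, 0L, 1L)
  zero <- fitness_field(rep(0, 4), rep(1, 4))
  expect_error(event_distribution(occ, zero, motility_params(), lat, 1L),
               class = "moranfield_logic_error")  # N_r = 0
})

test_that("absorbing states are fixed points and zero motility gives one event per update", {
  lat <- build_lattice(3, 3)
  field <- fitness_field(rep(1, 9), rep(2, 9))
  set.seed(31)
  all_a <- rep(0L, 9)
  for (k in 1:20) {
    upd <- death_birth_update(all_a, field, motility_params(2, 2), lat)
    expect_equal(as.integer(upd), all_a)
  }
  occ <- initial_state(lat, 5)
  for (k in 1:50) {
    occ <- death_birth_update(occ, field, motility_params(), lat)
    expect_equal(attr(occ, "n_elementary") <= 1, TRUE)
    # population conservation: every site occupied by exactly one 0/1 cell
    expect_equal(length(occ), 9L)
    expect_true(all(occ %in% c(0L, 1L)))
  }
})

test_that("single-update transition probability on a 1x3 path matches enumeration", {
  # start (B, A, A), neutral, m = 0: reaching (B, B, A) needs death at the
  # middle site (1/3) and the B neighbour to win the division (1/2)
  lat <- build_lattice(1, 3)
  field <- homogeneous_field(3)
  set.seed(61)
  n <- 20000
  hits <- 0L
  for (k in seq_len(n)) {
    upd <- as.integer(death_birth_update(c(1L, 0L, 0L), field, motility_params(), lat))
    if (identical(upd, c(1L, 1L, 0L))) hits <- hits + 1L
  }
  p <- 1 / 6
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the migration kernel reduces to the plain kernel when motility vanishes", {
  lat <- build_lattice(3, 4)
  set.seed(2)
  field <- sample_field_pair(lat, fitness_uniform(1, 0.5), fitness_uniform(1.2, 0.6))
  for (start in c(1L, 6L, 12L)) {
    set.seed(100 + start)
    a <- run_to_absorption(initial_state(lat, start), field, motility_params(), lat,
                           kernel = "plain")
    set.seed(100 + start)
    b <- run_to_absorption(initial_state(lat, start), field, motility_params(), lat,
                           kernel = "migration")
    expect_identical(a$occupancy, b$occupancy)
    expect_equal(a$n_updates, b$n_updates)
    expect_equal(a$n_elementary, b$n_elementary)
  }
})

test_that("compiled engine and pure-R reference replay identical trajectories", {
  lat <- build_lattice(3, 4)
  set.seed(2)
  field <- sample_field_pair(lat, fitness_uniform(1, 0.5), fitness_uniform(1.2, 0.6))
  for (mot in list(motility_params(), motility_params(0.5, 2))) {
    set.seed(99)
    a <- run_to_absorption(initial_state(lat, 5), field, mot, lat, engine = "compiled")
    set.seed(99)
    b <- run_to_absorption(initial_state(lat, 5), field, mot, lat, engine = "reference")
    expect_identical(a$occupancy, b$occupancy)
    expect_equal(a$n_updates, b$n_updates)
    expect_equal(a$n_elementary, b$n_elementary)
    expect_equal(a$fixed, b$fixed)
  }
})

test_that("already-absorbed states return without updates", {
  lat <- build_lattice(2, 2)
  field <- homogeneous_field(4)
  res0 <- run_to_absorption(rep(0L, 4), field, motility_params(), lat)
  expect_false(res0$fixed)
  expect_equal(res0$n_updates, 0)
  res1 <- run_to_absorption(rep(1L, 4), field, motility_params(), lat)
  expect_true(res1$fixed)
  expect_equal(res1$n_updates, 0)
})

test_that("runaway cascades and non-absorbing runs raise diagnosable errors", {
  # zero fitness everywhere with motile mutants: the vacancy can never be
  # refilled by a birth, so the cascade must hit the cap
  lat <- build_lattice(1, 2)
  zero <- fitness_field(c(0, 0), c(0, 0))
  set.seed(1)
  expect_error(
    run_to_absorption(c(1L, 0L), zero, motility_params(m_B = 1), lat,
                      cascade_cap = 100),
    "cap")
  set.seed(1)
  expect_error(
    run_to_absorption(c(1L, 0L), zero, motility_params(m_B = 1), lat,
                      cascade_cap = 100, engine = "reference"),
    class = "moranfield_cascade_error")

  # an unfinished run is distinguishable from absorption and carries the state
  lat3 <- build_lattice(3, 3)
  occ <- rep(0L, 9); occ[1:4] <- 1L
  set.seed(5)
  err <- tryCatch(
    run_to_absorption(occ, homogeneous_field(9), motility_params(), lat3,
                      max_updates = 2),
    condition = function(c) c)
  expect_s3_class(err, "moranfield_max_updates")
  expect_length(err$occupancy, 9)
})

test_that("simulated fixation from each small-lattice start agrees with the exact oracle", {
  # neutral 2x2: every start has exact probability 1/4
  lat <- build_lattice(2, 2)
  field <- homogeneous_field(4)
  ex <- exact_fixation_probability(lat, field)
  set.seed(71)
  fr <- estimate_fixation_single_config(field, motility_params(), lat, 20000)
  expect_lt(abs(as.numeric(fr) - ex$average),
            3 * sqrt(ex$average * (1 - ex$average) / 20000))

  # 3x3 with a checkerboard mutant field: non-trivial site dependence
  lat9 <- build_lattice(3, 3)
  cbf <- fitness_field(rep(1, 9), checkerboard_field(0.5, 1.5, lat9))
  ex9 <- exact_fixation_probability(lat9, cbf)
  set.seed(72)
  fr9 <- estimate_fixation_single_config(cbf, motility_params(), lat9, 20000)
  expect_lt(abs(as.numeric(fr9) - ex9$average),
            3 * sqrt(ex9$average * (1 - ex9$average) / 20000))
})

test_that("immotile residents with zero fitness can never exclude the mutant", {
  lat <- build_lattice(2, 2)
  field <- fitness_field(rep(0, 4), rep(1, 4))
  expect_equal(exact_fixation_probability(lat, field)$average, 1)
  set.seed(81)
  fr <- estimate_fixation_single_config(field, motility_params(), lat, 500)
  expect_equal(as.numeric(fr), 1)
})

test_that("fixation probability increases with the mutant fitness mean", {
  lat <- build_lattice(21, 21)
  n <- 2000
  set.seed(91)
  f_neutral <- as.numeric(
    estimate_fixation_single_config(homogeneous_field(441, 1, 1), motility_params(), lat, n))
  f_adv <- as.numeric(
    estimate_fixation_single_config(homogeneous_field(441, 1, 1.5), motility_params(), lat, n))
  se_n <- sqrt(f_neutral * (1 - f_neutral) / n)
  se_a <- sqrt(f_adv * (1 - f_adv) / n)
  expect_gt(f_adv - 3 * se_a, f_neutral + 3 * se_n)
})
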