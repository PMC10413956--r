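# Synthetic-data generator: mosaic geometry, line of sight, the
# correlated random walk, and dataset-level reproducibility.

test_that("line of sight matches hand-built geometry", {
  open_arena <- habitat_mosaic(20)
  expect_true(line_of_sight(c(0, 0), c(20, 20), open_arena))

  blocker <- habitat_mosaic(20, data.frame(x = 10, y = 10, r = 1,
                                           species = "sage"))
  expect_false(line_of_sight(c(5, 10), c(15, 10), blocker)) # chord hits disc
  expect_true(line_of_sight(c(5, 5), c(15, 5), blocker))    # passes clear

  # discs containing an endpoint are transparent
  expect_true(line_of_sight(c(10, 10), c(15, 10), blocker))
  expect_true(line_of_sight(c(15, 10), c(10.5, 10), blocker))

  # zero-length transition is never obstructed
  expect_true(line_of_sight(c(5, 10), c(5, 10), blocker))
})

test_that("closed-form line of sight agrees with 1-cm brute-force
           sampling on random geometry", {
  set.seed(31)
  for (i in 1:500) {
    m <- habitat_mosaic(40, data.frame(
      x = runif(5, 5, 35), y = runif(5, 5, 35),
      r = runif(5, 0.3, 3), species = "sage"))
    p0 <- runif(2, 0, 40); p1 <- runif(2, 0, 40)
    expect_identical(line_of_sight(p0, p1, m), brute_los(p0, p1, m))
  }
})

test_that("removing a patch never obstructs a visible transition", {
  set.seed(32)
  m <- habitat_mosaic(40, data.frame(
    x = runif(8, 5, 35), y = runif(8, 5, 35),
    r = runif(8, 0.5, 3), species = "greasewood"))
  for (i in 1:100) {
    p0 <- runif(2, 0, 40); p1 <- runif(2, 0, 40)
    vis <- line_of_sight(p0, p1, m)
    drop <- sample(8, 1)
    m2 <- habitat_mosaic(40, m$patches[-drop, ])
    if (vis) expect_true(line_of_sight(p0, p1, m2))
  }
})

test_that("mosaic generation is seeded, bounded, and matches the
           Monte-Carlo cover oracle", {
  cfg <- simulation_config(arena_side = 100, master_seed = 1L)
  expect_identical(generate_mosaic(cfg, 77L)$patches,
                   generate_mosaic(cfg, 77L)$patches)

  cfg0 <- cfg; cfg0$n_patches <- 0L
  expect_equal(nrow(generate_mosaic(cfg0, 1L)$patches), 0L)

  cfg_big <- cfg; cfg_big$n_patches <- 100000L
  expect_error(generate_mosaic(cfg_big, 1L), "80%")

  m <- generate_mosaic(cfg, 123L)
  p <- m$patches
  expect_true(all(p$x - p$r >= 0 & p$x + p$r <= 100 &
                    p$y - p$r >= 0 & p$y + p$r <= 100))
  # vegetated-area fraction: MC point-in-patch vs independent-overlap
  # expectation 1 - prod(1 - a_i)
  set.seed(99)
  pts <- matrix(runif(2 * 20000, 0, 100), ncol = 2)
  in_veg <- vapply(seq_len(nrow(pts)), function(i)
    !is.na(patch_at(pts[i, 1], pts[i, 2], m)), logical(1))
  expected <- 1 - prod(1 - pi * p$r^2 / 100^2)
  expect_lt(abs(mean(in_veg) - expected), 0.02)
})

test_that("the walk respects p_move corners and the ballistic limit", {
  m <- habitat_mosaic(100)
  frozen <- simulate_observation(
    species_movement_params("s", p_move = 0, step_mu_log = 1,
                            step_sigma_log = 0.5, kappa_turn = 1),
    m, n_fixes = 31, seed = 1)
  expect_equal(path_length(compute_steps(frozen)), 0)
  expect_true(all(frozen$fixes$x == frozen$fixes$x[1]))

  # large arena so boundary reflections are rare over a ~30 m path
  m_big <- habitat_mosaic(10000)
  ballistic <- species_movement_params("s", p_move = 1,
                                       step_mu_log = log(1),
                                       step_sigma_log = 0.3,
                                       kappa_turn = 200)
  si <- vapply(1:200, function(s)
    straightness_index(simulate_observation(ballistic, m_big, 31,
                                            seed = s)),
    numeric(1))
  expect_gte(mean(si > 0.95), 0.95)
})

test_that("pooled movement frequency concentrates at p_move", {
  m <- habitat_mosaic(100)
  pars <- species_movement_params("s", p_move = 0.5, step_mu_log = 0,
                                  step_sigma_log = 0.5, kappa_turn = 1)
  moved <- unlist(lapply(1:500, function(s) {
    compute_steps(simulate_observation(pars, m, 31, seed = 1000 + s))$moved
  }))
  expect_equal(mean(moved), 0.5, tolerance = 0.01)
})

test_that("habitat labels agree with the point-in-patch geometry and
           visibility flags with line of sight", {
  ds <- small_dataset(n = 6L, seed = 8L)
  mosaic <- attr(ds, "mosaic")
  for (obs in ds$observations[1:4]) {
    f <- obs$fixes
    for (i in seq_len(nrow(f))) {
      pid <- patch_at(f$x[i], f$y[i], mosaic)
      expect_identical(f$habitat[i],
                       if (is.na(pid)) "open" else "vegetation")
      if (!is.na(pid))
        expect_identical(f$plant_species[i], mosaic$patches$species[pid])
      if (i > 1)
        expect_identical(f$visible_from_previous[i],
                         line_of_sight(c(f$x[i - 1], f$y[i - 1]),
                                       c(f$x[i], f$y[i]), mosaic))
    }
  }
})

test_that("open-arena simulations are fully visible", {
  cfg <- simulation_config(n_visual = 5L, n_chemosensory = 5L,
                           n_patches = 0L, master_seed = 17L)
  ds <- generate_dataset(cfg)
  vi <- vapply(ds$observations, visibility_index, numeric(1))
  expect_true(all(vi == 1))
})

test_that("datasets are a pure function of the master seed", {
  cfg <- simulation_config(n_visual = 6L, n_chemosensory = 6L,
                           arena_side = 80, master_seed = 55L)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_fixes_csv(generate_dataset(cfg), f1)
  write_fixes_csv(generate_dataset(cfg), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  cfg2 <- cfg; cfg2$master_seed <- 56L
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_fixes_csv(generate_dataset(cfg2), f3)
  expect_false(unname(tools::md5sum(f1)) == unname(tools::md5sum(f3)))
})

test_that("dataset structure matches the configuration", {
  ds <- small_dataset(n = 10L, seed = 66L)
  expect_length(ds$observations, 20L)
  expect_setequal(dataset_species(ds), c("visual", "chemosensory"))
  nf <- vapply(ds$observations, n_fixes, integer(1))
  expect_true(all(nf >= 10L & nf <= 31L))
  expect_error(
    generate_dataset(simulation_config(),
                     list(preset_params("visual"),
                          preset_params("visual"))),
    "duplicate")
})
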