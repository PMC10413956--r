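# Path segmentation metrics: step decomposition, whole-path metrics,
# turn angles, and their invariance properties.

test_that("steps carry Euclidean lengths and movement flags", {
  obs <- make_obs(rbind(c(0, 0), c(3, 4), c(3, 4)))
  s <- compute_steps(obs)
  expect_equal(s$length, c(5, 0))
  expect_equal(s$moved, c(TRUE, FALSE))
  expect_true(is.na(s$heading[2]))

  full <- make_obs(cbind(0:30, 0))
  expect_equal(nrow(compute_steps(full)), 30L) # 31 fixes -> 30 intervals

  single <- observation("o", "l", "visual",
                        fixes = data.frame(t = 0, x = 0, y = 0,
                                           habitat = "open"),
                        validate = FALSE)
  expect_error(compute_steps(single), "fewer than 2")
})

test_that("move_epsilon reclassifies small displacements", {
  obs <- make_obs(rbind(c(0, 0), c(0.005, 0), c(1, 0)))
  expect_equal(compute_steps(obs)$moved, c(TRUE, TRUE))
  expect_equal(compute_steps(obs, move_epsilon = 0.01)$moved,
               c(FALSE, TRUE))
})

test_that("whole-path metrics match hand values and a brute-force oracle", {
  straight <- make_obs(cbind(0:30, 0))
  expect_equal(path_length(compute_steps(straight)), 30)
  expect_equal(net_displacement(straight), 30)
  expect_equal(straightness_index(straight), 1)

  stationary <- make_obs(cbind(rep(0, 31), rep(0, 31)))
  expect_equal(path_length(compute_steps(stationary)), 0)
  expect_true(is.na(straightness_index(stationary))) # no path shape

  out_back <- make_obs(cbind(c(0:15, 14:0), 0))
  expect_equal(straightness_index(out_back), 0)

  loop <- make_obs(cbind(c(0:7, 8:1, rep(0, 15)), 0))
  expect_equal(net_displacement(loop), 0)

  set.seed(42)
  for (i in 1:50) {
    obs <- random_obs(31L)
    s <- compute_steps(obs)
    f <- obs$fixes
    oracle <- sum(sqrt(diff(f$x)^2 + diff(f$y)^2)) # independent re-summation
    expect_equal(path_length(s), oracle, tolerance = 1e-12)
    expect_lte(net_displacement(obs), path_length(s) + 1e-9)
    si <- straightness_index(obs)
    if (!is.na(si)) expect_true(si >= 0 && si <= 1)
  }
})

test_that("incomplete observations report no whole-path metrics", {
  short <- make_obs(cbind(0:19, 0))
  expect_true(is.na(path_length(compute_steps(short))))
  expect_true(is.na(net_displacement(short)))
  expect_true(is.na(straightness_index(short)))
  s <- summarize_observation(short)
  expect_false(s$complete)
  expect_gt(length(s$step_lengths), 0L)
  expect_true(is.na(s$path_length))
})

test_that("turn angles follow the heading-difference convention", {
  collinear <- make_obs(rbind(c(0, 0), c(1, 0), c(2, 0)))
  ta <- turn_angles(compute_steps(collinear))
  expect_equal(ta$signed, 0)
  expect_equal(ta$absolute, 0)

  left <- make_obs(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(turn_angles(compute_steps(left))$signed, 90)

  # pause mid-path: heading carried across the non-movement interval
  paused <- make_obs(rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0)))
  ta <- turn_angles(compute_steps(paused))
  expect_equal(ta$signed, 0)
  expect_length(ta$signed, 1L)
  # drop-across-pause alternative yields no turn at all here
  ta2 <- turn_angles(compute_steps(paused), across_pauses = FALSE)
  expect_length(ta2$signed, 0L)

  one_move <- make_obs(rbind(c(0, 0), c(1, 0), c(1, 0)))
  expect_length(turn_angles(compute_steps(one_move))$signed, 0L)
})

test_that("turn angles are invariant under rotation and translation,
           and signed angles negate under reflection", {
  set.seed(7)
  for (i in 1:25) {
    obs <- random_obs(20L)
    base <- turn_angles(compute_steps(obs))$signed
    phi <- runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    xy <- as.matrix(obs$fixes[, c("x", "y")]) %*% t(Rm)
    rot <- make_obs(sweep(xy, 2, c(runif(1, -50, 50), runif(1, -50, 50)),
                          "+"))
    rot_signed <- turn_angles(compute_steps(rot))$signed
    expect_lt(max(abs(rot_signed - base), 0), 1e-9)
    refl <- make_obs(cbind(obs$fixes$x, -obs$fixes$y))
    refl_signed <- turn_angles(compute_steps(refl))$signed
    expect_lt(max(abs(refl_signed + base), 0), 1e-9)
    expect_lt(max(abs(abs(refl_signed) - abs(base)), 0), 1e-9)
  }
})

test_that("proportion moving and visibility index count transitions", {
  obs <- make_obs(rbind(c(0, 0), c(1, 0), c(1, 0), c(2, 0), c(2, 0)))
  expect_equal(proportion_moving(compute_steps(obs)), 0.5)

  vis <- make_obs(cbind(0:4, 0), visible = c(NA, TRUE, TRUE, TRUE, FALSE))
  expect_equal(visibility_index(vis), 0.75)
  all_clear <- make_obs(cbind(0:4, 0))
  expect_equal(visibility_index(all_clear), 1)
  missing <- make_obs(cbind(0:4, 0),
                      visible = c(NA, TRUE, NA, TRUE, TRUE))
  expect_warning(vi <- visibility_index(missing), "missing")
  expect_true(is.na(vi))
})

test_that("path summaries satisfy their internal invariants on
           simulated observations", {
  ds <- small_dataset(n = 15L, seed = 99L)
  for (obs in ds$observations) {
    s <- summarize_observation(obs)
    steps <- compute_steps(obs)
    expect_equal(length(s$turn_angles_signed),
                 max(length(s$step_lengths) - 1L, 0L))
    expect_equal(s$turn_angles_abs, abs(s$turn_angles_signed))
    expect_true(all(s$turn_angles_abs >= 0 & s$turn_angles_abs <= 180))
    expect_true(s$proportion_moving >= 0 && s$proportion_moving <= 1)
    if (s$complete) {
      expect_equal(s$path_length, sum(steps$length), tolerance = 1e-12)
      expect_lte(s$net_displacement, s$path_length + 1e-9)
      if (!is.na(s$straightness_index))
        expect_true(s$straightness_index >= 0 && s$straightness_index <= 1)
    } else {
      expect_true(is.na(s$path_length) && is.na(s$net_displacement))
    }
  }
  # metric values invariant to observation order
  rev_ds <- fix_dataset(rev(ds$observations), ds$provenance)
  a <- summarize_dataset(ds); a <- a[order(a$observation_id), ]
  b <- summarize_dataset(rev_ds); b <- b[order(b$observation_id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})
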