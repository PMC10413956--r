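# Regression stages: record assembly, the step-length mixed model, and
# the observer-effect trend.

# Balanced simulated design: n_ind individuals x m records, known SVL
# slope, random intercept sd sigma_b, residual sd sigma_e.
sim_records <- function(n_ind = 30, m = 8, beta_svl = 0, sigma_b = 0.3,
                        sigma_e = 1) {
  svl <- rnorm(n_ind, 100, 10)
  b <- rnorm(n_ind, 0, sigma_b)
  data.frame(
    lizard_id = rep(sprintf("l%03d", seq_len(n_ind)), each = m),
    step_length = rep(10 + beta_svl * svl + b, each = m) +
      rnorm(n_ind * m, 0, sigma_e),
    t = rep(seq_len(m), n_ind),
    sex = rep(sample(c("M", "F"), n_ind, replace = TRUE), each = m),
    svl_mm = rep(svl, each = m),
    air_temp_c = rnorm(n_ind * m, 25, 2),
    wind_speed_ms = rnorm(n_ind * m, 2, 0.5),
    stringsAsFactors = FALSE)
}

test_that("step records cover exactly the moving intervals and drop
           incomplete covariates listwise", {
  ds <- small_dataset(n = 6L, seed = 12L)
  rec <- suppressMessages(build_step_records(ds, "visual"))
  # oracle recount: moving steps of visual observations
  oracle <- sum(vapply(ds$observations, function(o) {
    if (o$species != "visual") return(0L)
    sum(compute_steps(o)$moved)
  }, integer(1)))
  expect_equal(nrow(rec) + attr(rec, "n_dropped"), oracle)
  expect_true(all(rec$step_length > 0))

  # knock out one weather value: exactly one more record drops
  ds2 <- ds
  vis_ids <- which(vapply(ds2$observations,
                          function(o) o$species == "visual", logical(1)))
  o <- ds2$observations[[vis_ids[1]]]
  moving_to <- compute_steps(o)$from_t[compute_steps(o)$moved][1]
  o$fixes$wind_speed_ms[match(moving_to, o$fixes$t)] <- NA
  ds2$observations[[vis_ids[1]]] <- o
  expect_message(rec2 <- build_step_records(ds2, "visual"), "dropped")
  expect_equal(nrow(rec2), nrow(rec) - 1L)

  expect_error(build_step_records(ds, "no_such_species"), "no observations")
})

test_that("the mixed model recovers a known SVL slope", {
  set.seed(41)
  rec <- sim_records(n_ind = 50, m = 20, beta_svl = 0.05)
  class(rec) <- c("step_records", "data.frame")
  fit <- fit_step_length_lmm(rec)
  svl_row <- fit$fixed_effects[fit$fixed_effects$effect == "svl_mm", ]
  expect_equal(svl_row$estimate, 0.05, tolerance = 0.25)
  expect_lt(svl_row$p, 0.05)
  expect_true(svl_row$between_individual)
  expect_equal(fit$n_individuals, 50L)
  # containment df: individuals minus between-individual columns
  expect_equal(svl_row$df_den,
               50 - sum(fit$fixed_effects$between_individual))
  expect_true(all(fit$variance_components >= 0))
})

test_that("degenerate designs are flagged", {
  set.seed(42)
  rec1 <- sim_records(n_ind = 1, m = 20)
  class(rec1) <- c("step_records", "data.frame")
  expect_error(fit_step_length_lmm(rec1), "single individual")

  # no individual variance: fit close to OLS, singularity tolerated
  rec0 <- sim_records(n_ind = 25, m = 8, sigma_b = 0)
  class(rec0) <- c("step_records", "data.frame")
  fit <- fit_step_length_lmm(rec0)
  ols <- lm(step_length ~ sex + svl_mm + air_temp_c + wind_speed_ms,
            data = rec0)
  expect_equal(fit$fixed_effects$estimate, unname(coef(ols)),
               tolerance = 0.05)
})

test_that("estimates are invariant to record order and id relabeling", {
  set.seed(43)
  rec <- sim_records(n_ind = 20, m = 6, beta_svl = 0.03)
  class(rec) <- c("step_records", "data.frame")
  fit1 <- fit_step_length_lmm(rec)
  shuffled <- rec[sample(nrow(rec)), ]
  shuffled$lizard_id <- paste0("zz_", shuffled$lizard_id)
  class(shuffled) <- c("step_records", "data.frame")
  fit2 <- fit_step_length_lmm(shuffled)
  expect_equal(fit1$fixed_effects$estimate, fit2$fixed_effects$estimate,
               tolerance = 1e-6)
  expect_equal(fit1$variance_components, fit2$variance_components,
               tolerance = 1e-6)
})

test_that("log-transform and Satterthwaite options are honoured", {
  set.seed(44)
  rec <- sim_records(n_ind = 15, m = 6)
  rec$step_length <- exp(rec$step_length / 10)
  class(rec) <- c("step_records", "data.frame")
  fit_log <- fit_step_length_lmm(rec, response_transform = "log")
  expect_equal(fit_log$response_transform, "log")
  if (requireNamespace("lmerTest", quietly = TRUE)) {
    fit_s <- fit_step_length_lmm(rec, df_method = "satterthwaite")
    expect_equal(fit_s$df_method, "satterthwaite")
    expect_true(all(is.finite(fit_s$fixed_effects$df_den)))
  }
})

test_that("the observer-effect trend detects a perfect time trend and
           reports df = (1, n - 2)", {
  # response rises deterministically with the minute index
  obs <- lapply(1:4, function(k) {
    xs <- cumsum(c(0, 0.1 * (0:29)))  # step i has length 0.1 * i...
    make_obs(cbind(xs, 0), id = paste0("o", k),
             lizard = paste0("l", k))
  })
  ds <- fix_dataset(obs)
  tr <- suppressWarnings(observer_effect_trend(ds, "visual", "step_length"))
  expect_lt(tr$p, 1e-6)
  expect_gt(tr$slope, 0)
  expect_equal(tr$df[2], tr$n - 2L)

  # flat response: F = 0, p = 1
  flat <- lapply(1:3, function(k)
    make_obs(cbind(0:30, 0), id = paste0("f", k),
             lizard = paste0("fl", k)))
  tr0 <- observer_effect_trend(fix_dataset(flat), "visual", "step_length")
  expect_equal(tr0$F, 0)
  expect_equal(tr0$p, 1)
})

test_that("a time-free response yields a flat trend (Monte Carlo)", {
  set.seed(45)
  cover <- replicate(100, {
    obs <- lapply(1:3, function(k)
      random_obs(31L, p_move = 1, id = paste0("o", k),
                 lizard = paste0("l", k)))
    tr <- observer_effect_trend(fix_dataset(obs), "visual",
                                "step_length")
    tr$p > 0.05
  })
  expect_gte(mean(cover), 0.85) # ~95% coverage, Monte-Carlo slack
})
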