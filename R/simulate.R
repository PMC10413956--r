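# Correlated-random-walk simulator over a vegetation-patch mosaic.
#
# The generator stands in for field data: two species of foragers with
# contrasting movement frequency, step-length scale, turn concentration
# and cover bias, observed for 30 minutes at 1-min fixes.  Every draw is
# a pure function of (config, params, master_seed): per-observation
# sub-seeds come from a documented counter scheme (see derive_seed()).

#' Species movement parameters for the simulator
#'
#' @param label species label carried into the dataset.
#' @param p_move probability of moving in any 1-min interval.
#' @param step_mu_log,step_sigma_log lognormal parameters of moving-step
#'   length (metres); the median step is `exp(step_mu_log)`.
#' @param kappa_turn von Mises concentration of signed turn angles; the
#'   expected mean resultant length is `I1(kappa)/I0(kappa)`.
#' @param cover_bias probability that a moving animal currently in the
#'   open steers toward a vegetation patch instead of drawing a plain
#'   correlated turn.  A steered move aims at the target patch centre
#'   (with aiming noise `kappa_steer`) and stops there rather than
#'   overshooting; the target persists across consecutive steered moves
#'   until the animal reaches vegetation.
#' @param plant_preference named numeric weights over plant species,
#'   used when choosing which patch to steer toward.
#' @param open_start must the starting fix be in the open?
#' @param svl_mean_mm,svl_sd_mm normal parameters for snout-vent length.
#' @param sense_range_m patches within this range are candidate steering
#'   targets; beyond it the nearest patch is used.
#' @param kappa_steer von Mises concentration of the aiming error around
#'   the direction to the target patch centre.
#' @param target_min_m lower bound on the centre distance of candidate
#'   steering targets, so a steered approach spans a couple of 1-min
#'   steps as a bush-to-bush forager's does.
#' @param turn_sign_persistence probability that an unsteered turn keeps
#'   the sign of the previous turn.  0.5 gives independent von Mises
#'   turns; values above 0.5 produce looping, area-restricted search
#'   paths while leaving the marginal turn-angle distribution (and so
#'   the mean resultant length) unchanged, because the von Mises
#'   magnitude is symmetric and the sign chain is balanced.
#' @return object of class `species_movement_params`.
#' @export
species_movement_params <- function(label, p_move, step_mu_log,
                                    step_sigma_log, kappa_turn,
                                    cover_bias = 0,
                                    plant_preference = NULL,
                                    open_start = FALSE,
                                    svl_mean_mm = 90, svl_sd_mm = 8,
                                    sense_range_m = 20,
                                    kappa_steer = 20,
                                    target_min_m = 5,
                                    turn_sign_persistence = 0.5) {
  stopifnot(p_move >= 0, p_move <= 1, step_sigma_log > 0, kappa_turn >= 0,
            cover_bias >= 0, cover_bias <= 1, sense_range_m > 0,
            kappa_steer >= 0,
            turn_sign_persistence >= 0, turn_sign_persistence <= 1)
  if (is.null(plant_preference))
    plant_preference <- stats::setNames(rep(1, length(PLANT_SPECIES)),
                                        PLANT_SPECIES)
  structure(list(label = label, p_move = p_move,
                 step_mu_log = step_mu_log, step_sigma_log = step_sigma_log,
                 kappa_turn = kappa_turn, cover_bias = cover_bias,
                 plant_preference = plant_preference,
                 open_start = open_start,
                 svl_mean_mm = svl_mean_mm, svl_sd_mm = svl_sd_mm,
                 sense_range_m = sense_range_m,
                 kappa_steer = kappa_steer,
                 target_min_m = target_min_m,
                 turn_sign_persistence = turn_sign_persistence),
            class = "species_movement_params")
}

#' Shipped species presets
#'
#' Two presets contrasting a sit-and-wait visual forager with a widely
#' ranging chemosensory forager:
#'
#' * `"visual"`: moves in 44% of intervals, median step 2.1 m, turn
#'   concentration giving an expected mean resultant length near 0.34,
#'   weak cover attraction (0.1), starts in the open, prefers greasewood
#'   when steering to vegetation, and alternates turn signs
#'   (`turn_sign_persistence = 0.25`) -- the course-keeping zig-zag of a
#'   stalking searcher, which straightens the path without changing the
#'   turn-angle distribution.
#' * `"chemosensory"`: moves in 75% of intervals, median step 4.2 m,
#'   expected resultant length near 0.28, strong cover attraction (0.5)
#'   with bush-to-bush steering over a 14 m sensing range,
#'   near-uniform preference over sage and greasewood, and persistent
#'   turn signs (`turn_sign_persistence = 0.85`) -- looping,
#'   area-restricted search that lowers path straightness at the same
#'   turn-angle distribution.
#'
#' The quantitative anchors are movement frequencies and step-length
#' medians typical of the two foraging modes; the presets aim to
#' reproduce qualitative contrasts (movement frequency, step scale, path
#' straightness, habitat bias), not any particular field dataset.
#'
#' @param name `"visual"` or `"chemosensory"`.
#' @return a `species_movement_params`.
#' @export
preset_params <- function(name = c("visual", "chemosensory")) {
  name <- match.arg(name)
  if (name == "visual") {
    species_movement_params(
      label = "visual", p_move = 0.44,
      step_mu_log = log(2.1), step_sigma_log = 0.95,
      kappa_turn = 0.72,      # A(0.72) ~ 0.34
      cover_bias = 0.1,
      plant_preference = c(greasewood = 0.70, sage = 0.15, shadscale = 0.05,
                           rabbit_brush = 0.04, horse_brush = 0.03,
                           ryegrass = 0.03),
      open_start = TRUE,
      svl_mean_mm = 105, svl_sd_mm = 8,
      turn_sign_persistence = 0.25)
  } else {
    species_movement_params(
      label = "chemosensory", p_move = 0.75,
      step_mu_log = log(4.2), step_sigma_log = 0.75,
      kappa_turn = 0.585,     # A(0.585) ~ 0.28
      cover_bias = 0.5,
      plant_preference = c(greasewood = 0.42, sage = 0.42, shadscale = 0.06,
                           rabbit_brush = 0.04, horse_brush = 0.03,
                           ryegrass = 0.03),
      open_start = FALSE,
      svl_mean_mm = 78, svl_sd_mm = 6,
      sense_range_m = 14,
      turn_sign_persistence = 0.85)
  }
}

#' Simulation configuration
#'
#' @param n_visual,n_chemosensory observations per species for the
#'   shipped presets (used by [generate_dataset()] defaults).
#' @param n_fixes fixes per complete observation (<= 31; default 31,
#'   i.e. a 30-min observation).
#' @param truncation_prob probability an observation is cut short; a
#'   truncated observation has a uniform length of 10..30 fixes.
#' @param arena_side arena side length, metres.
#' @param n_patches number of vegetation patches; the default gives
#'   roughly 15% vegetated cover.
#' @param patch_r_meanlog,patch_r_sdlog lognormal parameters of patch
#'   radius (metres).
#' @param plant_weights named weights for patch plant species.
#' @param master_seed integer master seed; every random element of the
#'   dataset derives from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_visual = 61L, n_chemosensory = 51L,
                              n_fixes = 31L, truncation_prob = 0.15,
                              arena_side = 150, n_patches = NULL,
                              patch_r_meanlog = log(1.2),
                              patch_r_sdlog = 0.35,
                              plant_weights = NULL,
                              master_seed = 1L) {
  stopifnot(n_fixes >= 2L, n_fixes <= MAX_FIXES,
            truncation_prob >= 0, truncation_prob <= 1)
  if (is.null(plant_weights))
    plant_weights <- c(greasewood = 0.40, sage = 0.40, shadscale = 0.08,
                       rabbit_brush = 0.05, horse_brush = 0.04,
                       ryegrass = 0.03)
  if (is.null(n_patches)) {
    # target ~15% vegetated cover: n * pi * E[r^2] = 0.15 * side^2
    er2 <- exp(2 * patch_r_meanlog + 2 * patch_r_sdlog^2)
    n_patches <- round(0.15 * arena_side^2 / (pi * er2))
  }
  structure(list(n_visual = as.integer(n_visual),
                 n_chemosensory = as.integer(n_chemosensory),
                 n_fixes = as.integer(n_fixes),
                 truncation_prob = truncation_prob,
                 arena_side = arena_side,
                 n_patches = as.integer(n_patches),
                 patch_r_meanlog = patch_r_meanlog,
                 patch_r_sdlog = patch_r_sdlog,
                 plant_weights = plant_weights,
                 master_seed = as.integer(master_seed)),
            class = "simulation_config")
}

# Pick a steering target patch for an animal at (x, y): candidates are
# patches a few steps ahead (centre distance between min_target_m and
# the sensing range, falling back to the nearest patch when none
# qualifies), sampled with weight plant_preference / (1 + d).  The lower
# distance bound makes a steered approach span a couple of 1-min steps,
# as a bush-to-bush forager's does, instead of terminating immediately.
choose_target_patch <- function(x, y, mosaic, params) {
  p <- mosaic$patches
  if (nrow(p) == 0L) return(NA_integer_)
  d <- sqrt((p$x - x)^2 + (p$y - y)^2)
  cand <- which(d <= params$sense_range_m & d >= params$target_min_m)
  if (length(cand) == 0L) return(which.min(d))
  pref <- params$plant_preference[p$species[cand]]
  pref[is.na(pref)] <- min(params$plant_preference)
  w <- as.numeric(pref) / (1 + d[cand])
  if (all(w <= 0)) return(cand[which.min(d[cand])])
  cand[sample.int(length(cand), 1L, prob = w)]
}

# Reflect a coordinate into [0, side] (repeated folding).
reflect_coord <- function(v, side) {
  v <- v %% (2 * side)
  ifelse(v > side, 2 * side - v, v)
}

#' Simulate one focal observation
#'
#' Correlated random walk: the start position is uniform over the arena
#' (re-drawn until it lands in the open when `params$open_start`), the
#' initial heading uniform.  Each minute the animal moves with
#' probability `p_move`; a moving animal draws a lognormal step length
#' and a von Mises(0, `kappa_turn`) signed turn, except that with
#' probability `cover_bias` an animal in the open steers toward a
#' vegetation patch: the heading is replaced by the direction to the
#' target patch centre plus von Mises(0, `kappa_steer`) aiming noise,
#' the step stops at the patch centre instead of overshooting, and the
#' target persists across consecutive steered moves until cover is
#' reached.  The arena boundary reflects;
#' after a reflected move the realised displacement direction becomes
#' the new heading.  Habitat and plant labels come from the exact
#' point-in-patch test and the visibility flag from [line_of_sight()].
#'
#' @param params a `species_movement_params`.
#' @param mosaic a `habitat_mosaic`.
#' @param n_fixes number of fixes (>= 2).
#' @param seed integer RNG seed.
#' @param observation_id,lizard_id identifiers.
#' @param sex,svl_mm,mass_g animal covariates; drawn from the params when
#'   `NA`.
#' @param weather optional data frame with columns `t`, `air_temp_c`,
#'   `wind_speed_ms` covering minutes `0..n_fixes - 1`.
#' @return an `observation`.
#' @export
simulate_observation <- function(params, mosaic, n_fixes = 31L, seed = 1L,
                                 observation_id = "obs_1",
                                 lizard_id = "liz_1",
                                 sex = NA_character_, svl_mm = NA_real_,
                                 mass_g = NA_real_, weather = NULL) {
  stopifnot(inherits(params, "species_movement_params"),
            inherits(mosaic, "habitat_mosaic"), n_fixes >= 2L)
  side <- mosaic$arena_side
  with_seed(seed, {
    if (is.na(sex)) sex <- sample(c("M", "F"), 1L)
    if (is.na(svl_mm))
      svl_mm <- round(stats::rnorm(1, params$svl_mean_mm, params$svl_sd_mm), 1)
    if (is.na(mass_g)) # simple cubic allometry with lognormal scatter
      mass_g <- round(3e-5 * svl_mm^3 * stats::rlnorm(1, 0, 0.1), 1)
    x <- numeric(n_fixes); y <- numeric(n_fixes)
    x[1] <- stats::runif(1, 0, side); y[1] <- stats::runif(1, 0, side)
    if (params$open_start) {
      tries <- 0L
      while (!is.na(patch_at(x[1], y[1], mosaic)) && tries < 200L) {
        x[1] <- stats::runif(1, 0, side); y[1] <- stats::runif(1, 0, side)
        tries <- tries + 1L
      }
    }
    heading <- stats::runif(1, -180, 180)
    target <- NA_integer_ # persistent steering target patch
    prev_sign <- sample(c(-1, 1), 1L) # turn-sign state
    for (i in 2:n_fixes) {
      if (stats::runif(1) < params$p_move) {
        in_open <- is.na(patch_at(x[i - 1], y[i - 1], mosaic))
        if (!in_open) target <- NA_integer_ # reached cover: drop target
        steer <- in_open && nrow(mosaic$patches) > 0 &&
          stats::runif(1) < params$cover_bias
        len <- stats::rlnorm(1, params$step_mu_log, params$step_sigma_log)
        if (steer) {
          if (is.na(target))
            target <- choose_target_patch(x[i - 1], y[i - 1], mosaic,
                                          params)
          d_target <- sqrt((mosaic$patches$x[target] - x[i - 1])^2 +
                             (mosaic$patches$y[target] - y[i - 1])^2)
          to_patch <- atan2(mosaic$patches$y[target] - y[i - 1],
                            mosaic$patches$x[target] - x[i - 1]) * RAD2DEG
          heading <- wrap_deg(to_patch + rvonmises(1, 0, params$kappa_steer))
          len <- min(len, d_target) # stop at the bush, don't overshoot
        } else {
          target <- NA_integer_
          turn <- rvonmises(1, 0, params$kappa_turn)
          if (params$turn_sign_persistence != 0.5 && turn != 0) {
            keep <- stats::runif(1) < params$turn_sign_persistence
            turn <- abs(turn) * (if (keep) prev_sign else -prev_sign)
          }
          if (turn != 0) prev_sign <- sign(turn)
          heading <- wrap_deg(heading + turn)
        }
        nx <- x[i - 1] + len * cos(heading * DEG2RAD)
        ny <- y[i - 1] + len * sin(heading * DEG2RAD)
        nx <- reflect_coord(nx, side); ny <- reflect_coord(ny, side)
        x[i] <- nx; y[i] <- ny
        if (nx != x[i - 1] || ny != y[i - 1])
          heading <- wrap_deg(atan2(ny - y[i - 1], nx - x[i - 1]) * RAD2DEG)
      } else {
        x[i] <- x[i - 1]; y[i] <- y[i - 1]
      }
    }
    pidx <- vapply(seq_len(n_fixes),
                   function(i) patch_at(x[i], y[i], mosaic), integer(1))
    habitat <- ifelse(is.na(pidx), "open", "vegetation")
    plant <- ifelse(is.na(pidx), NA_character_,
                    mosaic$patches$species[pidx])
    vis <- c(NA, vapply(2:n_fixes, function(i)
      line_of_sight(c(x[i - 1], y[i - 1]), c(x[i], y[i]), mosaic),
      logical(1)))
    tt <- 0:(n_fixes - 1L)
    if (is.null(weather)) {
      air <- rep(NA_real_, n_fixes); wind <- rep(NA_real_, n_fixes)
    } else {
      m <- match(tt, weather$t)
      air <- weather$air_temp_c[m]; wind <- weather$wind_speed_ms[m]
    }
    observation(observation_id, lizard_id, params$label, sex, svl_mm,
                mass_g,
                fixes = data.frame(t = tt, x = x, y = y, habitat = habitat,
                                   plant_species = plant,
                                   visible_from_previous = vis,
                                   air_temp_c = air, wind_speed_ms = wind,
                                   stringsAsFactors = FALSE))
  })
}

# Slow random-walk weather series shared by all observations of a
# dataset at matching minute indices.
simulate_weather <- function(n_minutes, seed) {
  with_seed(seed, {
    air <- cumsum(c(stats::rnorm(1, 25, 2),
                    stats::rnorm(n_minutes - 1, 0.05, 0.15)))
    wind <- pmax(cumsum(c(stats::rnorm(1, 2.5, 0.5),
                          stats::rnorm(n_minutes - 1, 0, 0.2))), 0)
    data.frame(t = 0:(n_minutes - 1L),
               air_temp_c = round(air, 2),
               wind_speed_ms = round(wind, 2))
  })
}

#' Generate a full synthetic dataset
#'
#' One mosaic and one weather series per dataset; per-observation
#' sub-seeds derive from the master seed by a fixed counter scheme
#' (`derive_seed(master, species_index, observation_index)`), so the
#' dataset is a pure function of `(config, params, master_seed)`.
#' Observations are truncated (uniform length 10..30 fixes) with
#' probability `config$truncation_prob`.
#'
#' @param config a `simulation_config`.
#' @param params_by_species list of `species_movement_params`, one per
#'   species; defaults to the two shipped presets.
#' @param n_per_species integer vector of observation counts aligned
#'   with `params_by_species`; defaults to
#'   `c(config$n_visual, config$n_chemosensory)`.
#' @return a `fix_dataset` with generator provenance.
#' @export
generate_dataset <- function(config = simulation_config(),
                             params_by_species = list(
                               preset_params("visual"),
                               preset_params("chemosensory")),
                             n_per_species = NULL) {
  labels <- vapply(params_by_species, function(p) p$label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate species labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (is.null(n_per_species))
    n_per_species <- c(config$n_visual, config$n_chemosensory)[
      seq_along(params_by_species)]
  stopifnot(length(n_per_species) == length(params_by_species))
  mosaic <- generate_mosaic(config, derive_seed(config$master_seed, 0L, 0L))
  weather <- simulate_weather(MAX_FIXES,
                              derive_seed(config$master_seed, 0L, 1L))
  obs <- list()
  for (s in seq_along(params_by_species)) {
    params <- params_by_species[[s]]
    for (i in seq_len(n_per_species[s])) {
      seed_i <- derive_seed(config$master_seed, s, i)
      nf <- with_seed(derive_seed(config$master_seed, s + 100L, i), {
        if (stats::runif(1) < config$truncation_prob)
          sample(10:30, 1L) else config$n_fixes
      })
      obs[[length(obs) + 1L]] <- simulate_observation(
        params, mosaic, n_fixes = nf, seed = seed_i,
        observation_id = sprintf("%s_%03d", params$label, i),
        lizard_id = sprintf("lz_%s_%03d", params$label, i),
        weather = weather)
    }
  }
  ds <- fix_dataset(obs, provenance = list(
    source = "pathseg synthetic generator",
    generator_version = "1",
    master_seed = config$master_seed,
    n_per_species = stats::setNames(as.list(n_per_species), labels),
    arena_side = config$arena_side,
    n_patches = nrow(mosaic$patches)))
  attr(ds, "mosaic") <- mosaic
  ds
}

#' Write a mosaic as a JSON sidecar
#' @param mosaic a `habitat_mosaic`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mosaic_json <- function(mosaic, path) {
  jsonlite::write_json(list(arena_side = mosaic$arena_side,
                            patches = mosaic$patches),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mosaic JSON sidecar
#' @param path path written by [write_mosaic_json()].
#' @return a `habitat_mosaic`.
#' @export
read_mosaic_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  patches <- if (length(x$patches) == 0) empty_patches() else
    as.data.frame(x$patches)
  habitat_mosaic(x$arena_side, patches)
}
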