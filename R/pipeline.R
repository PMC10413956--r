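# Full-analysis orchestration: per-species movement summaries,
# between-species comparisons, circular statistics, habitat-use
# contingency tables, regression stages, and report export.

#' Analysis run configuration
#'
#' @param move_epsilon movement threshold, metres (default 0: any
#'   recorded displacement is movement).
#' @param across_pauses carry heading across non-movement intervals when
#'   forming turn angles?
#' @param circular_angles `"signed"` (default) or `"folded"`: the angle
#'   convention fed to the circular tests.  Medians, KS comparisons and
#'   histograms always use folded angles in \[0, 180\].
#' @param pooling `"pooled"` (fix-level values pooled by species; note
#'   this treats fixes from one individual as independent) or
#'   `"per_individual"` (one value per observation: median step length,
#'   median folded turn angle, proportion of fixes in the open).
#' @param lmm_df_method `"containment"` or `"satterthwaite"`.
#' @param lmm_transform `"identity"` or `"log"` response for the
#'   step-length mixed model.
#' @param fit_models fit the mixed-effects and observer-trend stages?
#' @param alpha significance level used when flagging results.
#' @param turn_bin_deg turn-angle histogram bin width, degrees.
#' @param step_bin_m step-length histogram bin width, metres.
#' @return object of class `run_config`.
#' @export
run_config <- function(move_epsilon = 0,
                       across_pauses = TRUE,
                       circular_angles = c("signed", "folded"),
                       pooling = c("pooled", "per_individual"),
                       lmm_df_method = c("containment", "satterthwaite"),
                       lmm_transform = c("identity", "log"),
                       fit_models = TRUE,
                       alpha = 0.05,
                       turn_bin_deg = 45,
                       step_bin_m = 2) {
  structure(list(move_epsilon = move_epsilon,
                 across_pauses = isTRUE(across_pauses),
                 circular_angles = match.arg(circular_angles),
                 pooling = match.arg(pooling),
                 lmm_df_method = match.arg(lmm_df_method),
                 lmm_transform = match.arg(lmm_transform),
                 fit_models = isTRUE(fit_models),
                 alpha = alpha,
                 turn_bin_deg = turn_bin_deg,
                 step_bin_m = step_bin_m),
            class = "run_config")
}

med_range <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    return(c(median = NA_real_, min = NA_real_, max = NA_real_, n = 0))
  c(median = stats::median(x), min = min(x), max = max(x), n = length(x))
}

# Per-species habitat / visibility / plant counts from the raw fixes.
habitat_counts <- function(dataset) {
  tab <- as_fix_table(dataset)
  species <- unique(tab$species)
  cover <- t(vapply(species, function(s) {
    h <- tab$habitat[tab$species == s]
    c(open = sum(h == "open"), vegetation = sum(h == "vegetation"))
  }, numeric(2)))
  vis_raw <- tab$visible_from_previous
  visibility <- t(vapply(species, function(s) {
    v <- vis_raw[tab$species == s]
    v <- v[!is.na(v)]
    c(clear = sum(v), obstructed = sum(!v))
  }, numeric(2)))
  plants <- sort(unique(tab$plant_species[!is.na(tab$plant_species)]))
  plant <- if (length(plants) >= 2L) {
    m <- t(vapply(species, function(s) {
      p <- tab$plant_species[tab$species == s & !is.na(tab$plant_species)]
      vapply(plants, function(pl) sum(p == pl), numeric(1))
    }, numeric(length(plants))))
    colnames(m) <- plants
    m
  } else NULL
  list(cover = cover, visibility = visibility, plant = plant)
}

#' Run the complete movement and habitat-use analysis
#'
#' Executes the full chain on a two-species dataset: path metrics per
#' observation, per-species median (range) summaries for the five
#' movement metrics, Mann-Whitney comparisons, Kolmogorov-Smirnov
#' distribution tests for step length and folded turn angle, circular
#' statistics per species (mean resultant length, Rayleigh uniformity,
#' von Mises fit with Watson U-squared conformity), a two-proportion z
#' test of the proportion of intervals with movement, turn-angle versus
#' step-length correlations, habitat-use chi-squares (open/vegetation,
#' visibility, plant species), the step-length mixed model and the
#' observer-effect trend per species.
#'
#' Incomplete observations contribute step lengths and turn angles to
#' pooled analyses but no whole-path metrics.  Stage failures are
#' trapped and recorded in `$errors`, leaving a partial report.
#'
#' @param dataset a `fix_dataset` with exactly two species.
#' @param config a `run_config`.
#' @return object of class `analysis_report`.
#' @export
run_full_analysis <- function(dataset, config = run_config()) {
  species <- dataset_species(dataset)
  if (length(species) != 2L)
    stop("the analysis requires exactly two species; found ",
         length(species), " (", paste(species, collapse = ", "), ")")
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  summaries <- summarize_dataset(dataset, config$move_epsilon,
                                 config$across_pauses)
  sub <- lapply(species, function(s) subset_species(dataset, s))
  names(sub) <- species
  steps_by_sp <- lapply(sub, pooled_step_lengths, config$move_epsilon)
  turns_signed <- lapply(sub, pooled_turn_angles, config$move_epsilon,
                         folded = FALSE, config$across_pauses)
  turns_folded <- lapply(turns_signed, abs)

  # --- per-species median (range) of the five movement metrics --------
  per_species <- lapply(species, function(s) {
    ss <- summaries[summaries$species == s, ]
    rbind(step_length = med_range(steps_by_sp[[s]]),
          path_length = med_range(ss$path_length),
          net_displacement = med_range(ss$net_displacement),
          straightness_index = med_range(ss$straightness_index),
          turn_angle = med_range(turns_folded[[s]]))
  })
  names(per_species) <- species

  # --- between-species comparisons ------------------------------------
  pool_metric <- function(metric) {
    if (config$pooling == "pooled") {
      switch(metric,
             step_length = steps_by_sp,
             turn_angle = turns_folded)
    } else {
      col <- switch(metric, step_length = "median_step_length",
                    turn_angle = "median_turn_angle_abs")
      lapply(species, function(s)
        stats::na.omit(summaries[summaries$species == s, col]))
    }
  }
  obs_metric <- function(col) {
    lapply(species, function(s)
      stats::na.omit(summaries[summaries$species == s, col]))
  }
  movement_comparisons <- list(
    step_length = stage("mw_step_length", {
      v <- pool_metric("step_length"); mann_whitney_u(v[[1]], v[[2]])
    }),
    path_length = stage("mw_path_length", {
      v <- obs_metric("path_length"); mann_whitney_u(v[[1]], v[[2]])
    }),
    net_displacement = stage("mw_net_displacement", {
      v <- obs_metric("net_displacement"); mann_whitney_u(v[[1]], v[[2]])
    }),
    straightness_index = stage("mw_straightness", {
      v <- obs_metric("straightness_index"); mann_whitney_u(v[[1]], v[[2]])
    }),
    turn_angle = stage("mw_turn_angle", {
      v <- pool_metric("turn_angle"); mann_whitney_u(v[[1]], v[[2]])
    }))

  distribution_tests <- list(
    step_length = stage("ks_step_length", {
      v <- pool_metric("step_length"); ks_two_sample(v[[1]], v[[2]])
    }),
    turn_angle = stage("ks_turn_angle", {
      v <- pool_metric("turn_angle"); ks_two_sample(v[[1]], v[[2]])
    }))

  # --- circular statistics --------------------------------------------
  circ_in <- if (config$circular_angles == "signed") turns_signed else
    turns_folded
  circular_results <- lapply(species, function(s) {
    ang <- circ_in[[s]]
    list(summary = stage(paste0("circ_summary_", s), circular_mean_R(ang)),
         rayleigh = stage(paste0("rayleigh_", s), rayleigh_test(ang)),
         vonmises = stage(paste0("vonmises_", s),
                          vonmises_fit_and_gof(ang)))
  })
  names(circular_results) <- species

  # --- proportion of intervals with movement --------------------------
  prop_tab <- lapply(species, function(s) {
    ss <- summaries[summaries$species == s, ]
    k <- sum(round(ss$proportion_moving * ss$n_intervals))
    n <- sum(ss$n_intervals)
    c(k = k, n = n)
  })
  proportion_moving_test <- stage("proportion_moving", {
    two_proportion_z(prop_tab[[1]]["k"], prop_tab[[1]]["n"],
                     prop_tab[[2]]["k"], prop_tab[[2]]["n"])
  })
  names(prop_tab) <- species

  # --- turn angle vs step length correlation --------------------------
  correlation_results <- lapply(species, function(s) {
    stage(paste0("correlation_", s), {
      pr <- turn_step_pairs(sub[[s]], config$move_epsilon,
                            config$across_pauses)
      pearson_correlation(pr$turn_angle_abs, pr$step_length)
    })
  })
  names(correlation_results) <- species

  # --- habitat use -----------------------------------------------------
  counts <- habitat_counts(dataset)
  if (config$pooling == "pooled") {
    habitat_tables <- list(
      cover = list(counts = counts$cover,
                   test = stage("chi_cover", chi_square_rxc(counts$cover))),
      visibility = list(counts = counts$visibility,
                        test = stage("chi_visibility",
                                     chi_square_rxc(counts$visibility))),
      plant = list(counts = counts$plant,
                   test = if (is.null(counts$plant)) NULL else
                     stage("chi_plant", chi_square_rxc(counts$plant))))
  } else {
    # per-individual mode: compare per-observation open fractions and
    # visibility indices between species by rank test
    open_frac <- lapply(sub, function(d) {
      vapply(d$observations, function(o)
        mean(o$fixes$habitat == "open"), numeric(1))
    })
    vis_idx <- lapply(species, function(s)
      stats::na.omit(summaries[summaries$species == s,
                               "visibility_index"]))
    habitat_tables <- list(
      cover = list(counts = counts$cover,
                   test = stage("mw_open_fraction",
                                mann_whitney_u(open_frac[[1]],
                                               open_frac[[2]]))),
      visibility = list(counts = counts$visibility,
                        test = stage("mw_visibility",
                                     mann_whitney_u(vis_idx[[1]],
                                                    vis_idx[[2]]))),
      plant = list(counts = counts$plant,
                   test = if (is.null(counts$plant)) NULL else
                     stage("chi_plant", chi_square_rxc(counts$plant))))
  }

  # --- regression stages ----------------------------------------------
  model_results <- NULL
  observer_effect <- NULL
  if (config$fit_models) {
    model_results <- lapply(species, function(s) {
      stage(paste0("lmm_", s), {
        rec <- suppressMessages(
          build_step_records(dataset, s, config$move_epsilon))
        fit_step_length_lmm(rec, config$lmm_transform,
                            config$lmm_df_method)
      })
    })
    names(model_results) <- species
    observer_effect <- lapply(species, function(s) {
      list(step_length = stage(paste0("trend_step_", s),
             observer_effect_trend(dataset, s, "step_length",
                                   config$move_epsilon)),
           turn_angle_abs = stage(paste0("trend_turn_", s),
             observer_effect_trend(dataset, s, "turn_angle_abs",
                                   config$move_epsilon)))
    })
    names(observer_effect) <- species
  }

  n_tests <- 5L + 2L + 2L * length(species) + 1L + length(species) + 3L
  structure(list(
    species = species,
    summaries = summaries,
    per_species_summaries = per_species,
    movement_comparisons = movement_comparisons,
    distribution_tests = distribution_tests,
    circular_results = circular_results,
    proportion_moving = prop_tab,
    proportion_moving_test = proportion_moving_test,
    correlation_results = correlation_results,
    habitat_tables = habitat_tables,
    model_results = model_results,
    observer_effect = observer_effect,
    errors = errors,
    provenance = list(config = unclass(config),
                      dataset_provenance = dataset$provenance,
                      n_observations = length(dataset$observations),
                      n_tests_performed = n_tests,
                      multiple_testing_note = paste(
                        "No multiple-testing adjustment is applied;",
                        n_tests, "tests were performed."))),
    class = "analysis_report")
}

# Pair each turn angle with the length of the outgoing step (the step
# taken after the turn), per observation.
turn_step_pairs <- function(dataset, move_epsilon = 0,
                            across_pauses = TRUE) {
  rows <- lapply(dataset$observations, function(o) {
    s <- compute_steps(o, move_epsilon)
    mv <- s[s$moved, , drop = FALSE]
    if (nrow(mv) < 2L) return(NULL)
    signed <- wrap_deg(diff(mv$heading))
    keep <- if (across_pauses) rep(TRUE, length(signed)) else
      mv$from_t[-1L] == mv$to_t[-nrow(mv)]
    data.frame(turn_angle_abs = abs(signed[keep]),
               step_length = mv$length[-1L][keep])
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) data.frame(turn_angle_abs = numeric(0),
                               step_length = numeric(0)) else out
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("==== Movement and habitat-use analysis ====\n")
  cat(sprintf("Species: %s | observations: %d | pooling: %s\n",
              paste(x$species, collapse = " vs "),
              x$provenance$n_observations,
              x$provenance$config$pooling))
  cat("\n-- Movement metrics, median (range) --\n")
  for (s in x$species) {
    cat(sprintf("%s:\n", s))
    m <- x$per_species_summaries[[s]]
    for (i in seq_len(nrow(m)))
      cat(sprintf("  %-19s %8.3f (%.2f-%.2f)  n = %d\n",
                  rownames(m)[i], m[i, "median"], m[i, "min"],
                  m[i, "max"], m[i, "n"]))
  }
  cat("\n-- Between-species comparisons (Mann-Whitney) --\n")
  for (nm in names(x$movement_comparisons)) {
    r <- x$movement_comparisons[[nm]]
    if (!is.null(r))
      cat(sprintf("  %-19s U = %.1f, p = %.4g\n", nm, r$U_reported, r$p))
  }
  for (nm in names(x$distribution_tests)) {
    r <- x$distribution_tests[[nm]]
    if (!is.null(r))
      cat(sprintf("  KS %-16s D = %.3f, p = %.4g\n", nm, r$D, r$p))
  }
  if (!is.null(x$proportion_moving_test))
    cat(sprintf("  moving intervals: %.1f%% vs %.1f%%, z = %.2f, p = %.4g\n",
                100 * x$proportion_moving_test$p1_hat,
                100 * x$proportion_moving_test$p2_hat,
                x$proportion_moving_test$z, x$proportion_moving_test$p))
  cat("\n-- Circular statistics on turn angles --\n")
  for (s in x$species) {
    cr <- x$circular_results[[s]]
    if (!is.null(cr$rayleigh))
      cat(sprintf(
        "  %s: R = %.3f, Rayleigh z = %.2f (n = %d), p = %.4g, kappa = %.3f\n",
        s, cr$rayleigh$R, cr$rayleigh$z, cr$rayleigh$n, cr$rayleigh$p,
        if (is.null(cr$vonmises)) NA_real_ else cr$vonmises$kappa))
  }
  cat("\n-- Habitat use --\n")
  for (nm in names(x$habitat_tables)) {
    h <- x$habitat_tables[[nm]]
    if (is.null(h$test)) next
    if (inherits(h$test, "chi_square_result")) {
      cat(sprintf("  %-11s chi2 = %.1f, df = %d, p = %.4g\n",
                  nm, h$test$chi2, h$test$df, h$test$p))
    } else {
      cat(sprintf("  %-11s U = %.1f, p = %.4g\n", nm, h$test$U_reported,
                  h$test$p))
    }
  }
  if (length(x$errors) > 0) {
    cat("\n-- Stage errors --\n")
    for (nm in names(x$errors)) cat(sprintf("  %s: %s\n", nm, x$errors[[nm]]))
  }
  cat("\n", x$provenance$multiple_testing_note, "\n", sep = "")
  invisible(x)
}
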