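# Export of an analysis report: machine-readable CSV tables, histogram
# data, a human-readable markdown summary, and a JSON provenance block.

fmt_num <- function(x) formatC(x, digits = 12, format = "g")

#' Export an analysis report to a directory
#'
#' Writes:
#' * `path_summaries.csv` — one row per observation (all path metrics);
#' * `movement_metrics.csv` — the median (range) layout, five metric
#'   rows by two species;
#' * `comparisons.csv` — every between-species test (statistic, sample
#'   sizes, p);
#' * `circular.csv` — circular summaries, Rayleigh and von Mises
#'   results per species;
#' * `habitat_<table>.csv` — contingency counts for cover, visibility
#'   and plant use;
#' * `models.csv`, `observer_effect.csv` — regression stages (when
#'   fitted);
#' * `turn_angle_histogram.csv`, `step_length_histogram.csv` — binned
#'   counts per species (bin widths from the run configuration);
#' * `report.md` — human-readable summary;
#' * `provenance.json` — configuration, seeds, counts and the
#'   multiple-testing note.
#'
#' Numeric fields are written with 12 significant digits.
#'
#' @param report an `analysis_report`.
#' @param path output directory (created if needed).
#' @param dataset optional `fix_dataset`, used for histogram data; when
#'   omitted histograms are built from the report's pooled vectors
#'   recomputation is skipped and histogram files are not written.
#' @return the directory path, invisibly.
#' @export
export_report <- function(report, path, dataset = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
    utils::write.csv(df, file.path(path, name), row.names = FALSE,
                     quote = FALSE, na = "")
  }
  wr(report$summaries, "path_summaries.csv")

  sp <- report$species
  mm <- do.call(rbind, lapply(sp, function(s) {
    m <- report$per_species_summaries[[s]]
    data.frame(species = s, metric = rownames(m),
               median = m[, "median"], min = m[, "min"], max = m[, "max"],
               n = m[, "n"], row.names = NULL, stringsAsFactors = FALSE)
  }))
  wr(mm, "movement_metrics.csv")

  comp_rows <- list()
  add_row <- function(...) comp_rows[[length(comp_rows) + 1L]] <<-
    data.frame(..., stringsAsFactors = FALSE)
  for (nm in names(report$movement_comparisons)) {
    r <- report$movement_comparisons[[nm]]
    if (!is.null(r))
      add_row(test = "mann_whitney", quantity = nm, statistic = r$U_reported,
              statistic2 = r$U2, z = r$z, n1 = r$n1, n2 = r$n2, p = r$p)
  }
  for (nm in names(report$distribution_tests)) {
    r <- report$distribution_tests[[nm]]
    if (!is.null(r))
      add_row(test = "kolmogorov_smirnov", quantity = nm, statistic = r$D,
              statistic2 = NA, z = NA, n1 = r$n1, n2 = r$n2, p = r$p)
  }
  if (!is.null(report$proportion_moving_test)) {
    r <- report$proportion_moving_test
    add_row(test = "two_proportion_z", quantity = "proportion_moving",
            statistic = r$z, statistic2 = NA, z = r$z, n1 = r$n1,
            n2 = r$n2, p = r$p)
  }
  for (s in sp) {
    r <- report$correlation_results[[s]]
    if (!is.null(r))
      add_row(test = "pearson_correlation",
              quantity = paste0("turn_vs_step_", s), statistic = r$r,
              statistic2 = NA, z = NA, n1 = r$n, n2 = NA, p = r$p)
  }
  wr(do.call(rbind, comp_rows), "comparisons.csv")

  circ <- do.call(rbind, lapply(sp, function(s) {
    cr <- report$circular_results[[s]]
    data.frame(species = s,
               n = cr$summary$n, R = cr$summary$R,
               mean_angle = cr$summary$mean_angle,
               rayleigh_z = cr$rayleigh$z, rayleigh_p = cr$rayleigh$p,
               kappa = cr$vonmises$kappa,
               watson_u2 = cr$vonmises$gof_statistic,
               gof_p_lower = cr$vonmises$gof_p_range[1],
               gof_p_upper = cr$vonmises$gof_p_range[2],
               stringsAsFactors = FALSE)
  }))
  wr(circ, "circular.csv")

  for (nm in names(report$habitat_tables)) {
    h <- report$habitat_tables[[nm]]
    if (is.null(h$counts)) next
    df <- as.data.frame(h$counts)
    df <- cbind(species = rownames(h$counts), df)
    rownames(df) <- NULL
    if (!is.null(h$test) && inherits(h$test, "chi_square_result")) {
      df$chi2 <- h$test$chi2; df$df <- h$test$df; df$p <- h$test$p
    } else if (!is.null(h$test)) {
      df$U <- h$test$U_reported; df$p <- h$test$p
    }
    wr(df, paste0("habitat_", nm, ".csv"))
  }

  if (!is.null(report$model_results)) {
    mr <- do.call(rbind, lapply(sp, function(s) {
      m <- report$model_results[[s]]
      if (is.null(m)) return(NULL)
      cbind(data.frame(species = s, stringsAsFactors = FALSE),
            m$fixed_effects,
            data.frame(var_individual = m$variance_components["individual"],
                       var_residual = m$variance_components["residual"],
                       n_records = m$n_records,
                       n_individuals = m$n_individuals,
                       singular = m$singular, df_method = m$df_method,
                       row.names = NULL))
    }))
    if (!is.null(mr)) wr(mr, "models.csv")
  }
  if (!is.null(report$observer_effect)) {
    oe <- do.call(rbind, lapply(sp, function(s) {
      do.call(rbind, lapply(report$observer_effect[[s]], function(r) {
        if (is.null(r)) return(NULL)
        data.frame(species = s, response = r$response, slope = r$slope,
                   F = r$F, df1 = r$df[1], df2 = r$df[2], p = r$p,
                   n = r$n, stringsAsFactors = FALSE)
      }))
    }))
    if (!is.null(oe)) wr(oe, "observer_effect.csv")
  }

  if (!is.null(dataset)) {
    cfg <- report$provenance$config
    tb <- cfg$turn_bin_deg %||% 45
    sb <- cfg$step_bin_m %||% 2
    th <- do.call(rbind, lapply(sp, function(s) {
      ang <- pooled_turn_angles(subset_species(dataset, s),
                                cfg$move_epsilon %||% 0, folded = TRUE,
                                cfg$across_pauses %||% TRUE)
      breaks <- seq(0, 180, by = tb)
      ct <- table(cut(ang, breaks, include.lowest = TRUE, right = TRUE))
      data.frame(species = s, bin_lower = head(breaks, -1),
                 bin_upper = breaks[-1], count = as.integer(ct),
                 stringsAsFactors = FALSE)
    }))
    wr(th, "turn_angle_histogram.csv")
    sh <- do.call(rbind, lapply(sp, function(s) {
      sl <- pooled_step_lengths(subset_species(dataset, s),
                                cfg$move_epsilon %||% 0)
      top <- max(sl, sb)
      breaks <- seq(0, ceiling(top / sb) * sb, by = sb)
      ct <- table(cut(sl, breaks, include.lowest = TRUE, right = TRUE))
      data.frame(species = s, bin_lower = head(breaks, -1),
                 bin_upper = breaks[-1], count = as.integer(ct),
                 stringsAsFactors = FALSE)
    }))
    wr(sh, "step_length_histogram.csv")
  }

  md <- utils::capture.output(print(report))
  if (is.null(report$model_results))
    md <- c(md, "", "Regression stages were not fitted for this run.")
  writeLines(c("# Analysis report", "", "```", md, "```"),
             file.path(path, "report.md"))
  jsonlite::write_json(report$provenance,
                       file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(path)
}
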