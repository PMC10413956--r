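# Regression stages: within-species step-length variation (random
# intercept per individual) and the observer-effect trend over the
# course of an observation.
#
# The mixed model is fitted by REML through lme4; this module adds the
# record assembly, the choice of response transform, and F tests with a
# containment denominator-df rule (Satterthwaite optional via lmerTest).

#' Assemble step-length records for regression
#'
#' One record per moving interval of each observation of the species:
#' step length, the minute index at the start of the interval, the
#' animal covariates, and the weather at that minute (taken from the
#' interval's starting fix).  Records with any missing covariate are
#' dropped listwise; the number dropped is reported via a message and
#' the `n_dropped` field.
#'
#' @param dataset a `fix_dataset`.
#' @param species species label to extract.
#' @param move_epsilon movement threshold in metres.
#' @return data frame of class `step_records` with columns `lizard_id`,
#'   `step_length`, `t`, `sex`, `svl_mm`, `air_temp_c`,
#'   `wind_speed_ms` and attribute `n_dropped`.
#' @export
build_step_records <- function(dataset, species, move_epsilon = 0) {
  sub <- subset_species(dataset, species)
  rows <- lapply(sub$observations, function(o) {
    s <- compute_steps(o, move_epsilon)
    mv <- s[s$moved, , drop = FALSE]
    if (nrow(mv) == 0L) return(NULL)
    m <- match(mv$from_t, o$fixes$t)
    data.frame(lizard_id = o$lizard_id,
               step_length = mv$length,
               t = mv$from_t,
               sex = o$sex,
               svl_mm = o$svl_mm,
               air_temp_c = o$fixes$air_temp_c[m],
               wind_speed_ms = o$fixes$wind_speed_ms[m],
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(rec)) stop("no moving steps for species '", species, "'")
  complete <- stats::complete.cases(rec)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(n_dropped, " record(s) dropped for missing covariates")
  rec <- rec[complete, , drop = FALSE]
  attr(rec, "n_dropped") <- n_dropped
  class(rec) <- c("step_records", "data.frame")
  rec
}

#' Mixed-effects model for step length
#'
#' Linear mixed model with a random intercept per individual and fixed
#' effects sex, snout-vent length, air temperature and wind speed,
#' fitted by restricted maximum likelihood.  Each fixed effect is
#' reported with an F statistic (`F = t^2`, numerator df 1) and a
#' p-value using the chosen denominator-df rule:
#'
#' * `"containment"` (default): effects constant within individuals
#'   (sex, SVL) use `n_individuals - q_b`, where `q_b` is the number of
#'   between-individual fixed-effect columns including the intercept;
#'   within-individual effects (weather) use
#'   `n_records - n_individuals - q_w`.
#' * `"satterthwaite"`: per-effect df from lmerTest.
#'
#' @param records a `step_records` data frame.
#' @param response_transform `"identity"` or `"log"` (natural log of
#'   step length; step lengths are strongly right-skewed).
#' @param df_method `"containment"` or `"satterthwaite"`.
#' @return list of class `mixed_model_result`: `fixed_effects` (data
#'   frame with estimate, std_error, F, df_num, df_den, p),
#'   `variance_components` (named: individual, residual), `n_records`,
#'   `n_individuals`, `singular` (logical), `df_method`,
#'   `response_transform`.
#' @export
fit_step_length_lmm <- function(records,
                                response_transform = c("identity", "log"),
                                df_method = c("containment",
                                              "satterthwaite")) {
  response_transform <- match.arg(response_transform)
  df_method <- match.arg(df_method)
  n_ind <- length(unique(records$lizard_id))
  if (n_ind < 2L)
    stop("random intercept not identifiable with a single individual")
  if (nrow(records) < 10L)
    stop("at least 10 records required")
  records$.y <- if (response_transform == "log") log(records$step_length)
                else records$step_length
  # fixed-effect terms with no variation (e.g. single-sex data) are dropped
  terms <- c("sex", "svl_mm", "air_temp_c", "wind_speed_ms")
  keep <- vapply(terms, function(v) length(unique(records[[v]])) > 1L,
                 logical(1))
  terms <- terms[keep]
  form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + "),
                                  "+ (1 | lizard_id)"))
  use_satt <- df_method == "satterthwaite"
  if (use_satt && !requireNamespace("lmerTest", quietly = TRUE)) {
    warning("lmerTest unavailable; falling back to containment df")
    use_satt <- FALSE
    df_method <- "containment"
  }
  fit <- if (use_satt) {
    lmerTest::lmer(form, data = records, REML = TRUE)
  } else {
    lme4::lmer(form, data = records, REML = TRUE)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_ind <- vc$vcov[vc$grp == "lizard_id"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  singular <- lme4::isSingular(fit)
  co <- as.data.frame(stats::coef(summary(fit)))
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  tval <- est / se
  eff_names <- rownames(co)
  # classify columns as between- or within-individual
  X <- stats::model.matrix(fit)
  between <- vapply(seq_len(ncol(X)), function(j) {
    all(tapply(X[, j], records$lizard_id,
               function(v) max(v) - min(v)) < 1e-10)
  }, logical(1))
  q_b <- sum(between)
  q_w <- sum(!between)
  if (use_satt) {
    df_den <- co[, "df"]
  } else {
    df_den <- ifelse(between,
                     n_ind - q_b,
                     nrow(records) - n_ind - q_w)
    df_den <- pmax(df_den, 1)
  }
  Fval <- tval^2
  pval <- stats::pf(Fval, 1, df_den, lower.tail = FALSE)
  fixed <- data.frame(effect = eff_names, estimate = est, std_error = se,
                      F = Fval, df_num = 1L, df_den = df_den, p = pval,
                      between_individual = between,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(fixed_effects = fixed,
                 variance_components = c(individual = var_ind,
                                         residual = var_res),
                 n_records = nrow(records), n_individuals = n_ind,
                 singular = singular, df_method = df_method,
                 response_transform = response_transform),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf(
    "Step-length mixed model (%s response, %s df): %d records, %d individuals%s\n",
    x$response_transform, x$df_method, x$n_records, x$n_individuals,
    if (x$singular) " [singular fit]" else ""))
  cat(sprintf("  variance components: individual %.4g, residual %.4g\n",
              x$variance_components["individual"],
              x$variance_components["residual"]))
  fe <- x$fixed_effects
  for (i in seq_len(nrow(fe)))
    cat(sprintf("  %-14s est %8.4f  F(1, %.0f) = %8.3f  p = %.4g\n",
                fe$effect[i], fe$estimate[i], fe$df_den[i], fe$F[i],
                fe$p[i]))
  invisible(x)
}

#' Observer-effect trend over the observation period
#'
#' Least-squares regression of a movement response on the minute index,
#' pooled across all observations of the species, with an F test of the
#' slope (df = 1, n - 2).  A flat trend is consistent with the animals
#' not reacting to the observers as the observation progresses.
#'
#' @param dataset a `fix_dataset`.
#' @param species species label.
#' @param response `"step_length"` (moving steps, indexed by the minute
#'   starting the interval) or `"turn_angle_abs"` (folded turn angles,
#'   indexed by the minute starting the outgoing step).
#' @param move_epsilon movement threshold in metres.
#' @return list of class `trend_test_result`: `slope` (units per
#'   minute), `F`, `df` (length-2), `p`, `n`, `response`.
#' @export
observer_effect_trend <- function(dataset, species,
                                  response = c("step_length",
                                               "turn_angle_abs"),
                                  move_epsilon = 0) {
  response <- match.arg(response)
  sub <- subset_species(dataset, species)
  vals <- lapply(sub$observations, function(o) {
    s <- compute_steps(o, move_epsilon)
    mv <- s[s$moved, , drop = FALSE]
    if (response == "step_length") {
      data.frame(t = mv$from_t, y = mv$length)
    } else {
      if (nrow(mv) < 2L) return(NULL)
      data.frame(t = mv$from_t[-1L], y = abs(wrap_deg(diff(mv$heading))))
    }
  })
  d <- do.call(rbind, c(vals, list(make.row.names = FALSE)))
  if (is.null(d) || nrow(d) < 10L)
    stop("fewer than 10 pooled response values for species '", species, "'")
  if (stats::var(d$y) == 0)
    return(structure(list(slope = 0, F = 0, df = c(1L, nrow(d) - 2L),
                          p = 1, n = nrow(d), response = response),
                     class = "trend_test_result"))
  fit <- stats::lm(y ~ t, data = d)
  an <- stats::anova(fit)
  structure(list(slope = unname(stats::coef(fit)["t"]),
                 F = an$`F value`[1L],
                 df = c(an$Df[1L], an$Df[2L]),
                 p = an$`Pr(>F)`[1L],
                 n = nrow(d), response = response),
            class = "trend_test_result")
}

#' @export
print.trend_test_result <- function(x, ...) {
  cat(sprintf(
    "Observer-effect trend (%s): slope %.4g/min, F(%d, %d) = %.3f, p = %.4g\n",
    x$response, x$slope, x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}
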