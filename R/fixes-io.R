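# Domain types and CSV input/output for focal-observation fix tables.
#
# A "fix" is one recorded animal location at a 1-min interval of a 30-min
# focal observation; a full observation is 31 fixes (t = 0..30).  The fix
# table is a denormalised CSV: one row per fix, observation-level
# covariates repeated on every row, absent values as empty fields.

FIX_COLUMNS <- c("observation_id", "lizard_id", "species", "sex", "svl_mm",
                 "mass_g", "t_min", "x_m", "y_m", "habitat", "plant_species",
                 "visible_from_previous", "air_temp_c", "wind_speed_ms")

MAX_FIXES <- 31L # 30-min observation sampled at 1-min intervals

#' Construct a single focal observation
#'
#' @param observation_id,lizard_id identifier strings.
#' @param species species label (e.g. `"visual"`, `"chemosensory"`).
#' @param sex one of `"M"`, `"F"`, `"unknown"`.
#' @param svl_mm snout-vent length, mm.
#' @param mass_g body mass, g.
#' @param fixes data frame with columns `t` (integer minute index), `x`,
#'   `y` (metres), `habitat` (`"open"` or `"vegetation"`),
#'   `plant_species` (character, `NA` when in the open),
#'   `visible_from_previous` (logical, `NA` on the first fix),
#'   `air_temp_c`, `wind_speed_ms` (numeric, may be `NA`).
#' @param validate if `TRUE` (default), stop on any invariant violation.
#' @return object of class `observation`.
#' @seealso [validate_observation()]
#' @export
observation <- function(observation_id, lizard_id, species, sex = "unknown",
                        svl_mm = NA_real_, mass_g = NA_real_, fixes,
                        validate = TRUE) {
  fixes <- as.data.frame(fixes)
  needed <- c("t", "x", "y", "habitat", "plant_species",
              "visible_from_previous", "air_temp_c", "wind_speed_ms")
  for (col in setdiff(needed, names(fixes))) {
    fixes[[col]] <- switch(col,
      plant_species = NA_character_,
      visible_from_previous = NA,
      habitat = "open",
      NA_real_)
  }
  fixes <- fixes[needed]
  fixes$t <- as.integer(fixes$t)
  fixes$visible_from_previous <- as.logical(fixes$visible_from_previous)
  fixes$plant_species <- as.character(fixes$plant_species)
  obs <- structure(
    list(observation_id = as.character(observation_id),
         lizard_id = as.character(lizard_id),
         species = as.character(species),
         sex = as.character(sex),
         svl_mm = as.numeric(svl_mm),
         mass_g = as.numeric(mass_g),
         fixes = fixes),
    class = "observation")
  if (validate) {
    v <- validate_observation(obs)
    if (length(v) > 0)
      stop("invalid observation '", obs$observation_id, "': ",
           paste(v, collapse = "; "))
  }
  obs
}

#' Number of fixes in an observation
#' @param obs an `observation`.
#' @return integer count of fixes.
#' @export
n_fixes <- function(obs) nrow(obs$fixes)

#' Is an observation complete (full 30 minutes, 31 fixes)?
#' @param obs an `observation`.
#' @return logical.
#' @export
is_complete <- function(obs) n_fixes(obs) == MAX_FIXES

#' Validate an observation against the fix-table invariants
#'
#' Checks, without raising, that minute indices are strictly increasing
#' and within 0..30, that the observation holds between 2 and 31 fixes,
#' that a plant species is recorded exactly when the fix is in
#' vegetation, and that the visibility flag is absent exactly on the
#' first fix.  Violations are returned as data, never thrown.
#'
#' @param obs an `observation`.
#' @return character vector of violation messages, empty when valid; each
#'   message names the offending field and fix index.
#' @export
validate_observation <- function(obs) {
  v <- character(0)
  f <- obs$fixes
  n <- nrow(f)
  if (n < 2L || n > MAX_FIXES)
    v <- c(v, sprintf("fixes: observation has %d fixes (must be 2..%d)",
                      n, MAX_FIXES))
  if (n >= 1L) {
    if (anyNA(f$t)) {
      v <- c(v, "t: missing minute index")
    } else {
      if (any(f$t < 0L | f$t > 30L))
        v <- c(v, sprintf("t: minute index out of 0..30 at fix %s",
                          paste(which(f$t < 0L | f$t > 30L), collapse = ",")))
      if (n >= 2L && any(diff(f$t) <= 0L))
        v <- c(v, sprintf("t: not strictly increasing at fix %s",
                          paste(which(diff(f$t) <= 0L) + 1L, collapse = ",")))
    }
    if (anyNA(f$x) || anyNA(f$y))
      v <- c(v, "x/y: missing coordinate")
    bad_hab <- !(f$habitat %in% c("open", "vegetation"))
    if (any(bad_hab))
      v <- c(v, sprintf("habitat: unknown label at fix %s",
                        paste(which(bad_hab), collapse = ",")))
    plant_wrong <- xor(!is.na(f$plant_species), f$habitat == "vegetation")
    plant_wrong[bad_hab] <- FALSE
    if (any(plant_wrong))
      v <- c(v, sprintf(
        "plant_species: present iff habitat is vegetation violated at fix %s",
        paste(which(plant_wrong), collapse = ",")))
    if (!is.na(f$visible_from_previous[1L]))
      v <- c(v, "visible_from_previous: must be absent at the first fix (fix 1)")
  }
  v
}

#' Bundle observations into a dataset
#'
#' @param observations list of `observation` objects.
#' @param provenance named list of free-text metadata (source, seed,
#'   generator version, ...).
#' @return object of class `fix_dataset`.
#' @export
fix_dataset <- function(observations, provenance = list()) {
  ids <- vapply(observations, function(o) o$observation_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate observation_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lids <- vapply(observations, function(o) o$lizard_id, character(1))
  if (anyDuplicated(lids))
    stop("each lizard may appear in exactly one observation; duplicated: ",
         paste(unique(lids[duplicated(lids)]), collapse = ", "))
  names(observations) <- ids
  structure(list(observations = observations, provenance = provenance),
            class = "fix_dataset")
}

#' @export
print.fix_dataset <- function(x, ...) {
  sp <- table(vapply(x$observations, function(o) o$species, character(1)))
  cat(sprintf("Fix dataset: %d observations (%s)\n",
              length(x$observations),
              paste(sprintf("%s: %d", names(sp), sp), collapse = ", ")))
  nf <- vapply(x$observations, n_fixes, integer(1))
  cat(sprintf("  complete (31-fix) observations: %d; fixes total: %d\n",
              sum(nf == MAX_FIXES), sum(nf)))
  invisible(x)
}

#' @export
print.observation <- function(x, ...) {
  cat(sprintf("Observation %s (lizard %s, %s, %s): %d fixes, t %d..%d\n",
              x$observation_id, x$lizard_id, x$species, x$sex,
              n_fixes(x), x$fixes$t[1], x$fixes$t[nrow(x$fixes)]))
  invisible(x)
}

#' Species labels present in a dataset
#' @param dataset a `fix_dataset`.
#' @return character vector of unique species labels, in first-appearance order.
#' @export
dataset_species <- function(dataset) {
  unique(vapply(dataset$observations, function(o) o$species, character(1)))
}

#' Subset a dataset to one species
#' @param dataset a `fix_dataset`.
#' @param species species label.
#' @return a `fix_dataset` containing only that species' observations.
#' @export
subset_species <- function(dataset, species) {
  keep <- vapply(dataset$observations, function(o) o$species == species,
                 logical(1))
  if (!any(keep)) stop("no observations for species '", species, "'")
  fix_dataset(dataset$observations[keep], dataset$provenance)
}

#' Flatten a dataset to one row per fix
#' @param dataset a `fix_dataset`.
#' @return data frame in the canonical fix-table column order.
#' @export
as_fix_table <- function(dataset) {
  if (length(dataset$observations) == 0L) {
    empty <- c(rep(list(character(0)), 4L), rep(list(numeric(0)), 2L),
               list(integer(0)), rep(list(numeric(0)), 2L),
               rep(list(character(0)), 2L), list(logical(0)),
               rep(list(numeric(0)), 2L))
    return(as.data.frame(stats::setNames(empty, FIX_COLUMNS)))
  }
  rows <- lapply(dataset$observations, function(o) {
    f <- o$fixes
    data.frame(observation_id = o$observation_id,
               lizard_id = o$lizard_id,
               species = o$species,
               sex = o$sex,
               svl_mm = o$svl_mm,
               mass_g = o$mass_g,
               t_min = f$t,
               x_m = f$x,
               y_m = f$y,
               habitat = f$habitat,
               plant_species = f$plant_species,
               visible_from_previous = f$visible_from_previous,
               air_temp_c = f$air_temp_c,
               wind_speed_ms = f$wind_speed_ms,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a fix-table CSV into a dataset
#'
#' The file must carry a header with the canonical columns (see
#' [write_fixes_csv()]); rows are grouped by `observation_id` and must be
#' ordered by minute index within each observation.  All observation and
#' fix invariants are enforced: a malformed file fails with an error
#' naming the offending column or observation.
#'
#' @param path path to a CSV file.
#' @return a `fix_dataset`.
#' @export
read_fixes_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  chr_cols <- c("observation_id", "lizard_id", "species", "sex",
                "habitat", "plant_species")
  cc <- stats::setNames(rep("character", length(chr_cols)), chr_cols)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = cc[intersect(chr_cols,
                                                   scan_header(path))],
                         na.strings = "")
  missing_cols <- setdiff(FIX_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop("fix table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) return(fix_dataset(list(), list(source = path)))
  raw$visible_from_previous <- as.logical(raw$visible_from_previous)
  obs_list <- lapply(split(raw, factor(raw$observation_id,
                                       levels = unique(raw$observation_id))),
                     function(g) {
    obs <- observation(
      observation_id = g$observation_id[1L],
      lizard_id = g$lizard_id[1L],
      species = g$species[1L],
      sex = g$sex[1L],
      svl_mm = g$svl_mm[1L],
      mass_g = g$mass_g[1L],
      fixes = data.frame(t = g$t_min, x = g$x_m, y = g$y_m,
                         habitat = g$habitat,
                         plant_species = g$plant_species,
                         visible_from_previous = g$visible_from_previous,
                         air_temp_c = g$air_temp_c,
                         wind_speed_ms = g$wind_speed_ms,
                         stringsAsFactors = FALSE),
      validate = FALSE)
    v <- validate_observation(obs)
    if (length(v) > 0)
      stop("invalid observation '", obs$observation_id, "': ",
           paste(v, collapse = "; "))
    obs
  })
  fix_dataset(unname(obs_list), provenance = list(source = path))
}

scan_header <- function(path) {
  strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
}

#' Write a dataset as a fix-table CSV
#'
#' Deterministic output: canonical column order
#' (`observation_id, lizard_id, species, sex, svl_mm, mass_g, t_min, x_m,
#' y_m, habitat, plant_species, visible_from_previous, air_temp_c,
#' wind_speed_ms`), absent values as empty fields, and numerics printed
#' with 17 significant digits so re-reading reproduces every double
#' exactly.  Two writes of the same dataset are byte-identical.
#'
#' @param dataset a `fix_dataset`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_fixes_csv <- function(dataset, path) {
  tab <- as_fix_table(dataset)
  for (col in names(tab)) {
    x <- tab[[col]]
    tab[[col]] <- if (is.numeric(x)) {
      ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
    } else if (is.logical(x)) {
      ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
    } else {
      ifelse(is.na(x), "", as.character(x))
    }
  }
  con <- file(path, open = "wb") # binary mode: stable newlines
  on.exit(close(con))
  writeLines(paste(FIX_COLUMNS, collapse = ","), con)
  if (nrow(tab) > 0)
    writeLines(do.call(paste, c(unname(tab), list(sep = ","))), con)
  invisible(path)
}

#' Read an analysis configuration file
#'
#' YAML key-value file whose entries override the defaults of
#' [run_config()]; unknown keys are rejected.
#'
#' @param path path to a YAML file.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
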