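VISIT_MANDATORY <- c("participant_id", "visit_index", "age", "sex",
                     "wrat3_std")

#' Read a long-format visits table
#'
#' One row per participant-visit; UTF-8 CSV with "." decimals and empty
#' strings as missing. Unparseable numeric cells become missing values
#' with a logged count; row order is preserved. Range invariants
#' (IADL 0-16, IQCODE 16-80, memory Likert 1-7) are enforced.
#'
#' @param path CSV path.
#' @return Visits data frame.
#' @export
read_visits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  missing_cols <- setdiff(VISIT_MANDATORY, names(df))
  if (length(missing_cols))
    stop("visits file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) {
    warning("visits file has an empty data section")
    return(df)
  }
  num_cols <- setdiff(names(df),
                      c("participant_id", "self_memory_problem",
                        "latent_state"))
  bad <- 0L
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) {
      parsed <- suppressWarnings(as.numeric(df[[cl]]))
      bad <- bad + sum(is.na(parsed) & !is.na(df[[cl]]))
      df[[cl]] <- parsed
    }
  }
  if (bad > 0)
    message(bad, " unparseable cell(s) set to missing")
  check_range <- function(x, lo, hi, what) {
    out <- x[!is.na(x)]
    if (length(out) && (any(out < lo) || any(out > hi)))
      stop(sprintf("%s outside its %g-%g range", what, lo, hi),
           call. = FALSE)
  }
  check_range(df$iadl, 0, 16, "iadl")
  check_range(df$iqcode, 16, 80, "iqcode")
  check_range(df$self_memory_likert, 1, 7, "self_memory_likert")
  ord <- order(df$participant_id, df$visit_index)
  chk <- df[ord, ]
  same <- duplicated(chk$participant_id)
  if (any(diff(chk$visit_index)[same[-1]] <= 0, na.rm = TRUE) ||
      any(diff(chk$age)[same[-1]] <= 0, na.rm = TRUE))
    stop("visit_index and age must strictly increase within participant",
         call. = FALSE)
  df
}

#' @rdname read_visits
#' @param visits Visits data frame (extra generator-truth columns are
#'   kept).
#' @export
write_visits <- function(visits, path) {
  write.csv(visits, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write per-scan PET tables
#'
#' The on-disk schema is `participant_id, scan_age, global_pib_dvr,
#' suvr_entorhinal, suvr_hippocampus`; generator truth columns are
#' dropped on write.
#'
#' @param path CSV path.
#' @return PET data frame.
#' @export
read_pet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("participant_id", "scan_age", "global_pib_dvr")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("PET file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dvr <- df$global_pib_dvr
  if (any(dvr[!is.na(dvr)] <= 0))
    stop("global_pib_dvr must be positive", call. = FALSE)
  df
}

#' @rdname read_pet
#' @param pet PET data frame.
#' @export
write_pet <- function(pet, path) {
  keep <- intersect(c("participant_id", "scan_age", "global_pib_dvr",
                      "suvr_entorhinal", "suvr_hippocampus"), names(pet))
  write.csv(pet[keep], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Serialize / restore a fitted norm model
#'
#' The model itself is one CSV row per test (coefficients, residual SD,
#' robust n); fitted per-composite standard-score scales, when present,
#' go to a companion `*_scales.csv`.
#'
#' @param model A `norm_model`.
#' @param path CSV path.
#' @export
write_norm_model <- function(model, path) {
  write.csv(as.data.frame(model), path, row.names = FALSE, quote = FALSE)
  scales <- attr(model, "composite_scale")
  if (!is.null(scales))
    write.csv(data.frame(composite = names(scales), scale = scales),
              scales_path(path), row.names = FALSE, quote = FALSE)
  invisible(path)
}

scales_path <- function(path) sub("(\\.csv)?$", "_scales.csv",
                                  path, ignore.case = TRUE)

#' @rdname write_norm_model
#' @param specs Test specification table to re-attach.
#' @export
read_norm_model <- function(path, specs = default_test_specs()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("test", "intercept", "age_slope", "sex_offset",
            "literacy_slope", "residual_sd", "robust_n")
  if (!all(need %in% names(df)))
    stop("norm model file lacks required columns", call. = FALSE)
  if (any(df$residual_sd <= 0))
    stop("residual_sd must be positive", call. = FALSE)
  model <- structure(df[need], specs = specs,
                     class = c("norm_model", "data.frame"))
  sp <- scales_path(path)
  if (file.exists(sp)) {
    sc <- read.csv(sp, stringsAsFactors = FALSE)
    attr(model, "composite_scale") <- setNames(sc$scale, sc$composite)
  }
  model
}

#' Read a run configuration file
#'
#' A YAML file whose top-level keys mirror [sim_config()] scalar
#' arguments (under `sim:`), [flag_thresholds()] arguments (under
#' `thresholds:`), plus `analyses`, `alpha`, `fdr_q` and `seed`. The
#' transition matrix may be given under `sim: transition_matrix:` as a
#' list of four rows.
#'
#' @param path YAML path.
#' @return List with `sim` ([sim_config()]), `thresholds`
#'   ([flag_thresholds()]), `analyses`, `alpha`, `fdr_q`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$transition_matrix)) {
    tm <- do.call(rbind, sim_args$transition_matrix)
    dimnames(tm) <- list(STATUS_LEVELS, STATUS_LEVELS)
    sim_args$transition_matrix <- tm
  }
  if (!is.null(y$seed)) sim_args$seed <- y$seed
  list(sim = do.call(sim_config, sim_args),
       thresholds = do.call(flag_thresholds, y$thresholds %||% list()),
       analyses = y$analyses %||% c("concurrent", "change", "progression",
                                    "biomarkers"),
       alpha = y$alpha %||% 0.05,
       fdr_q = y$fdr_q %||% 0.05)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[sort(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}
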