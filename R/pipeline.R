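# Pipeline orchestration: preprocess -> qc -> fit -> summarize ->
# bioefficacy, with CSV/JSON inputs and outputs.

#' Run configuration
#'
#' @param subjects_csv,curves_csv input paths; see Details for formats.
#' @param out_dir output directory for qc.csv, params.csv, summary.csv,
#'   bioefficacy.csv and report.json.
#' @param mode \code{"fd"} when curves.csv carries fraction-of-dose
#'   columns (\code{fd_c10}, \code{fd_c5}); \code{"concentration"} when it
#'   carries plasma concentrations (\code{conc_c10_umol_L},
#'   \code{conc_c5_umol_L}) to be converted via [fd_from_concentration()].
#' @param qc a [qc_config()].
#' @param fit a [fit_config()].
#' @param truncation_day upper limit (days) for the graphical AUC.
#' @param isotope_ratio_day sampling day for the single-sample isotope
#'   ratio.
#' @param seed integer seed (reserved for stochastic stages).
#' @return A list of class \code{"run_config"}.
#' @details \code{curves.csv} is long format with columns
#'   \code{subject_id}, \code{time_d} and the two analyte columns; missing
#'   values are empty cells.  \code{subjects.csv} has columns
#'   \code{subject_id}, \code{body_weight}, \code{mean_plasma_retinol},
#'   \code{dose_retinol}, \code{dose_bc_alltrans}, \code{dose_bc_cis},
#'   \code{dose_bc_alpha}.
#' @export
run_config <- function(subjects_csv, curves_csv, out_dir,
                       mode = c("fd", "concentration"),
                       qc = qc_config(), fit = fit_config(),
                       truncation_day = 14, isotope_ratio_day = 2,
                       seed = 1L) {
  mode <- match.arg(mode)
  structure(list(subjects_csv = subjects_csv, curves_csv = curves_csv,
                 out_dir = out_dir, mode = mode, qc = qc, fit = fit,
                 truncation_day = truncation_day,
                 isotope_ratio_day = isotope_ratio_day,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' Top-level keys mirror the arguments of [run_config()]; \code{qc} and
#' \code{fit} may be nested objects overriding individual defaults.
#'
#' @param path JSON file path.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  qc <- do.call(qc_config, as.list(j$qc))
  fit <- do.call(fit_config, as.list(j$fit))
  run_config(
    subjects_csv = j$subjects_csv, curves_csv = j$curves_csv,
    out_dir = j$out_dir,
    mode = if (is.null(j$mode)) "fd" else j$mode,
    qc = qc, fit = fit,
    truncation_day = if (is.null(j$truncation_day)) 14
                     else j$truncation_day,
    isotope_ratio_day = if (is.null(j$isotope_ratio_day)) 2
                        else j$isotope_ratio_day,
    seed = if (is.null(j$seed)) 1L else j$seed)
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop_invalid("input file not found: ", path)
  df <- try(utils::read.csv(path, stringsAsFactors = FALSE),
            silent = TRUE)
  if (inherits(df, "try-error") || nrow(df) == 0L)
    stop_invalid("could not parse ", path,
                 ": empty or malformed CSV")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_invalid(path, " is missing required column(s): ",
                 paste(missing, collapse = ", "))
  df
}

#' Read the subject table
#'
#' @param path subjects.csv path.
#' @return Named list of [subject_record()] objects.
#' @export
read_subjects <- function(path) {
  df <- read_table_checked(path, c("subject_id", "body_weight",
                                   "mean_plasma_retinol"))
  dose_col <- function(nm, default)
    if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  d <- default_doses()
  recs <- lapply(seq_len(nrow(df)), function(i)
    subject_record(df$subject_id[i], df$body_weight[i],
                   df$mean_plasma_retinol[i],
                   dose_retinol = dose_col("dose_retinol",
                                           d[["retinol"]])[i],
                   dose_bc_alltrans = dose_col("dose_bc_alltrans",
                                               d[["bc_alltrans"]])[i],
                   dose_bc_cis = dose_col("dose_bc_cis", d[["bc_cis"]])[i],
                   dose_bc_alpha = dose_col("dose_bc_alpha",
                                            d[["bc_alpha"]])[i]))
  names(recs) <- df$subject_id
  recs
}

#' Read tracer curves for a cohort
#'
#' @param path curves.csv path (long format; see [run_config()]).
#' @param mode \code{"fd"} or \code{"concentration"}.
#' @param subjects subject records (required in concentration mode for
#'   plasma volumes and doses).
#' @return Named list (per subject) of lists with [tracer_curve()]
#'   elements \code{C10} and \code{C5}.
#' @export
read_curves <- function(path, mode = c("fd", "concentration"),
                        subjects = NULL) {
  mode <- match.arg(mode)
  cols <- if (mode == "fd") c("fd_c10", "fd_c5")
          else c("conc_c10_umol_L", "conc_c5_umol_L")
  df <- read_table_checked(path, c("subject_id", "time_d", cols))
  out <- lapply(split(df, df$subject_id), function(sd) {
    sd <- sd[order(sd$time_d), ]
    if (anyDuplicated(sd$time_d))
      stop_invalid("duplicate time points for subject ",
                   sd$subject_id[1])
    if (mode == "fd") {
      mk <- function(col, lab) {
        keep <- is.finite(sd[[col]])
        tracer_curve(lab, sd$time_d[keep], sd[[col]][keep],
                     observed = TRUE)
      }
      list(C10 = mk("fd_c10", "C10"), C5 = mk("fd_c5", "C5"))
    } else {
      if (is.null(subjects))
        stop_invalid("concentration mode requires the subject table")
      rec <- subjects[[as.character(sd$subject_id[1])]]
      if (is.null(rec))
        stop_invalid("no subject record for ", sd$subject_id[1])
      pv <- plasma_volume(rec$body_weight)
      rae <- rae_dose(rec$dose_bc_alltrans, rec$dose_bc_cis,
                      rec$dose_bc_alpha)
      list(C10 = fd_from_concentration(sd$time_d, sd$conc_c10_umol_L,
                                       pv, rec$dose_retinol,
                                       label = "C10"),
           C5 = fd_from_concentration(sd$time_d, sd$conc_c5_umol_L,
                                      pv, rae, label = "C5"))
    }
  })
  out[order(names(out))]
}

fmt6 <- function(x) signif(x, 6)

#' Run the full analysis pipeline
#'
#' Executes preprocess, quality-control screening, per-subject two-stage
#' fitting, kinetic summarization and bioefficacy estimation, and writes
#' \code{qc.csv}, \code{params.csv}, \code{summary.csv},
#' \code{bioefficacy.csv} and \code{report.json} (cohort means and SDs
#' plus all warnings) into the output directory.
#'
#' @param config a [run_config()] object.
#' @return Invisibly, the report as a list.
#' @export
run_pipeline <- function(config) {
  set.seed(config$seed)
  subjects <- read_subjects(config$subjects_csv)
  curves <- read_curves(config$curves_csv, config$mode, subjects)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
    message(msg)
  }

  qc <- screen_cohort(curves, config$qc)
  utils::write.csv(qc, file.path(config$out_dir, "qc.csv"),
                   row.names = FALSE)
  included <- qc$subject_id[qc$included]
  if (length(included) == 0L)
    stop_invalid("empty cohort: all subjects excluded by screening")
  for (id in qc$subject_id[!qc$included])
    note("excluded ", id, ": ", qc$reason_codes[qc$subject_id == id])

  param_rows <- list()
  summary_rows <- list()
  bio_rows <- list()
  degenerate <- character(0)
  for (id in included) {
    cc <- curves[[id]]
    fit <- fit_subject(cc, config = config$fit)
    if (!fit$retinol$converged)
      note("retinol-arm fit did not converge for ", id)
    if (!fit$carotene$converged)
      note("carotene-arm fit did not converge for ", id)
    for (badp in c(fit$retinol$poorly_identified,
                   fit$carotene$poorly_identified))
      note("poorly identified parameter for ", id, ": ", badp)
    ests <- c(fit$retinol$estimates, fit$carotene$estimates)
    fsds <- c(fit$retinol$fsd, fit$carotene$fsd)
    param_rows[[id]] <- data.frame(
      subject_id = id, parameter = names(ests),
      estimate = fmt6(unname(ests)), fsd = fmt6(unname(fsds)),
      flag = ifelse(names(ests) %in% c(fit$retinol$poorly_identified,
                                       fit$carotene$poorly_identified),
                    "poorly_identified", ""))

    if (fit$retinol$degenerate || fit$carotene$degenerate) {
      note("degenerate fit for ", id, " (",
           paste(c(fit$retinol$at_bounds, fit$carotene$at_bounds),
                 collapse = ", "),
           " at a parameter bound): excluded from cohort summaries")
      degenerate <- c(degenerate, id)
      next
    }

    rec <- subjects[[id]]
    M5 <- rec$mean_plasma_retinol * plasma_volume(rec$body_weight)
    ks <- kinetic_summary(fit$params, M5)
    summary_rows[[id]] <- data.frame(subject_id = id,
                                     t(vapply(unclass(ks), fmt6,
                                              numeric(1))))
    bio_model <- model_based_bioefficacy(fit$params)
    bio_graph <- tryCatch(
      graphical_bioefficacy(
        truncate_curve(cc$C10, config$truncation_day),
        truncate_curve(cc$C5, config$truncation_day),
        interpolate = TRUE),
      error = function(e) {
        note("graphical bioefficacy failed for ", id, ": ",
             conditionMessage(e))
        NA_real_
      })
    bio_iso <- tryCatch(
      isotope_ratio(cc$C10, cc$C5, config$isotope_ratio_day),
      error = function(e) {
        note("isotope ratio failed for ", id, ": ", conditionMessage(e))
        NA_real_
      })
    bio_rows[[id]] <- data.frame(subject_id = id,
                                 model_based = fmt6(bio_model),
                                 graphical = fmt6(bio_graph),
                                 isotope_ratio_d2 = fmt6(bio_iso))
  }

  if (length(summary_rows) == 0L)
    stop_invalid("empty cohort: every fitted subject was degenerate")
  params_df <- do.call(rbind, param_rows)
  summary_df <- do.call(rbind, summary_rows)
  bio_df <- do.call(rbind, bio_rows)
  names(summary_df) <- c("subject_id", "M5_umol", "M6_umol", "DR_umol_d",
                         "FCR65_per_d", "FCR55_per_d", "thalf5_h",
                         "thalf6_d", "T55_d", "T65_d", "TSYS_d", "v5",
                         "tt5_d", "TTP50_h", "days_of_stores_d",
                         "dietary_input_U1_umol_d")
  utils::write.csv(params_df, file.path(config$out_dir, "params.csv"),
                   row.names = FALSE)
  utils::write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  cohort_row <- data.frame(
    subject_id = "cohort_mean_sd",
    model_based = sprintf("%s +/- %s",
                          fmt6(mean(bio_df$model_based)),
                          fmt6(stats::sd(bio_df$model_based))),
    graphical = sprintf("%s +/- %s",
                        fmt6(mean(bio_df$graphical, na.rm = TRUE)),
                        fmt6(stats::sd(bio_df$graphical, na.rm = TRUE))),
    isotope_ratio_d2 = sprintf("%s +/- %s",
                               fmt6(mean(bio_df$isotope_ratio_d2,
                                         na.rm = TRUE)),
                               fmt6(stats::sd(bio_df$isotope_ratio_d2,
                                              na.rm = TRUE))))
  bio_out <- rbind(data.frame(lapply(bio_df, as.character),
                              stringsAsFactors = FALSE),
                   cohort_row)
  utils::write.csv(bio_out, file.path(config$out_dir, "bioefficacy.csv"),
                   row.names = FALSE)

  mean_sd <- function(x) list(mean = fmt6(mean(x, na.rm = TRUE)),
                              sd = fmt6(stats::sd(x, na.rm = TRUE)))
  report <- list(
    n_input = nrow(qc), n_included = length(included),
    n_summarized = nrow(summary_df),
    degenerate_fits = degenerate,
    excluded = qc[!qc$included, c("subject_id", "reason_codes")],
    kinetics = lapply(summary_df[-1], mean_sd),
    bioefficacy = list(
      model_based = mean_sd(bio_df$model_based),
      graphical = mean_sd(bio_df$graphical),
      isotope_ratio_d2 = mean_sd(bio_df$isotope_ratio_d2)),
    warnings = warnings_log)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}

truncate_curve <- function(cv, day) {
  keep <- cv$time <= day + 1e-9
  tracer_curve(attr(cv, "label"), cv$time[keep], cv$fd[keep],
               observed = TRUE)
}
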