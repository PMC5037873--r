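# Synthetic-cohort generator.  Emulates the two-week dual-tracer study
# design: subjects dispersed around the reference cohort means, sampled on
# the study schedule, with proportional (lognormal) measurement noise on
# the fraction-of-dose observations.

#' Synthetic-population configuration
#'
#' Defaults reproduce the design of the reference study: 30 subjects,
#' sampling at 0, 2, 4, 6, 8, 10, 12 h and 1, 2, 7, 14 d, per-subject
#' kinetic parameters dispersed around the reference cohort means/SDs
#' ([reference_cohort_params()]), body weight 65.2 +/- 10 kg, plasma
#' retinol 1.53 +/- 0.27 umol/L truncated to the observed range
#' (1.13-2.32), 5\% proportional measurement noise and the study doses.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed; the cohort is bit-exact for a given
#'   (config, seed) pair.
#' @param parameter_means,parameter_sds named numeric vectors over the
#'   eleven model parameters.
#' @param body_weight_mean,body_weight_sd kg.
#' @param plasma_retinol_mean,plasma_retinol_sd,plasma_retinol_range
#'   umol/L; draws are truncated to the range.
#' @param noise_cv proportional measurement noise (coefficient of
#'   variation) applied to each positive fraction-of-dose observation.
#' @param schedule sampling times, days.
#' @param doses named vector as [default_doses()].
#' @param dt_max cap for sampled delay times, days.
#' @return A list of class \code{"population_config"}.
#' @export
population_config <- function(n_subjects = 30,
                              seed = 1L,
                              parameter_means = reference_cohort_params()$mean,
                              parameter_sds = reference_cohort_params()$sd,
                              body_weight_mean = 65.2,
                              body_weight_sd = 10.0,
                              plasma_retinol_mean = 1.53,
                              plasma_retinol_sd = 0.27,
                              plasma_retinol_range = c(1.13, 2.32),
                              noise_cv = 0.05,
                              schedule = default_schedule(),
                              doses = default_doses(),
                              dt_max = 1) {
  if (n_subjects < 1) stop_invalid("n_subjects must be >= 1")
  if (any(parameter_sds < 0)) stop_invalid("parameter SDs must be >= 0")
  if (any(parameter_means <= 0 & parameter_sds > 0))
    stop_invalid("zero parameter mean with nonzero SD")
  check_times(schedule)
  structure(list(n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed),
                 parameter_means = parameter_means,
                 parameter_sds = parameter_sds,
                 body_weight_mean = body_weight_mean,
                 body_weight_sd = body_weight_sd,
                 plasma_retinol_mean = plasma_retinol_mean,
                 plasma_retinol_sd = plasma_retinol_sd,
                 plasma_retinol_range = plasma_retinol_range,
                 noise_cv = noise_cv,
                 schedule = schedule,
                 doses = doses,
                 dt_max = dt_max),
            class = "population_config")
}

# Lognormal draw moment-matched to an arithmetic mean and SD.
rlnorm_matched <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  cv2 <- (sd / mean)^2
  sigma2 <- log(1 + cv2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2,
                sdlog = sqrt(sigma2))
}

#' Draw per-subject model parameters from the population
#'
#' Each parameter is drawn independently from a lognormal distribution
#' moment-matched to its population mean and SD (several parameters have
#' CV > 1, which rules out normal draws), delay times are capped at
#' \code{dt_max}, and the cross-arm equality constraints are then applied
#' by construction.
#'
#' @param config a [population_config()].
#' @param n number of subjects (default \code{config$n_subjects}).
#' @return A list of [subject_params()] objects.
#' @export
sample_parameters <- function(config, n = config$n_subjects) {
  set.seed(config$seed)
  draw_parameters(config, n)
}

# Draws from the current RNG state (no reseeding); used internally so a
# whole cohort can be generated from one seed.
draw_parameters <- function(config, n) {
  m <- config$parameter_means
  s <- config$parameter_sds
  draws <- vapply(names(m), function(nm)
    rlnorm_matched(n, m[[nm]], s[[nm]]), numeric(n))
  draws <- matrix(draws, nrow = n,
                  dimnames = list(NULL, names(m)))
  draws[, "DT3"] <- pmin(draws[, "DT3"], config$dt_max)
  draws[, "DT13"] <- pmin(draws[, "DT13"], config$dt_max)
  lapply(seq_len(n), function(i) {
    d <- draws[i, ]
    subject_params(
      retinol_arm_params(L21 = d[["L21"]], L52 = d[["L52"]],
                         DT3 = d[["DT3"]], L54 = d[["L54"]],
                         L65 = d[["L65"]], L56 = d[["L56"]],
                         L106 = d[["L106"]], dt_max = config$dt_max),
      carotene_arm_params(P11 = d[["P11"]], L1512 = d[["L1512"]],
                          DT13 = d[["DT13"]], L1514 = d[["L1514"]],
                          dt_max = config$dt_max)
    )
  })
}

#' Generate noisy observed curves for one subject
#'
#' Simulates both arms on the schedule and multiplies each positive
#' fraction-of-dose value by lognormal noise with the configured
#' coefficient of variation (mean 1).  The t = 0 observation stays exactly
#' zero.
#'
#' @param params a [subject_params()] object.
#' @param config a [population_config()].
#' @return A list with observed [tracer_curve()] elements \code{C10} and
#'   \code{C5}.
#' @export
generate_subject_curves <- function(params, config = population_config()) {
  noisy <- function(arm) {
    cv <- simulate_fd(params, arm, config$schedule)
    fd <- cv$fd
    if (config$noise_cv > 0) {
      pos <- fd > 0
      s2 <- log(1 + config$noise_cv^2)
      fd[pos] <- fd[pos] * stats::rlnorm(sum(pos), -s2 / 2, sqrt(s2))
    }
    tracer_curve(arm, cv$time, fd, observed = TRUE)
  }
  list(C10 = noisy("C10"), C5 = noisy("C5"))
}

#' Inject a screening anomaly into a clean curve pair
#'
#' Deterministically perturbs a clean pair so that [screen_subject()]
#' flags exactly the requested reason code: drop a critical sample
#' (\code{MISSING_CRITICAL}); push one terminal observation below zero
#' (\code{NEGATIVE_FD}); tilt both curves upward over the terminal window
#' (\code{POSITIVE_TERMINAL_SLOPE}; both curves so the isotope ratio is
#' untouched); move the carotene-derived curve toward
#' (\code{CURVES_CONVERGE}) or away from (\code{CURVES_DIVERGE}) the
#' reference curve over time; or scale the reference curve's peak above
#' the plausibility bound (\code{ABNORMAL_PEAK}; a constant factor, which
#' leaves both slope tests untouched).
#'
#' @param curves list with elements \code{C10} and \code{C5}.
#' @param kind one of the six reason codes.
#' @param config a [qc_config()] (used to aim the perturbation).
#' @return The perturbed curve pair.
#' @export
inject_anomaly <- function(curves, kind, config = qc_config()) {
  kind <- match.arg(kind, c("MISSING_CRITICAL", "NEGATIVE_FD",
                            "POSITIVE_TERMINAL_SLOPE", "CURVES_CONVERGE",
                            "CURVES_DIVERGE", "ABNORMAL_PEAK"))
  c10 <- curves$C10
  c5 <- curves$C5
  window <- config$terminal_window
  tilt <- function(cv, k) {
    sel <- cv$time >= min(window) - 1e-9
    fd <- cv$fd
    fd[sel] <- fd[sel] * exp(k * (cv$time[sel] - min(window)))
    tracer_curve(attr(cv, "label"), cv$time, fd, observed = TRUE)
  }
  switch(kind,
    MISSING_CRITICAL = {
      # drop an early critical sample: leaves the terminal window (and so
      # all slope tests) untouched
      drop_t <- min(config$critical_times)
      keep <- abs(c10$time - drop_t) > 1e-9
      c10 <- tracer_curve("C10", c10$time[keep], c10$fd[keep],
                          observed = TRUE)
    },
    NEGATIVE_FD = {
      # a negative value at a non-critical time outside the terminal
      # window (background over-subtraction)
      i <- which.min(abs(c5$time - 1))
      fd <- c5$fd
      fd[i] <- -10 * config$negative_tol - 0.001
      c5 <- tracer_curve("C5", c5$time, fd, observed = TRUE)
    },
    POSITIVE_TERMINAL_SLOPE = {
      # tilt both curves equally (the isotope ratio is untouched), then
      # rescale both by a common constant so the peak bound is not hit
      c10 <- tilt(c10, 0.4)
      c5 <- tilt(c5, 0.4)
      fac <- 0.9 * config$peak_bound / max(c10$fd)
      if (fac < 1) {
        c10 <- tracer_curve("C10", c10$time, c10$fd * fac,
                            observed = TRUE)
        c5 <- tracer_curve("C5", c5$time, c5$fd * fac, observed = TRUE)
      }
    },
    # converging/diverging pairs keep every individual terminal slope
    # negative: the reference curve falls faster toward the lower carotene
    # curve (converge), or the carotene curve falls away from it (diverge)
    CURVES_CONVERGE = c10 <- tilt(c10, -0.5),
    CURVES_DIVERGE = c5 <- tilt(c5, -0.5),
    ABNORMAL_PEAK = {
      fac <- 1.3 * config$peak_bound / max(c10$fd)
      if (fac > 1)
        c10 <- tracer_curve("C10", c10$time, c10$fd * fac,
                            observed = TRUE)
    }
  )
  list(C10 = c10, C5 = c5)
}

#' Generate a full synthetic cohort
#'
#' Draws subject records and true kinetic parameters, simulates noisy
#' observed curves for every subject, and optionally injects screening
#' anomalies into designated subjects.
#'
#' The clean subjects are, by default, drawn conditionally on passing the
#' quality-control screen: the reference cohort statistics describe
#' subjects that were retained by exactly such a screen, so the
#' post-screening population is what the generator emulates.  (Independent
#' lognormal tails otherwise occasionally produce legitimate but
#' implausibly fast absorption with peak fractions of dose above the
#' screening bound.)
#'
#' @param config a [population_config()].
#' @param anomalies optional named character vector mapping subject index
#'   (as character) to a reason code, e.g. \code{c("31" = "NEGATIVE_FD")};
#'   those subjects receive [inject_anomaly()] perturbations.
#' @param qc a [qc_config()] used to aim injected anomalies and to
#'   condition clean subjects.
#' @param condition_on_qc logical; if \code{TRUE}, clean subjects are
#'   redrawn until their noisy curve pair passes [screen_subject()].
#' @return A list of class \code{"synthetic_cohort"} with elements
#'   \code{subjects} (list of [subject_record()]), \code{true_params}
#'   (list of [subject_params()]), \code{curves} (per-subject lists with
#'   \code{C10}/\code{C5}) and \code{config}.
#' @export
generate_cohort <- function(config = population_config(),
                            anomalies = NULL, qc = qc_config(),
                            condition_on_qc = TRUE) {
  set.seed(config$seed)
  n <- config$n_subjects
  if (!is.null(anomalies)) {
    idx <- as.integer(names(anomalies))
    if (anyNA(idx) || any(idx < 1 | idx > n))
      stop_invalid("anomaly indices must name subjects 1..", n)
  }
  ids <- sprintf("S%02d", seq_len(n))
  subjects <- vector("list", n)
  params <- vector("list", n)
  curves <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- if (!is.null(anomalies) && as.character(i) %in%
                  names(anomalies)) anomalies[[as.character(i)]] else NULL
    repeat {
      p <- draw_parameters(config, 1)[[1]]
      bw <- rlnorm_matched(1, config$body_weight_mean,
                           config$body_weight_sd)
      pr <- rtrunc_norm(1, config$plasma_retinol_mean,
                        config$plasma_retinol_sd,
                        config$plasma_retinol_range)
      cc <- generate_subject_curves(p, config)
      # anomalies are injected into otherwise-clean subjects, so the base
      # draw is conditioned regardless of whether a perturbation follows
      if (condition_on_qc &&
          !screen_subject(cc$C10, cc$C5, qc)$included) next
      break
    }
    if (!is.null(kind)) cc <- inject_anomaly(cc, kind, qc)
    subjects[[i]] <- subject_record(
      ids[i], bw, pr,
      dose_retinol = config$doses[["retinol"]],
      dose_bc_alltrans = config$doses[["bc_alltrans"]],
      dose_bc_cis = config$doses[["bc_cis"]],
      dose_bc_alpha = config$doses[["bc_alpha"]])
    params[[i]] <- p
    curves[[i]] <- cc
  }
  names(curves) <- ids
  structure(list(subjects = subjects, true_params = params,
                 curves = curves, config = config,
                 anomalies = anomalies),
            class = "synthetic_cohort")
}

rtrunc_norm <- function(n, mean, sd, range) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Write a synthetic cohort to CSV files
#'
#' Writes \code{subjects.csv} (one row per subject record),
#' \code{curves.csv} (long format: subject_id, time_d, fd_c10, fd_c5),
#' \code{truth.csv} (the generating parameters, one row per subject x
#' parameter) and \code{config.json} (a configuration echo) into
#' \code{dir}.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  subj <- do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$subject_id, body_weight = s$body_weight,
               mean_plasma_retinol = s$mean_plasma_retinol,
               dose_retinol = s$dose_retinol,
               dose_bc_alltrans = s$dose_bc_alltrans,
               dose_bc_cis = s$dose_bc_cis,
               dose_bc_alpha = s$dose_bc_alpha)))
  curves <- do.call(rbind, lapply(names(cohort$curves), function(id) {
    p <- cohort$curves[[id]]
    tt <- sort(unique(c(p$C10$time, p$C5$time)))
    data.frame(subject_id = id, time_d = tt,
               fd_c10 = p$C10$fd[match(tt, p$C10$time)],
               fd_c5 = p$C5$fd[match(tt, p$C5$time)])
  }))
  truth <- do.call(rbind, lapply(seq_along(cohort$true_params),
    function(i) {
      p <- cohort$true_params[[i]]
      ra <- p$retinol_arm
      ca <- p$carotene_arm
      vals <- c(L21 = ra$L21, L52 = ra$L52, DT3 = ra$DT3, L54 = ra$L54,
                L65 = ra$L65, L56 = ra$L56, L106 = ra$L106,
                L1512 = ca$L1512, DT13 = ca$DT13, L1514 = ca$L1514,
                P11 = ca$P11)
      data.frame(subject_id = cohort$subjects[[i]]$subject_id,
                 parameter = names(vals), value = unname(vals))
    }))
  paths <- file.path(dir, c("subjects.csv", "curves.csv", "truth.csv",
                            "config.json"))
  utils::write.csv(subj, paths[1], row.names = FALSE)
  utils::write.csv(curves, paths[2], row.names = FALSE)
  utils::write.csv(truth, paths[3], row.names = FALSE)
  cfg <- cohort$config
  cfg$schedule <- as.numeric(cfg$schedule)
  jsonlite::write_json(unclass(cfg), paths[4], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
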