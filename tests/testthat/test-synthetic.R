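# Synthetic-cohort generator: population sampling, noise model,
# anomaly injection, reproducibility, and end-to-end recovery.

test_that("degenerate dispersion reproduces the population means exactly", {
  cfg <- population_config(n_subjects = 3, seed = 1,
                           parameter_sds = reference_cohort_params()$sd * 0)
  ps <- sample_parameters(cfg)
  m <- reference_cohort_params()$mean
  for (p in ps) {
    expect_equal(p$retinol_arm$L21, m[["L21"]])
    expect_equal(p$retinol_arm$L106, m[["L106"]])
    expect_equal(p$carotene_arm$P11, m[["P11"]])
  }
})

test_that("sampling is bit-exact for a given seed", {
  cfg <- population_config(n_subjects = 4, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$curves, b$curves)
  expect_identical(a$true_params, b$true_params)
  c2 <- generate_cohort(population_config(n_subjects = 4, seed = 43))
  expect_false(identical(a$curves, c2$curves))
})

test_that("lognormal draws are moment-matched to the population", {
  cfg <- population_config(n_subjects = 10000, seed = 8)
  set.seed(cfg$seed)
  m <- cfg$parameter_means
  s <- cfg$parameter_sds
  draws <- retikin:::rlnorm_matched(10000, m[["L106"]], s[["L106"]])
  expect_lt(abs(mean(draws) / 0.0599 - 1), 0.02)
  expect_lt(abs(stats::sd(draws) / 0.0231 - 1), 0.05)
  expect_error(population_config(parameter_means = m * 0),
               "zero parameter mean")
})

test_that("multiplicative noise has the configured coefficient of variation", {
  p <- reference_mean_params()
  cfg <- population_config(schedule = c(0, 2), noise_cv = 0.05)
  set.seed(12)
  vals <- replicate(400, generate_subject_curves(p, cfg)$C10$fd[2])
  expect_lt(abs(stats::sd(vals) / mean(vals) - 0.05), 0.005)
  expect_equal(generate_subject_curves(p, cfg)$C10$fd[1], 0)
  # zero noise reproduces the model output exactly
  cfg0 <- population_config(noise_cv = 0)
  cc <- generate_subject_curves(p, cfg0)
  expect_equal(cc$C10$fd, simulate_fd(p, "C10", cfg0$schedule)$fd)
})

test_that("the reference-mean peak lies in the plausible band", {
  p <- reference_mean_params()
  set.seed(4)
  cc <- generate_subject_curves(p, population_config())
  expect_gt(max(cc$C10$fd), 0.02)
  expect_lt(max(cc$C10$fd), 0.30)
})

test_that("each injected anomaly triggers exactly its reason code", {
  set.seed(19)
  cfg <- population_config()
  pair <- generate_subject_curves(reference_mean_params(), cfg)
  for (kind in c("MISSING_CRITICAL", "NEGATIVE_FD",
                 "POSITIVE_TERMINAL_SLOPE", "CURVES_CONVERGE",
                 "CURVES_DIVERGE", "ABNORMAL_PEAK")) {
    bad <- inject_anomaly(pair, kind)
    v <- screen_subject(bad$C10, bad$C5)
    expect_identical(v$reason_codes, kind)
  }
})

test_that("a written cohort round-trips through the CSV readers", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(population_config(n_subjects = 3, seed = 5))
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("subjects.csv", "curves.csv", "truth.csv", "config.json")))))
  subs <- read_subjects(file.path(dir, "subjects.csv"))
  expect_length(subs, 3)
  expect_equal(subs[["S01"]]$body_weight, co$subjects[[1]]$body_weight,
               tolerance = 1e-12)
  curves <- read_curves(file.path(dir, "curves.csv"), "fd")
  expect_equal(curves[["S02"]]$C10$fd, co$curves[[2]]$C10$fd,
               tolerance = 1e-12)
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_setequal(unique(truth$parameter),
                  names(reference_cohort_params()$mean))
})

test_that("fitting a generated cohort recovers the population", {
  # end-to-end recovery at the study's design size: n = 30 subjects,
  # 5% noise; cohort medians of the well-identified exchange parameters
  # come back within 10%, the cohort-mean bioefficacy within 1.5
  # percentage points
  cfg <- population_config(n_subjects = 30, seed = 2024)
  co <- generate_cohort(cfg)
  fits <- lapply(co$curves, fit_subject)
  for (nm in c("L65", "L56", "L106")) {
    truth <- vapply(co$true_params,
                    function(p) p$retinol_arm[[nm]], numeric(1))
    est <- vapply(fits, function(f) f$retinol$estimates[[nm]],
                  numeric(1))
    expect_lt(abs(stats::median(est) / stats::median(truth) - 1), 0.10)
  }
  bio_true <- mean(vapply(co$true_params, model_based_bioefficacy,
                          numeric(1)))
  bio_est <- mean(vapply(fits, function(f)
    model_based_bioefficacy(f$params), numeric(1)))
  expect_lt(abs(bio_est - bio_true), 0.015)
})
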