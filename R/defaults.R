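# Reference cohort values: model-predicted kinetic parameters (means and
# SDs, n = 30) for healthy young adults of European ancestry with low
# vitamin A stores, plus the anthropometry and dosing of the two-week
# dual-tracer study design the package emulates.

#' Reference cohort parameter dispersion
#'
#' Published cohort means and SDs of the model parameters for healthy young
#' adults with low vitamin A stores (n = 30).  These are the package-wide
#' defaults: fitting uses the means as initial values and the synthetic
#' cohort generator disperses subjects around them.
#'
#' @return A list with numeric vectors \code{mean} and \code{sd}, named by
#'   parameter (\code{L21}, \code{L52}, \code{DT3}, \code{L54}, \code{L65},
#'   \code{L56}, \code{L106}, \code{L1512}, \code{DT13}, \code{L1514},
#'   \code{P11}).  Rates are per day, delay times in days, \code{P11}
#'   dimensionless.
#' @export
reference_cohort_params <- function() {
  list(
    mean = c(L21 = 24.2, L52 = 0.114, DT3 = 0.113, L54 = 2.98,
             L65 = 5.50, L56 = 0.169, L106 = 0.0599,
             L1512 = 0.110, DT13 = 0.152, L1514 = 1.43, P11 = 10.9),
    sd   = c(L21 = 39.0, L52 = 0.191, DT3 = 0.0442, L54 = 5.18,
             L65 = 2.11, L56 = 0.108, L106 = 0.0231,
             L1512 = 0.205, DT13 = 0.0327, L1514 = 0.872, P11 = 5.54)
  )
}

#' Subject-level parameters at the reference cohort means
#'
#' @return A [subject_params()] object built from the cohort-mean
#'   coefficients of [reference_cohort_params()].
#' @export
reference_mean_params <- function() {
  m <- reference_cohort_params()$mean
  subject_params(
    retinol_arm_params(L21 = m[["L21"]], L52 = m[["L52"]], DT3 = m[["DT3"]],
                       L54 = m[["L54"]], L65 = m[["L65"]], L56 = m[["L56"]],
                       L106 = m[["L106"]]),
    carotene_arm_params(P11 = m[["P11"]], L1512 = m[["L1512"]],
                        DT13 = m[["DT13"]], L1514 = m[["L1514"]])
  )
}

#' Blood-sampling schedule of the study design
#'
#' Samples at 0, 2, 4, 6, 8, 10 and 12 h, then 1, 2, 7 and 14 d after
#' dosing.
#'
#' @return Numeric vector of sampling times in days.
#' @export
default_schedule <- function() {
  c(c(0, 2, 4, 6, 8, 10, 12) / 24, 1, 2, 7, 14)
}

#' Administered tracer doses of the study design
#'
#' 1 mg of labeled retinyl acetate (2.954 umol) and 2 mg of labeled
#' beta-carotene whose isomeric composition was 88.5\% all-trans, 10.0\%
#' cis-beta-carotene and 1.5\% alpha-carotene (3.237, 0.366 and 0.055 umol).
#'
#' @return Named numeric vector (umol): \code{retinol},
#'   \code{bc_alltrans}, \code{bc_cis}, \code{bc_alpha}.
#' @export
default_doses <- function() {
  c(retinol = 2.954, bc_alltrans = 3.237, bc_cis = 0.366,
    bc_alpha = 0.055)
}

#' Reference cohort anthropometry
#'
#' @return A list with body weight mean/SD (kg), plasma retinol mean/SD and
#'   truncation range (umol/L).
#' @export
reference_cohort_anthropometry <- function() {
  list(body_weight_mean = 65.2, body_weight_sd = 10.0,
       plasma_retinol_mean = 1.53, plasma_retinol_sd = 0.27,
       plasma_retinol_range = c(1.13, 2.32))
}
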