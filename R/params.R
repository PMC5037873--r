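#' @keywords internal
"_PACKAGE"

# ---- validation helpers ----

stop_invalid <- function(...) {
  stop(structure(
    class = c("retikin_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_finite_nonneg <- function(x, what) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < 0)
    stop_invalid(what, " must be a single finite nonnegative number (got ",
                 deparse(substitute(x)), " = ", format(x), ")")
  as.numeric(x)
}

#' Construct retinol-arm model parameters
#'
#' Fractional transfer coefficients (per day) and the chylomicron delay time
#' for the preformed-retinol arm of the dual-tracer compartmental model.
#' Compartment 1 is the dosing site, 2 the enterocyte, 3 a transport delay
#' (chylomicron production/metabolism and remnant uptake), 4 hepatic
#' processing, 5 plasma retinol bound to RBP, and 6 the exchanging
#' extravascular storage pool with irreversible loss \code{L106}.
#'
#' Absorption efficiency is fixed at 75\%: the unabsorbed loss from
#' compartment 1 is derived as \code{L01 = L21 / 3} (25\% is one-third of
#' 75\%), and the transfer into the delay is tied to the absorptive
#' transfer, \code{L32 = L21}.
#'
#' @param L21 per-day transfer from dosing site into enterocyte.
#' @param L52 per-day direct enterocyte-to-plasma transfer (portal route).
#' @param DT3 transport delay time, days (bounded by \code{dt_max}).
#' @param L54 per-day hepatic secretion of retinol into plasma.
#' @param L65 per-day plasma-to-stores transfer.
#' @param L56 per-day stores-to-plasma transfer.
#' @param L106 per-day irreversible loss from stores.
#' @param dt_max upper bound for the delay time, days.
#' @return An object of class \code{"retinol_arm"}: a named list of the seven
#'   free coefficients plus the derived \code{L01} and \code{L32}.
#' @examples
#' arm <- retinol_arm_params(L21 = 24.2, L52 = 0.114, DT3 = 0.113,
#'                           L54 = 2.98, L65 = 5.50, L56 = 0.169,
#'                           L106 = 0.0599)
#' arm$L01 / (arm$L21 + arm$L01)  # unabsorbed fraction, 0.25
#' @export
retinol_arm_params <- function(L21, L52, DT3, L54, L65, L56, L106,
                               dt_max = 1) {
  for (nm in c("L21", "L52", "DT3", "L54", "L65", "L56", "L106"))
    check_finite_nonneg(get(nm), nm)
  if (DT3 > dt_max)
    stop_invalid("DT3 = ", format(DT3), " exceeds the delay bound ", dt_max,
                 " d")
  structure(list(L21 = as.numeric(L21), L52 = as.numeric(L52),
                 DT3 = as.numeric(DT3), L54 = as.numeric(L54),
                 L65 = as.numeric(L65), L56 = as.numeric(L56),
                 L106 = as.numeric(L106),
                 L01 = as.numeric(L21) / 3,
                 L32 = as.numeric(L21)),
            class = "retinol_arm")
}

#' Construct beta-carotene-arm model parameters
#'
#' Parameters specific to the provitamin A arm: compartment 11 is the dosing
#' site (where the non-converted fraction of the dose is lost), 12 the
#' enterocyte pool of carotene-derived retinol, 13 a transport delay, 14
#' hepatic processing, 15 plasma and 16 stores.  The dimensionless constant
#' \code{P11} sets the non-converted loss \code{L011 = P11 * L1211}, so the
#' fraction of the oral beta-carotene dose absorbed and converted to retinol
#' is \code{1 / (1 + P11)}.
#'
#' The absorptive rate \code{L1211} and the plasma/stores exchange
#' coefficients are shared with the retinol arm and are filled in when the
#' two arms are combined with [subject_params()].  They may be supplied here
#' explicitly, in which case consistency is checked at combination time.
#'
#' @param P11 dimensionless non-conversion proportionality constant.
#' @param L1512 per-day direct enterocyte-to-plasma transfer.
#' @param DT13 transport delay time, days (bounded by \code{dt_max}).
#' @param L1514 per-day hepatic secretion into plasma.
#' @param L1211 optional explicit absorptive rate; must equal the retinol
#'   arm's \code{L21} when both are given to [subject_params()].
#' @param dt_max upper bound for the delay time, days.
#' @return An object of class \code{"carotene_arm"}.
#' @export
carotene_arm_params <- function(P11, L1512, DT13, L1514, L1211 = NULL,
                                dt_max = 1) {
  for (nm in c("P11", "L1512", "DT13", "L1514"))
    check_finite_nonneg(get(nm), nm)
  if (DT13 > dt_max)
    stop_invalid("DT13 = ", format(DT13), " exceeds the delay bound ",
                 dt_max, " d")
  if (!is.null(L1211)) check_finite_nonneg(L1211, "L1211")
  structure(list(P11 = as.numeric(P11), L1512 = as.numeric(L1512),
                 DT13 = as.numeric(DT13), L1514 = as.numeric(L1514),
                 L1211 = if (is.null(L1211)) NULL else as.numeric(L1211)),
            class = "carotene_arm")
}

#' Combine the two tracer arms into one subject model
#'
#' Ties the arms together: the carotene arm inherits the absorptive rate
#' (\code{L1211 = L21}, hence \code{L1312 = L1211}) and the plasma/stores
#' exchange coefficients (\code{L1615 = L65}, \code{L1516 = L56},
#' \code{L2016 = L106}) from the retinol arm.  If the carotene arm carries
#' an explicit shared value that disagrees, construction fails.
#'
#' @param retinol_arm a [retinol_arm_params()] object.
#' @param carotene_arm a [carotene_arm_params()] object.
#' @return An object of class \code{"subject_params"} with elements
#'   \code{retinol_arm} and \code{carotene_arm} (the latter with all shared
#'   coefficients resolved).
#' @export
subject_params <- function(retinol_arm, carotene_arm) {
  if (!inherits(retinol_arm, "retinol_arm"))
    stop_invalid("retinol_arm must be a retinol_arm object")
  if (!inherits(carotene_arm, "carotene_arm"))
    stop_invalid("carotene_arm must be a carotene_arm object")
  if (!is.null(carotene_arm$L1211) &&
      abs(carotene_arm$L1211 - retinol_arm$L21) >
        1e-12 * max(1, retinol_arm$L21))
    stop_invalid("shared parameter mismatch: carotene-arm L1211 = ",
                 format(carotene_arm$L1211), " but retinol-arm L21 = ",
                 format(retinol_arm$L21))
  ca <- carotene_arm
  ca$L1211 <- retinol_arm$L21
  ca$L1312 <- ca$L1211
  ca$L011  <- ca$P11 * ca$L1211
  ca$L1615 <- retinol_arm$L65
  ca$L1516 <- retinol_arm$L56
  ca$L2016 <- retinol_arm$L106
  structure(list(retinol_arm = retinol_arm, carotene_arm = ca),
            class = "subject_params")
}

# Canonical per-arm coefficient set used by the simulator.  Both arms share
# the same topology: gut -> enterocyte -> {delay -> liver, direct} -> plasma
# <-> stores -> irreversible loss.
arm_coefficients <- function(params, arm = c("C10", "C5")) {
  arm <- match.arg(arm)
  if (!inherits(params, "subject_params"))
    stop_invalid("params must be a subject_params object")
  ra <- params$retinol_arm
  if (arm == "C10") {
    list(k_in = ra$L21, k_loss = ra$L01, k_direct = ra$L52,
         k_chain = ra$L32, dt = ra$DT3, k_liver = ra$L54,
         L65 = ra$L65, L56 = ra$L56, L106 = ra$L106)
  } else {
    ca <- params$carotene_arm
    list(k_in = ca$L1211, k_loss = ca$L011, k_direct = ca$L1512,
         k_chain = ca$L1312, dt = ca$DT13, k_liver = ca$L1514,
         L65 = ca$L1615, L56 = ca$L1516, L106 = ca$L2016)
  }
}

#' Fraction of the oral dose that is absorbed
#'
#' For the retinol arm this is fixed at \code{L21/(L21 + 0.333 L21)} = 0.75;
#' for the carotene arm it is \code{1/(1 + P11)}, the fraction of the dose
#' absorbed and converted to retinol.
#'
#' @param params a [subject_params()] object.
#' @param arm \code{"C10"} (retinyl acetate tracer) or \code{"C5"}
#'   (beta-carotene-derived tracer).
#' @return The absorbed fraction, dimensionless.
#' @export
absorbed_fraction <- function(params, arm = c("C10", "C5")) {
  arm <- match.arg(arm)
  k <- arm_coefficients(params, arm)
  if (k$k_in + k$k_loss <= 0)
    stop_invalid("absorptive rate is zero: absorbed fraction undefined")
  k$k_in / (k$k_in + k$k_loss)
}
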