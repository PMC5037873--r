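# Steady-state pool sizes and derived kinetic parameters.
#
# Once the fractional transfer coefficients are fitted, the tracee
# (unlabeled vitamin A) system is assumed to be in steady state: the plasma
# pool M5 (mean plasma retinol concentration x plasma volume) anchors the
# flux balance that yields the storage pool M6 and the disposal rate.

#' Steady-state vitamin A pools and disposal rate
#'
#' Flux balance on the storage compartment at steady state:
#' inflow \code{L65 * M5} equals outflow \code{(L56 + L106) * M6}, so
#' \code{M6 = L65 * M5 / (L56 + L106)}.  The disposal rate is the
#' irreversible loss \code{DR = L106 * M6} (umol/d), the system fractional
#' catabolic rate is \code{FCR65 = DR / M6} (analytically \code{L106}) and
#' the plasma fractional catabolic rate is \code{FCR55 = DR / M5}.
#'
#' @param arm a [retinol_arm_params()] object.
#' @param M5 plasma retinol pool size, umol (> 0).
#' @return A list with \code{M5}, \code{M6} (umol), \code{DR} (umol/d),
#'   \code{FCR65} and \code{FCR55} (per day).
#' @examples
#' arm <- reference_mean_params()$retinol_arm
#' steady_state(arm, M5 = 4.3)
#' @export
steady_state <- function(arm, M5) {
  if (!inherits(arm, "retinol_arm"))
    stop_invalid("arm must be a retinol_arm object")
  if (!is.numeric(M5) || length(M5) != 1L || !is.finite(M5) || M5 <= 0)
    stop_invalid("M5 must be a single positive number (umol)")
  if (arm$L106 <= 0)
    stop_invalid("L106 = 0: no steady state with finite stores")
  M6 <- arm$L65 * M5 / (arm$L56 + arm$L106)
  DR <- arm$L106 * M6
  list(M5 = M5, M6 = M6, DR = DR, FCR65 = DR / M6, FCR55 = DR / M5)
}

#' Half-life of a compartment
#'
#' \code{t1/2 = ln 2 / sum(rates)} where the rates are all fractional
#' transfer coefficients exiting the compartment.
#'
#' @param rates_out per-day exit rates (numeric vector).
#' @return Half-life in days.
#' @examples
#' half_life(5.50)                # plasma compartment at the cohort mean
#' half_life(c(0.169, 0.0599))    # storage compartment
#' @export
half_life <- function(rates_out) {
  if (!is.numeric(rates_out) || length(rates_out) == 0L ||
      anyNA(rates_out) || any(rates_out < 0))
    stop_invalid("rates_out must be nonnegative numbers")
  s <- sum(rates_out)
  if (s <= 0) stop_invalid("sum of exit rates must be positive")
  log(2) / s
}

#' Mean residence times in plasma and stores
#'
#' Computed from the negative inverse of the compartmental matrix of the
#' plasma/stores exchange subsystem,
#' \code{A = [[-L65, L56], [L65, -(L56 + L106)]]}: entry (i, j) of
#' \code{-solve(A)} is the mean total time spent in compartment i (plasma =
#' 1, stores = 2) per unit of tracer entering via compartment j, revisits
#' included.  T55 and T65 are the plasma and storage residence times for
#' tracer entering via plasma; their sum TSYS is the total system transit
#' time.
#'
#' @param arm a [retinol_arm_params()] object with \code{L106 > 0}.
#' @return A list with \code{T55}, \code{T65}, \code{TSYS} (days) and the
#'   full residence-time matrix \code{Tmat}.
#' @export
residence_times <- function(arm) {
  if (!inherits(arm, "retinol_arm"))
    stop_invalid("arm must be a retinol_arm object")
  if (arm$L106 <= 0)
    stop_invalid("L106 = 0: residence times are infinite")
  A <- matrix(c(-arm$L65, arm$L56,
                arm$L65, -(arm$L56 + arm$L106)),
              nrow = 2, byrow = TRUE)
  Tmat <- -solve(A)
  list(T55 = Tmat[1, 1], T65 = Tmat[2, 1],
       TSYS = Tmat[1, 1] + Tmat[2, 1], Tmat = Tmat)
}

#' Retinol recycling number and recycling time
#'
#' The recycling number \code{v5 = T55 / thalf5 - 1} is the mean number of
#' times a retinol molecule returns to plasma before irreversible loss; the
#' recycling time \code{tt5 = T65 / v5} is the mean time per recycling
#' excursion through the extravascular pool.
#'
#' @param T55 plasma residence time, days.
#' @param T65 storage residence time, days.
#' @param thalf5 plasma half-life, days.
#' @return A list with \code{v5} (dimensionless) and \code{tt5} (days).
#' @export
recycling <- function(T55, T65, thalf5) {
  if (!is.numeric(thalf5) || thalf5 <= 0)
    stop_invalid("thalf5 must be positive")
  v5 <- T55 / thalf5 - 1
  if (v5 <= 0)
    stop_invalid("no recycling (T55 <= thalf5): tt5 undefined")
  list(v5 = v5, tt5 = T65 / v5)
}

#' Mean time to plasma (TTP50\%)
#'
#' The time at which half of the absorbed tracer has made its first arrival
#' in the plasma compartment, found as the root of the cumulative
#' first-pass arrival curve ([cumulative_plasma_arrival()]) at 0.5.
#' First-pass arrival counts inflow from the absorptive pathway only;
#' recycled returns from stores are excluded (instantaneous plasma content
#' never reaches half of the absorbed dose in this model class, so the
#' cumulative first-pass reading is the consistent one).
#'
#' @param params a [subject_params()] object.
#' @param arm \code{"C10"} or \code{"C5"}.
#' @param t_max upper bracket for the root search, days.
#' @param tol_hours root tolerance in hours.
#' @return TTP50\% in hours.
#' @export
ttp50 <- function(params, arm = c("C10", "C5"), t_max = 50,
                  tol_hours = 0.01) {
  arm <- match.arg(arm)
  k <- arm_coefficients(params, arm)
  # dense solution, then linear interpolation across the 0.5 crossing
  # (grid step 0.002 d keeps the interpolation error far below tol_hours)
  step <- min(0.002, tol_hours / 24)
  horizon <- min(5, t_max)
  repeat {
    grid <- seq(0, horizon, by = step)
    arr <- cumulative_plasma_arrival(params, arm, grid[-1])
    a <- cummax(c(0, arr$arrival))   # clear solver dust at the plateau
    if (max(a) >= 0.5 || horizon >= t_max) break
    horizon <- min(horizon * 4, t_max)
  }
  if (max(a) < 0.5)
    stop_invalid("cumulative arrival never reaches 0.5 before t_max = ",
                 t_max, " d")
  i <- which(a >= 0.5)[1]
  root <- if (i == 1L) grid[1] else
    grid[i - 1] + (0.5 - a[i - 1]) / (a[i] - a[i - 1]) * step
  root * 24
}

#' Days of vitamin A stores
#'
#' Total body stores divided by the disposal rate: the number of days the
#' storage pool would last if intake stopped and disposal continued at the
#' current rate.
#'
#' @param M6 storage pool, umol.
#' @param DR disposal rate, umol/d (> 0).
#' @return Days of stores.
#' @examples
#' days_of_stores(123, 6.7)  # ~18 d
#' @export
days_of_stores <- function(M6, DR) {
  if (!is.numeric(DR) || any(DR <= 0))
    stop_invalid("DR must be positive")
  if (!is.numeric(M6) || any(M6 < 0))
    stop_invalid("M6 must be nonnegative")
  M6 / DR
}

#' Full per-subject kinetic summary
#'
#' Combines the steady-state solution, half-lives, residence times,
#' recycling parameters, TTP50\% and days of stores into one record.
#' \code{dietary_input_U1 = DR / 0.75} is reported as a convenience: at
#' steady state the absorbed dietary input must balance disposal, so with
#' 75\% absorption the implied dietary vitamin A intake is DR / 0.75.  It
#' is an extrapolation of the steady-state assumption, not a fitted
#' quantity.
#'
#' @param params a [subject_params()] object.
#' @param M5 plasma retinol pool size, umol.
#' @return An object of class \code{"kinetic_summary"}: a named list with
#'   M5, M6 (umol), DR (umol/d), FCR65, FCR55 (per day), thalf5 (hours),
#'   thalf6 (days), T55, T65, TSYS (days), v5, tt5 (days), TTP50 (hours),
#'   days_of_stores (days) and dietary_input_U1 (umol/d).
#' @export
kinetic_summary <- function(params, M5) {
  if (!inherits(params, "subject_params"))
    stop_invalid("params must be a subject_params object")
  ra <- params$retinol_arm
  ss <- steady_state(ra, M5)
  th5 <- half_life(ra$L65)                 # days
  th6 <- half_life(c(ra$L56, ra$L106))     # days
  rt <- residence_times(ra)
  rc <- recycling(rt$T55, rt$T65, th5)
  structure(list(
    M5 = ss$M5, M6 = ss$M6, DR = ss$DR,
    FCR65 = ss$FCR65, FCR55 = ss$FCR55,
    thalf5 = th5 * 24, thalf6 = th6,
    T55 = rt$T55, T65 = rt$T65, TSYS = rt$TSYS,
    v5 = rc$v5, tt5 = rc$tt5,
    TTP50 = ttp50(params, "C10"),
    days_of_stores = days_of_stores(ss$M6, ss$DR),
    dietary_input_U1 = ss$DR / 0.75
  ), class = "kinetic_summary")
}
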