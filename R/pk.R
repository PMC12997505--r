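#' One-compartment first-order-absorption PK parameters
#'
#' Linear PK for a subcutaneously dosed monoclonal antibody. The defaults are
#' synthetic, chosen so the terminal half-life is ~40 days (ln 2 * V/F / CL/F
#' = 40.4 d with the defaults, within the 38-53 day Phase I range for an
#' ultra-long-acting anti-IL-5 antibody) with absorption giving a tmax of
#' about a week; they are configurable and carry no claim of being estimated
#' values.
#'
#' @param ka absorption rate constant (1/day), > 0.
#' @param cl_f apparent clearance CL/F (L/day), > 0.
#' @param v_f apparent volume V/F (L), > 0.
#' @return object of class `pk_params`; the implied elimination half-life is
#'   stored as `t_half`.
#' @export
pk_params <- function(ka = 0.5, cl_f = 0.12, v_f = 7) {
  if (ka <= 0 || cl_f <= 0 || v_f <= 0)
    stop("all PK parameters must be > 0", call. = FALSE)
  ke <- cl_f / v_f
  structure(list(ka = ka, cl_f = cl_f, v_f = v_f, ke = ke,
                 t_half = log(2) / ke),
            class = "pk_params")
}

#' A dosing regimen
#'
#' @param dose dose in mg, >= 0.
#' @param interval_weeks dosing interval in weeks (e.g. 26 for Q26W), > 0.
#' @param n_doses number of administrations.
#' @param horizon_weeks simulation horizon in weeks.
#' @return object of class `regimen`.
#' @examples
#' regimen(100, 26, 2, 52) # 100 mg SC Q26W over one year
#' @export
regimen <- function(dose, interval_weeks = 26, n_doses = 2,
                    horizon_weeks = 52) {
  if (dose < 0) stop("'dose' must be >= 0", call. = FALSE)
  if (interval_weeks <= 0) stop("'interval_weeks' must be > 0", call. = FALSE)
  structure(list(dose = dose, interval_weeks = interval_weeks,
                 n_doses = as.integer(n_doses),
                 horizon_weeks = horizon_weeks,
                 dose_times_days = 7 * interval_weeks * (seq_len(n_doses) - 1),
                 horizon_days = 7 * horizon_weeks),
            class = "regimen")
}

#' Concentration-time profile of a regimen
#'
#' Superposition of closed-form one-compartment first-order-absorption
#' (Bateman) terms over all administered doses:
#' \deqn{C(t) = \sum_i \frac{D_i}{V/F} \frac{k_a}{k_a - k_e}
#'   (e^{-k_e (t - \tau_i)} - e^{-k_a (t - \tau_i)})}
#' for \eqn{t \ge \tau_i}; the flip-flop degenerate case \eqn{k_a = k_e} uses
#' the limit \eqn{(D/V) k_a (t-\tau) e^{-k_a (t-\tau)}}. Linear in dose.
#'
#' @param t time(s) in days since first dose, >= 0.
#' @param reg a [regimen()].
#' @param pk a [pk_params()].
#' @return concentration in ug/mL (mg/L numerically equal).
#' @export
pk_concentration <- function(t, reg, pk) {
  stopifnot(inherits(reg, "regimen"), inherits(pk, "pk_params"))
  if (any(t < 0)) stop("negative time", call. = FALSE)
  conc <- numeric(length(t))
  for (tau in reg$dose_times_days) {
    dt <- t - tau
    on <- dt >= 0
    if (!any(on)) next
    d <- dt[on]
    term <- if (abs(pk$ka - pk$ke) < 1e-12) {
      (reg$dose / pk$v_f) * pk$ka * d * exp(-pk$ka * d)
    } else {
      (reg$dose / pk$v_f) * pk$ka / (pk$ka - pk$ke) *
        (exp(-pk$ke * d) - exp(-pk$ka * d))
    }
    conc[on] <- conc[on] + term
  }
  conc
}
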