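#' Predict log BEC from the dose-time response model
#'
#' Deterministic model prediction (no residual error). The treatment branch
#' (dose > 0) uses the logistic dose-time effect with the time-varying ED50;
#' the placebo branch (dose = 0) is `b1 + E1 + E3 * ln_base` and is free of
#' dose, Emax and ED50. The relative-bioavailability multiplier `F` is applied
#' to arms whose nominal dose is 2 mg (effective dose 2F mg) and is 1 for all
#' other arms.
#'
#' @param params a [dose_time_params()] object.
#' @param dose dose in mg (0 = placebo). Vectorized (recycled with `day`).
#' @param day study day, >= 0.
#' @param ln_base log baseline BEC (log GI/L).
#' @param b random-effect triple (b1, b2, b3); either a length-3 vector used
#'   for all records or an n x 3 matrix.
#' @return numeric vector of predicted log BEC (log GI/L).
#' @examples
#' p <- depemokimab_dose_time_params()
#' # logistic midpoint: at dose = ED50 and Day 182 the effect is half Emax - E0
#' predict_log_bec(p, dose = exp(p$lned50), day = 182, ln_base = log(0.26))
#' @export
predict_log_bec <- function(params, dose, day, ln_base, b = c(0, 0, 0)) {
  stopifnot(inherits(params, "dose_time_params"))
  if (any(dose < 0)) stop("'dose' must be >= 0 (0 = placebo)", call. = FALSE)
  if (any(day < 0)) stop("'day' must be >= 0", call. = FALSE)
  n <- max(length(dose), length(day), length(ln_base))
  dose <- rep_len(dose, n); day <- rep_len(day, n)
  ln_base <- rep_len(ln_base, n)
  if (is.matrix(b)) {
    stopifnot(ncol(b) == 3L)
    b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  } else {
    stopifnot(length(b) == 3L)
    b <- matrix(b, n, 3, byrow = TRUE)
  }
  out <- numeric(n)
  pbo <- dose == 0
  out[pbo] <- b[pbo, 1] + params$e1 + params$e3 * ln_base[pbo]
  if (any(!pbo)) {
    d <- dose[!pbo]
    ln_dose_eff <- log(d) + ifelse(d == 2, log(params$f), 0)
    arg <- params$slp * (b[!pbo, 3] + params$lned50 +
                           params$ke * (day[!pbo] - 182) - ln_dose_eff)
    out[!pbo] <- b[!pbo, 1] + params$e0 + params$e2 * ln_base[!pbo] +
      (params$emax + b[!pbo, 2] - params$e0) / (1 + exp(arg))
  }
  out
}
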