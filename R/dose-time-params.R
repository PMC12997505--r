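#' Parameters of the log-BEC dose-time response model
#'
#' Container for the fixed effects, random-effect covariance and residual
#' variance of the nonlinear mixed-effects model of log blood eosinophil
#' count after a single subcutaneous dose:
#'
#' treatment (dose > 0):
#' \deqn{\log BEC = b_1 + E_0 + E_2 \ln(BASE) +
#'   \frac{E_{max} + b_2 - E_0}
#'        {1 + \exp\{SLP (b_3 + LNED_{50} + KE (t - 182) - \log F - \ln dose)\}}}
#' placebo (dose = 0):
#' \deqn{\log BEC = b_1 + E_1 + E_3 \ln(BASE)}
#'
#' with subject random effects \eqn{(b_1, b_2, b_3) \sim N(0, S2B)} on the
#' intercept, Emax and log-ED50, i.i.d. lognormal residual error of log-scale
#' variance `s2y`, and the relative-bioavailability multiplier `F` applied to
#' the 2 mg arm only (effective dose = 2F mg). `lned50` is the log
#' half-maximal dose at Day 182; `ke` (per day) is the rate at which the ED50
#' grows with time as drug washes out.
#'
#' @param e0,e1 treatment/placebo intercepts (log GI/L scale).
#' @param e2,e3 baseline-BEC covariate slopes (dimensionless, on log baseline
#'   in GI/L).
#' @param emax maximum-effect asymptote (log scale); more negative = deeper
#'   suppression.
#' @param lned50 log half-maximal dose at Day 182 (log mg).
#' @param ke rate of increase of the ED50 (per day), > 0.
#' @param slp Hill slope, > 0.
#' @param f relative bioavailability multiplier for the 2 mg dose, > 0.
#' @param s2b 3x3 random-effect covariance (b1, b2, b3). Symmetrized, and
#'   projected to the nearest positive semi-definite matrix (with a warning)
#'   if rounding has made it indefinite.
#' @param s2y residual variance on the log scale, > 0.
#' @return object of class `dose_time_params`.
#' @seealso [depemokimab_dose_time_params()] for the published reference set,
#'   [predict_log_bec()], [generate_phase1()].
#' @export
dose_time_params <- function(e0, e1, e2, e3, emax, lned50, ke, slp, f = 1,
                             s2b = diag(0, 3), s2y = 0) {
  for (nm in c("e0", "e1", "e2", "e3", "emax", "lned50", "ke", "slp", "f", "s2y")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (ke <= 0) stop("'ke' must be > 0", call. = FALSE)
  if (slp <= 0) stop("'slp' must be > 0", call. = FALSE)
  if (f <= 0) stop("'f' must be > 0", call. = FALSE)
  if (s2y < 0) stop("'s2y' must be >= 0", call. = FALSE)
  s2b <- as_valid_covariance(s2b, "s2b")
  structure(
    list(e0 = e0, e1 = e1, e2 = e2, e3 = e3, emax = emax, lned50 = lned50,
         ke = ke, slp = slp, f = f, s2b = s2b, s2y = s2y),
    class = "dose_time_params")
}

# Symmetrize and project a covariance to the nearest PSD matrix by clipping
# negative eigenvalues; refuses matrices that are badly indefinite.
as_valid_covariance <- function(m, name) {
  m <- as.matrix(m)
  if (!is.numeric(m) || nrow(m) != 3L || ncol(m) != 3L || anyNA(m))
    stop("'", name, "' must be a numeric 3x3 matrix without NAs", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8 * (1 + max(abs(m))))
    stop("'", name, "' must be symmetric", call. = FALSE)
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  tol <- 1e-10 * max(1, abs(ev$values[1]))
  if (min(ev$values) < -0.1 * max(abs(ev$values)))
    stop("'", name, "' is not positive semi-definite (eigenvalues ",
         paste(signif(ev$values, 4), collapse = ", "), ")", call. = FALSE)
  if (min(ev$values) < -tol) {
    warning("'", name, "' slightly indefinite; projected to nearest PSD matrix")
    vals <- pmax(ev$values, 0)
    m <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    m <- (m + t(m)) / 2
  }
  dimnames(m) <- list(c("b1", "b2", "b3"), c("b1", "b2", "b3"))
  m
}

#' Reference dose-time response estimates for depemokimab
#'
#' The posterior-mean parameter set from the published Bayesian dose-time
#' response analysis of the depemokimab first-time-in-human trial in
#' mild-to-moderate asthma (48 patients, single subcutaneous doses of
#' 2-300 mg). Useful as a ground truth for the synthetic-data generator and
#' as the center of synthetic posteriors.
#'
#' @return a `dose_time_params` object.
#' @examples
#' p <- depemokimab_dose_time_params()
#' exp(p$lned50) # ED50 at Day 182, about 19.1 mg
#' @export
depemokimab_dose_time_params <- function() {
  s2b <- matrix(c(0.2096, -0.2058, 0.0550,
                  -0.2058, 0.5194, -0.2120,
                  0.0550, -0.2120, 0.3850), 3, 3, byrow = TRUE)
  dose_time_params(
    e0 = -0.2601, e1 = -0.6583, e2 = 0.5128, e3 = 0.5084,
    emax = -2.6047, lned50 = 2.9513, ke = 0.0207, slp = 1.2358,
    f = 2.3730, s2b = s2b, s2y = 0.0804)
}

#' Posterior means and SDs of the reference dose-time analysis
#'
#' Marginal posterior summaries (mean, SD) of the fixed effects of the
#' reference depemokimab analysis, used by [synthetic_posterior_normal()] to
#' build a synthetic posterior when only printed summaries are available.
#'
#' @return data.frame with columns `parameter`, `mean`, `sd`.
#' @export
depemokimab_posterior_summary <- function() {
  data.frame(
    parameter = c("e0", "e1", "e2", "e3", "emax", "lned50", "ke", "slp", "f"),
    mean = c(-0.2601, -0.6583, 0.5128, 0.5084, -2.6047, 2.9513, 0.0207,
             1.2358, 2.3730),
    sd = c(0.3054, 0.4209, 0.1995, 0.3865, 0.2451, 0.2093, 0.00263,
           0.2222, 0.9708))
}

#' @export
print.dose_time_params <- function(x, ...) {
  cat("Dose-time response parameters (log BEC scale)\n")
  cat(sprintf("  E0 %.4f  E1 %.4f  E2 %.4f  E3 %.4f\n", x$e0, x$e1, x$e2, x$e3))
  cat(sprintf("  Emax %.4f  LNED50 %.4f (ED50 Day 182 = %.2f mg)\n",
              x$emax, x$lned50, exp(x$lned50)))
  cat(sprintf("  KE %.4f /day  Hill %.3f  F(2 mg) %.3f  S2Y %.4f\n",
              x$ke, x$slp, x$f, x$s2y))
  cat("  random-effect covariance S2B:\n")
  print(round(x$s2b, 4))
  invisible(x)
}
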