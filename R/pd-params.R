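#' Population PK/PD parameters of the indirect-response BEC model
#'
#' Fixed effects, covariate coefficients and variance components of the
#' eosinophil turnover model. The covariate model (evaluated by
#' [realize_subject()]) is, for observed baseline `BEOS` (GI/L) and one
#' disease flag:
#' \deqn{KRO_i = \exp(\theta_{KRO} + \theta_{BEOS1} \log(BEOS/0.26) +
#'   \theta_{disease} + \eta_1) \cdot \theta_{200622}}
#' \deqn{KOUT_i = 24 \exp(\theta_{KOUT})\quad (\theta_{KOUT}\ per\ hour)}
#' \deqn{IC_{50,i} = \exp(\theta_{IC50})}
#' \deqn{I_{max,i} = \exp(\theta_{Imax} + \theta_{BEOS2} \log(BEOS/0.26) + \eta_2)}
#' \deqn{GAMA_i = \theta_{GAMA}}
#' with \eqn{\eta \sim N(0, \omega^2)} and observation model
#' \eqn{Y = IPRED \cdot e^{\epsilon}}, \eqn{\epsilon \sim N(0, \sigma^2)}.
#' The reference baseline 0.26 GI/L is the published centering constant.
#' Defaults are the published depemokimab population estimates (the disease
#' shifts and several structural parameters fixed from a 16-study
#' mepolizumab meta-analysis).
#'
#' @param theta_kro log typical baseline BEC (log GI/L).
#' @param theta_kout log elimination rate (per HOUR; converted to /day by the
#'   24x factor in [realize_subject()]).
#' @param theta_ic50 log IC50 (log ug/mL).
#' @param theta_imax log maximal-inhibition floor fraction; exp(theta_imax)
#'   must lie in (0, 1).
#' @param theta_gama Hill coefficient (linear scale).
#' @param theta_beos1,theta_beos2 baseline-BEC covariate slopes on KRO and
#'   Imax.
#' @param disease_kro named vector of disease shifts on log KRO.
#' @param study200622_mult multiplier applied when the 200622-study flag is
#'   set.
#' @param omega2_kro,omega2_imax between-patient variances (log scale).
#' @param sigma residual SD (log scale), > 0.
#' @return object of class `pd_params`.
#' @export
pd_params <- function(theta_kro = -1.73, theta_kout = -4.35,
                      theta_ic50 = -2.34, theta_imax = -1.77,
                      theta_gama = 1.61, theta_beos1 = 0.563,
                      theta_beos2 = -0.380,
                      disease_kro = c(severe_asthma = 0.438, CRSwNP = 0.132,
                                      EGPA = 0.208, HES = 1.27),
                      study200622_mult = 0.5,
                      omega2_kro = 0.0853, omega2_imax = 0.294,
                      sigma = 0.350) {
  if (omega2_kro < 0 || omega2_imax < 0)
    stop("omega2 variances must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  if (exp(theta_imax) <= 0 || exp(theta_imax) >= 1)
    stop("exp(theta_imax) must lie in (0, 1)", call. = FALSE)
  structure(list(theta_kro = theta_kro, theta_kout = theta_kout,
                 theta_ic50 = theta_ic50, theta_imax = theta_imax,
                 theta_gama = theta_gama, theta_beos1 = theta_beos1,
                 theta_beos2 = theta_beos2, disease_kro = disease_kro,
                 study200622_mult = study200622_mult,
                 omega2_kro = omega2_kro, omega2_imax = omega2_imax,
                 sigma = sigma),
            class = "pd_params")
}

#' Realize individual PK/PD parameters from the covariate model
#'
#' Applies the covariate equations of [pd_params()] exactly: log-additive
#' baseline-BEC and disease effects with exponential random effects, the
#' 24x per-hour to per-day conversion for KOUT, and the optional
#' 200622-study multiplier on KRO. In simulation, eta2 values that would
#' push Imax to 1 or above are rejected upstream; here Imax >= 1 is an
#' error.
#'
#' @param pd a [pd_params()].
#' @param baseline_obs observed baseline BEC (GI/L), > 0.
#' @param disease `"severe_asthma"`, `"CRSwNP"`, `"EGPA"`, `"HES"` or
#'   `"none"` (reference: no disease shift).
#' @param etas length-2 vector (eta1 on KRO, eta2 on Imax).
#' @param study200622 logical flag for the 200622-study KRO multiplier.
#' @return object of class `subject_pkpd`: list with `kro` (GI/L), `kout`
#'   (1/day), `ic50` (ug/mL), `imax` (fraction in (0,1)), `gama`,
#'   `baseline_obs`, `disease`.
#' @examples
#' pd <- pd_params()
#' realize_subject(pd, 0.26, "none")$kro # exp(-1.73) = 0.177 GI/L
#' @export
realize_subject <- function(pd, baseline_obs, disease = "none",
                            etas = c(0, 0), study200622 = FALSE) {
  stopifnot(inherits(pd, "pd_params"))
  if (baseline_obs <= 0) stop("'baseline_obs' must be > 0", call. = FALSE)
  if (length(disease) != 1)
    stop("exactly one disease label must be given", call. = FALSE)
  if (!disease %in% c(names(pd$disease_kro), "none"))
    stop("unknown disease '", disease, "'", call. = FALSE)
  shift <- if (disease == "none") 0 else pd$disease_kro[[disease]]
  lb <- log(baseline_obs / 0.26)
  kro <- exp(pd$theta_kro + pd$theta_beos1 * lb + shift + etas[1]) *
    (if (study200622) pd$study200622_mult else 1)
  imax <- exp(pd$theta_imax + pd$theta_beos2 * lb + etas[2])
  if (imax >= 1)
    stop("realized Imax >= 1; eta2 too large for the inhibitory model",
         call. = FALSE)
  structure(list(kro = kro, kout = 24 * exp(pd$theta_kout),
                 ic50 = exp(pd$theta_ic50), imax = imax,
                 gama = pd$theta_gama, baseline_obs = baseline_obs,
                 disease = disease),
            class = "subject_pkpd")
}

#' Reporting transforms for population-model estimates
#'
#' The standard population-modeling report arithmetic: percent relative
#' standard error `rse_pct(est, se) = 100 se/est`; percent CV of an
#' exponential random effect `cv_pct(omega2) = 100 sqrt(exp(omega2) - 1)`;
#' and the back-transformed 95% CI of a log-scale estimate,
#' `exp(theta +/- 1.96 se)`.
#'
#' @param est,theta estimate (natural or log scale as named).
#' @param se standard error.
#' @param omega2 log-scale variance.
#' @param level confidence level (default 0.95).
#' @return numeric scalar or length-2 vector (CI).
#' @examples
#' round(cv_pct(0.0853), 1)            # 29.8
#' round(ci_backtransform(-1.73, 0.0529), 3) # 0.160 0.197
#' @export
rse_pct <- function(est, se) 100 * se / est

#' @rdname rse_pct
#' @export
cv_pct <- function(omega2) 100 * sqrt(exp(omega2) - 1)

#' @rdname rse_pct
#' @export
ci_backtransform <- function(theta, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  exp(theta + c(-1, 1) * z * se)
}

#' @rdname rse_pct
#' @export
ci_linear <- function(theta, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  theta + c(-1, 1) * z * se
}
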