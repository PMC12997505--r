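#' Exacerbation-rate dose-response model parameters
#'
#' Negative-binomial model of annualized asthma exacerbation counts with an
#' Emax dose-response on the rate:
#' \deqn{\lambda(d) = \lambda_0 \left(1 - E_{frac} \frac{d^h}{ED_{50}^h + d^h}\right)}
#' Counts over a follow-up of `followup_years` are NB with mean
#' \eqn{\lambda(d) T} and variance \eqn{\mu + \mu^2 / k} (dispersion `k`).
#'
#' Defaults are synthetic assumptions calibrated to public anti-IL-5
#' severe-asthma results (placebo rate ~2/year, ~50% maximal reduction,
#' dispersion ~0.8); the true ED50 location is treated as unknown and can be
#' re-sampled per design via [sample_designs()].
#'
#' @param lambda0 placebo annualized rate, > 0 (events/year).
#' @param emax_frac maximal fractional rate reduction in (0, 1).
#' @param ed50 half-maximal dose in mg, > 0.
#' @param hill Hill slope (default 1; then ED90 = 9 ED50).
#' @param k NB dispersion, > 0.
#' @param followup_years follow-up duration, > 0.
#' @return object of class `exacerbation_params`.
#' @export
exacerbation_params <- function(lambda0 = 2.0, emax_frac = 0.5, ed50 = 20,
                                hill = 1, k = 0.8, followup_years = 1) {
  if (lambda0 <= 0) stop("'lambda0' must be > 0", call. = FALSE)
  if (emax_frac < 0 || emax_frac >= 1)
    stop("'emax_frac' must be in [0, 1)", call. = FALSE)
  if (ed50 <= 0) stop("'ed50' must be > 0", call. = FALSE)
  if (k <= 0) stop("NB dispersion 'k' must be > 0", call. = FALSE)
  if (followup_years <= 0) stop("'followup_years' must be > 0", call. = FALSE)
  structure(list(lambda0 = lambda0, emax_frac = emax_frac, ed50 = ed50,
                 hill = hill, k = k, followup_years = followup_years),
            class = "exacerbation_params")
}

#' Annualized exacerbation rate at a dose
#'
#' @param params an [exacerbation_params()] object.
#' @param dose dose in mg (vectorized).
#' @return annualized rate(s), events/year.
#' @export
exacerbation_rate <- function(params, dose) {
  stopifnot(inherits(params, "exacerbation_params"))
  h <- params$hill
  params$lambda0 * (1 - params$emax_frac * dose^h / (params$ed50^h + dose^h))
}

#' Simulate per-subject annualized exacerbation counts for a trial
#'
#' Each subject's count over the follow-up period is drawn from a negative
#' binomial with mean `rate(dose) * followup_years` and dispersion `k`
#' (variance mu + mu^2/k); the annualized rate is exactly count / T.
#'
#' @param design a [trial_design()] (active doses + placebo, balanced arms).
#' @param params an [exacerbation_params()] truth.
#' @param seed optional integer seed.
#' @return data.frame with columns `ID`, `DOSE`, `COUNT`, `T_YEARS`, `RATE`.
#' @export
generate_exacerbation_counts <- function(design, params, seed = NULL) {
  stopifnot(inherits(design, "trial_design"), inherits(params, "exacerbation_params"))
  if (!is.null(seed)) { rs <- local_rng(seed); on.exit(restore_rng(rs)) }
  doses <- c(0, design$active_doses)
  n <- design$n_per_arm
  tt <- params$followup_years
  out <- do.call(rbind, lapply(seq_along(doses), function(a) {
    mu <- exacerbation_rate(params, doses[a]) * tt
    cnt <- rnbinom(n, size = params$k, mu = mu)
    data.frame(ID = (a - 1L) * n + seq_len(n), DOSE = doses[a],
               COUNT = cnt, T_YEARS = tt, RATE = cnt / tt)
  }))
  rownames(out) <- NULL
  out
}
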