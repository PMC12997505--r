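#' Fit the Bayesian nonlinear mixed-effects dose-time response model
#'
#' Fits the log-BEC dose-time model (see [dose_time_params()]) by MCMC
#' (Gibbs/Metropolis via JAGS). Only records from `fit_day_min` onward (the
#' return-to-baseline window, default Day 57) enter the likelihood; records
#' on `validation_day` (default Day 29) are held out for posterior-predictive
#' validation. Priors are weakly informative: N(0, 10^2) on the fixed effects
#' (log scales), half-normal on the residual SD, truncated normals keeping KE
#' and the Hill slope positive, normal on log F, and a Wishart prior on the
#' random-effect precision (inverse-Wishart on the covariance); all exposed
#' through `priors`.
#'
#' @param panel long-format BEC panel with columns `ID`, `DOSE`, `DAY`,
#'   `BASE`, `DV` (see [generate_phase1()]). Must contain at least two
#'   distinct active dose levels and a placebo arm.
#' @param priors named list overriding any of `fixed_sd` (default 10),
#'   `ke_sd` (1), `slp_mean` (1), `slp_sd` (2), `lf_sd` (1), `sdy_sd` (1),
#'   `wishart_df` (4), `wishart_scale` (diag(3)).
#' @param n_chains,n_iter,n_adapt,n_burn MCMC settings; the default
#'   4 x 2500 = 10,000 retained draws.
#' @param fit_day_min first study day entering the likelihood.
#' @param validation_day day held out for validation (NULL to disable).
#' @param seed integer seed (also seeds the JAGS RNGs).
#' @param quiet suppress JAGS progress output.
#' @return object of class `dose_time_fit`: a list with `draws` (data.frame,
#'   one row per retained draw: fixed effects, the six covariance entries
#'   `s2b11..s2b33` and `s2y`), `mcmc` (a [coda::mcmc.list]), `geweke`
#'   (z-score per parameter, first chain), `converged` (no fixed-effect
#'   |z| > 3), `ess` (effective sample sizes), `holdout` (the validation
#'   records) and `meta`.
#' @seealso [derive_quantities()], [posterior_summary()],
#'   [predictive_coverage()].
#' @export
fit_dose_time <- function(panel, priors = list(), n_chains = 2,
                          n_iter = 2500, n_adapt = 500, n_burn = 500,
                          fit_day_min = 57, validation_day = 29,
                          seed = 1L, quiet = TRUE) {
  need <- c("ID", "DOSE", "DAY", "BASE", "DV")
  if (!all(need %in% names(panel)))
    stop("panel must have columns ", paste(need, collapse = ", "), call. = FALSE)
  active <- unique(panel$DOSE[panel$DOSE > 0])
  if (length(active) < 2)
    stop("dose-response unidentifiable: need >= 2 distinct active dose levels",
         call. = FALSE)
  if (!any(panel$DOSE == 0))
    stop("panel must contain a placebo arm (DOSE = 0)", call. = FALSE)

  pr <- modifyList(list(fixed_sd = 10, ke_sd = 1, slp_mean = 1, slp_sd = 2,
                        lf_sd = 1, sdy_sd = 1, wishart_df = 4,
                        wishart_scale = diag(3)), priors)

  fit_dat <- panel[panel$DAY >= fit_day_min, , drop = FALSE]
  holdout <- if (!is.null(validation_day))
    panel[panel$DAY == validation_day, , drop = FALSE] else panel[0, ]
  sub <- match(fit_dat$ID, sort(unique(fit_dat$ID)))

  dl <- list(
    N = nrow(fit_dat), S = max(sub),
    y = log(fit_dat$DV), lb = log(fit_dat$BASE), day = fit_dat$DAY,
    sub = sub, trt = as.numeric(fit_dat$DOSE > 0),
    lde = ifelse(fit_dat$DOSE > 0, log(pmax(fit_dat$DOSE, 1e-12)), 0),
    is2 = as.numeric(fit_dat$DOSE == 2),
    zero3 = rep(0, 3), R3 = pr$wishart_scale, wdf = pr$wishart_df,
    prec_fix = 1 / pr$fixed_sd^2, prec_ke = 1 / pr$ke_sd^2,
    slp_mean = pr$slp_mean, prec_slp = 1 / pr$slp_sd^2,
    prec_lf = 1 / pr$lf_sd^2, prec_sdy = 1 / pr$sdy_sd^2)

  model_str <- "
model {
  for (i in 1:N) {
    mu[i] <- ifelse(trt[i] > 0.5,
      b[sub[i],1] + E0 + E2*lb[i] + (Emax + b[sub[i],2] - E0) /
        (1 + exp(SLP*(b[sub[i],3] + LNED50 + KE*(day[i]-182) - lde[i] - lF*is2[i]))),
      b[sub[i],1] + E1 + E3*lb[i])
    y[i] ~ dnorm(mu[i], tau_y)
  }
  for (j in 1:S) { b[j,1:3] ~ dmnorm(zero3, Pb) }
  Pb ~ dwish(R3, wdf)
  Sb <- inverse(Pb)
  E0 ~ dnorm(0, prec_fix); E1 ~ dnorm(0, prec_fix)
  E2 ~ dnorm(0, prec_fix); E3 ~ dnorm(0, prec_fix)
  Emax ~ dnorm(0, prec_fix); LNED50 ~ dnorm(0, prec_fix)
  KE ~ dnorm(0, prec_ke) T(0,)
  SLP ~ dnorm(slp_mean, prec_slp) T(0,)
  lF ~ dnorm(0, prec_lf)
  sd_y ~ dnorm(0, prec_sdy) T(0,)
  tau_y <- pow(sd_y, -2)
  s2y <- pow(sd_y, 2)
}"
  inits <- lapply(seq_len(n_chains), function(ch) list(
    E0 = 0, E1 = 0, E2 = 0.5, E3 = 0.5, Emax = -2, LNED50 = 3, KE = 0.02,
    SLP = 1, lF = 0.5, sd_y = 0.3,
    .RNG.name = "base::Mersenne-Twister", .RNG.seed = seed + ch))
  jm <- rjags::jags.model(textConnection(model_str), data = dl, inits = inits,
                          n.chains = n_chains, n.adapt = n_adapt, quiet = quiet)
  if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
  pars <- c("E0", "E1", "E2", "E3", "Emax", "LNED50", "KE", "SLP", "lF",
            "Sb", "s2y")
  samp <- rjags::coda.samples(jm, pars, n.iter = n_iter,
                              progress.bar = "none")

  dm <- do.call(rbind, lapply(samp, as.matrix))
  draws <- data.frame(
    e0 = dm[, "E0"], e1 = dm[, "E1"], e2 = dm[, "E2"], e3 = dm[, "E3"],
    emax = dm[, "Emax"], lned50 = dm[, "LNED50"], ke = dm[, "KE"],
    slp = dm[, "SLP"], f = exp(dm[, "lF"]),
    s2b11 = dm[, "Sb[1,1]"], s2b12 = dm[, "Sb[1,2]"], s2b13 = dm[, "Sb[1,3]"],
    s2b22 = dm[, "Sb[2,2]"], s2b23 = dm[, "Sb[2,3]"], s2b33 = dm[, "Sb[3,3]"],
    s2y = dm[, "s2y"])

  fixed <- c("e0", "e1", "e2", "e3", "emax", "lned50", "ke", "slp")
  ch1 <- as.matrix(samp[[1]])
  gw <- vapply(c(E0 = "E0", E1 = "E1", E2 = "E2", E3 = "E3", Emax = "Emax",
                 LNED50 = "LNED50", KE = "KE", SLP = "SLP"),
               function(p) geweke_z(ch1[, p]), numeric(1))
  converged <- all(is.finite(gw)) && max(abs(gw)) <= 3
  if (!converged)
    warning("possible non-convergence: |Geweke z| > 3 for ",
            paste(names(gw)[abs(gw) > 3], collapse = ", "))
  ess <- tryCatch(coda::effectiveSize(samp[, c("E0", "E1", "E2", "E3", "Emax",
                                               "LNED50", "KE", "SLP")]),
                  error = function(e) NULL)
  structure(list(draws = draws, mcmc = samp, geweke = gw,
                 converged = converged, ess = ess, holdout = holdout,
                 meta = list(n_chains = n_chains, n_iter = n_iter,
                             n_fit_obs = nrow(fit_dat),
                             fit_day_min = fit_day_min,
                             validation_day = validation_day, seed = seed,
                             priors = pr)),
            class = "dose_time_fit")
}

#' @export
print.dose_time_fit <- function(x, ...) {
  cat(sprintf("Bayesian dose-time fit: %d draws (%d chains), %d observations (Day >= %s)\n",
              nrow(x$draws), x$meta$n_chains, x$meta$n_fit_obs, x$meta$fit_day_min))
  cat(sprintf("converged (|Geweke z| <= 3 on fixed effects): %s\n", x$converged))
  print(posterior_summary(x), digits = 4)
  invisible(x)
}

#' Posterior summary table
#'
#' Mean, SD, median and 95% highest-posterior-density interval per
#' parameter, in the layout conventional for dose-time response reports.
#'
#' @param fit a `dose_time_fit`, or a data.frame of draws.
#' @param params columns to summarize (default all).
#' @return data.frame with one row per parameter.
#' @export
posterior_summary <- function(fit, params = NULL) {
  draws <- if (inherits(fit, "dose_time_fit")) fit$draws else as.data.frame(fit)
  if (!is.null(params)) draws <- draws[, params, drop = FALSE]
  hpd <- coda::HPDinterval(coda::as.mcmc(as.matrix(draws)), prob = 0.95)
  data.frame(parameter = names(draws),
             mean = vapply(draws, mean, 1), sd = vapply(draws, sd, 1),
             median = vapply(draws, median, 1),
             hpd_lower = hpd[, 1], hpd_upper = hpd[, 2], row.names = NULL)
}

#' Posterior-predictive coverage of held-out records
#'
#' For each held-out record, computes the central `prob` posterior-predictive
#' interval of log BEC (fixed effects + new random effects + residual drawn
#' per posterior draw) and reports the fraction of records covered. Used to
#' validate the fitted model on the Day-29 visit excluded from the
#' likelihood.
#'
#' @param fit a `dose_time_fit` with a non-empty `holdout`.
#' @param prob interval probability (default 0.95).
#' @param n_draws posterior draws to use (subsampled; default up to 1000).
#' @param seed integer seed for the new random effects/residuals.
#' @return list with `coverage` (fraction in interval) and `n` records.
#' @export
predictive_coverage <- function(fit, prob = 0.95, n_draws = 1000, seed = 1L) {
  stopifnot(inherits(fit, "dose_time_fit"))
  hd <- fit$holdout
  if (nrow(hd) == 0) stop("fit has no held-out records", call. = FALSE)
  rs <- local_rng(seed); on.exit(restore_rng(rs))
  dr <- fit$draws
  idx <- if (nrow(dr) > n_draws)
    round(seq(1, nrow(dr), length.out = n_draws)) else seq_len(nrow(dr))
  dr <- dr[idx, ]
  a <- (1 - prob) / 2
  covered <- logical(nrow(hd))
  for (r in seq_len(nrow(hd))) {
    pred <- vapply(seq_len(nrow(dr)), function(k) {
      p <- draw_to_params(dr[k, ])
      b <- if (all(p$s2b == 0)) c(0, 0, 0) else {
        ev <- eigen(p$s2b, symmetric = TRUE)
        as.numeric(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(3)))
      }
      predict_log_bec(p, hd$DOSE[r], hd$DAY[r], log(hd$BASE[r]), b) +
        rnorm(1, 0, sqrt(p$s2y))
    }, numeric(1))
    qi <- quantile(pred, c(a, 1 - a), names = FALSE)
    covered[r] <- log(hd$DV[r]) >= qi[1] && log(hd$DV[r]) <= qi[2]
  }
  list(coverage = mean(covered), n = nrow(hd))
}

# Convert one row of a draws data.frame into a dose_time_params object.
draw_to_params <- function(d) {
  s2b <- if (all(c("s2b11", "s2b12", "s2b13", "s2b22", "s2b23", "s2b33") %in%
                 names(d))) {
    matrix(c(d$s2b11, d$s2b12, d$s2b13,
             d$s2b12, d$s2b22, d$s2b23,
             d$s2b13, d$s2b23, d$s2b33), 3, 3)
  } else diag(0, 3)
  suppressWarnings(dose_time_params(
    e0 = d$e0, e1 = d$e1, e2 = d$e2, e3 = d$e3, emax = d$emax,
    lned50 = d$lned50, ke = d$ke, slp = d$slp, f = if ("f" %in% names(d)) d$f else 1,
    s2b = s2b, s2y = if ("s2y" %in% names(d)) d$s2y else 0))
}

#' Write/read posterior draws as CSV
#'
#' One column per parameter, one row per retained draw.
#'
#' @param draws data.frame of draws (e.g. `fit$draws`).
#' @param path file path.
#' @return `read_draws` returns the draws data.frame.
#' @export
write_draws <- function(draws, path) {
  write.csv(draws, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) read.csv(path, stringsAsFactors = FALSE)
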