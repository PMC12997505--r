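#' Run replicate trials over a grid of designs
#'
#' Convenience driver: for each combination of active-arm count and per-arm
#' sample size, samples `n_designs` random designs and analyzes one simulated
#' trial per design.
#'
#' @param arm_counts active-arm counts (subset of 2-5).
#' @param n_per_arm_grid per-arm sample sizes.
#' @param params an [exacerbation_params()] truth.
#' @param n_designs replicate designs per cell.
#' @param ed50_sdlog lognormal sdlog of the design-level true ED50
#'   (0 = fixed).
#' @param seed integer master seed.
#' @return data.frame with one row per simulated trial: `arms`, `n_per_arm`,
#'   `design_id`, `glm_reject`, `emax_reject`, `ed90_hat`, `ed90_lo`,
#'   `ed90_hi`, convergence flags.
#' @export
run_trial_grid <- function(arm_counts, n_per_arm_grid, params,
                           n_designs = 100, ed50_sdlog = 0, seed = 1L) {
  out <- list()
  for (na in arm_counts) for (np in n_per_arm_grid) {
    cell_seed <- as.integer((seed + 1009 * na + 9973 * np) %% 2147483647)
    designs <- sample_designs(na, n_designs, n_per_arm = np,
                              ed50_median = params$ed50,
                              ed50_sdlog = ed50_sdlog, seed = cell_seed)
    for (i in seq_along(designs)) {
      tr <- run_trial(designs[[i]], params,
                      seed = as.integer((cell_seed + i) %% 2147483647))
      out[[length(out) + 1L]] <- data.frame(
        arms = na, n_per_arm = np, design_id = i,
        glm_converged = tr$glm_converged, glm_reject = tr$glm_reject,
        emax_converged = tr$emax_converged, emax_reject = tr$emax_reject,
        ed90_hat = tr$ed90_hat, ed90_lo = tr$ed90_interval[1],
        ed90_hi = tr$ed90_interval[2])
    }
  }
  do.call(rbind, out)
}

#' Summarize power and ED90 precision across simulated trials
#'
#' Per (arms, n_per_arm) cell: GLM power (rejection of the top dose vs.
#' placebo at two-sided alpha), Emax-model power (dose-response LRT), the
#' median/IQR/IDR of the estimated ED90, and the probability that the ED90
#' interval is tighter than the pharmacology benchmark — both widths measured
#' on the log scale, log(upper/lower), with the default benchmark taken from
#' the reference Day-182 ED50 credible interval (log(29.0640/12.9929)).
#'
#' @param results data.frame from [run_trial_grid()].
#' @param benchmark_log_width pharmacology benchmark interval width on the
#'   log scale.
#' @return data.frame with one row per cell; cells with no replicates are
#'   absent (reported as missing, never as zero power).
#' @export
summarize_trials <- function(results,
                             benchmark_log_width = log(29.0640 / 12.9929)) {
  cells <- unique(results[, c("arms", "n_per_arm")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    r <- results[results$arms == cells$arms[i] &
                   results$n_per_arm == cells$n_per_arm[i], ]
    if (nrow(r) == 0) return(NULL)
    ed <- r$ed90_hat[r$emax_converged & is.finite(r$ed90_hat)]
    w <- log(r$ed90_hi / r$ed90_lo)
    w <- w[is.finite(w) & w > 0]
    q <- if (length(ed)) quantile(ed, c(0.1, 0.25, 0.5, 0.75, 0.9),
                                  names = FALSE) else rep(NA_real_, 5)
    data.frame(arms = cells$arms[i], n_per_arm = cells$n_per_arm[i],
               n_trials = nrow(r),
               glm_power = mean(r$glm_reject[r$glm_converged]),
               emax_power = mean(r$emax_reject[r$emax_converged]),
               ed90_median = q[3], ed90_iqr_lo = q[2], ed90_iqr_hi = q[4],
               ed90_idr_lo = q[1], ed90_idr_hi = q[5],
               p_better_than_benchmark = if (length(w))
                 mean(w < benchmark_log_width) else NA_real_)
  })
  do.call(rbind, out)
}
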