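#' Candidate dose list for dose-ranging designs
#'
#' The 15 candidate active doses (mg) from which simulated Phase IIb designs
#' draw: the 12 QDM grid doses plus fillers 15, 120 and 250 mg.
#'
#' @return sorted numeric vector of 15 doses.
#' @export
candidate_doses <- function() {
  sort(c(qdm_default_grid()$doses, 15, 120, 250))
}

#' A dose-ranging trial design
#'
#' Balanced parallel-group design: 2-5 distinct active doses plus placebo,
#' `n_per_arm` patients per arm (10-200), total N within 60-600.
#'
#' @param active_doses distinct active doses in mg.
#' @param n_per_arm patients per arm (balanced, placebo included).
#' @param true_ed50 optional design-specific true ED50 (mg) used when the
#'   dose-response location is treated as uncertain.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(active_doses, n_per_arm, true_ed50 = NA_real_) {
  if (anyDuplicated(active_doses)) stop("doses must be distinct", call. = FALSE)
  if (length(active_doses) < 1) stop("need at least one active dose", call. = FALSE)
  if (n_per_arm < 1 || n_per_arm != round(n_per_arm))
    stop("'n_per_arm' must be a positive integer", call. = FALSE)
  structure(list(active_doses = sort(as.numeric(active_doses)),
                 n_per_arm = as.integer(n_per_arm),
                 n_total = as.integer((length(active_doses) + 1) * n_per_arm),
                 true_ed50 = true_ed50),
            class = "trial_design")
}

#' Randomly sample dose-ranging designs
#'
#' Samples `n_designs` designs with `n_arms` distinct active doses drawn
#' uniformly (without replacement within a design, with replacement across
#' designs) from the candidate list; a placebo arm is added to each. When
#' `ed50_sdlog > 0`, each design also receives its own true ED50 drawn
#' lognormally around `ed50_median`, propagating uncertainty in the unknown
#' dose-response location.
#'
#' @param n_arms number of active arms per design, in 2-5.
#' @param n_designs number of designs.
#' @param n_per_arm patients per arm (10-200).
#' @param doses candidate dose list (default [candidate_doses()]).
#' @param ed50_median,ed50_sdlog lognormal distribution of the design-level
#'   true ED50 (sdlog 0 = fixed at the median).
#' @param seed integer seed.
#' @return list of [trial_design()] objects.
#' @export
sample_designs <- function(n_arms, n_designs, n_per_arm = 50,
                           doses = candidate_doses(),
                           ed50_median = 20, ed50_sdlog = 0, seed = 1L) {
  if (!n_arms %in% 2:5)
    stop("'n_arms' must be between 2 and 5", call. = FALSE)
  if (n_per_arm < 10 || n_per_arm > 200)
    stop("'n_per_arm' must be within 10-200", call. = FALSE)
  rs <- local_rng(seed); on.exit(restore_rng(rs))
  lapply(seq_len(n_designs), function(i) {
    d <- sample(doses, n_arms, replace = FALSE)
    ed50 <- if (ed50_sdlog > 0) rlnorm(1, log(ed50_median), ed50_sdlog)
            else ed50_median
    trial_design(d, n_per_arm, true_ed50 = ed50)
  })
}
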