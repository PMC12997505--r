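#' Configuration of a Phase-I-like single-ascending-dose BEC trial
#'
#' Describes the structure of a first-time-in-human single-ascending-dose
#' trial in mild-to-moderate asthma: dose arms (including placebo), subjects
#' per arm, the BEC sampling schedule, and the lognormal baseline-BEC
#' distribution with the eligibility floor of 0.2 GI/L (200 cells/uL at
#' screening) applied by rejection sampling.
#'
#' The default schedule has dense sampling to Day 29 and ~4-weekly visits
#' thereafter to Day 280; with 48 subjects it yields a panel of ~620 records
#' of which ~290 fall on Day 57 onward (the model-development window) and 48
#' on Day 29 (the validation visit).
#'
#' @param dose_arms doses in mg, 0 = placebo. Default five active arms
#'   2-300 mg plus placebo.
#' @param n_per_arm subjects per arm (positive integer).
#' @param sampling_days strictly increasing study days.
#' @param baseline_gm geometric-mean baseline BEC (GI/L), > 0.
#' @param baseline_gsd geometric SD of baseline BEC, >= 1.
#' @param baseline_floor screening eligibility floor (GI/L).
#' @param seed master integer seed. Per-subject streams are derived
#'   deterministically from it, so adding or removing arms does not reshuffle
#'   the draws of other arms.
#' @return object of class `phase1_config`.
#' @export
phase1_config <- function(dose_arms = c(0, 2, 10, 30, 100, 300),
                          n_per_arm = 8,
                          sampling_days = c(2, 5, 9, 15, 22, 29, 43, 57, 85,
                                            113, 169, 225, 280),
                          baseline_gm = 0.30, baseline_gsd = 1.75,
                          baseline_floor = 0.2, seed = 1L) {
  if (any(dose_arms < 0)) stop("doses must be >= 0", call. = FALSE)
  if (anyDuplicated(dose_arms)) stop("dose arms must be distinct", call. = FALSE)
  if (n_per_arm < 1 || n_per_arm != round(n_per_arm))
    stop("'n_per_arm' must be a positive integer", call. = FALSE)
  if (any(diff(sampling_days) <= 0))
    stop("'sampling_days' must be strictly increasing", call. = FALSE)
  if (baseline_gm <= 0) stop("'baseline_gm' must be > 0", call. = FALSE)
  if (baseline_gsd < 1) stop("'baseline_gsd' must be >= 1", call. = FALSE)
  structure(list(dose_arms = as.numeric(dose_arms), n_per_arm = as.integer(n_per_arm),
                 sampling_days = as.numeric(sampling_days),
                 baseline_gm = baseline_gm, baseline_gsd = baseline_gsd,
                 baseline_floor = baseline_floor, seed = as.integer(seed)),
            class = "phase1_config")
}

# Deterministic per-subject seed stream: depends only on (master, arm index,
# subject index), so changing the arm list length leaves other arms untouched.
subject_seed <- function(master, arm_idx, subj_idx) {
  as.integer((as.numeric(master) + 104729 * arm_idx + 7919 * subj_idx) %%
               2147483646) + 1L
}

#' Generate a synthetic Phase-I-like BEC panel
#'
#' Simulates one longitudinal BEC record per subject per sampling day from
#' the dose-time response model: each subject receives a random-effect triple
#' (b1, b2, b3) from the 3x3 covariance `truth$s2b`, a lognormal baseline
#' truncated below at the screening floor, and log BEC equal to the model
#' prediction plus i.i.d. N(0, s2y) residual (lognormal on the natural
#' scale).
#'
#' @param config a [phase1_config()].
#' @param truth a [dose_time_params()] ground truth (the covariance must be
#'   positive semi-definite).
#' @return data.frame in NONMEM-style long format with columns `ID`, `ARM`
#'   (arm label), `DOSE` (mg), `DAY`, `BASE` (baseline BEC, GI/L) and `DV`
#'   (observed BEC, GI/L).
#' @examples
#' truth <- depemokimab_dose_time_params()
#' panel <- generate_phase1(phase1_config(n_per_arm = 2), truth)
#' head(panel)
#' @export
generate_phase1 <- function(config, truth) {
  stopifnot(inherits(config, "phase1_config"), inherits(truth, "dose_time_params"))
  chol_s2b <- if (all(truth$s2b == 0)) NULL else {
    ev <- eigen(truth$s2b, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  }
  days <- config$sampling_days
  res <- vector("list", length(config$dose_arms) * config$n_per_arm)
  id <- 0L
  for (a in seq_along(config$dose_arms)) {
    dose <- config$dose_arms[a]
    for (j in seq_len(config$n_per_arm)) {
      id <- id + 1L
      rs <- local_rng(subject_seed(config$seed, a, j))
      base <- draw_baseline(config$baseline_gm, config$baseline_gsd,
                            config$baseline_floor)
      b <- if (is.null(chol_s2b)) c(0, 0, 0) else as.numeric(chol_s2b %*% rnorm(3))
      mu <- predict_log_bec(truth, dose, days, log(base), b)
      eps <- if (truth$s2y > 0) rnorm(length(days), 0, sqrt(truth$s2y)) else 0
      restore_rng(rs)
      res[[id]] <- data.frame(
        ID = id, ARM = if (dose == 0) "placebo" else paste0(dose, "mg"),
        DOSE = dose, DAY = days, BASE = base, DV = exp(mu + eps))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# rejection sampling of a truncated lognormal baseline
draw_baseline <- function(gm, gsd, floor) {
  sdlog <- log(gsd)
  if (sdlog == 0) return(max(gm, floor))
  for (i in 1:10000) {
    x <- rlnorm(1, log(gm), sdlog)
    if (x >= floor) return(x)
  }
  stop("baseline rejection sampling failed: floor too far above the distribution")
}

# Temporarily install a seeded RNG state, returning the previous state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Read/write the NONMEM-style long BEC panel
#'
#' Plain CSV with columns `ID, ARM, DOSE, DAY, BASE, DV` (BEC in GI/L).
#'
#' @param panel data.frame as returned by [generate_phase1()].
#' @param path file path.
#' @return `read_bec_panel` returns the panel data.frame.
#' @export
write_bec_panel <- function(panel, path) {
  stopifnot(all(c("ID", "DOSE", "DAY", "BASE", "DV") %in% names(panel)))
  write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bec_panel
#' @export
read_bec_panel <- function(path) {
  panel <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("ID", "DOSE", "DAY", "BASE", "DV")
  if (!all(need %in% names(panel)))
    stop("panel must have columns ", paste(need, collapse = ", "), call. = FALSE)
  panel
}
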