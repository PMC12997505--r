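#' Go/consider/no-go decision thresholds
#'
#' Reference pharmacology thresholds for quantitative decision making. The
#' Minimum Value (MV) and Target Value (TV) are the 78% and 84% BEC
#' reductions vs. placebo established with mepolizumab 100 mg in the MUSCA
#' and MENSA severe-asthma trials, expressed as log BEC ratios
#' (log(1 - 0.78) and log(1 - 0.84)). "Exceeding an X% reduction" means the
#' simulated log ratio falls at or below log(1 - X), so the TV (deeper
#' reduction, more negative log ratio) is the stricter threshold.
#'
#' A regimen is a "go" when P(exceed MV) > `go_prob` AND
#' P(exceed TV) >= `nogo_prob` (the conjunction makes go/no-go a partition),
#' a "no-go" when P(exceed TV) < `nogo_prob`, and a "consider" otherwise.
#'
#' In `threshold_mode = "sampled"` the MV/TV log ratios are drawn per
#' posterior draw from normals centered at the point thresholds with the
#' supplied SEs, reflecting sampling uncertainty in the reference trials.
#'
#' @param mv_reduction,tv_reduction fractional reductions defining MV and TV
#'   (defaults 0.78 and 0.84; TV must be the larger reduction).
#' @param go_prob,nogo_prob decision probabilities (defaults 0.80 and 0.10).
#' @param threshold_mode `"point"` (default) or `"sampled"`.
#' @param mv_se,tv_se SEs of the log-ratio thresholds in sampled mode.
#' @return object of class `decision_thresholds` with elements
#'   `mv_log_ratio`, `tv_log_ratio`, `go_prob`, `nogo_prob`, ...
#' @export
decision_thresholds <- function(mv_reduction = 0.78, tv_reduction = 0.84,
                                go_prob = 0.80, nogo_prob = 0.10,
                                threshold_mode = c("point", "sampled"),
                                mv_se = 0, tv_se = 0) {
  threshold_mode <- match.arg(threshold_mode)
  mv <- log(1 - mv_reduction); tv <- log(1 - tv_reduction)
  if (!(tv < mv && mv < 0))
    stop("need tv_log_ratio < mv_log_ratio < 0 (TV is the deeper reduction)",
         call. = FALSE)
  if (!(nogo_prob > 0 && nogo_prob < go_prob && go_prob < 1))
    stop("need 0 < nogo_prob < go_prob < 1", call. = FALSE)
  structure(list(mv_log_ratio = mv, tv_log_ratio = tv, go_prob = go_prob,
                 nogo_prob = nogo_prob, threshold_mode = threshold_mode,
                 mv_se = mv_se, tv_se = tv_se),
            class = "decision_thresholds")
}

#' Build a synthetic posterior from printed summaries
#'
#' When only marginal posterior means and SDs are available (as in a
#' published table), an independent-normal draw matrix is the transparent
#' surrogate posterior. Posterior correlations are lost, which widens
#' derived contrasts; conclusions drawn from it are qualitative.
#'
#' @param summary data.frame with columns `parameter`, `mean`, `sd`
#'   (default [depemokimab_posterior_summary()]).
#' @param n number of draws (default 10000).
#' @param seed integer seed.
#' @return data.frame of draws, one column per parameter.
#' @export
synthetic_posterior_normal <- function(summary = depemokimab_posterior_summary(),
                                       n = 10000, seed = 1L) {
  rs <- local_rng(seed); on.exit(restore_rng(rs))
  out <- as.data.frame(lapply(seq_len(nrow(summary)), function(i)
    rnorm(n, summary$mean[i], summary$sd[i])))
  names(out) <- summary$parameter
  out
}

#' Simulate the log BEC change from placebo at a dose and day
#'
#' For each posterior draw, evaluates the population-level (random effects at
#' zero) log BEC ratio of treatment to the no-treatment state.
#'
#' Two contrast definitions are available:
#' * `"dose_effect"` (default): the treatment-branch prediction at dose d
#'   minus its dose-to-zero limit, i.e. the logistic effect term
#'   \eqn{(E_{max} - E_0) / (1 + \exp\{SLP(LNED_{50} + KE(t-182) - \ln d_{eff})\})}.
#'   Intercept and baseline terms cancel; this treats the placebo arm as an
#'   unbiased image of the no-drug state and is the definition under which
#'   the reference analysis' decision boundary (go at >= 60 mg at Day 182)
#'   is reproduced.
#' * `"arm_contrast"`: treatment minus placebo submodel prediction at a
#'   common reference baseline, \eqn{E_0 - E_1 + (E_2 - E_3)\ln(base)} plus
#'   the effect term. This propagates the (finite-sample) difference between
#'   the two arm intercepts into every contrast.
#'
#' @param draws data.frame of posterior draws (columns `e0`, `e1`, `e2`,
#'   `e3`, `emax`, `lned50`, `ke`, `slp`, `f`; the arm-contrast mode needs
#'   the intercept/baseline columns, the dose-effect mode only the effect
#'   ones).
#' @param dose dose in mg, > 0.
#' @param day study day.
#' @param mode contrast definition, see Details.
#' @param ref_baseline reference baseline BEC in GI/L (arm-contrast mode).
#' @return numeric vector of log ratios, one per draw.
#' @export
simulate_change_from_placebo <- function(draws, dose, day,
                                         mode = c("dose_effect", "arm_contrast"),
                                         ref_baseline = 0.26) {
  mode <- match.arg(mode)
  draws <- as.data.frame(draws)
  if (nrow(draws) == 0) stop("empty posterior", call. = FALSE)
  if (dose <= 0) stop("'dose' must be > 0", call. = FALSE)
  f <- if ("f" %in% names(draws)) draws$f else 1
  ln_dose_eff <- log(dose) + if (dose == 2) log(pmax(f, 1e-12)) else 0
  eff <- (draws$emax - draws$e0) /
    (1 + exp(draws$slp * (draws$lned50 + draws$ke * (day - 182) - ln_dose_eff)))
  if (mode == "dose_effect") return(eff)
  eff + draws$e0 - draws$e1 + (draws$e2 - draws$e3) * log(ref_baseline)
}

#' Classify exceedance probabilities into go / consider / no-go
#'
#' Applies the prespecified decision rules: "no_go" iff P(exceed TV) <
#' `nogo_prob`; "go" iff P(exceed TV) >= `nogo_prob` and P(exceed MV) >
#' `go_prob`; otherwise "consider". The three rules partition every
#' (p_mv, p_tv) pair with p_tv <= p_mv.
#'
#' @param p_mv,p_tv probabilities of exceeding MV and TV (vectorized).
#' @param thresholds a [decision_thresholds()] object.
#' @return character vector in {"go", "consider", "no_go"}.
#' @examples
#' th <- decision_thresholds()
#' classify_decision(0.90, 0.20, th) # "go"
#' classify_decision(0.70, 0.05, th) # "no_go"
#' classify_decision(0.70, 0.15, th) # "consider"
#' @export
classify_decision <- function(p_mv, p_tv, thresholds) {
  stopifnot(inherits(thresholds, "decision_thresholds"))
  if (any(p_mv < 0 | p_mv > 1 | p_tv < 0 | p_tv > 1, na.rm = TRUE))
    stop("probabilities must be in [0, 1]", call. = FALSE)
  if (any(p_tv > p_mv + 1e-12, na.rm = TRUE))
    stop("p_tv > p_mv violates threshold ordering (TV is stricter than MV)",
         call. = FALSE)
  ifelse(p_tv < thresholds$nogo_prob, "no_go",
         ifelse(p_mv > thresholds$go_prob, "go", "consider"))
}

#' Default QDM dose and day grids
#'
#' 12 single doses spanning 2-300 mg and 12 sampling times at approximately
#' 4-week intervals from Day 28 to Day 280.
#'
#' @return list with `doses` (mg) and `days`.
#' @export
qdm_default_grid <- function() {
  list(doses = c(2, 5, 10, 20, 30, 40, 60, 80, 100, 150, 200, 300),
       days = round(seq(28, 280, length.out = 12)))
}

#' Build the QDM decision grid
#'
#' For every (dose, day) cell, computes the probability across posterior
#' draws that the log BEC ratio vs. placebo exceeds the MV and TV reductions
#' (i.e. falls at or below the corresponding log ratios) and classifies the
#' cell go / consider / no-go.
#'
#' @param draws posterior draws (see [simulate_change_from_placebo()]).
#' @param thresholds a [decision_thresholds()].
#' @param doses,days grid vectors (defaults [qdm_default_grid()]).
#' @param mode,ref_baseline passed to [simulate_change_from_placebo()].
#' @param seed seed used in sampled-threshold mode.
#' @return object of class `qdm_grid`: a data.frame with columns `dose`,
#'   `day`, `p_mv`, `p_tv`, `decision`.
#' @export
build_qdm_grid <- function(draws, thresholds = decision_thresholds(),
                           doses = qdm_default_grid()$doses,
                           days = qdm_default_grid()$days,
                           mode = c("dose_effect", "arm_contrast"),
                           ref_baseline = 0.26, seed = 1L) {
  mode <- match.arg(mode)
  if (length(doses) == 0 || length(days) == 0)
    stop("dose and day grids must be non-empty", call. = FALSE)
  draws <- as.data.frame(draws)
  n <- nrow(draws)
  if (thresholds$threshold_mode == "sampled") {
    rs <- local_rng(seed); on.exit(restore_rng(rs))
    mv_thr <- rnorm(n, thresholds$mv_log_ratio, thresholds$mv_se)
    tv_thr <- rnorm(n, thresholds$tv_log_ratio, thresholds$tv_se)
    tv_thr <- pmin(tv_thr, mv_thr) # preserve TV stricter than MV drawwise
  } else {
    mv_thr <- rep(thresholds$mv_log_ratio, n)
    tv_thr <- rep(thresholds$tv_log_ratio, n)
  }
  grid <- expand.grid(dose = doses, day = days, KEEP.OUT.ATTRS = FALSE)
  pm <- pt <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r <- simulate_change_from_placebo(draws, grid$dose[i], grid$day[i],
                                      mode = mode, ref_baseline = ref_baseline)
    pm[i] <- mean(r <= mv_thr)
    pt[i] <- mean(r <= tv_thr)
  }
  grid$p_mv <- pm
  grid$p_tv <- pt
  grid$decision <- classify_decision(grid$p_mv, grid$p_tv, thresholds)
  class(grid) <- c("qdm_grid", "data.frame")
  attr(grid, "thresholds") <- thresholds
  grid
}

#' Heatmap of a QDM decision grid
#'
#' Tri-color dose-by-day tile plot (green go, yellow consider, red no-go)
#' annotated with P(exceed MV). Requires ggplot2.
#'
#' @param grid a `qdm_grid`.
#' @return a ggplot object.
#' @export
plot_qdm_grid <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  gd <- as.data.frame(grid)
  gd$decision <- factor(gd$decision, levels = c("go", "consider", "no_go"))
  ggplot2::ggplot(gd, ggplot2::aes(factor(.data$day), factor(.data$dose),
                                   fill = .data$decision)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$p_mv)),
                       size = 2.6) +
    ggplot2::scale_fill_manual(values = c(go = "#4daf4a", consider = "#ffd92f",
                                          no_go = "#e41a1c"), drop = FALSE) +
    ggplot2::labs(x = "Day post dose", y = "Dose (mg)",
                  fill = "Decision",
                  title = "Probability of exceeding reference BEC pharmacology")
}
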