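#' Disease-specific baseline BEC distributions
#'
#' Lognormal baseline blood eosinophil distributions for the four
#' eosinophil-driven diseases handled by the PK/PD module. The geometric
#' means/GSDs are synthetic defaults chosen to emulate the Phase III
#' reference populations (the trials report baselines but the generating
#' distributions are not public): severe asthma and CRSwNP around
#' 0.3-0.45 GI/L, EGPA suppressed by maintenance corticosteroids, HES
#' strongly elevated. All values are configurable.
#'
#' @return data.frame of per-disease defaults (`gm` geometric mean in GI/L,
#'   `gsd` geometric SD).
#' @export
disease_baseline_defaults <- function() {
  data.frame(
    disease = c("severe_asthma", "CRSwNP", "EGPA", "HES"),
    gm = c(0.29, 0.44, 0.17, 1.40),
    gsd = c(2.0, 2.0, 2.2, 2.2))
}

#' Sample baseline BEC for a disease population
#'
#' Draws lognormal baselines for the requested disease. The EGPA
#' "true baseline" scenario (`fixed = TRUE`) returns the fixed value of
#' 1.0 GI/L (1000 cells/uL), the diagnostic threshold for untreated EGPA
#' regarded as the true baseline once oral corticosteroids are tapered.
#'
#' @param disease one of `"severe_asthma"`, `"CRSwNP"`, `"EGPA"`, `"HES"`.
#' @param n number of draws.
#' @param gm,gsd geometric mean (GI/L) and geometric SD; defaults looked up
#'   from [disease_baseline_defaults()].
#' @param fixed logical; if `TRUE` return `fixed_value` for every subject
#'   (EGPA true-baseline scenario).
#' @param fixed_value the fixed baseline in GI/L (default 1.0).
#' @param seed optional integer seed.
#' @return numeric vector of baselines in GI/L.
#' @examples
#' sample_baseline_bec("EGPA", 5, fixed = TRUE) # rep(1.0, 5)
#' @export
sample_baseline_bec <- function(disease, n, gm = NULL, gsd = NULL,
                                fixed = FALSE, fixed_value = 1.0, seed = NULL) {
  defs <- disease_baseline_defaults()
  if (!disease %in% defs$disease)
    stop("unknown disease '", disease, "'; expected one of ",
         paste(defs$disease, collapse = ", "), call. = FALSE)
  if (fixed) return(rep(fixed_value, n))
  row <- defs[defs$disease == disease, ]
  if (is.null(gm)) gm <- row$gm
  if (is.null(gsd)) gsd <- row$gsd
  if (gm <= 0 || gsd < 1) stop("need gm > 0 and gsd >= 1", call. = FALSE)
  if (!is.null(seed)) { rs <- local_rng(seed); on.exit(restore_rng(rs)) }
  if (gsd == 1) rep(gm, n) else rlnorm(n, log(gm), log(gsd))
}
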