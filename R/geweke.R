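#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `first_frac` of a chain with the mean of
#' the last `last_frac`, standardized by spectral-density estimates of the
#' asymptotic variance of each segment mean:
#' \deqn{z = \frac{\bar x_A - \bar x_B}{\sqrt{\hat s_A/n_A + \hat s_B/n_B}}}
#' where \eqn{\hat s} is the spectral density at frequency zero of the
#' segment (estimated from a fitted autoregressive model, which accounts for
#' autocorrelation). For a stationary chain z is asymptotically standard
#' normal; |z| > 3 flags non-convergence.
#'
#' @param chain numeric vector, length >= 100.
#' @param first_frac,last_frac fractions of the chain used for the early and
#'   late windows (defaults 0.1 and 0.5; must not overlap).
#' @return the z-score; 0 with a warning for a degenerate (constant) chain.
#' @examples
#' set.seed(1)
#' abs(geweke_z(rnorm(2000))) < 3  # stationary chain passes
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100) stop("chain too short for the Geweke diagnostic (need >= 100)",
                    call. = FALSE)
  if (first_frac <= 0 || last_frac <= 0 || first_frac + last_frac > 1)
    stop("need first_frac > 0, last_frac > 0 and first_frac + last_frac <= 1",
         call. = FALSE)
  if (var(chain) == 0) {
    warning("degenerate (constant) chain; Geweke z set to 0")
    return(0)
  }
  a <- chain[seq_len(floor(first_frac * n))]
  b <- chain[seq.int(n - floor(last_frac * n) + 1L, n)]
  se2 <- function(x) spectrum0(x) / length(x)
  (mean(a) - mean(b)) / sqrt(se2(a) + se2(b))
}

# Spectral density at frequency zero via an AR fit (order by AIC), the same
# estimator family used by standard MCMC diagnostics.
spectrum0 <- function(x) {
  x <- as.numeric(x)
  if (var(x) == 0) return(0)
  fit <- tryCatch(ar(x, aic = TRUE, order.max = min(30, length(x) %/% 4)),
                  error = function(e) NULL)
  if (is.null(fit)) return(var(x))
  if (fit$order == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}
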