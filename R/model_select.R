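#' Residual sum of squares
#'
#' Unweighted sum of squared differences between fitted and measured
#' normalized intensities, summed over all RF power and offset
#' combinations.
#'
#' @param fit_intensities,exp_intensities Equal-length numeric vectors.
#' @return RSS (dimensionless).
#' @export
rss <- function(fit_intensities, exp_intensities) {
  if (length(fit_intensities) != length(exp_intensities))
    stop("rss: length mismatch")
  sum((fit_intensities - exp_intensities)^2)
}

#' Akaike information criterion from an RSS fit
#'
#' `AIC = N log(RSS/N) + 2K` when `N/K >= 40`; otherwise the small-sample
#' corrected form adds `2K(K+1)/(N-K-1)`.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of data points.
#' @param k Number of floating parameters.
#' @return AIC (dimensionless).
#' @export
aic <- function(rss, n, k) {
  if (rss <= 0) stop("aic: rss must be > 0")
  base <- n * log(rss / n) + 2 * k
  if (n / k >= 40) return(base)
  if (n <= k + 1) stop("aic: small-sample correction needs n > k + 1")
  base + 2 * k * (k + 1) / (n - k - 1)
}

#' Bayesian information criterion from an RSS fit
#'
#' `BIC = N log(RSS/N) + K log(N)`.
#'
#' @inheritParams aic
#' @return BIC (dimensionless).
#' @export
bic <- function(rss, n, k) {
  if (rss <= 0) stop("bic: rss must be > 0")
  n * log(rss / n) + k * log(n)
}

#' Akaike/Schwarz weight of the exchange model
#'
#' `w = exp(-delta/2) / (1 + exp(-delta/2))` with
#' `delta = IC(with exchange) - IC(without exchange)`, so the weight tends
#' to 1 when the exchange model is decisively better. Satisfies
#' `w(delta) + w(-delta) = 1` and saturates without overflow.
#'
#' @param delta Information-criterion difference (exchange minus
#'   no-exchange).
#' @return Weight in (0, 1).
#' @export
model_weight <- function(delta) {
  stats::plogis(-0.5 * delta)
}

#' Dual-threshold model selection between exchange and no-exchange fits
#'
#' The improvement from adding exchange is called statistically
#' significant when both the AIC and the BIC weight of the exchange model
#' exceed `threshold` and the reduced chi-square decreases with the
#' inclusion of exchange.
#'
#' @param fit_ex,fit_noex `fit_result` objects from [fit_two_state()]
#'   with and without exchange, fit to identical data.
#' @param threshold Weight threshold (default 0.995).
#' @return A `selection_report` with the two RSS, AIC, BIC, reduced
#'   chi-square values, the exchange-model weights and the `decision`
#'   string (`"exchange-significant"` or `"not-significant"`).
#' @export
select_models <- function(fit_ex, fit_noex, threshold = 0.995) {
  stopifnot(inherits(fit_ex, "fit_result"), inherits(fit_noex, "fit_result"),
            fit_ex$n == fit_noex$n)
  w_aic <- model_weight(fit_ex$aic - fit_noex$aic)
  w_bic <- model_weight(fit_ex$bic - fit_noex$bic)
  significant <- w_aic > threshold && w_bic > threshold &&
    fit_ex$r_chi2 < fit_noex$r_chi2
  structure(list(rss_ex = fit_ex$rss, rss_noex = fit_noex$rss,
                 aic_ex = fit_ex$aic, aic_noex = fit_noex$aic,
                 bic_ex = fit_ex$bic, bic_noex = fit_noex$bic,
                 w_aic_ex = w_aic, w_bic_ex = w_bic,
                 r_chi2_ex = fit_ex$r_chi2, r_chi2_noex = fit_noex$r_chi2,
                 threshold = threshold,
                 decision = if (significant) "exchange-significant"
                            else "not-significant"),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Model selection (exchange vs no exchange)\n")
  cat(sprintf("  wAIC+ex = %.5f  wBIC+ex = %.5f  (threshold %.3f)\n",
              x$w_aic_ex, x$w_bic_ex, x$threshold))
  cat(sprintf("  rchi2: %.4g (ex) vs %.4g (no ex)\n",
              x$r_chi2_ex, x$r_chi2_noex))
  cat("  decision:", x$decision, "\n")
  invisible(x)
}
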