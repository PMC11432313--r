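#' Funnel-plot data
#'
#' Per-effect rows (rr, standard error `sqrt(v)`, precision `1/se`) for
#' plotting effect size against precision; asymmetry of the resulting
#' funnel suggests publication bias.
#'
#' @param effects Data frame with columns `rr` and `v`.
#' @return Data frame with columns `rr`, `se`, `precision` aligned with
#'   the input rows.
#' @export
funnel_data <- function(effects) {
  stopifnot(is.data.frame(effects), all(c("rr", "v") %in% names(effects)))
  se <- sqrt(effects$v)
  data.frame(rr = effects$rr, se = se, precision = 1 / se)
}

#' Egger's regression test for funnel asymmetry
#'
#' Regresses the standardised effects `rr_i / se_i` on precision
#' `1 / se_i`; the intercept estimates funnel asymmetry and its z
#' statistic (intercept over its standard error, two-sided normal p)
#' is the test of publication bias.
#'
#' @param effects Data frame with columns `rr` and `v` (`k >= 3`,
#'   non-constant standard errors).
#' @return List with `intercept`, `se`, `z`, `p_value`, `slope`
#'   (the precision coefficient, an estimate of the common effect), `k`.
#' @export
egger_test <- function(effects) {
  .check_effects(effects, 3L)
  se <- sqrt(effects$v)
  if (diff(range(se)) < 1e-12)
    stop("Egger regression is degenerate when all standard errors are equal",
         call. = FALSE)
  zstd <- effects$rr / se
  prec <- 1 / se
  fit <- stats::lm(zstd ~ prec)
  est <- summary(fit)$coefficients
  z <- est["(Intercept)", "Estimate"] / est["(Intercept)", "Std. Error"]
  list(intercept = est["(Intercept)", "Estimate"],
       se = est["(Intercept)", "Std. Error"],
       z = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       slope = est["prec", "Estimate"],
       k = nrow(effects))
}

#' Rosenthal's fail-safe N
#'
#' The number of unpublished null studies that would have to exist to
#' bring the combined (Stouffer) evidence below one-tailed significance.
#' With `z_i = rr_i / sqrt(v_i)` and `S = |sum(z_i)|`, it is the
#' smallest integer `N >= 0` such that `S / sqrt(k + N) < z_alpha`.
#'
#' @param effects Data frame with columns `rr` and `v`.
#' @param alpha One-tailed significance level. Default 0.05.
#' @param z_alpha Critical value; defaults to `qnorm(1 - alpha)`
#'   (1.6449 at alpha = 0.05). Pass 1.645 to match the rounded
#'   textbook constant.
#' @return Non-negative integer.
#' @export
fail_safe_n <- function(effects, alpha = 0.05, z_alpha = NULL) {
  .check_effects(effects, 1L)
  if (is.null(z_alpha)) z_alpha <- stats::qnorm(1 - alpha)
  S <- abs(sum(effects$rr / sqrt(effects$v)))
  k <- nrow(effects)
  n <- max(0, ceiling(S^2 / z_alpha^2 - k))
  # enforce the strict inequality at the boundary
  while (S / sqrt(k + n) >= z_alpha) n <- n + 1
  as.integer(n)
}

#' Publication-bias report
#'
#' Bundles [funnel_data()], [egger_test()] and [fail_safe_n()].
#'
#' @inheritParams egger_test
#' @param alpha One-tailed level for the fail-safe N. Default 0.05.
#' @return A `bias_report` list with `egger`, `fail_safe_n`, `funnel`.
#' @export
bias_report <- function(effects, alpha = 0.05) {
  structure(
    list(egger = egger_test(effects),
         fail_safe_n = fail_safe_n(effects, alpha = alpha),
         funnel = funnel_data(effects)),
    class = "bias_report"
  )
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("Publication-bias diagnostics (k = %d)\n", x$egger$k))
  cat(sprintf("  Egger intercept %.4f (z = %.4f, p = %.4g)\n",
              x$egger$intercept, x$egger$z, x$egger$p_value))
  cat(sprintf("  Rosenthal fail-safe N = %d\n", x$fail_safe_n))
  invisible(x)
}
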