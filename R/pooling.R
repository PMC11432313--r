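#' @title Inverse-variance pooling and heterogeneity
#'
#' @description
#' Fixed-effects and REML random-effects pooling of log response ratios,
#' with Cochran's Q, I-squared and tau-squared heterogeneity statistics.
#' The pooled estimate is `RR+ = sum(w_i * rr_i) / sum(w_i)` with
#' `w_i = 1/v_i` (fixed effects) or `w_i = 1/(v_i + tau2)` (random
#' effects), standard error `1/sqrt(sum(w_i))` and a 95% CI using the
#' 1.96 normal quantile.
#' @name pooling
NULL

.new_pooled_result <- function(rr_plus, se, k, q, df, p_value, tau2, i2,
                               model, conf_mult = 1.96) {
  structure(
    list(rr_plus = rr_plus, se = se,
         ci_low = rr_plus - conf_mult * se,
         ci_high = rr_plus + conf_mult * se,
         k = k, q = q, df = df, p_value = p_value,
         tau2 = tau2, i2 = i2, model = model),
    class = "pooled_result"
  )
}

#' @export
print.pooled_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s-effects pooled log response ratio (k = %d)\n",
              x$model, x$k))
  cat(sprintf("  RR+ = %.*f  (SE %.*f, 95%% CI %.*f to %.*f)\n",
              digits, x$rr_plus, digits, x$se,
              digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  Q = %.*f (df = %d, p = %.4g), tau^2 = %.*f, I^2 = %.2f%%\n",
              digits, x$q, x$df, x$p_value, digits, x$tau2, x$i2))
  invisible(x)
}

.check_effects <- function(effects, k_min = 1L) {
  stopifnot(is.data.frame(effects),
            all(c("rr", "v") %in% names(effects)))
  if (nrow(effects) < k_min)
    stop("need at least ", k_min, " effect(s), got ", nrow(effects),
         call. = FALSE)
  if (any(!is.finite(effects$rr)) || any(!is.finite(effects$v)) ||
      any(effects$v <= 0))
    stop("effects must have finite rr and strictly positive v", call. = FALSE)
  invisible(effects)
}

#' Cochran's Q heterogeneity statistic
#'
#' The inverse-variance-weighted sum of squared deviations of the effects
#' from a pooled value, referred to a chi-square distribution with `k - 1`
#' degrees of freedom under homogeneity.
#'
#' @param effects Data frame with columns `rr` and `v`.
#' @param center Value the deviations are taken from; defaults to the
#'   fixed-effects pooled estimate.
#' @return List with `q`, `df` (`k - 1`) and `p_value` (upper chi-square
#'   tail; `NA` when `k < 2`).
#' @export
cochran_q <- function(effects, center = NULL) {
  .check_effects(effects, 1L)
  w <- 1 / effects$v
  if (is.null(center)) center <- sum(w * effects$rr) / sum(w)
  k <- nrow(effects)
  q <- sum(w * (effects$rr - center)^2)
  df <- k - 1L
  p <- if (k >= 2L) stats::pchisq(q, df = df, lower.tail = FALSE) else NA_real_
  list(q = q, df = df, p_value = p)
}

#' I-squared heterogeneity percentage
#'
#' `I^2 = max(0, (Q - df) / Q) * 100`: the share of total variability in
#' the effects attributable to between-effect heterogeneity rather than
#' sampling error, truncated at 0 and reported as a percentage.
#'
#' @param q Cochran Q statistic (>= 0).
#' @param df Degrees of freedom (>= 1).
#' @return Percentage in `[0, 100]`; 0 when `q = 0`.
#' @export
i_squared <- function(q, df) {
  stopifnot(q >= 0, df >= 1)
  if (q == 0) return(0)
  max(0, (q - df) / q) * 100
}

#' Fixed-effects pooled estimate
#'
#' Pools effects with weights `1/v_i`, assuming one common true effect.
#'
#' @param effects Data frame with columns `rr` and `v`.
#' @param conf_mult Normal quantile for the CI half-width. Default 1.96.
#' @return A `pooled_result` (tau2 = 0, model = "fixed").
#' @export
#' @examples
#' eff <- data.frame(rr = c(0, 1), v = c(1, 1))
#' fixed_effects_pool(eff) # RR+ = 0.5, SE = 0.7071
fixed_effects_pool <- function(effects, conf_mult = 1.96) {
  .check_effects(effects, 1L)
  w <- 1 / effects$v
  rr_plus <- sum(w * effects$rr) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- cochran_q(effects, center = rr_plus)
  k <- nrow(effects)
  i2 <- if (k >= 2L) i_squared(het$q, het$df) else 0
  .new_pooled_result(rr_plus, se, k, het$q, het$df, het$p_value,
                     tau2 = 0, i2 = i2, model = "fixed",
                     conf_mult = conf_mult)
}

#' DerSimonian-Laird tau-squared (method of moments)
#'
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effects weights. Used as a fast moment estimate and as a
#' cross-check for the REML estimate.
#'
#' @param effects Data frame with columns `rr` and `v` (`k >= 2`).
#' @return Non-negative between-effect variance estimate.
#' @export
dl_tau2 <- function(effects) {
  .check_effects(effects, 2L)
  w <- 1 / effects$v
  q <- cochran_q(effects)$q
  k <- nrow(effects)
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(0)
  max(0, (q - (k - 1)) / denom)
}

# Restricted log-likelihood of tau2 for rr ~ N(X beta, diag(v + tau2)),
# up to an additive constant.
.reml_loglik <- function(tau2, rr, v, X) {
  w <- 1 / (v + tau2)
  XtW <- t(X * w)
  A <- XtW %*% X
  beta <- solve(A, XtW %*% rr)
  r <- rr - X %*% beta
  -0.5 * (sum(log(v + tau2)) + determinant(A, logarithm = TRUE)$modulus[1] +
            sum(w * r^2))
}

#' REML estimate of the between-effect variance
#'
#' Maximises the restricted log-likelihood of the model
#' `rr_i ~ Normal(x_i' beta, v_i + tau2)` over `tau2 >= 0` by bounded
#' one-dimensional search on `[0, 10 * var(rr)]` (deterministic; the
#' DerSimonian-Laird estimate is also evaluated as a candidate so the
#' optimum is never worse than the moment start).
#'
#' @param effects Data frame with columns `rr` and `v`.
#' @param design Optional model matrix (defaults to an intercept column).
#' @param tol Convergence tolerance of the search. Default `1e-10`.
#' @return Non-negative REML tau-squared.
#' @export
reml_tau2 <- function(effects, design = NULL, tol = 1e-10) {
  .check_effects(effects, 2L)
  rr <- effects$rr
  v <- effects$v
  X <- if (is.null(design)) matrix(1, nrow(effects), 1L) else as.matrix(design)
  if (nrow(X) != length(rr))
    stop("design rows must align with effects", call. = FALSE)
  if (nrow(X) <= ncol(X))
    stop("need more effects than design columns for REML", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  upper <- max(10 * stats::var(rr), 10 * max(v), 1e-6)
  opt <- stats::optimize(.reml_loglik, interval = c(0, upper), rr = rr,
                         v = v, X = X, maximum = TRUE, tol = tol)
  # candidate set guards against a maximum on the boundary or at the
  # moment estimate that the golden-section bracket missed
  cand <- c(opt$maximum, 0)
  if (is.null(design)) cand <- c(cand, dl_tau2(effects))
  ll <- vapply(cand, function(t2) .reml_loglik(t2, rr, v, X), numeric(1))
  tau2 <- cand[which.max(ll)]
  max(0, tau2)
}

#' Random-effects pooled estimate (REML)
#'
#' Estimates the between-effect variance by [reml_tau2()], then pools with
#' weights `1/(v_i + tau2)`. Q, its p-value and I-squared are reported
#' from the fixed-effects weighting (the scale on which the homogeneity
#' test is defined).
#'
#' @inheritParams fixed_effects_pool
#' @return A `pooled_result` (model = "random").
#' @export
random_effects_pool <- function(effects, conf_mult = 1.96) {
  .check_effects(effects, 2L)
  tau2 <- reml_tau2(effects)
  w <- 1 / (effects$v + tau2)
  rr_plus <- sum(w * effects$rr) / sum(w)
  se <- 1 / sqrt(sum(w))
  het <- cochran_q(effects)
  i2 <- i_squared(het$q, het$df)
  .new_pooled_result(rr_plus, se, nrow(effects), het$q, het$df, het$p_value,
                     tau2 = tau2, i2 = i2, model = "random",
                     conf_mult = conf_mult)
}

#' Forest-table export
#'
#' One row per effect (rr, CI from its own sampling variance, and its
#' percentage weight under each model) followed by the pooled fixed- and
#' random-effects rows — the data behind a forest plot.
#'
#' @param effects An `effect_sizes` data frame.
#' @return Data frame with columns `label`, `rr`, `ci_low`, `ci_high`,
#'   `weight_fixed_pct`, `weight_random_pct`.
#' @export
forest_table <- function(effects) {
  .check_effects(effects, 2L)
  fe <- fixed_effects_pool(effects)
  re <- random_effects_pool(effects)
  w_f <- (1 / effects$v) / sum(1 / effects$v) * 100
  w_r <- (1 / (effects$v + re$tau2)) / sum(1 / (effects$v + re$tau2)) * 100
  lab <- if (all(c("study_id", "variable") %in% names(effects))) {
    paste(effects$study_id, effects$variable,
          paste0(effects$temperature_c, "C"), sep = " / ")
  } else sprintf("effect %d", seq_len(nrow(effects)))
  se_i <- sqrt(effects$v)
  rbind(
    data.frame(label = lab, rr = effects$rr,
               ci_low = effects$rr - 1.96 * se_i,
               ci_high = effects$rr + 1.96 * se_i,
               weight_fixed_pct = w_f, weight_random_pct = w_r,
               stringsAsFactors = FALSE),
    data.frame(label = c("Pooled (fixed)", "Pooled (random)"),
               rr = c(fe$rr_plus, re$rr_plus),
               ci_low = c(fe$ci_low, re$ci_low),
               ci_high = c(fe$ci_high, re$ci_high),
               weight_fixed_pct = c(100, NA),
               weight_random_pct = c(NA, 100),
               stringsAsFactors = FALSE)
  )
}
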