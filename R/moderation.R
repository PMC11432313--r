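#' @title Moderator meta-regression and subgroup analysis
#'
#' @description
#' Per-trait subgroup pooling, the heterogeneity partition
#' `Qt = Qm + Qe` (exact under fixed-effects weighting), coefficient
#' tests under random-effects weighting, and the temperature-response
#' profile with its fitted optimum.
#' @name moderation
NULL

#' Build a moderator design matrix
#'
#' Constructs the model matrix (intercept plus the requested moderator
#' columns) for a set of effects, dropping effects with a missing value
#' in any requested moderator.
#'
#' @param effects An `effect_sizes` data frame.
#' @param moderators Character subset of
#'   `c("temperature_c", "rel_humidity_pct", "photoperiod_light_h")`.
#' @return List with `effects` (complete-moderator subset), `X` (model
#'   matrix with an `intercept` column) and `dropped` (number of effects
#'   removed for missing moderators).
#' @export
moderator_design <- function(effects,
                             moderators = "temperature_c") {
  allowed <- c("temperature_c", "rel_humidity_pct", "photoperiod_light_h")
  stopifnot(is.data.frame(effects), length(moderators) >= 1)
  bad <- setdiff(moderators, allowed)
  if (length(bad))
    stop("unknown moderator(s): ", paste(bad, collapse = ", "), call. = FALSE)
  M <- as.matrix(effects[, moderators, drop = FALSE])
  keep <- stats::complete.cases(M)
  eff <- effects[keep, , drop = FALSE]
  M <- M[keep, , drop = FALSE]
  X <- cbind(intercept = 1, M)
  for (j in seq_len(ncol(M))) {
    if (length(unique(M[, j])) < 2L)
      stop("moderator '", moderators[j], "' is constant (collinear with ",
           "the intercept)", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient across columns: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  list(effects = eff, X = X, dropped = sum(!keep))
}

#' Moderator meta-regression with heterogeneity partition
#'
#' Fits the mixed-effects meta-regression `rr_i ~ x_i' beta` twice:
#'
#' * with fixed-effects weights `1/v_i`, to form the exact partition of
#'   total heterogeneity `Qt` into the part explained by the moderators
#'   (`Qm`, the omnibus model statistic, chi-square with `p - 1` df) and
#'   the residual part (`Qe`, chi-square with `k - p` df), satisfying
#'   `Qt = Qm + Qe` identically;
#' * with random-effects weights `1/(v_i + tau2)` (tau2 from REML on the
#'   same design unless supplied), for the reported coefficients and
#'   their standard errors.
#'
#' @param design A list from [moderator_design()], or an `effect_sizes`
#'   data frame (in which case `moderators` is used to build the design).
#' @param tau2 Optional between-effect variance; estimated by
#'   [reml_tau2()] on the design when `NULL`.
#' @param moderators Passed to [moderator_design()] when `design` is a
#'   data frame.
#' @return A `moderator_test` list: `q_t`, `q_m`, `q_e`, `df_m`, `df_e`,
#'   `p_value` (of `q_m`), `p_value_qe`, `coefficients` (term, estimate,
#'   se, z, p under random-effects weighting), `tau2`, `k`.
#' @export
meta_regression <- function(design, tau2 = NULL,
                            moderators = "temperature_c") {
  if (is.data.frame(design))
    design <- moderator_design(design, moderators)
  eff <- design$effects
  X <- design$X
  k <- nrow(eff)
  p <- ncol(X)
  if (k <= p)
    stop("need more effects (", k, ") than coefficients (", p, ")",
         call. = FALSE)
  .check_effects(eff, 2L)
  rr <- eff$rr
  v <- eff$v

  # fixed-weight fit -> exact Qt = Qm + Qe partition
  w <- 1 / v
  XtW <- t(X * w)
  beta_f <- solve(XtW %*% X, XtW %*% rr)
  fitted_f <- drop(X %*% beta_f)
  ybar <- sum(w * rr) / sum(w)
  q_t <- sum(w * (rr - ybar)^2)
  q_e <- sum(w * (rr - fitted_f)^2)
  q_m <- sum(w * (fitted_f - ybar)^2)
  df_m <- p - 1L
  df_e <- k - p
  p_qm <- stats::pchisq(q_m, df_m, lower.tail = FALSE)
  p_qe <- stats::pchisq(q_e, df_e, lower.tail = FALSE)

  # random-effects coefficient table
  if (is.null(tau2)) tau2 <- reml_tau2(eff, design = X)
  ws <- 1 / (v + tau2)
  XtWs <- t(X * ws)
  A <- XtWs %*% X
  beta_r <- solve(A, XtWs %*% rr)
  vcov_r <- solve(A)
  se_r <- sqrt(diag(vcov_r))
  z <- drop(beta_r) / se_r
  coef_tab <- data.frame(
    term = colnames(X),
    estimate = drop(beta_r),
    se = se_r,
    z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    stringsAsFactors = FALSE
  )
  rownames(coef_tab) <- NULL

  structure(
    list(q_t = q_t, q_m = q_m, q_e = q_e, df_m = df_m, df_e = df_e,
         p_value = p_qm, p_value_qe = p_qe,
         coefficients = coef_tab, tau2 = tau2, k = k,
         dropped = design$dropped %||% 0L),
    class = "moderator_test"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.moderator_test <- function(x, digits = 4, ...) {
  cat(sprintf("Moderator meta-regression (k = %d, tau^2 = %.*f)\n",
              x$k, digits, x$tau2))
  cat(sprintf("  Qm = %.*f (df = %d, p = %.4g); Qe = %.*f (df = %d); Qt = %.*f\n",
              digits, x$q_m, x$df_m, x$p_value,
              digits, x$q_e, x$df_e, digits, x$q_t))
  print(x$coefficients, digits = digits)
  invisible(x)
}

#' Heterogeneity gate for moderator introduction
#'
#' Moderators are introduced into the model only when residual
#' heterogeneity is high; the gate is `I^2 > threshold` (strict), with
#' the conventional 75% "high heterogeneity" default.
#'
#' @param pooled A `pooled_result`.
#' @param threshold Percentage in `[0, 100]`. Default 75.
#' @return `TRUE` when meta-regression should run.
#' @export
moderator_gate <- function(pooled, threshold = 75) {
  stopifnot(inherits(pooled, "pooled_result"),
            threshold >= 0, threshold <= 100)
  pooled$i2 > threshold
}

#' Per-trait subgroup pooling
#'
#' Runs an independent random-effects pooling (fixed-effects when a trait
#' has a single effect) within each trait variable.
#'
#' @param effects An `effect_sizes` data frame with a `variable` column.
#' @return Named list of `pooled_result`, one per trait present (sorted);
#'   empty groups are skipped with a warning.
#' @export
subgroup_pool <- function(effects) {
  stopifnot(is.data.frame(effects), "variable" %in% names(effects))
  vars <- sort(unique(effects$variable))
  out <- list()
  for (v in vars) {
    sub <- effects[effects$variable == v, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("trait '", v, "' has no effects; skipped")
      next
    }
    out[[v]] <- if (nrow(sub) >= 2L) random_effects_pool(sub)
                else fixed_effects_pool(sub)
  }
  out
}

#' Temperature-response profile and thermal optimum
#'
#' Pools effects within each treatment temperature (random-effects where
#' a temperature has two or more effects) and fits a weighted quadratic
#' `rr ~ T + T^2` across all effects, with weights `1/(v + tau2)`
#' (tau2 from REML on the quadratic design). The optimum is the vertex
#' `-b1 / (2 b2)`, clamped to the observed temperature range; a profile
#' with no interior vertex in the beneficial direction is flagged
#' monotone and the best observed endpoint is reported.
#'
#' @param effects An `effect_sizes` data frame.
#' @param direction `"max"` (default) if a larger pooled rr is
#'   favourable at the optimum, `"min"` otherwise.
#' @return A `temperature_profile` list: `by_temperature` (data frame of
#'   per-temperature pooled rr and CI), `coefficients` (intercept, T,
#'   T^2), `optimum_c`, `monotone` flag, `tau2`.
#' @export
temperature_profile <- function(effects, direction = c("max", "min")) {
  direction <- match.arg(direction)
  .check_effects(effects, 3L)
  temps <- sort(unique(effects$temperature_c))
  if (length(temps) < 3L)
    stop("need >= 3 distinct treatment temperatures to fit curvature, got ",
         length(temps), call. = FALSE)

  rows <- lapply(temps, function(tt) {
    sub <- effects[effects$temperature_c == tt, , drop = FALSE]
    pr <- if (nrow(sub) >= 2L) random_effects_pool(sub)
          else fixed_effects_pool(sub)
    data.frame(temperature_c = tt, k = pr$k, rr = pr$rr_plus,
               ci_low = pr$ci_low, ci_high = pr$ci_high)
  })
  by_temp <- do.call(rbind, rows)

  # centre T for conditioning; vertex mapped back to the raw scale
  tc <- effects$temperature_c - mean(temps)
  X <- cbind(intercept = 1, t = tc, t2 = tc^2)
  tau2 <- reml_tau2(effects, design = X)
  w <- 1 / (effects$v + tau2)
  XtW <- t(X * w)
  beta <- drop(solve(XtW %*% X, XtW %*% effects$rr))
  b1 <- beta[["t"]]; b2 <- beta[["t2"]]

  rng <- range(temps)
  want_max <- direction == "max"
  monotone <- FALSE
  if ((want_max && b2 < 0) || (!want_max && b2 > 0)) {
    vertex <- -b1 / (2 * b2) + mean(temps)
    optimum <- min(max(vertex, rng[1]), rng[2])
    if (vertex < rng[1] || vertex > rng[2]) monotone <- TRUE
  } else {
    # curvature in the unfavourable direction: profile is monotone (or
    # dished) over the range; best endpoint wins
    fend <- function(tt) {
      z <- tt - mean(temps)
      beta[["intercept"]] + b1 * z + b2 * z^2
    }
    vals <- vapply(rng, fend, numeric(1))
    optimum <- rng[if (want_max) which.max(vals) else which.min(vals)]
    monotone <- TRUE
  }

  structure(
    list(by_temperature = by_temp,
         coefficients = c(intercept = beta[["intercept"]], t = b1, t2 = b2),
         center = mean(temps),
         optimum_c = optimum, monotone = monotone, tau2 = tau2,
         direction = direction),
    class = "temperature_profile"
  )
}

#' @export
print.temperature_profile <- function(x, ...) {
  cat(sprintf("Temperature-response profile (%d temperatures)\n",
              nrow(x$by_temperature)))
  cat(sprintf("  optimum = %.2f C%s (quadratic vertex, direction = %s)\n",
              x$optimum_c, if (x$monotone) " [monotone over range]" else "",
              x$direction))
  print(x$by_temperature, row.names = FALSE)
  invisible(x)
}
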