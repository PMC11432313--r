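#' Log response ratio
#'
#' The effect size for ratio-scale outcomes: `ln(x_t / x_c)`, the natural
#' log of the treatment mean over the control mean. Symmetric
#' (`rr(a, b) = -rr(b, a)`) and invariant to a common rescaling of both
#' means.
#'
#' @param x_t,x_c Strictly positive treatment and control means.
#' @return The log response ratio `ln(x_t) - ln(x_c)`.
#' @export
#' @examples
#' log_response_ratio(5, 10) # ln(0.5)
log_response_ratio <- function(x_t, x_c) {
  if (any(!is.finite(x_t)) || any(!is.finite(x_c)) ||
      any(x_t <= 0) || any(x_c <= 0))
    stop("means must be finite and > 0 (log undefined otherwise)",
         call. = FALSE)
  log(x_t) - log(x_c)
}

#' Sampling variance of the log response ratio
#'
#' `v = s_t^2 / (n_t * x_t^2) + s_c^2 / (n_c * x_c^2)`, the delta-method
#' variance of `ln(x_t / x_c)` from group standard deviations, sample
#' sizes and means. Symmetric under swapping the two groups.
#'
#' @param s_t,s_c Group standard deviations (>= 0).
#' @param n_t,n_c Group sample sizes (>= 1).
#' @param x_t,x_c Group means (> 0).
#' @return The sampling variance (0 is possible when both SDs are 0; see
#'   [compute_effects()] for the downstream floor).
#' @export
#' @examples
#' rr_variance(1, 4, 10, 1, 4, 10) # 0.005
rr_variance <- function(s_t, n_t, x_t, s_c, n_c, x_c) {
  if (any(x_t <= 0) || any(x_c <= 0))
    stop("means must be > 0", call. = FALSE)
  if (any(n_t < 1) || any(n_c < 1))
    stop("sample sizes must be >= 1", call. = FALSE)
  if (any(s_t < 0) || any(s_c < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  s_t^2 / (n_t * x_t^2) + s_c^2 / (n_c * x_c^2)
}

#' Compute effect sizes for a table of contrast pairs
#'
#' Applies [log_response_ratio()] and [rr_variance()] to every pair and
#' attaches inverse-variance weights and the treatment-condition
#' moderators. Pairs whose variance is exactly zero (both SDs zero)
#' receive a small floor variance instead of an infinite weight, with a
#' warning and a `degenerate_v` flag.
#'
#' @param pairs A `contrast_pairs` data frame from
#'   [pair_control_treatment()].
#' @param v_floor Variance substituted when `v = 0`. Default `1e-8`.
#' @return An `effect_sizes` data frame: `study_id`, `variable`,
#'   `temperature_c`, `rel_humidity_pct`, `photoperiod_light_h`, `rr`,
#'   `v`, `w` (`= 1/v`), `degenerate_v`.
#' @export
compute_effects <- function(pairs, v_floor = 1e-8) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0L) {
    out <- data.frame(study_id = character(0), variable = character(0),
                      temperature_c = numeric(0),
                      rel_humidity_pct = numeric(0),
                      photoperiod_light_h = numeric(0),
                      rr = numeric(0), v = numeric(0), w = numeric(0),
                      degenerate_v = logical(0))
    class(out) <- c("effect_sizes", "data.frame")
    return(out)
  }
  rr <- log_response_ratio(pairs$mean_t, pairs$mean_c)
  v <- rr_variance(pairs$sd_t, pairs$n_t, pairs$mean_t,
                   pairs$sd_c, pairs$n_c, pairs$mean_c)
  degenerate <- v == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " pair(s) with zero sampling variance; ",
            "variance floored at ", format(v_floor))
    v[degenerate] <- v_floor
  }
  out <- data.frame(
    study_id = pairs$study_id,
    variable = pairs$variable,
    temperature_c = pairs$temperature_c,
    rel_humidity_pct = pairs$rel_humidity_pct,
    photoperiod_light_h = pairs$photoperiod_light_h,
    rr = rr, v = v, w = 1 / v,
    degenerate_v = degenerate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("effect_sizes", "data.frame")
  out
}

#' Write effect sizes to CSV
#'
#' @param effects An `effect_sizes` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_effects_csv <- function(effects, path) {
  cols <- c("study_id", "variable", "temperature_c", "rel_humidity_pct",
            "photoperiod_light_h", "rr", "v", "w")
  utils::write.csv(as.data.frame(effects)[, cols], path, row.names = FALSE)
  invisible(path)
}
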