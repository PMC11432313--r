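#' Optimal environmental conditions for a trait
#'
#' Groups a trait's effects by unique observed condition cell
#' (treatment temperature, relative humidity, photoperiod), pools each
#' cell with fixed effects, and returns the cell whose pooled log
#' response ratio is most extreme in the trait's beneficial direction:
#' most negative for duration traits (fastest development), most
#' positive for quantity traits (most eggs, longest laying window).
#' Only effects with complete moderators are considered. Ties are broken
#' toward the lower temperature (with a warning).
#'
#' The construction — argmin/argmax over observed cells of the
#' cell-pooled effect — is this package's operational definition of an
#' "optimal condition"; no interpolation between observed cells is
#' attempted.
#'
#' @param effects An `effect_sizes` data frame.
#' @param variable Trait name from [trait_vocabulary()].
#' @param direction Override of [direction_map()] for this call.
#' @return An `optimal_conditions` list: `variable`, `direction`,
#'   `best_temperature_c`, `best_rel_humidity_pct`,
#'   `best_photoperiod_light_h`, `cell_pooled_effect` (a
#'   `pooled_result`), `n_cells`, `cells` (per-cell summary table).
#' @export
optimal_conditions <- function(effects, variable, direction = NULL) {
  stopifnot(is.data.frame(effects))
  if (is.null(direction)) direction <- direction_map(variable)
  direction <- match.arg(direction, c("minimize_duration",
                                      "maximize_quantity"))
  sub <- effects[effects$variable == variable, , drop = FALSE]
  ok <- stats::complete.cases(sub[, c("temperature_c", "rel_humidity_pct",
                                      "photoperiod_light_h")])
  sub <- sub[ok, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no complete-moderator effects for trait '", variable, "'",
         call. = FALSE)

  key <- paste(sub$temperature_c, sub$rel_humidity_pct,
               sub$photoperiod_light_h, sep = "\r")
  cells <- lapply(split(sub, key), function(g) {
    pr <- fixed_effects_pool(g)
    data.frame(temperature_c = g$temperature_c[1L],
               rel_humidity_pct = g$rel_humidity_pct[1L],
               photoperiod_light_h = g$photoperiod_light_h[1L],
               rr = pr$rr_plus, ci_low = pr$ci_low, ci_high = pr$ci_high,
               k = pr$k)
  })
  tab <- do.call(rbind, cells)
  rownames(tab) <- NULL
  score <- if (direction == "minimize_duration") tab$rr else -tab$rr
  best_score <- min(score)
  hit <- which(score <= best_score + 1e-12)
  if (length(hit) > 1L) {
    warning("tie between ", length(hit), " condition cells for '", variable,
            "'; lower temperature wins")
    hit <- hit[order(tab$temperature_c[hit])]
  }
  best <- hit[1L]
  sel <- sub$temperature_c == tab$temperature_c[best] &
    sub$rel_humidity_pct == tab$rel_humidity_pct[best] &
    sub$photoperiod_light_h == tab$photoperiod_light_h[best]
  structure(
    list(variable = variable, direction = direction,
         best_temperature_c = tab$temperature_c[best],
         best_rel_humidity_pct = tab$rel_humidity_pct[best],
         best_photoperiod_light_h = tab$photoperiod_light_h[best],
         cell_pooled_effect = fixed_effects_pool(sub[sel, , drop = FALSE]),
         n_cells = nrow(tab), cells = tab),
    class = "optimal_conditions"
  )
}

#' @export
print.optimal_conditions <- function(x, ...) {
  cat(sprintf("Optimal conditions for '%s' (%s, %d cells considered)\n",
              x$variable, x$direction, x$n_cells))
  cat(sprintf("  %.4g C, RH %.4g%%, L:D = %g:%g  (pooled rr %.4f, k = %d)\n",
              x$best_temperature_c, x$best_rel_humidity_pct,
              x$best_photoperiod_light_h, 24 - x$best_photoperiod_light_h,
              x$cell_pooled_effect$rr_plus, x$cell_pooled_effect$k))
  invisible(x)
}

#' Optimal-conditions table for every trait present
#'
#' Applies [optimal_conditions()] to each trait with complete-moderator
#' effects and assembles the rows into one table (the analogue of a
#' per-stage optimal-environment summary).
#'
#' @param effects An `effect_sizes` data frame.
#' @return Data frame with columns `variable`, `direction`,
#'   `optimal_temperature_c`, `optimal_rh_pct`, `optimal_photoperiod`,
#'   `pooled_rr`, `ci_low`, `ci_high`, `k`, `n_cells`.
#' @export
optimal_table <- function(effects) {
  vars <- sort(unique(effects$variable))
  rows <- list()
  for (v in vars) {
    oc <- tryCatch(optimal_conditions(effects, v), error = function(e) NULL)
    if (is.null(oc)) next
    rows[[v]] <- data.frame(
      variable = v, direction = oc$direction,
      optimal_temperature_c = oc$best_temperature_c,
      optimal_rh_pct = oc$best_rel_humidity_pct,
      optimal_photoperiod = sprintf("%g:%g", oc$best_photoperiod_light_h,
                                    24 - oc$best_photoperiod_light_h),
      pooled_rr = oc$cell_pooled_effect$rr_plus,
      ci_low = oc$cell_pooled_effect$ci_low,
      ci_high = oc$cell_pooled_effect$ci_high,
      k = oc$cell_pooled_effect$k,
      n_cells = oc$n_cells,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
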