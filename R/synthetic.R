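#' Configuration for the synthetic multi-study generator
#'
#' Builds the parameter set for [synthesize_dataset()]. The generator
#' emulates multi-study temperature-gradient rearing experiments:
#'
#' * duration traits follow the degree-day model
#'   `mean duration = K / (T - T0)` (development rate linear in
#'   temperature above a base threshold `T0`), so durations decrease
#'   monotonically with temperature;
#' * quantity traits (e.g. fecundity) follow a peaked log-quadratic
#'   thermal performance curve
#'   `log mean = log(scale) - (T - peak)^2 / (2 width^2)`, so the log
#'   response ratio is an exact quadratic in temperature with its vertex
#'   at `quantity_peak_c`;
#' * each study runs all configured temperatures at one (relative
#'   humidity, photoperiod) setting, assigned deterministically by
#'   cycling over `rh_levels` and `photoperiod_levels` so the ground
#'   truth does not depend on the noise seed;
#' * humidity and photoperiod act as multiplicative log-scale moderators
#'   on the treatment response (slopes per percent RH and per light
#'   hour, centred at `rh_ref` / `photoperiod_ref`);
#' * between-study heterogeneity is a Normal(0, `tau2_true`) log-scale
#'   study effect on the treatment response; within-observation noise is
#'   lognormal with mean-CV `cv` scaled by `1/sqrt(n)`.
#'
#' @param n_studies Number of studies. Default 20.
#' @param temperatures Sorted treatment/control temperatures (C).
#'   Default `c(18, 21, 24, 27, 30, 33, 36)`; the lowest is every
#'   study's control.
#' @param traits Subset of [trait_vocabulary()]. Default four duration
#'   traits plus fecundity.
#' @param duration_K Degree-day constant (degree-days). Default 270.
#' @param duration_T0 Base developmental threshold (C). Default 12; all
#'   temperatures must exceed it.
#' @param quantity_peak_c Thermal optimum of quantity traits (C).
#'   Default 32.
#' @param quantity_width_c Gaussian width of the performance curve (C).
#'   Default 6.
#' @param quantity_scale Peak trait value (e.g. eggs). Default 1000.
#' @param rh_levels,photoperiod_levels Condition pools cycled across
#'   studies. Defaults `c(60, 65, 70, 75, 80)` percent and
#'   `c(10, 12, 14, 16)` light hours.
#' @param rh_ref,photoperiod_ref Moderator centring. Defaults 70% and
#'   12 h.
#' @param humidity_slope Log-scale treatment-response slope per percent
#'   RH. Default 0.02.
#' @param photoperiod_slope Log-scale slope per light hour. Default 0.01.
#' @param tau2_true Between-study variance of the log-scale study
#'   effect. Default 0.04.
#' @param cv Within-observation coefficient of variation. Default 0.1.
#' @param n_range Sample-size range (uniform integer draw). Default
#'   `c(20, 60)`.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_studies = 20,
                             temperatures = c(18, 21, 24, 27, 30, 33, 36),
                             traits = c("egg", "egg_to_adult", "life_cycle",
                                        "pupal_period", "fecundity"),
                             duration_K = 270, duration_T0 = 12,
                             quantity_peak_c = 32, quantity_width_c = 6,
                             quantity_scale = 1000,
                             rh_levels = c(60, 65, 70, 75, 80),
                             photoperiod_levels = c(10, 12, 14, 16),
                             rh_ref = 70, photoperiod_ref = 12,
                             humidity_slope = 0.02,
                             photoperiod_slope = 0.01,
                             tau2_true = 0.04, cv = 0.1,
                             n_range = c(20, 60)) {
  temperatures <- sort(unique(temperatures))
  stopifnot(n_studies >= 1, length(temperatures) >= 2,
            tau2_true >= 0, cv > 0,
            length(n_range) == 2, n_range[1] >= 1,
            n_range[2] >= n_range[1])
  bad <- setdiff(traits, trait_vocabulary())
  if (length(bad))
    stop("unknown trait(s): ", paste(bad, collapse = ", "), call. = FALSE)
  dur <- intersect(traits, .duration_traits)
  if (length(dur) && any(temperatures <= duration_T0))
    stop("all temperatures must exceed the base threshold T0 = ",
         duration_T0, " for duration traits", call. = FALSE)
  structure(
    list(n_studies = n_studies, temperatures = temperatures, traits = traits,
         duration_K = duration_K, duration_T0 = duration_T0,
         quantity_peak_c = quantity_peak_c,
         quantity_width_c = quantity_width_c,
         quantity_scale = quantity_scale,
         rh_levels = rh_levels, photoperiod_levels = photoperiod_levels,
         rh_ref = rh_ref, photoperiod_ref = photoperiod_ref,
         humidity_slope = humidity_slope,
         photoperiod_slope = photoperiod_slope,
         tau2_true = tau2_true, cv = cv, n_range = n_range),
    class = "synthetic_config"
  )
}

# deterministic study -> (RH, photoperiod) assignment (independent of seed)
.study_conditions <- function(config, study_index) {
  rh <- config$rh_levels[(study_index - 1L) %% length(config$rh_levels) + 1L]
  ph <- config$photoperiod_levels[
    (study_index - 1L) %% length(config$photoperiod_levels) + 1L]
  c(rh = rh, photoperiod = ph)
}

# noise-free trait mean at temperature T (no moderators, no study effect)
.base_mean <- function(config, variable, temperature) {
  if (variable %in% .duration_traits) {
    config$duration_K / (temperature - config$duration_T0)
  } else {
    config$quantity_scale *
      exp(-(temperature - config$quantity_peak_c)^2 /
            (2 * config$quantity_width_c^2))
  }
}

.moderator_shift <- function(config, rh, photoperiod) {
  config$humidity_slope * (rh - config$rh_ref) +
    config$photoperiod_slope * (photoperiod - config$photoperiod_ref)
}

#' Closed-form true log response ratio
#'
#' The noise-free log response ratio of a treatment temperature against
#' the study's lowest-temperature control, including the study's
#' moderator shift. For duration traits this is
#' `ln((T_min - T0) / (T - T0)) + shift`; for quantity traits the exact
#' quadratic `((T_min - peak)^2 - (T - peak)^2) / (2 width^2) + shift`.
#'
#' @param config A `synthetic_config`.
#' @param study Study index in `1:n_studies`.
#' @param variable Trait name in `config$traits`.
#' @param temperature A treatment temperature in `config$temperatures`.
#' @return The true log response ratio.
#' @export
true_rr <- function(config, study, variable, temperature) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!study %in% seq_len(config$n_studies))
    stop("unknown study index: ", study, call. = FALSE)
  if (!variable %in% config$traits)
    stop("trait '", variable, "' not in config", call. = FALSE)
  if (!temperature %in% config$temperatures)
    stop("temperature ", temperature, " not in config", call. = FALSE)
  tmin <- config$temperatures[1L]
  cond <- .study_conditions(config, study)
  base <- log(.base_mean(config, variable, temperature)) -
    log(.base_mean(config, variable, tmin))
  shift <- if (temperature == tmin) 0
           else .moderator_shift(config, cond[["rh"]], cond[["photoperiod"]])
  base + shift
}

#' Generate a synthetic multi-study observation table
#'
#' Draws one observation per (study, trait, temperature): a study-level
#' log effect `u ~ Normal(0, tau2_true)` and the study's moderator shift
#' scale the treatment means multiplicatively (the control mean is the
#' untouched base model), observed means are the true means times
#' lognormal noise with log-SD `cv / sqrt(n)`, and each row's SD is
#' `cv` times its observed mean.
#'
#' @param config A `synthetic_config`.
#' @param seed Integer RNG seed; a fixed seed gives byte-identical
#'   output.
#' @return List with `observations` (canonical observation data frame,
#'   all rows `dispersion_kind = "SD"`) and `ground_truth` (list:
#'   `true_effects` data frame of closed-form per-(study, trait,
#'   temperature) log response ratios, `tau2_true`, `humidity_slope`,
#'   `photoperiod_slope`, and per-trait `optimum_c`).
#' @export
synthesize_dataset <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  temps <- config$temperatures
  tmin <- temps[1L]
  rows <- vector("list", config$n_studies * length(config$traits))
  truth <- vector("list", length(rows))
  idx <- 0L
  for (s in seq_len(config$n_studies)) {
    cond <- .study_conditions(config, s)
    sid <- sprintf("study_%03d", s)
    for (tr in config$traits) {
      idx <- idx + 1L
      u <- stats::rnorm(1L, 0, sqrt(config$tau2_true))
      shift <- .moderator_shift(config, cond[["rh"]], cond[["photoperiod"]])
      n <- sample(seq(config$n_range[1L], config$n_range[2L]),
                  length(temps), replace = TRUE)
      base <- vapply(temps, function(tt) .base_mean(config, tr, tt),
                     numeric(1))
      true_mean <- base * exp(ifelse(temps == tmin, 0, shift + u))
      obs_mean <- true_mean * exp(stats::rnorm(length(temps), 0,
                                               config$cv / sqrt(n)))
      rows[[idx]] <- data.frame(
        study_id = sid, variable = tr, temperature_c = temps,
        rel_humidity_pct = cond[["rh"]],
        photoperiod = sprintf("%g:%g", cond[["photoperiod"]],
                              24 - cond[["photoperiod"]]),
        photoperiod_light_h = cond[["photoperiod"]],
        mean = obs_mean, dispersion_value = config$cv * obs_mean,
        dispersion_kind = "SD", n = n,
        stringsAsFactors = FALSE
      )
      truth[[idx]] <- data.frame(
        study_id = sid, variable = tr, temperature_c = temps[-1L],
        true_rr = log(base[-1L] / base[1L]) + shift,
        stringsAsFactors = FALSE
      )
    }
  }
  observations <- do.call(rbind, rows)
  rownames(observations) <- NULL
  optimum <- vapply(config$traits, function(tr) {
    if (tr %in% .duration_traits) max(temps)
    else min(max(config$quantity_peak_c, min(temps)), max(temps))
  }, numeric(1))
  list(
    observations = observations,
    ground_truth = list(
      true_effects = do.call(rbind, truth),
      tau2_true = config$tau2_true,
      humidity_slope = config$humidity_slope,
      photoperiod_slope = config$photoperiod_slope,
      optimum_c = optimum
    )
  )
}

#' Write an observation table to the canonical CSV
#'
#' @param observations Observation data frame (from
#'   [synthesize_dataset()] or compatible).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(observations, path) {
  cols <- c("study_id", "variable", "temperature_c", "rel_humidity_pct",
            "photoperiod", "mean", "dispersion_value", "dispersion_kind", "n")
  utils::write.csv(observations[, cols], path, row.names = FALSE)
  invisible(path)
}
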