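#' Run the full meta-analysis pipeline
#'
#' Orchestrates ingest -> effect sizes -> pooling -> per-trait subgroup
#' pooling -> moderator meta-regression (gated on I-squared) ->
#' temperature profile -> optimal conditions -> publication-bias
#' diagnostics, optionally writing every artifact as CSV/JSON plus a run
#' manifest. The analysis path is fully deterministic given its input.
#'
#' @param input Path to a canonical observation CSV, or an observation
#'   data frame (e.g. `synthesize_dataset()$observations`).
#' @param out_dir Output directory for artifacts; `NULL` (default) skips
#'   writing.
#' @param dialect Optional column remapping for CSV input (see
#'   [read_observations()]).
#' @param impute_sd Impute missing SDs as mean/10? Default `TRUE`.
#' @param i2_threshold I-squared gate (percent) above which moderator
#'   meta-regression runs. Default 75.
#' @param moderators Moderator columns tested one at a time. Default
#'   humidity and photoperiod.
#' @param conf_mult CI multiplier. Default 1.96 (95%).
#' @return A `faw_pipeline` list: `observations`, `pairs`, `effects`,
#'   `overall_fixed`, `overall_random`, `by_trait`, `moderator_tests`
#'   (per trait x moderator, `NULL` where gated off or not estimable),
#'   `profile`, `optimal`, `bias`, `manifest`.
#' @export
run_pipeline <- function(input, out_dir = NULL, dialect = NULL,
                         impute_sd = TRUE, i2_threshold = 75,
                         moderators = c("rel_humidity_pct",
                                        "photoperiod_light_h"),
                         conf_mult = 1.96) {
  observations <- if (is.character(input)) {
    read_observations(input, dialect = dialect)
  } else {
    stopifnot(is.data.frame(input))
    input
  }
  observations <- resolve_sd(observations, impute = impute_sd)
  pairs <- pair_control_treatment(observations)
  effects <- compute_effects(pairs)
  if (nrow(effects) < 2L)
    stop("pipeline needs at least 2 effects; got ", nrow(effects),
         call. = FALSE)

  overall_fixed <- fixed_effects_pool(effects, conf_mult = conf_mult)
  overall_random <- random_effects_pool(effects, conf_mult = conf_mult)
  by_trait <- subgroup_pool(effects)

  n_studies <- length(unique(effects$study_id))
  moderator_tests <- list()
  for (tr in names(by_trait)) {
    sub <- effects[effects$variable == tr, , drop = FALSE]
    if (n_studies < 2L) {
      warning("single study: moderator stage skipped")
      break
    }
    if (!moderator_gate(by_trait[[tr]], i2_threshold)) next
    for (m in moderators) {
      key <- paste(tr, m, sep = ".")
      moderator_tests[[key]] <- tryCatch(
        meta_regression(sub, moderators = m),
        error = function(e) {
          warning("moderator test skipped for ", key, ": ",
                  conditionMessage(e))
          NULL
        })
    }
  }

  profile <- tryCatch(temperature_profile(effects),
                      error = function(e) {
                        warning("temperature profile skipped: ",
                                conditionMessage(e))
                        NULL
                      })
  optimal <- optimal_table(effects)
  bias <- tryCatch(bias_report(effects),
                   error = function(e) {
                     warning("bias diagnostics skipped: ",
                             conditionMessage(e))
                     NULL
                   })

  manifest <- list(
    package_version = as.character(utils::packageVersion("fawmeta")),
    n_observations = nrow(observations),
    n_pairs = nrow(pairs),
    n_effects = nrow(effects),
    n_studies = n_studies,
    n_traits = length(by_trait),
    n_sd_imputed = sum(observations$sd_imputed),
    i2_threshold = i2_threshold,
    moderators = moderators,
    conf_mult = conf_mult
  )

  result <- structure(
    list(observations = observations, pairs = pairs, effects = effects,
         overall_fixed = overall_fixed, overall_random = overall_random,
         by_trait = by_trait, moderator_tests = moderator_tests,
         profile = profile, optimal = optimal, bias = bias,
         manifest = manifest),
    class = "faw_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

.pooled_row <- function(label, p) {
  data.frame(label = label, model = p$model, k = p$k, rr_plus = p$rr_plus,
             se = p$se, ci_low = p$ci_low, ci_high = p$ci_high,
             q = p$q, df = p$df, p_value = p$p_value,
             tau2 = p$tau2, i2 = p$i2, stringsAsFactors = FALSE)
}

#' Write pipeline artifacts
#'
#' Writes effects, pooled summaries, moderator tests, the temperature
#' profile, the optimal-conditions table, funnel data and a JSON run
#' manifest into `out_dir`.
#'
#' @param result A `faw_pipeline` object.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(result, out_dir) {
  stopifnot(inherits(result, "faw_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)

  write_effects_csv(result$effects, fp("effects.csv"))

  pooled <- rbind(
    .pooled_row("overall", result$overall_fixed),
    .pooled_row("overall", result$overall_random),
    do.call(rbind, lapply(names(result$by_trait), function(v)
      .pooled_row(v, result$by_trait[[v]])))
  )
  utils::write.csv(pooled, fp("pooled.csv"), row.names = FALSE)

  if (length(result$moderator_tests)) {
    mt <- do.call(rbind, lapply(names(result$moderator_tests), function(nm) {
      x <- result$moderator_tests[[nm]]
      if (is.null(x)) return(NULL)
      slope <- x$coefficients[2L, ]
      data.frame(test = nm, term = slope$term, estimate = slope$estimate,
                 se = slope$se, q_m = x$q_m, df_m = x$df_m,
                 p_value = x$p_value, q_e = x$q_e, q_t = x$q_t,
                 tau2 = x$tau2, k = x$k, stringsAsFactors = FALSE)
    }))
    if (!is.null(mt))
      utils::write.csv(mt, fp("moderator_tests.csv"), row.names = FALSE)
  }

  if (!is.null(result$profile))
    utils::write.csv(result$profile$by_temperature, fp("profile.csv"),
                     row.names = FALSE)
  if (!is.null(result$optimal))
    utils::write.csv(result$optimal, fp("optimal_conditions.csv"),
                     row.names = FALSE)
  if (!is.null(result$bias)) {
    utils::write.csv(result$bias$funnel, fp("funnel.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(egger = result$bias$egger[c("intercept", "se", "z", "p_value")],
           fail_safe_n = result$bias$fail_safe_n),
      fp("bias.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.faw_pipeline <- function(x, ...) {
  cat("Fall armyworm thermal meta-analysis pipeline\n")
  cat(sprintf("  %d observations, %d effects, %d studies, %d traits\n",
              x$manifest$n_observations, x$manifest$n_effects,
              x$manifest$n_studies, x$manifest$n_traits))
  print(x$overall_random)
  if (!is.null(x$profile))
    cat(sprintf("  thermal optimum (overall profile): %.2f C\n",
                x$profile$optimum_c))
  invisible(x)
}
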