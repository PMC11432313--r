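#' Trait vocabulary
#'
#' The closed set of life-history trait names the pipeline recognises:
#' the six larval instars, egg, pupal and whole-cycle durations, the
#' oviposition traits, adult longevity, fecundity and eclosion rate.
#'
#' @return Character vector of the 16 recognised trait names.
#' @export
trait_vocabulary <- function() {
  c("1st instar", "2nd instar", "3rd instar", "4th instar", "5th instar",
    "6th instar", "adult_longevity", "eclosion_rate", "egg", "egg_to_adult",
    "fecundity", "life_cycle", "oviposition_period", "pre_oviposition_period",
    "pupa_developmental_duration", "pupal_period")
}

# Traits where a smaller value (shorter duration) is biologically favourable.
.duration_traits <- c(
  "1st instar", "2nd instar", "3rd instar", "4th instar", "5th instar",
  "6th instar", "egg", "egg_to_adult", "life_cycle",
  "pre_oviposition_period", "pupa_developmental_duration", "pupal_period"
)

# Traits where a larger value (more eggs, longer laying window, higher
# emergence, longer adult life) is favourable.
.quantity_traits <- c(
  "adult_longevity", "eclosion_rate", "fecundity", "oviposition_period"
)

#' Beneficial direction for a trait
#'
#' Maps each trait in the vocabulary to the direction in which its pooled
#' log response ratio is favourable: developmental durations are best
#' minimised (faster development), while fecundity, oviposition period,
#' eclosion rate and adult longevity are best maximised.
#'
#' Adult longevity is a judgement call: reports disagree on whether warm
#' temperatures lengthen or shorten adult life, so the default
#' (`maximize_quantity`) can be overridden per call in
#' [optimal_conditions()].
#'
#' @param variable Trait name from [trait_vocabulary()].
#' @return `"minimize_duration"` or `"maximize_quantity"`.
#' @export
#' @examples
#' direction_map("egg")       # minimize_duration
#' direction_map("fecundity") # maximize_quantity
direction_map <- function(variable) {
  stopifnot(is.character(variable), length(variable) == 1L)
  if (variable %in% .duration_traits) return("minimize_duration")
  if (variable %in% .quantity_traits) return("maximize_quantity")
  stop("unknown trait variable: '", variable, "'", call. = FALSE)
}
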