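#' @title Observation tables: reading, validation and dispersion handling
#'
#' @description
#' Observation tables hold one row per measured trait mean under one
#' environmental condition (temperature, relative humidity, photoperiod)
#' in one study. Canonical columns:
#' `study_id`, `variable`, `temperature_c`, `rel_humidity_pct`,
#' `photoperiod`, `mean`, `dispersion_value`, `dispersion_kind`, `n`.
#' `dispersion_kind` is one of `"SD"`, `"SE"`, `"MISSING"`; `photoperiod`
#' accepts `"12:12"` or `"L:D = 12:12"` and is parsed to light hours.
#' @name ingest
NULL

.canonical_columns <- c(
  "study_id", "variable", "temperature_c", "rel_humidity_pct",
  "photoperiod", "mean", "dispersion_value", "dispersion_kind", "n"
)

#' Parse a photoperiod string to light hours
#'
#' Accepts `"12:12"`, `"L:D = 16:8"`, `"L:D=14:10"` or a bare number of
#' light hours. Light and dark hours must sum to 24 when both are given.
#'
#' @param x Character (or numeric) vector of photoperiod entries.
#' @return Numeric vector of light hours in `[0, 24]`; `NA` where the entry
#'   is empty or missing.
#' @export
#' @examples
#' parse_photoperiod(c("L:D = 16:8", "12:12", ""))
parse_photoperiod <- function(x) {
  if (is.numeric(x)) {
    bad <- !is.na(x) & (x < 0 | x > 24)
    if (any(bad)) stop("photoperiod light hours outside [0, 24]", call. = FALSE)
    return(as.numeric(x))
  }
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s) || s == "" || toupper(s) == "NA") next
    s <- sub("^[Ll]\\s*:\\s*[Dd]\\s*=?\\s*", "", s)
    if (grepl(":", s, fixed = TRUE)) {
      parts <- suppressWarnings(as.numeric(strsplit(s, ":", fixed = TRUE)[[1]]))
      if (length(parts) != 2L || anyNA(parts))
        stop("unparseable photoperiod: '", x[i], "'", call. = FALSE)
      if (abs(sum(parts) - 24) > 1e-8)
        stop("photoperiod '", x[i], "' light + dark hours != 24", call. = FALSE)
      out[i] <- parts[1L]
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop("unparseable photoperiod: '", x[i], "'", call. = FALSE)
      out[i] <- v
    }
  }
  bad <- !is.na(out) & (out < 0 | out > 24)
  if (any(bad)) stop("photoperiod light hours outside [0, 24]", call. = FALSE)
  out
}

#' Convert a standard error to a standard deviation
#'
#' Inverts the definition SE = SD / sqrt(n), so SD = SE * sqrt(n). (Some
#' write-ups describe this conversion as a division; that direction would
#' shrink the dispersion twice and is not a recognised conversion, so the
#' multiplicative inverse is used.)
#'
#' @param se Non-negative standard error.
#' @param n Sample size (>= 1).
#' @return Standard deviation in the same units as `se`.
#' @export
#' @examples
#' convert_se_to_sd(0.5, 16) # 2
convert_se_to_sd <- function(se, n) {
  if (any(n < 1)) stop("sample size must be >= 1", call. = FALSE)
  if (any(se < 0)) stop("standard error must be >= 0", call. = FALSE)
  se * sqrt(n)
}

#' Impute a missing standard deviation from the mean
#'
#' When a study reports neither SD nor SE, one tenth of the reported mean
#' is used as the standard deviation (a 10% coefficient of variation).
#'
#' @param mean Strictly positive trait mean.
#' @return Imputed standard deviation, `mean / 10`.
#' @export
impute_sd <- function(mean) {
  if (any(!is.finite(mean)) || any(mean <= 0))
    stop("mean must be finite and > 0 to impute an SD", call. = FALSE)
  mean / 10
}

#' Resolve every row's dispersion to a standard deviation
#'
#' SD rows pass through; SE rows are converted with [convert_se_to_sd()];
#' rows with missing dispersion are imputed with [impute_sd()] unless
#' `impute = FALSE`, in which case they are dropped with a warning.
#'
#' @param records Observation data frame (canonical columns).
#' @param impute Impute missing SDs as mean/10? Default `TRUE`.
#' @return The data frame with `dispersion_kind` all `"SD"` and a logical
#'   `sd_imputed` column.
#' @export
resolve_sd <- function(records, impute = TRUE) {
  stopifnot(is.data.frame(records))
  kind <- toupper(records$dispersion_kind)
  if (!all(kind %in% c("SD", "SE", "MISSING")))
    stop("dispersion_kind must be SD, SE or MISSING", call. = FALSE)
  miss <- kind == "MISSING"
  if (!impute && any(miss)) {
    warning(sum(miss), " row(s) without SD/SE dropped (imputation disabled)")
    records <- records[!miss, , drop = FALSE]
    kind <- kind[!miss]
    miss <- rep(FALSE, nrow(records))
  }
  sd <- records$dispersion_value
  se_rows <- which(kind == "SE")
  if (length(se_rows))
    sd[se_rows] <- convert_se_to_sd(records$dispersion_value[se_rows],
                                    records$n[se_rows])
  if (any(miss)) sd[miss] <- impute_sd(records$mean[miss])
  records$dispersion_value <- sd
  records$dispersion_kind <- rep("SD", nrow(records))
  records$sd_imputed <- miss
  records
}

.validate_observations <- function(df) {
  problems <- character(0)
  reject <- rep(FALSE, nrow(df))
  flag <- function(bad, msg) {
    bad <- which(bad)
    if (length(bad)) {
      problems <<- c(problems, paste0("row ", bad, ": ", msg))
      reject[bad] <<- TRUE
    }
  }
  flag(!is.finite(df$temperature_c), "temperature_c not a finite number")
  flag(!is.na(df$rel_humidity_pct) &
         (df$rel_humidity_pct < 0 | df$rel_humidity_pct > 100),
       "rel_humidity_pct outside [0, 100]")
  flag(!is.na(df$photoperiod_light_h) &
         (df$photoperiod_light_h < 0 | df$photoperiod_light_h > 24),
       "photoperiod_light_h outside [0, 24]")
  flag(!is.finite(df$mean) | df$mean <= 0, "mean not a positive number")
  flag(!is.finite(df$n) | df$n < 1 | df$n != round(df$n),
       "n not a positive integer")
  kind <- toupper(df$dispersion_kind)
  flag(!kind %in% c("SD", "SE", "MISSING"), "dispersion_kind not SD/SE/MISSING")
  flag(kind != "MISSING" & (!is.finite(df$dispersion_value) |
                              df$dispersion_value < 0),
       "dispersion_value negative or missing for SD/SE row")
  list(keep = !reject, problems = problems)
}

#' Read and validate an observation CSV
#'
#' Reads a UTF-8, comma-separated, headered table of trait observations,
#' optionally remapping column names, parses photoperiod strings to light
#' hours, and validates every row. Rows violating the invariants
#' (humidity outside 0-100, non-positive mean, non-integer n, ...) are
#' rejected with row-indexed diagnostics attached as a warning.
#'
#' @param path CSV file path.
#' @param dialect Optional named list/character vector remapping canonical
#'   column names to the file's column names, e.g.
#'   `list(temperature_c = "temp")`.
#' @param strict If `TRUE` (default `FALSE`) any invalid row is an error
#'   instead of a warning-and-drop.
#' @return Data frame of validated observations with canonical columns and
#'   `photoperiod_light_h` (numeric light hours).
#' @export
read_observations <- function(path, dialect = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  cols <- .canonical_columns
  names(cols) <- cols
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    unknown <- setdiff(names(dialect), .canonical_columns)
    if (length(unknown))
      stop("dialect maps unknown field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cols[names(dialect)] <- dialect
  }
  missing_cols <- cols[!cols %in% names(raw)]
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- raw[, unname(cols)]
  names(df) <- names(cols)

  num_fields <- c("temperature_c", "rel_humidity_pct", "mean",
                  "dispersion_value", "n")
  for (f in num_fields) {
    v <- df[[f]]
    if (!is.numeric(v)) {
      vs <- trimws(as.character(v))
      vs[vs %in% c("", "NA", "na")] <- NA
      parsed <- suppressWarnings(as.numeric(vs))
      bad <- which(is.na(parsed) & !is.na(vs))
      if (length(bad))
        stop("unparseable numeric in column '", f, "' at row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      v <- parsed
    }
    df[[f]] <- v
  }
  df$photoperiod_light_h <- parse_photoperiod(df$photoperiod)
  df$study_id <- as.character(df$study_id)
  df$variable <- as.character(df$variable)
  df$dispersion_kind <- toupper(trimws(as.character(df$dispersion_kind)))
  # blank dispersion_value on an SD/SE row is effectively MISSING
  df$dispersion_kind[is.na(df$dispersion_value) &
                       df$dispersion_kind %in% c("SD", "SE")] <- "MISSING"

  chk <- .validate_observations(df)
  if (length(chk$problems)) {
    msg <- paste(chk$problems, collapse = "; ")
    if (strict) stop("invalid observation row(s): ", msg, call. = FALSE)
    warning("rejected ", sum(!chk$keep), " invalid row(s): ", msg)
  }
  out <- df[chk$keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair treatments with their study's lowest-temperature control
#'
#' Within each `(study_id, variable)` group the single record at the
#' minimum temperature is the control; every other record becomes one
#' contrast pair against that shared control. Groups with only one
#' temperature yield no pairs (with a warning); ties at the minimum
#' temperature are broken by first occurrence in input order (with a
#' warning).
#'
#' @param records Observation data frame, SD-resolved (see [resolve_sd()]).
#' @return A `contrast_pairs` data frame: one row per pair with control
#'   (`*_c`) and treatment (`*_t`) means, SDs and sample sizes, plus the
#'   treatment-condition moderators `temperature_c`, `rel_humidity_pct`,
#'   `photoperiod_light_h` and the control temperature.
#' @export
pair_control_treatment <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 0)
  if (nrow(records) && !all(toupper(records$dispersion_kind) == "SD"))
    stop("records must be SD-resolved before pairing (see resolve_sd)",
         call. = FALSE)
  key <- interaction(records$study_id, records$variable, drop = TRUE,
                     sep = "\r")
  pieces <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    g <- records[idx, , drop = FALSE]
    # order-independence: sort by temperature, then original position
    ord <- order(g$temperature_c)
    g <- g[ord, , drop = FALSE]
    tmin <- g$temperature_c[1L]
    if (all(g$temperature_c == tmin)) {
      warning("group (", g$study_id[1L], ", ", g$variable[1L],
              ") has a single temperature; no pairs formed")
      return(NULL)
    }
    at_min <- which(g$temperature_c == tmin)
    if (length(at_min) > 1L) {
      warning("group (", g$study_id[1L], ", ", g$variable[1L],
              ") has ", length(at_min), " rows at the minimum temperature; ",
              "first occurrence used as control")
    }
    ctrl <- g[at_min[1L], , drop = FALSE]
    trt <- g[-at_min, , drop = FALSE]
    data.frame(
      study_id = trt$study_id,
      variable = trt$variable,
      temperature_c = trt$temperature_c,
      rel_humidity_pct = trt$rel_humidity_pct,
      photoperiod_light_h = trt$photoperiod_light_h,
      control_temperature_c = ctrl$temperature_c,
      mean_t = trt$mean, sd_t = trt$dispersion_value, n_t = trt$n,
      mean_c = ctrl$mean, sd_c = ctrl$dispersion_value, n_c = ctrl$n,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(study_id = character(0), variable = character(0),
                      temperature_c = numeric(0),
                      rel_humidity_pct = numeric(0),
                      photoperiod_light_h = numeric(0),
                      control_temperature_c = numeric(0),
                      mean_t = numeric(0), sd_t = numeric(0), n_t = numeric(0),
                      mean_c = numeric(0), sd_c = numeric(0), n_c = numeric(0))
  # canonical row order: study, variable, treatment temperature
  out <- out[order(out$study_id, out$variable, out$temperature_c), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contrast_pairs", "data.frame")
  out
}
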