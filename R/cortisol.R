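## Diurnal saliva cleaning and summary indices, plus hair steroid change
## scores. The cleaning order is fixed: natural log transform, 3-SD
## winsorization per sampling occasion across the full sample, averaging of
## the two sampling days, then index computation.

#' Natural-log transform saliva concentrations
#'
#' Replaces each concentration (nmol/l) by its natural log. Non-positive
#' concentrations are outside the domain of the log; those samples are
#' flagged invalid and dropped with a warning.
#'
#' @param saliva data.frame/data.table with at least a `nmol_l` column
#'   (long format: one row per subject, timepoint, day, occasion).
#' @return The table with an added `log_nmol` column; invalid rows removed.
#' @export
log_transform <- function(saliva) {
  saliva <- data.table::as.data.table(saliva)
  bad <- !is.na(saliva$nmol_l) & saliva$nmol_l <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive saliva concentration(s) flagged ",
            "invalid and excluded")
    saliva <- saliva[!bad]
  }
  saliva[, log_nmol := log(nmol_l)]
  saliva[]
}

#' Winsorize a vector at mean +/- k SD
#'
#' Values diverging more than `k` standard deviations from the mean of the
#' input vector (single pass: mean and SD computed with the outliers
#' included) are clipped to the respective boundary. Missing values
#' propagate.
#'
#' @param x numeric vector (at least 3 non-missing values).
#' @param k SD multiple defining the boundary; the conventional and default
#'   choice is 3.
#' @param center,scale optional frozen mean and SD; supplying the values
#'   from a first pass makes the operation idempotent.
#' @return `x` with out-of-boundary values clipped.
#' @export
winsorize_3sd <- function(x, k = 3, center = NULL, scale = NULL) {
  n <- sum(!is.na(x))
  if (n < 3) stop("winsorization needs at least 3 non-missing values")
  m <- if (is.null(center)) mean(x, na.rm = TRUE) else center
  s <- if (is.null(scale)) stats::sd(x, na.rm = TRUE) else scale
  pmin(pmax(x, m - k * s), m + k * s)
}

#' Average the two sampling days of a cleaned saliva table
#'
#' Per subject, timepoint and occasion, the mean over available days; an
#' occasion missing on both days stays missing (i.e. absent from the
#' output).
#'
#' @param saliva cleaned table with a `log_nmol` column.
#' @return data.table with one row per subject, timepoint and
#'   `offset_min`, columns `log_nmol` (day mean) and `n_days`.
#' @export
average_days <- function(saliva) {
  saliva <- data.table::as.data.table(saliva)
  out <- saliva[!is.na(log_nmol),
                .(log_nmol = mean(log_nmol), n_days = .N),
                by = .(subject_id, timepoint, offset_min)]
  data.table::setorder(out, subject_id, timepoint, offset_min)
  out[]
}

## Extract the value at a nominal occasion from a named series (names =
## offsets in minutes); NA when absent.
#' @keywords internal
occ <- function(series, offset) {
  v <- series[as.character(offset)]
  unname(v)
}

#' Cortisol awakening response of one averaged series
#'
#' Change score from the awakening sample to the larger of the 30- and
#' 60-min samples. If the awakening value already exceeds both, the 30-min
#' sample operationalizes the (inverse) response, being the closer of the
#' two post-awakening probes.
#'
#' @param series named numeric vector of day-averaged log concentrations;
#'   names are nominal offsets in minutes (`"0"`, `"30"`, ...).
#' @return The change score, or `NA` if the awakening sample or both
#'   post-awakening samples are missing (or the 30-min sample is missing in
#'   the inverse case).
#' @export
compute_car <- function(series) {
  s0 <- occ(series, 0); s30 <- occ(series, 30); s60 <- occ(series, 60)
  if (is.na(s0) || (is.na(s30) && is.na(s60))) return(NA_real_)
  peak <- max(s30, s60, na.rm = TRUE)
  if (peak > s0) return(peak - s0)
  if (is.na(s30)) return(NA_real_)  # inverse response needs the 30-min probe
  s30 - s0
}

#' Diurnal slope of one averaged series
#'
#' Change score from awakening to the final sample of the day (600 min
#' after awakening); negative values indicate the normative decline.
#'
#' @inheritParams compute_car
#' @return `S600 - S0`, or `NA` if either endpoint is missing.
#' @export
compute_slope <- function(series) {
  s0 <- occ(series, 0); s600 <- occ(series, 600)
  if (is.na(s0) || is.na(s600)) return(NA_real_)
  s600 - s0
}

#' Total diurnal output: area under the curve with respect to ground
#'
#' Trapezoidal area over awakening-relative minutes spanned by the
#' awakening, 240-, 360-, 480- and 600-min samples. The 30- and 60-min
#' awakening-response samples never enter. All five included occasions must
#' be present; no interpolation is attempted.
#'
#' @inheritParams compute_car
#' @param offsets occasions included in the area (minutes).
#' @param times optional named vector of actual sampling times (minutes) to
#'   use as trapezoid abscissae instead of the nominal offsets.
#' @return The area (log-concentration x minutes), or `NA` if any included
#'   occasion is missing.
#' @export
compute_aucg <- function(series, offsets = AUCG_OFFSETS, times = NULL) {
  y <- vapply(offsets, function(o) {
    v <- occ(series, o)
    if (is.null(v) || length(v) == 0) NA_real_ else v
  }, 0)
  if (anyNA(y)) return(NA_real_)
  x <- offsets
  if (!is.null(times)) {
    x <- vapply(offsets, function(o) unname(times[as.character(o)]), 0)
    if (anyNA(x)) x <- offsets
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Diurnal cortisol indices for a full saliva table
#'
#' Composes the cleaning pipeline (log transform, per-occasion 3-SD
#' winsorization across the full sample, day averaging) and computes the
#' three summary indices per subject and timepoint, with per-index sample
#' availability counts.
#'
#' @param saliva raw saliva table: `subject_id`, `timepoint`, `day`,
#'   `offset_min`, `nmol_l` (optionally `actual_min`).
#' @param winsorize clip outliers at `sd_limit` SDs (default TRUE).
#' @param sd_limit SD multiple for winsorization.
#' @param winsorize_scope `"occasion"` (default): mean/SD per sampling
#'   occasion, pooling subjects, timepoints and days; `"global"`: one
#'   mean/SD over every sample.
#' @param use_actual_times use jittered actual sampling times as trapezoid
#'   abscissae for the area index (default: nominal design offsets).
#' @return data.table: `subject_id`, `timepoint`, `car`, `slope`, `aucg`,
#'   `n_car`, `n_slope`, `n_aucg` (occasions available to each index).
#' @export
diurnal_indices <- function(saliva, winsorize = TRUE, sd_limit = 3,
                            winsorize_scope = c("occasion", "global"),
                            use_actual_times = FALSE) {
  winsorize_scope <- match.arg(winsorize_scope)
  empty <- data.table::data.table(
    subject_id = character(), timepoint = character(), car = numeric(),
    slope = numeric(), aucg = numeric(), n_car = integer(),
    n_slope = integer(), n_aucg = integer())
  if (is.null(saliva) || nrow(saliva) == 0) return(empty)
  cleaned <- log_transform(saliva)
  if (nrow(cleaned) == 0) return(empty)
  if (winsorize) {
    if (winsorize_scope == "occasion") {
      cleaned[, log_nmol := winsorize_3sd(log_nmol, sd_limit),
              by = offset_min]
    } else {
      cleaned[, log_nmol := winsorize_3sd(log_nmol, sd_limit)]
    }
  }
  avg <- average_days(cleaned)
  times <- NULL
  if (use_actual_times && "actual_min" %in% names(saliva)) {
    at <- data.table::as.data.table(saliva)[
      , .(actual_min = mean(actual_min)),
      by = .(subject_id, timepoint, offset_min)]
    avg <- merge(avg, at, by = c("subject_id", "timepoint", "offset_min"),
                 all.x = TRUE, sort = FALSE)
  }
  one <- function(sd_) {
    series <- stats::setNames(sd_$log_nmol, sd_$offset_min)
    tms <- if (use_actual_times && "actual_min" %in% names(sd_))
      stats::setNames(sd_$actual_min, sd_$offset_min) else NULL
    list(car = compute_car(series),
         slope = compute_slope(series),
         aucg = compute_aucg(series, times = tms),
         n_car = sum(c(0, 30, 60) %in% sd_$offset_min),
         n_slope = sum(c(0, 600) %in% sd_$offset_min),
         n_aucg = sum(AUCG_OFFSETS %in% sd_$offset_min))
  }
  out <- avg[, one(.SD), by = .(subject_id, timepoint)]
  data.table::setorder(out, subject_id, timepoint)
  out[]
}

#' Hair steroid change scores per 3-month interval
#'
#' Hair is sampled at each timepoint; the proximal 3 cm segment reflects
#' accumulation over the preceding 3-month interval. The change score for a
#' consecutive interval (Ta, Tb) is the Tb value minus the Ta value, by
#' default after natural log transformation (consistent with the saliva
#' handling).
#'
#' @param hair table: `subject_id`, `timepoint`, `cortisol_pg_mg`,
#'   `cortisone_pg_mg`.
#' @param log transform values by natural log before differencing.
#' @return data.table: `subject_id`, `t_a`, `t_b`, `d_cortisol`,
#'   `d_cortisone`.
#' @export
hair_change <- function(hair, log = TRUE) {
  hair <- data.table::as.data.table(hair)
  f <- if (log) base::log else identity
  out <- list()
  for (i in seq_len(length(TIMEPOINTS) - 1L)) {
    a <- hair[timepoint == TIMEPOINTS[i]]
    b <- hair[timepoint == TIMEPOINTS[i + 1L]]
    m <- merge(a, b, by = "subject_id", suffixes = c("_a", "_b"))
    if (nrow(m) == 0) next
    out[[i]] <- m[, .(subject_id, t_a = TIMEPOINTS[i],
                      t_b = TIMEPOINTS[i + 1L],
                      d_cortisol = f(cortisol_pg_mg_b) - f(cortisol_pg_mg_a),
                      d_cortisone = f(cortisone_pg_mg_b) -
                        f(cortisone_pg_mg_a))]
  }
  if (!length(out))
    return(data.table::data.table(subject_id = character(),
                                  t_a = character(), t_b = character(),
                                  d_cortisol = numeric(),
                                  d_cortisone = numeric()))
  res <- data.table::rbindlist(out)
  data.table::setorder(res, subject_id, t_a)
  res[]
}
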