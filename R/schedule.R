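## Design constants -----------------------------------------------------------

#' Study design constants
#'
#' Cohorts, timepoints, training modules and hippocampal subfield labels used
#' throughout the package. Subfields are coded per hemisphere as
#' `L_SUB`, `L_CA13`, `L_CA4DG`, `R_SUB`, `R_CA13`, `R_CA4DG`
#' (subiculum, cornu ammonis 1-3, cornu ammonis 4 / dentate gyrus).
#'
#' @name design_constants
#' @keywords internal
NULL

COHORTS    <- c("TC1", "TC2", "TC3", "RCC")
TIMEPOINTS <- c("T0", "T1", "T2", "T3")
MODULES    <- c("Presence", "Affect", "Perspective")
SUBFIELDS  <- c("SUB", "CA13", "CA4DG")
HEMIS      <- c("L", "R")
SUBFIELD_LABELS <- as.vector(outer(HEMIS, SUBFIELDS, paste, sep = "_"))

## Sampling occasions of the diurnal saliva protocol, minutes after awakening.
SALIVA_OFFSETS <- c(0, 30, 60, 240, 360, 480, 600)
## Occasions entering the area-under-curve total output index (the two
## awakening-response samples at 30 and 60 min are excluded by design).
AUCG_OFFSETS <- c(0, 240, 360, 480, 600)

#' Training-module schedule of a cohort
#'
#' Maps a cohort and a consecutive 3-month measurement interval to the
#' training module practised during that interval. The two 9-month training
#' cohorts start with `Presence` and then swap the order of `Affect` and
#' `Perspective` (TC1: Affect then Perspective; TC2: Perspective then
#' Affect), so that each serves as active control for the other. TC3
#' completes a single `Affect` module (first interval only) and the retest
#' control cohort (RCC) trains nothing.
#'
#' @param cohort one of `"TC1"`, `"TC2"`, `"TC3"`, `"RCC"`.
#' @param interval character vector of two consecutive timepoint labels,
#'   e.g. `c("T1", "T2")`.
#' @return A module label (`"Presence"`, `"Affect"`, `"Perspective"`) or
#'   `"retest"` for the control cohort.
#' @examples
#' module_schedule("TC2", c("T1", "T2"))  # "Perspective"
#' module_schedule("RCC", c("T2", "T3"))  # "retest"
#' @export
module_schedule <- function(cohort, interval) {
  cohort <- match.arg(cohort, COHORTS)
  stopifnot(length(interval) == 2L)
  ia <- match(interval[1], TIMEPOINTS)
  ib <- match(interval[2], TIMEPOINTS)
  if (anyNA(c(ia, ib)) || ib - ia != 1L)
    stop("interval must be a consecutive pair among ",
         paste(TIMEPOINTS, collapse = ", "), call. = FALSE)
  if (cohort == "RCC") return("retest")
  key <- paste0("I", ia)  # I1 = (T0,T1), I2 = (T1,T2), I3 = (T2,T3)
  sched <- switch(cohort,
    TC1 = c(I1 = "Presence", I2 = "Affect",      I3 = "Perspective"),
    TC2 = c(I1 = "Presence", I2 = "Perspective", I3 = "Affect"),
    TC3 = c(I1 = "Affect"))
  if (!key %in% names(sched))
    stop("cohort ", cohort, " has no training interval (", interval[1], ",",
         interval[2], ")", call. = FALSE)
  unname(sched[key])
}

#' Measurement timepoints of a cohort
#'
#' TC1, TC2 and RCC are measured at all four timepoints; TC3 only at T0 and
#' T1 (it trained a single module).
#'
#' @param cohort cohort label.
#' @return Character vector of timepoint labels.
#' @export
cohort_timepoints <- function(cohort) {
  cohort <- match.arg(cohort, COHORTS)
  if (cohort == "TC3") TIMEPOINTS[1:2] else TIMEPOINTS
}

#' Consecutive measurement intervals of a cohort
#'
#' @param cohort cohort label.
#' @return A list of length-2 character vectors (Ta, Tb).
#' @export
cohort_intervals <- function(cohort) {
  tp <- cohort_timepoints(cohort)
  lapply(seq_len(length(tp) - 1L), function(i) tp[i:(i + 1L)])
}
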