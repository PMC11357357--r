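## Seed-based functional connectivity on cleaned parcel time series:
## framewise-displacement motion accounting, frame censoring, per-scan
## exclusion, seed-to-parcel correlation profiles (Fisher z, min-max
## rescaled to [0, 1]), baseline top-decile network definition, and network
## and region-level change measures.

#' Framewise displacement of a motion-parameter series
#'
#' Power convention: the sum of absolute frame-to-frame changes of the
#' three translations (mm) plus the three rotations (radians) converted to
#' arc length on a 50 mm sphere. The first frame has no predecessor and is
#' assigned 0.
#'
#' @param motion T x 6 matrix: columns 1-3 translations in mm, 4-6
#'   rotations in radians.
#' @param head_radius_mm sphere radius for the rotation conversion.
#' @return Numeric vector of length T.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  if (nrow(motion) < 2L) stop("motion needs at least 2 frames")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Censor high-motion frames from a scan
#'
#' Frames with framewise displacement at or above `threshold`, together
#' with the immediately preceding and subsequent frames, are removed from
#' the parcel and seed series before correlation (frame deletion is the
#' correlation-equivalent of spike regression).
#'
#' @param parcel_ts T x P matrix of parcel time series.
#' @param seed_ts numeric vector, matrix or list of seed series sharing T.
#' @param fd framewise-displacement series of length T.
#' @param threshold censoring threshold in mm (default 0.5).
#' @return A list: `parcel_ts`, `seed_ts` (censored), `flags` (logical),
#'   `n_censored`, `frac_censored`.
#' @export
scrub <- function(parcel_ts, seed_ts, fd, threshold = 0.5) {
  T_ <- nrow(parcel_ts)
  stopifnot(length(fd) == T_)
  bad <- which(fd >= threshold)
  flags <- rep(FALSE, T_)
  if (length(bad))
    flags[unique(pmin(pmax(c(bad - 1L, bad, bad + 1L), 1L), T_))] <- TRUE
  if (all(flags)) stop("all frames censored at threshold ", threshold)
  keep <- !flags
  cut_seed <- function(s) {
    if (is.list(s)) lapply(s, function(v) v[keep])
    else if (is.matrix(s)) s[keep, , drop = FALSE]
    else s[keep]
  }
  list(parcel_ts = parcel_ts[keep, , drop = FALSE],
       seed_ts = cut_seed(seed_ts), flags = flags,
       n_censored = sum(flags), frac_censored = sum(flags) / T_)
}

#' Exclude scans with excessive mean motion
#'
#' @param scans named list of scans (elements with `motion`,
#'   `subject_id`, `timepoint`).
#' @param mean_fd_limit scans whose mean framewise displacement exceeds
#'   this limit (mm) are dropped.
#' @return A list: `scans` (retained), `exclusions` (data.table with
#'   subject, timepoint and mean FD of dropped scans).
#' @export
exclude_high_motion <- function(scans, mean_fd_limit = 0.3) {
  mfd <- vapply(scans, function(sc) mean(framewise_displacement(sc$motion)),
                0)
  drop <- mfd > mean_fd_limit
  excl <- data.table::data.table(
    subject_id = vapply(scans[drop], `[[`, "", "subject_id"),
    timepoint = vapply(scans[drop], `[[`, "", "timepoint"),
    mean_fd = unname(mfd[drop]))
  list(scans = scans[!drop], exclusions = excl)
}

#' Seed connectivity profile of one scan
#'
#' Pearson correlation between the (scrubbed) seed series and each parcel
#' series, Fisher r-to-z transformed (r clipped to +/-(1 - `clip`) to keep
#' z finite) and min-max rescaled to [0, 1] across the parcels of the
#' profile. Zero-variance parcels yield no correlation; they are excluded
#' from the rescaling extrema and imputed at the profile minimum, with a
#' warning.
#'
#' @param parcel_ts T x P matrix (scrubbed).
#' @param seed numeric seed series of length T with positive variance.
#' @param clip clipping tolerance applied to |r| before `atanh`.
#' @return A list: `values` (rescaled, in [0, 1]), `raw_z` (Fisher z,
#'   `NA` for zero-variance parcels).
#' @export
seed_profile <- function(parcel_ts, seed, clip = 1e-7) {
  if (stats::sd(seed) == 0) stop("seed series has zero variance")
  sds <- apply(parcel_ts, 2L, stats::sd)
  r <- rep(NA_real_, ncol(parcel_ts))
  ok <- sds > 0
  if (any(!ok))
    warning(sum(!ok), " zero-variance parcel(s); imputed at profile minimum")
  r[ok] <- as.vector(stats::cor(seed, parcel_ts[, ok, drop = FALSE]))
  z <- atanh(pmin(pmax(r, -(1 - clip)), 1 - clip))
  rng <- range(z, na.rm = TRUE)
  if (rng[1] == rng[2])
    stop("degenerate profile: all finite z-values identical")
  values <- (z - rng[1]) / (rng[2] - rng[1])
  values[!ok] <- 0  # profile minimum after rescale
  list(values = values, raw_z = z)
}

#' Define a subfield's baseline functional network
#'
#' Averages baseline (T0) connectivity profiles across subjects, restricts
#' to the parcels ipsilateral to the subfield (parcels 1-200 left,
#' 201-400 right) and selects the top `fraction` (ceiling) by mean
#' profile value; ties break toward the lower parcel index. The network is
#' frozen for all later timepoints.
#'
#' @param profiles matrix (subjects x parcels) of baseline profile values
#'   for one subfield, or a list of profile vectors.
#' @param hemisphere `"L"` or `"R"` (the subfield's side).
#' @param fraction fraction of candidate parcels selected (default 0.10).
#' @param ipsilateral restrict candidates to the subfield's hemisphere
#'   (default). If `FALSE`, all parcels are candidates.
#' @return Sorted integer vector of parcel indices (full 400-parcel
#'   indexing).
#' @export
define_network <- function(profiles, hemisphere = c("L", "R"),
                           fraction = 0.10, ipsilateral = TRUE) {
  hemisphere <- match.arg(hemisphere)
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  if (nrow(profiles) < 2L)
    stop("network definition needs at least 2 baseline profiles")
  mp <- colMeans(profiles)
  cand <- if (!ipsilateral) seq_along(mp)
          else if (hemisphere == "L") 1:200 else 201:400
  cand <- cand[cand <= length(mp)]
  if (!length(cand)) stop("empty candidate parcel set")
  ## epsilon guards the ceiling against binary round-up (0.07*200 is not 14)
  k <- ceiling(fraction * length(cand) - 1e-9)
  ord <- cand[order(-mp[cand], cand)]
  sort(ord[seq_len(k)])
}

#' Mean connectivity of a profile over a network
#'
#' @param values profile value vector (length P).
#' @param network integer parcel indices.
#' @return Scalar mean.
#' @export
network_mean_fc <- function(values, network) mean(values[network])

#' Per-parcel connectivity change within a network
#'
#' @param profiles long data.table: `subject_id`, `timepoint`, `parcel`,
#'   `value` for one subfield.
#' @param network integer parcel indices (frozen baseline network).
#' @param interval length-2 character vector `(Ta, Tb)`.
#' @return data.table: `subject_id`, `parcel`, `delta` = value(Tb) -
#'   value(Ta); subjects missing either timepoint are skipped.
#' @export
region_change_table <- function(profiles, network, interval) {
  profiles <- data.table::as.data.table(profiles)
  a <- profiles[timepoint == interval[1] & parcel %in% network]
  b <- profiles[timepoint == interval[2] & parcel %in% network]
  m <- merge(a, b, by = c("subject_id", "parcel"), suffixes = c("_a", "_b"))
  out <- m[, .(subject_id, parcel, delta = value_b - value_a)]
  data.table::setorder(out, subject_id, parcel)
  out[]
}

#' Connectivity profiles and network scores for a whole dataset
#'
#' Runs the full functional stage on the scans of a `cohort_dataset`:
#' framewise displacement, high-motion scan exclusion, frame scrubbing,
#' per-subfield seed profiles, baseline network definition, and mean
#' network connectivity per scan.
#'
#' @param dataset a `cohort_dataset` with an `fmri` block.
#' @param fd_scrub_threshold frame censoring threshold (mm).
#' @param fd_exclude_mean mean-FD scan exclusion limit (mm).
#' @param network_fraction fraction of ipsilateral parcels per network.
#' @return A list: `profiles` (long data.table subject, timepoint,
#'   subfield, parcel, value, raw_z), `networks` (named list of parcel
#'   indices per subfield), `netfc` (data.table subject, timepoint,
#'   subfield, netfc), `exclusions`, `scrub_log`.
#' @export
connectivity_stage <- function(dataset, fd_scrub_threshold = 0.5,
                               fd_exclude_mean = 0.3,
                               network_fraction = 0.10) {
  stopifnot(!is.null(dataset$fmri))
  kept <- exclude_high_motion(dataset$fmri, fd_exclude_mean)
  prof_rows <- list()
  scrub_log <- list()
  for (key in names(kept$scans)) {
    sc <- kept$scans[[key]]
    fd <- framewise_displacement(sc$motion)
    cs <- scrub(sc$parcel_ts, sc$seed_ts, fd, fd_scrub_threshold)
    scrub_log[[key]] <- data.table::data.table(
      subject_id = sc$subject_id, timepoint = sc$timepoint,
      n_censored = cs$n_censored, frac_censored = cs$frac_censored)
    for (sf in names(cs$seed_ts)) {
      pr <- seed_profile(cs$parcel_ts, cs$seed_ts[[sf]])
      prof_rows[[paste(key, sf)]] <- data.table::data.table(
        subject_id = sc$subject_id, timepoint = sc$timepoint,
        subfield = sf, parcel = seq_along(pr$values),
        value = pr$values, raw_z = pr$raw_z)
    }
  }
  profiles <- data.table::rbindlist(prof_rows)
  networks <- list()
  netfc <- NULL
  if (nrow(profiles)) {
    for (sf in unique(profiles$subfield)) {
      base <- profiles[subfield == sf & timepoint == TIMEPOINTS[1]]
      if (length(unique(base$subject_id)) >= 2L) {
        wide <- data.table::dcast(base, subject_id ~ parcel,
                                  value.var = "value")
        mat <- as.matrix(wide[, -1])
        networks[[sf]] <- define_network(mat, sub("_.*", "", sf),
                                         network_fraction)
      }
    }
    nf <- profiles[subfield %in% names(networks),
                   .(netfc = {
                     net <- networks[[subfield[1]]]
                     network_mean_fc(value[match(net, parcel)],
                                     seq_along(net))
                   }),
                   by = .(subject_id, timepoint, subfield)]
    netfc <- nf
  }
  list(profiles = profiles, networks = networks, netfc = netfc,
       exclusions = kept$exclusions,
       scrub_log = data.table::rbindlist(scrub_log))
}
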