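## End-to-end pipeline: simulate -> cortisol indices -> connectivity ->
## change scores -> contrasts / associations -> PLS, driven by one config
## and one root seed, with per-stage record accounting.

#' Pipeline run configuration
#'
#' Collects every stage parameter. All randomness flows from `seed`
#' (stage-specific seeds are derived from it), so a seed plus a config
#' fully determines the run report.
#'
#' @param seed root integer seed.
#' @param out optional output directory; when set, every stage table plus
#'   `report.json` and a human-readable `summary.txt` are written there.
#' @param sim list of overrides passed to [sim_config()] (e.g.
#'   `n_per_cohort`, `module_effects`).
#' @param stages logical toggles: `volumes`, `cortisol`, `hair`, `fmri`,
#'   `contrasts`, `associations`, `pls`.
#' @param cortisol list: `winsorize`, `sd_limit`, `winsorize_scope`,
#'   `use_actual_times`, `hair_log`.
#' @param connectivity list: `fd_scrub_threshold`, `fd_exclude_mean`,
#'   `network_fraction`.
#' @param contrasts list: `names` (see [contrast_arms()]), `correction`
#'   (`"bh"`/`"bonferroni"`), `covariates`.
#' @param pls list: `model` (`"ca13"` or `"all"`), `n_perm`, `n_boot`,
#'   `within_group_perm`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out = NULL, sim = list(),
                       stages = list(), cortisol = list(),
                       connectivity = list(), contrasts = list(),
                       pls = list()) {
  cfg <- list(
    seed = as.integer(seed), out = out, sim = sim,
    stages = utils::modifyList(
      list(volumes = TRUE, cortisol = TRUE, hair = TRUE, fmri = TRUE,
           contrasts = TRUE, associations = TRUE, pls = TRUE), stages),
    cortisol = utils::modifyList(
      list(winsorize = TRUE, sd_limit = 3, winsorize_scope = "occasion",
           use_actual_times = FALSE, hair_log = TRUE), cortisol),
    connectivity = utils::modifyList(
      list(fd_scrub_threshold = 0.5, fd_exclude_mean = 0.3,
           network_fraction = 0.10), connectivity),
    contrasts = utils::modifyList(
      list(names = c("Affect_vs_Perspective", "Presence_vs_ActiveControl"),
           correction = "bh", covariates = TRUE), contrasts),
    pls = utils::modifyList(
      list(model = "ca13", n_perm = 1000, n_boot = 100,
           within_group_perm = FALSE), pls))
  class(cfg) <- "run_config"
  cfg
}

#' Long measure tables from stage outputs
#'
#' Convert stage outputs (volume table, diurnal index table, network
#' connectivity table) into the long `subject_id, timepoint, measure,
#' value` format consumed by [build_change_records()]. Measures are named
#' `volume:<subfield>`, `cortisol:<index>` and `netfc:<subfield>`.
#'
#' @param volumes,indices,netfc stage output tables.
#' @return A long data.table.
#' @export
measures_from_volumes <- function(volumes) {
  v <- data.table::as.data.table(volumes)
  v[, .(subject_id, timepoint, measure = paste0("volume:", subfield),
        value = volume_mm3)]
}

#' @rdname measures_from_volumes
#' @export
measures_from_indices <- function(indices) {
  idx <- data.table::as.data.table(indices)
  data.table::melt(idx[, .(subject_id, timepoint, car, slope, aucg)],
                   id.vars = c("subject_id", "timepoint"),
                   variable.name = "measure", value.name = "value",
                   variable.factor = FALSE)[
    , measure := paste0("cortisol:", measure)][]
}

#' @rdname measures_from_volumes
#' @export
measures_from_netfc <- function(netfc) {
  nf <- data.table::as.data.table(netfc)
  nf[, .(subject_id, timepoint, measure = paste0("netfc:", subfield),
         value = netfc)]
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on a freshly simulated cohort and
#' returns a run report with per-stage accounting, contrast and
#' association tables and the PLS summary. Identical `config` (including
#' seed) yields an identical report.
#'
#' @param config a [run_config()].
#' @return An object of class `run_report` (a nested list; see
#'   [write_report()]).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  stage_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, 4L))
  include <- c("volumes",
               if (st$cortisol) "saliva", if (st$hair) "hair",
               if (st$fmri) "fmri")
  sim_args <- utils::modifyList(config$sim, list(seed = stage_seeds[1]))
  scfg <- do.call(sim_config, sim_args)
  dataset <- simulate_cohort(scfg, include = include)

  ## the output path is not part of the analytic configuration: exclude it
  ## so reports from different directories stay byte-identical
  cfg_echo <- unclass(config)
  cfg_echo$out <- NULL
  report <- list(config = cfg_echo,
                 config_hash = fnv1a32(jsonlite::toJSON(
                   cfg_echo, auto_unbox = TRUE, null = "null")),
                 version = as.character(utils::packageVersion("hippostress")),
                 accounting = list(), counts = list())
  acct <- function(stage, input, retained, excluded) {
    report$accounting[[stage]] <<- list(input = input, retained = retained,
                                        excluded = excluded)
  }

  n_rec <- sum(vapply(dataset$subjects$cohort,
                      function(co) length(cohort_timepoints(co)), 0L))
  if (scfg$missing_rate > 0) {
    dataset <- inject_missingness(dataset, scfg$missing_rate,
                                  seed = stage_seeds[2])
    del <- nrow(attr(dataset, "deleted"))
    acct("missingness", n_rec, n_rec - del, del)
    n_rec <- n_rec - del
  } else acct("missingness", n_rec, n_rec, 0L)
  report$counts$subjects <- nrow(dataset$subjects)
  report$counts$subject_timepoints <- n_rec

  measures <- list(measures_from_volumes(dataset$volumes))

  indices <- NULL
  if (st$cortisol) {
    co <- config$cortisol
    n_in <- nrow(dataset$saliva)
    indices <- diurnal_indices(dataset$saliva, winsorize = co$winsorize,
                               sd_limit = co$sd_limit,
                               winsorize_scope = co$winsorize_scope,
                               use_actual_times = co$use_actual_times)
    acct("saliva_samples", n_in, n_in, 0L)  # invalid rows would warn
    report$counts$cortisol_profiles <- nrow(indices)
    measures <- c(measures, list(measures_from_indices(indices)))
  }

  hair_delta <- NULL
  if (st$hair && !is.null(dataset$hair)) {
    hair_delta <- hair_change(dataset$hair, log = config$cortisol$hair_log)
    report$counts$hair_changes <- nrow(hair_delta)
  }

  conn <- NULL
  if (st$fmri && !is.null(dataset$fmri)) {
    cn <- config$connectivity
    n_scan <- length(dataset$fmri)
    conn <- connectivity_stage(dataset,
                               fd_scrub_threshold = cn$fd_scrub_threshold,
                               fd_exclude_mean = cn$fd_exclude_mean,
                               network_fraction = cn$network_fraction)
    acct("fmri_scans", n_scan, n_scan - nrow(conn$exclusions),
         nrow(conn$exclusions))
    report$counts$networks <- length(conn$networks)
    if (!is.null(conn$netfc))
      measures <- c(measures, list(measures_from_netfc(conn$netfc)))
    ## per-parcel measures within the CA1-3 networks feed the
    ## region-level contrasts (parcel-wise FDR per network)
    for (sf in intersect(c("L_CA13", "R_CA13"), names(conn$networks))) {
      pp <- conn$profiles[subfield == sf & parcel %in% conn$networks[[sf]]]
      measures <- c(measures, list(
        pp[, .(subject_id, timepoint,
               measure = paste0("region:", sf, ":", parcel),
               value = value)]))
    }
  }

  measures <- data.table::rbindlist(measures)
  changes <- build_change_records(measures, dataset$subjects)
  report$counts$change_records <- nrow(changes)

  if (st$contrasts) {
    fam_tabs <- list()
    for (cname in config$contrasts$names) {
      for (fam in c("volume", "netfc", "region:L_CA13", "region:R_CA13")) {
        meas <- grep(paste0("^", fam, ":"), unique(changes$measure),
                     value = TRUE)
        if (!length(meas)) next
        rows <- lapply(meas, function(mm) {
          r <- tryCatch(fit_contrast(changes[measure == mm], cname,
                                     covariates = config$contrasts$covariates),
                        error = function(e) NULL)
          if (is.null(r)) return(NULL)
          data.table::data.table(contrast = cname, family = fam,
                                 measure = mm, t = r$t, df = r$df, p = r$p,
                                 d = r$d, n_a = r$arm_a$n, n_b = r$arm_b$n)
        })
        tab <- data.table::rbindlist(Filter(Negate(is.null), rows))
        if (nrow(tab))
          tab[, q := correct_multiplicity(p, config$contrasts$correction)]
        fam_tabs[[paste(cname, fam)]] <- tab
      }
    }
    report$contrasts <- data.table::rbindlist(fam_tabs, fill = TRUE)
  }

  if (st$associations && !is.null(indices)) {
    assoc <- list()
    brains <- grep("^(volume|netfc):(L|R)_CA13$", unique(changes$measure),
                   value = TRUE)
    for (mod in c("Affect", "overall")) {
      modf <- if (mod == "overall") MODULES else mod
      for (bm in brains) for (cm in c("cortisol:car", "cortisol:slope",
                                      "cortisol:aucg")) {
        r <- tryCatch(associate_change(changes[measure == bm],
                                       changes[measure == cm],
                                       modules = modf),
                      error = function(e) NULL)
        if (is.null(r)) next
        assoc[[paste(mod, bm, cm)]] <- data.table::data.table(
          modules = mod, brain = bm, cortisol = cm, t = r$t, df = r$df,
          p = r$p, slope = r$slope, n = r$n)
      }
    }
    assoc <- data.table::rbindlist(assoc)
    if (nrow(assoc))
      assoc[, q := correct_multiplicity(p, config$contrasts$correction),
            by = modules]
    report$associations <- assoc
  }

  if (st$pls && !is.null(indices)) {
    pls_in <- assemble_pls_input(changes, model = config$pls$model)
    if (!is.null(pls_in)) {
      fit <- behavioral_pls(pls_in$X, pls_in$Y, groups = pls_in$groups,
                            age = pls_in$age, sex = pls_in$sex,
                            subject = pls_in$subject,
                            n_perm = config$pls$n_perm,
                            n_boot = config$pls$n_boot,
                            seed = stage_seeds[3],
                            within_group_perm = config$pls$within_group_perm)
      report$pls <- list(
        model = config$pls$model, n = fit$n,
        brain_vars = colnames(pls_in$X), behavior_vars = colnames(pls_in$Y),
        s = fit$s, covexp = fit$covexp, perm_p = fit$perm_p,
        perm_q = fit$perm_q,
        brain_loadings = fit$brain_loadings[, 1],
        behavior_loadings = fit$behavior_loadings[, 1],
        brain_ci_lc1 = fit$boot$brain_ci[, 1, ],
        behavior_ci_lc1 = fit$boot$behavior_ci[, 1, ],
        expression = fit$expression)
      report$counts$pls_rows <- fit$n
    }
  }

  class(report) <- "run_report"
  if (!is.null(config$out))
    write_report(report, config$out, dataset = dataset, changes = changes,
                 indices = indices, conn = conn, hair_delta = hair_delta)
  report
}

#' Assemble the PLS input matrices from change records
#'
#' Rows are subject-intervals of the three training modules; brain columns
#' are the CA1-3 (model `"ca13"`) or all-subfield (model `"all"`) volume
#' and, when present, network-connectivity change scores; behavior columns
#' are the three diurnal index changes. Complete cases only.
#'
#' @param changes change-record table.
#' @param model `"ca13"` or `"all"`.
#' @return A list `X`, `Y`, `groups`, `age`, `sex`, `subject`, or `NULL`
#'   if fewer than 10 complete rows remain.
#' @export
assemble_pls_input <- function(changes, model = c("ca13", "all")) {
  model <- match.arg(model)
  changes <- data.table::as.data.table(changes)
  sub_pat <- if (model == "ca13") "(L|R)_CA13" else
    paste0("(L|R)_(", paste(SUBFIELDS, collapse = "|"), ")")
  brain_pat <- paste0("^(volume|netfc):", sub_pat, "$")
  dat <- changes[module %in% MODULES]
  wide <- data.table::dcast(dat,
                            subject_id + t_a + t_b + module + age + sex ~
                              measure, value.var = "delta")
  bcols <- grep(brain_pat, names(wide), value = TRUE)
  ycols <- intersect(c("cortisol:car", "cortisol:slope", "cortisol:aucg"),
                     names(wide))
  if (!length(bcols) || !length(ycols)) return(NULL)
  keep <- stats::complete.cases(wide[, c(bcols, ycols), with = FALSE])
  wide <- wide[keep]
  if (nrow(wide) < 10) return(NULL)
  list(X = as.matrix(wide[, bcols, with = FALSE]),
       Y = as.matrix(wide[, ycols, with = FALSE]),
       groups = wide$module, age = wide$age, sex = wide$sex,
       subject = wide$subject_id)
}

#' Write a run report and stage tables to disk
#'
#' `report.json` carries the machine-readable report (deterministic for a
#' given config and seed); `summary.txt` a short human-readable account.
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @param dataset,changes,indices,conn,hair_delta optional stage objects to
#'   serialize alongside.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, dataset = NULL, changes = NULL,
                         indices = NULL, conn = NULL, hair_delta = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass_deep(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(report$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(changes)) write_tsv(changes, file.path(dir, "changes.tsv"))
  if (!is.null(indices))
    write_tsv(indices, file.path(dir, "cortisol_indices.tsv"))
  if (!is.null(hair_delta))
    write_tsv(hair_delta, file.path(dir, "hair_changes.tsv"))
  if (!is.null(conn)) {
    write_tsv(conn$netfc, file.path(dir, "network_fc.tsv"))
    jsonlite::write_json(conn$networks, file.path(dir, "networks.json"),
                         auto_unbox = FALSE)
  }
  if (!is.null(report$contrasts) && nrow(report$contrasts))
    write_tsv(report$contrasts, file.path(dir, "contrasts.tsv"))
  if (!is.null(report$associations) && nrow(report$associations))
    write_tsv(report$associations, file.path(dir, "associations.tsv"))
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    paste("hippostress run, config hash", report$config_hash),
    paste("subjects:", report$counts$subjects),
    paste("subject-timepoints:", report$counts$subject_timepoints),
    if (!is.null(report$contrasts))
      c("contrasts:", utils::capture.output(print(report$contrasts))),
    if (!is.null(report$pls))
      c("PLS:", paste("  LC1 covexp",
                      round(report$pls$covexp[1], 1), "%, perm p",
                      signif(report$pls$perm_p[1], 3)))),
    con)
  invisible(dir)
}

## Recursively strip classes so jsonlite serializes uniformly.
#' @keywords internal
unclass_deep <- function(x) {
  if (data.table::is.data.table(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> hash", x$config_hash, "\n")
  cat("  subjects:", x$counts$subjects, " subject-timepoints:",
      x$counts$subject_timepoints, "\n")
  if (!is.null(x$contrasts) && nrow(x$contrasts)) {
    cat("  contrasts:\n")
    print(x$contrasts)
  }
  if (!is.null(x$pls))
    cat("  PLS LC1: covexp", round(x$pls$covexp[1], 1), "%, perm p",
        signif(x$pls$perm_p[1], 3), "\n")
  invisible(x)
}
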