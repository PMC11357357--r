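## Plain-text serialization of datasets and stage outputs: TSV tables,
## whitespace matrix files for per-scan time series, JSON for configs,
## networks and reports.

#' @keywords internal
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @keywords internal
read_tsv <- function(path) data.table::fread(path, sep = "\t")

#' Write a cohort dataset to a directory
#'
#' Writes `subjects.tsv`, `volumes.tsv`, `saliva.tsv`, `hair.tsv`, the
#' generating truth as `truth.json` (config and planted networks), and one
#' whitespace matrix file per scan block (`scan_<subject>_<tp>_parcels.txt`,
#' `..._seeds.txt`, `..._motion.txt`).
#'
#' @param dataset a `cohort_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(dataset$subjects, file.path(dir, "subjects.tsv"))
  for (blk in c("volumes", "saliva", "hair"))
    if (!is.null(dataset[[blk]]))
      write_tsv(dataset[[blk]], file.path(dir, paste0(blk, ".tsv")))
  if (!is.null(dataset$fmri)) {
    for (key in names(dataset$fmri)) {
      sc <- dataset$fmri[[key]]
      stem <- file.path(dir, paste0("scan_", sc$subject_id, "_",
                                    sc$timepoint))
      utils::write.table(sc$parcel_ts, paste0(stem, "_parcels.txt"),
                         row.names = FALSE, col.names = FALSE)
      seeds <- do.call(cbind, sc$seed_ts)
      utils::write.table(seeds, paste0(stem, "_seeds.txt"),
                         row.names = FALSE,
                         col.names = names(sc$seed_ts))
      utils::write.table(sc$motion, paste0(stem, "_motion.txt"),
                         row.names = FALSE, col.names = TRUE)
    }
  }
  truth <- dataset$truth
  jsonlite::write_json(
    list(config = unclass(truth$config), networks = truth$networks,
         mixers = truth$mixers),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read saliva / hair / subjects / volumes tables
#'
#' Thin readers for the TSV formats written by [write_cohort()] and
#' expected by the command-line stages.
#'
#' @param path file path.
#' @return A data.table.
#' @export
read_saliva <- function(path) read_tsv(path)

#' @rdname read_saliva
#' @export
read_hair <- function(path) read_tsv(path)

#' @rdname read_saliva
#' @export
read_subjects <- function(path) read_tsv(path)

#' @rdname read_saliva
#' @export
read_volumes <- function(path) read_tsv(path)

#' Read the per-scan matrix files of a directory back into a scan list
#'
#' @param dir directory containing `scan_*` files from [write_cohort()].
#' @return Named list of scans (`subject.timepoint` keys).
#' @export
read_scans <- function(dir) {
  stems <- unique(sub("_(parcels|seeds|motion)\\.txt$", "",
                      list.files(dir, pattern = "^scan_.*\\.txt$")))
  scans <- list()
  for (stem in stems) {
    parts <- strsplit(sub("^scan_", "", stem), "_")[[1]]
    tp <- parts[length(parts)]
    sid <- paste(parts[-length(parts)], collapse = "_")
    parcel_ts <- as.matrix(utils::read.table(
      file.path(dir, paste0(stem, "_parcels.txt"))))
    dimnames(parcel_ts) <- NULL
    seeds_df <- utils::read.table(file.path(dir, paste0(stem, "_seeds.txt")),
                                  header = TRUE, check.names = FALSE)
    motion <- as.matrix(utils::read.table(
      file.path(dir, paste0(stem, "_motion.txt")), header = TRUE))
    scans[[paste(sid, tp, sep = ".")]] <-
      list(subject_id = sid, timepoint = tp, parcel_ts = parcel_ts,
           seed_ts = as.list(seeds_df), motion = motion)
  }
  scans
}

## Deterministic 32-bit FNV-1a hash of a string, reported as hex; used to
## fingerprint the effective run configuration.
#' @keywords internal
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    ## 32-bit modular multiply in two 16-bit halves (doubles stay exact)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
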