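# Persistence: cohort containers, component bases, and run result tables.

write_table_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config %s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a cohort to disk
#'
#' Per-subject matrices go into a flat binary array container (`.bin`,
#' little-endian doubles) with a JSON sidecar carrying subject id,
#' dimensions, sampling rate and source labels; the manifest is written as
#' CSV and the configuration as YAML.
#'
#' @param cohort A `"coupling_cohort"` (time-series type).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "coupling_cohort"),
            identical(attr(cohort, "type"), "timeseries"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  yaml::write_yaml(list(n_sources = cfg$n_sources,
                        sampling_rate = cfg$sampling_rate,
                        duration = cfg$duration,
                        carrier_frequencies = cfg$carrier_frequencies,
                        seed = cfg$seed),
                   file.path(dir, "config.yaml"))
  for (id in names(cohort$recordings)) {
    x <- cohort$recordings[[id]]
    writeBin(as.vector(x), file.path(dir, paste0(id, ".bin")),
             size = 8, endian = "little")
    jsonlite::write_json(
      list(subject_id = id, n_sources = nrow(x), n_samples = ncol(x),
           sampling_rate = cfg$sampling_rate,
           source_labels = sprintf("src%02d", seq_len(nrow(x))),
           storage = "float64 little-endian, column-major"),
      file.path(dir, paste0(id, ".json")), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv`, `config.yaml` and the
#'   per-subject `.bin`/`.json` pairs.
#' @return A time-series `"coupling_cohort"`.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  recordings <- lapply(manifest$subject_id, function(id) {
    meta <- jsonlite::read_json(file.path(dir, paste0(id, ".json")),
                                simplifyVector = TRUE)
    v <- readBin(file.path(dir, paste0(id, ".bin")), what = "double",
                 n = meta$n_sources * meta$n_samples, size = 8,
                 endian = "little")
    matrix(v, meta$n_sources, meta$n_samples)
  })
  names(recordings) <- manifest$subject_id
  sim <- sim_config(n_sources = cfg$n_sources,
                    n_patients = max(2L, sum(manifest$group == "patient")),
                    n_controls = max(2L, sum(manifest$group == "control")),
                    n_reference = max(3L, sum(manifest$group == "reference")),
                    sampling_rate = cfg$sampling_rate,
                    duration = cfg$duration,
                    carrier_frequencies = cfg$carrier_frequencies,
                    seed = cfg$seed)
  structure(list(manifest = manifest, recordings = recordings,
                 ground_truth = NULL, config = sim),
            type = "timeseries", class = "coupling_cohort")
}

#' Persist a component basis
#'
#' Eigenvectors and the mean profile are stored as a binary double array
#' with a JSON metadata sidecar, so a basis fit once on a reference cohort
#' can be reused across study cohorts.
#'
#' @param basis A `"component_basis"`.
#' @param path Path prefix (writes `<path>.bin` and `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_component_basis <- function(basis, path) {
  writeBin(c(as.vector(basis$vectors), basis$mean_profile, basis$values),
           paste0(path, ".bin"), size = 8, endian = "little")
  jsonlite::write_json(
    list(mode = basis$mode, frequency = basis$frequency, k = basis$k,
         n_connections = nrow(basis$vectors), n_ref = basis$n_ref,
         layout = "vectors (connections x k), mean_profile, values"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a component basis written by [write_component_basis()]
#' @param path Path prefix used when writing.
#' @return A `"component_basis"`.
#' @export
read_component_basis <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nc <- meta$n_connections
  k <- meta$k
  v <- readBin(paste0(path, ".bin"), what = "double", n = nc * k + nc + k,
               size = 8, endian = "little")
  structure(list(vectors = matrix(v[seq_len(nc * k)], nc, k),
                 values = v[nc * k + nc + seq_len(k)],
                 mean_profile = v[nc * k + seq_len(nc)],
                 k = k, n_ref = meta$n_ref, mode = meta$mode,
                 frequency = meta$frequency),
            class = "component_basis")
}

#' Write all result tables of a pipeline run
#'
#' Emits `selection.tsv` (per-feature scores and significance),
#' `asymmetry.tsv`, `confidence.tsv`, `severity.tsv`, `feature_index.csv`,
#' `manifest.csv`, `accuracy.json` and `run_record.json`. Every TSV starts
#' with a `# config <hash>` header line identifying the configuration.
#'
#' @param run A `"coupling_run"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- run$record$hash
  write_table_hashed(run$fit$selection, file.path(dir, "selection.tsv"), h)
  if (!is.null(run$asymmetry)) {
    write_table_hashed(run$asymmetry, file.path(dir, "asymmetry.tsv"), h)
  }
  if (!is.null(run$confidence)) {
    write_table_hashed(run$confidence, file.path(dir, "confidence.tsv"), h)
  }
  if (!is.null(run$severity)) {
    write_table_hashed(run$severity, file.path(dir, "severity.tsv"), h)
  }
  utils::write.csv(attr(run$features, "feature_index"),
                   file.path(dir, "feature_index.csv"), row.names = FALSE)
  utils::write.csv(run$cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(run$accuracy)) {
    a <- run$accuracy
    jsonlite::write_json(
      list(config = h, sensitivity = a$sensitivity,
           specificity = a$specificity, accuracy = a$accuracy,
           n = as.list(a$n)),
      file.path(dir, "accuracy.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(hash = h, version = run$record$version,
         global_p = run$fit$global_p,
         n_significant = sum(run$fit$selection$significant),
         warnings = run$record$warnings),
    file.path(dir, "run_record.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
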