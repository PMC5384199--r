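#' Write a recording as delimited matrix + JSON sidecar
#'
#' Samples go to `<path>.csv` (one column per channel, one row per sample,
#' full double precision) and metadata (`fs`, `labels`, annotations) to
#' `<path>.json`.
#'
#' @param rec An `ofc_recording`.
#' @param path Output path stem (without extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ofc_recording"))
  utils::write.table(
    format(t(rec$samples), digits = 17, scientific = TRUE, trim = TRUE),
    paste0(path, ".csv"), sep = ",", row.names = FALSE,
    col.names = rec$labels, quote = FALSE)
  ann <- rec$annotations
  ann$protocol <- if (!is.null(ann$protocol)) unclass(ann$protocol)
  jsonlite::write_json(list(fs = rec$fs, labels = rec$labels,
                            annotations = ann),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording from delimited matrix + JSON sidecar
#'
#' @param path Path stem as used by [write_recording()].
#' @return An `ofc_recording`.
#' @export
read_recording <- function(path) {
  csv <- paste0(path, ".csv"); sidecar <- paste0(path, ".json")
  if (!file.exists(csv)) stop("missing samples file: ", csv)
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: expected file ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(csv, check.names = FALSE))
  if (!identical(sort(colnames(m)), sort(meta$labels)))
    stop("sidecar labels do not match sample columns: sidecar has [",
         paste(meta$labels, collapse = ", "), "], csv has [",
         paste(colnames(m), collapse = ", "), "]")
  ann <- meta$annotations %||% list()
  if (!is.null(ann$protocol))
    ann$protocol <- do.call(session_protocol,
                            ann$protocol[setdiff(names(ann$protocol),
                                                 "cond_window")])
  ofc_recording(t(m[, meta$labels, drop = FALSE]), meta$fs, meta$labels,
                annotations = ann)
}

#' Write a connectivity matrix as labeled TSV + JSON metadata
#'
#' @param cm A `connectivity_matrix`.
#' @param path Output path stem.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  utils::write.table(cm$matrix, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  jsonlite::write_json(list(band = cm$band, phase = cm$phase,
                            mode = cm$mode, n_epochs = cm$n_epochs),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Export an epoch set as a 3-column interval table (TSV)
#'
#' Columns phase, start, end; seconds; half-open intervals; time origin at
#' recording start.
#'
#' @param epochs An `epoch_set`.
#' @param path Output file.
#' @export
write_epochs <- function(epochs, path) {
  utils::write.table(as.data.frame(epochs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles everything a pipeline run needs; round-trips losslessly through
#' YAML.
#'
#' @param protocol A `session_protocol`.
#' @param band Analysis band, Hz (default theta).
#' @param mode Connectivity coefficient mode.
#' @param target_pair The channel pair of primary interest.
#' @param seed Integer seed for the synthetic cohorts.
#' @param groups List of `group_spec` objects (their protocols/seeds are
#'   overridden by this config for consistency).
#' @return Object of class `run_config`.
#' @export
run_config <- function(protocol = session_protocol(), band = theta_band(),
                       mode = c("zero-lag", "lagged-max"),
                       target_pair = c("AI_L", "BLA_R"), seed = 1,
                       groups = list(tg_group_spec(), wt_group_spec())) {
  mode <- match.arg(mode)
  structure(list(protocol = protocol, band = band, mode = mode,
                 target_pair = target_pair, seed = as.integer(seed),
                 groups = groups),
            class = "run_config")
}

#' Serialize / restore a run configuration (YAML)
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return [read_run_config()] returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$protocol <- unclass(x$protocol)
  x$groups <- lapply(x$groups, function(g) {
    g <- unclass(g)
    g$protocol <- unclass(g$protocol)
    g
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  proto_args <- function(p) p[setdiff(names(p), "cond_window")]
  groups <- lapply(x$groups, function(g) {
    g$protocol <- do.call(session_protocol, proto_args(g$protocol))
    g$cond_gains <- as.numeric(g$cond_gains)
    do.call(group_spec, g[setdiff(names(g), character())])
  })
  run_config(protocol = do.call(session_protocol, proto_args(x$protocol)),
             band = as.numeric(x$band), mode = x$mode,
             target_pair = as.character(x$target_pair),
             seed = x$seed, groups = groups)
}

# stable short hash of a config (for output provenance)
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(rapply(
    unclass(config), unclass, how = "replace")), auto_unbox = TRUE,
    digits = NA, force = TRUE), tf)
  unname(tools::md5sum(tf))
}
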