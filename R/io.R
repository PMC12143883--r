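#' Serialize and load photometry sessions
#'
#' A session is written as a directory of plain-text files so real exports
#' can be adapted to the same schema: `trace.csv` (`t_s`, `f`),
#' `events.csv` (`behavior`, `start_s`, `end_s`), `epochs.csv`
#' (`stimulus_label`, `stimulus_onset_s`, `epoch_end_s`), and `meta.yaml`
#' (`fs`, `t0_s`, `animal_id`, `condition`).
#'
#' @param session A `photometry_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_photometry_session <- function(session, dir) {
  stopifnot(inherits(session, "photometry_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- session$trace
  utils::write.csv(data.frame(t_s = trace_times(tr), f = tr$samples),
                   file.path(dir, "trace.csv"), row.names = FALSE)
  utils::write.csv(session$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(session$epochs, file.path(dir, "epochs.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(fs = tr$fs, t0_s = tr$t0_s,
                        animal_id = session$animal_id,
                        condition = session$condition),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_photometry_session
#' @return For `read_photometry_session`: a `photometry_session` (without
#'   ground truth, which only generated sessions carry).
#' @export
read_photometry_session <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  tr <- utils::read.csv(file.path(dir, "trace.csv"))
  structure(list(
    trace = photometry_trace(tr$f, fs = meta$fs, t0_s = meta$t0_s),
    events = utils::read.csv(file.path(dir, "events.csv"),
                             stringsAsFactors = FALSE),
    epochs = utils::read.csv(file.path(dir, "epochs.csv"),
                             stringsAsFactors = FALSE),
    animal_id = meta$animal_id,
    condition = meta$condition,
    ground_truth = NULL
  ), class = "photometry_session")
}

#' Read a simulation configuration from YAML
#'
#' The YAML holds any subset of [sim_config()] arguments; missing entries
#' take the defaults. `transient_amp`, `lif_params` and `group_effects` map
#' naturally from YAML mappings.
#'
#' @param path YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in c("transient_amp", "lif_params")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$bout_duration_s)) {
    raw$bout_duration_s <- unlist(raw$bout_duration_s)
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A [sim_config()] to write.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  for (nm in c("transient_amp", "lif_params")) out[[nm]] <- as.list(out[[nm]])
  yaml::write_yaml(out, path)
  invisible(path)
}
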