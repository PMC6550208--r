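#' Write a recording to CSV with a JSON sidecar
#'
#' The CSV carries the channel matrix (`time_s`, `spiro_v`, `rib_ohm`,
#' `abd_ohm`, `ax_v`, `ay_v`, `az_v`); the sidecar JSON carries the sampling
#' rate, flow constant, seed, config hash, and the phase annotations.
#'
#' @param rec A `respiration_recording`.
#' @param csv_path Output CSV path.
#' @param json_path Sidecar path; defaults to `csv_path` with `.json`
#'   appended.
#' @return `csv_path`, invisibly.
#' @export
write_recording <- function(rec, csv_path,
                            json_path = paste0(csv_path, ".json")) {
  stopifnot(inherits(rec, "respiration_recording"))
  utils::write.csv(rec$channels, csv_path, row.names = FALSE)
  meta <- list(fs = rec$fs,
               flow_constant_l_per_sv = rec$flow_constant_l_per_sv,
               seed = rec$seed, config_hash = rec$config_hash,
               annotations = rec$annotations)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(csv_path)
}

#' Read a recording written by [write_recording()]
#'
#' @param csv_path CSV path.
#' @param json_path Sidecar path.
#' @return A `respiration_recording`.
#' @export
read_recording <- function(csv_path, json_path = paste0(csv_path, ".json")) {
  channels <- utils::read.csv(csv_path)
  need <- c("time_s", "spiro_v", "rib_ohm", "abd_ohm", "ax_v", "ay_v", "az_v")
  missing <- setdiff(need, names(channels))
  if (length(missing))
    stop("recording CSV lacks channel(s): ", paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(list(channels = channels, fs = meta$fs,
                 annotations = as.data.frame(meta$annotations),
                 flow_constant_l_per_sv = meta$flow_constant_l_per_sv,
                 seed = meta$seed, config_hash = meta$config_hash),
            class = "respiration_recording")
}

#' Read a generator configuration from a YAML or JSON file
#'
#' Scalar fields override [generator_config()] defaults; `schedule` (a list
#' of phase records) and `motion` are passed through. The file extension
#' selects the parser (`.yaml`/`.yml` vs `.json`).
#'
#' @param path Config file path.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw
  if (!is.null(args$schedule) && !is.data.frame(args$schedule))
    args$schedule <- do.call(rbind, lapply(args$schedule, as.data.frame))
  if (!is.null(args$protocol)) {
    if (is.null(args$schedule))
      args$schedule <- protocol_schedule(args$protocol,
                                         rate_bpm = args$rate_bpm %||% 20)
    args$protocol <- NULL
    args$rate_bpm <- NULL
  }
  for (nm in c("amplitude_levels", "power_params_rib", "power_params_abd"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  known <- names(formals(generator_config))
  do.call(generator_config, args[intersect(names(args), known)])
}

#' Write a breath table to CSV
#'
#' Columns: `breath_id`, `start_s`, `end_s`, `exhaled_l`, `inhaled_l`,
#' `dr_rib_ohm`, `dr_abd_ohm` (when present), `period_s`.
#'
#' @param breaths A `breath_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breaths <- function(breaths, path) {
  cols <- intersect(c("breath_id", "start_s", "end_s", "exhaled_l",
                      "inhaled_l", "dr_rib_ohm", "dr_abd_ohm", "period_s"),
                    names(breaths))
  utils::write.csv(as.data.frame(breaths)[cols], path, row.names = FALSE)
  invisible(path)
}
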