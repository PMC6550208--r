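#' Configuration for an end-to-end analysis session
#'
#' @param protocol One of `"calibration"`, `"paced"`, `"test"`, `"pft"`,
#'   `"motion"`.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed; recorded in every output.
#' @param generator A [generator_config()]; defaults to the protocol's
#'   standard schedule with this seed. Motion defaults are enabled for the
#'   `motion` protocol.
#' @param model_path Path to a calibration-model JSON (required for the
#'   `test`, `pft`, and `motion` prediction stages when `model` is not
#'   given).
#' @param model A `kono_mead` model object (alternative to `model_path`).
#' @param rate_bpm Pacing rate for the `paced` protocol.
#' @param preprocess List of overrides for [preprocess_recording()]
#'   parameters.
#' @return A list of class `session_config`.
#' @export
session_config <- function(protocol = c("calibration", "paced", "test",
                                        "pft", "motion"),
                           out_dir, seed = 1L, generator = NULL,
                           model_path = NULL, model = NULL, rate_bpm = 20,
                           preprocess = list()) {
  protocol <- match.arg(protocol)
  if (is.null(generator)) {
    motion <- if (protocol == "motion")
      list(cadence_hz = 2.09, strain_artifact_amp_ohm = 0.3,
           half_cadence_amp_ohm = 0.1, accel_amp_v = 0.5) else NULL
    generator <- generator_config(protocol_schedule(protocol,
                                                    rate_bpm = rate_bpm),
                                  motion = motion, seed = seed)
  }
  structure(list(protocol = protocol, out_dir = out_dir,
                 seed = as.integer(seed), generator = generator,
                 model_path = model_path, model = model,
                 preprocess = preprocess),
            class = "session_config")
}

#' Run an end-to-end analysis session
#'
#' Generates (or loads) a recording, preprocesses it, segments breaths, and
#' then — depending on the protocol — fits the calibration model
#' (`calibration`), estimates paced rates (`paced`, `motion`), predicts
#' volumes with a previously fitted model and reports agreement (`test`,
#' `motion`), or computes forced-maneuver spirometry (`pft`). All outputs are
#' written under `config$out_dir` stamped with the seed and config hash;
#' rerunning with the same config reproduces them byte for byte.
#'
#' @param config A [session_config()].
#' @return A list (invisibly) with the stage results: `recording`, `truth`,
#'   `breaths`, plus protocol-specific elements (`model`, `rates`,
#'   `agreement`, `pft`) and `files`, the paths written.
#' @export
run_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_recording(config$generator)
  rec <- gen$recording
  prep <- do.call(preprocess_recording,
                  c(list(rec = rec), config$preprocess))
  breaths <- add_delta_r(segment_breaths(prep$flow), prep$rib, prep$abd)
  files <- character(0)
  res <- list(recording = rec, truth = gen$truth, breaths = breaths)
  stamp <- list(seed = config$seed, config_hash = rec$config_hash,
                protocol = config$protocol)
  message(sprintf("[%s] %d breaths segmented (%d in recording ground truth)",
                  config$protocol, nrow(breaths), nrow(gen$truth)))

  write_breaths(breaths, file.path(out, "breaths.csv"))
  files <- c(files, file.path(out, "breaths.csv"))

  if (config$protocol == "calibration") {
    fit <- kono_mead(exhaled_l ~ dr_rib_ohm + dr_abd_ohm, breaths)
    write_calibration(fit, file.path(out, "model.json"))
    files <- c(files, file.path(out, "model.json"))
    res$model <- fit
    writeLines(session_summary(fit, stamp), file.path(out, "summary.txt"))
    files <- c(files, file.path(out, "summary.txt"))
  }

  if (config$protocol %in% c("paced", "motion")) {
    rib <- detrend(prep$rib)
    res$rates <- list(
      period_bpm = estimate_rate_periods(rib),
      fft_hz = estimate_rate_fft(rib),
      motion_cutoff_hz = prep$motion_cutoff_hz)
  }

  if (config$protocol %in% c("test", "motion")) {
    model <- config$model
    if (is.null(model)) {
      if (is.null(config$model_path) || !file.exists(config$model_path %||% ""))
        stop("no calibration model: supply `model` or `model_path`")
      model <- read_calibration(config$model_path)
    }
    pred <- predict(model, breaths)
    results <- data.frame(breath_id = breaths$breath_id,
                          measured_l = breaths$exhaled_l,
                          predicted_l = pred)
    utils::write.csv(results, file.path(out, "predictions.csv"),
                     row.names = FALSE)
    rep <- agreement_report(results$measured_l, results$predicted_l)
    write_agreement(rep, file.path(out, "agreement.json"))
    files <- c(files, file.path(out, c("predictions.csv", "agreement.json")))
    res$agreement <- rep
  }

  if (config$protocol == "pft") {
    model <- config$model %||%
      (if (!is.null(config$model_path)) read_calibration(config$model_path)
       else NULL)
    res$pft <- pft_report(rec, prep, model)
    utils::write.csv(res$pft, file.path(out, "pft.csv"), row.names = FALSE)
    files <- c(files, file.path(out, "pft.csv"))
  }

  jsonlite::write_json(stamp, file.path(out, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  res$files <- c(files, file.path(out, "session.json"))
  invisible(res)
}

# Table-1-style per-subject summary lines for a fitted calibration.
session_summary <- function(fit, stamp) {
  c(sprintf("protocol: %s  seed: %d  config: %s",
            stamp$protocol, stamp$seed, stamp$config_hash),
    sprintf("power_rib_r2: %.4f", fit$rib_power$r2),
    sprintf("power_rib_see_l: %.4f", fit$rib_power$see),
    sprintf("power_abd_r2: %.4f", fit$abd_power$r2),
    sprintf("power_abd_see_l: %.4f", fit$abd_power$see),
    sprintf("mlr_adj_r2: %.4f", fit$adj_r2),
    sprintf("mlr_see_l: %.4f", fit$see),
    sprintf("n_breaths: %d", fit$n))
}

#' Forced-maneuver spirometry for a PFT recording
#'
#' Segments the recording into its annotated forced maneuvers, computes
#' measured FEV1/FVC/FEV1% from the integrated spirometer flow, ranks the
#' maneuvers (top 3 by FVC + FEV1), and — when a calibration model is
#' supplied — the strain-calculated counterparts via
#' [strain_volume_trace()].
#'
#' @param rec A `respiration_recording` with `pft` annotations.
#' @param prep Output of [preprocess_recording()] for `rec`.
#' @param model Optional `kono_mead` model for the calculated columns.
#' @return Data frame with one row per maneuver: measured metrics,
#'   `selected`, and (with a model) `calc_fev1_l`, `calc_fvc_l`,
#'   `calc_fev1_pct`.
#' @export
pft_report <- function(rec, prep, model = NULL) {
  ann <- rec$annotations
  man <- ann[ann$phase == "pft", , drop = FALSE]
  if (!nrow(man)) stop("protocol/data mismatch: recording has no pft phases")
  fs <- rec$fs
  traces <- list(); starts <- integer(0); windows <- list()
  for (i in seq_len(nrow(man))) {
    w <- (round(man$start_s[i] * fs) + 1L):min(round(man$end_s[i] * fs) + 1L,
                                               length(prep$flow$values))
    fl <- sampled_signal(prep$flow$values[w], fs, "L/s")
    i0 <- find_exhale_start(fl)
    vol <- integrate_flow(sampled_signal(pmax(fl$values, 0), fs, "L/s"))
    traces[[i]] <- vol; starts[i] <- i0; windows[[i]] <- w
  }
  out <- rank_maneuvers(traces, starts)
  if (!is.null(model)) {
    calc <- lapply(seq_along(windows), function(i) {
      w <- windows[[i]]
      rib <- sampled_signal(prep$rib$values[w], fs, "ohm")
      abd <- sampled_signal(prep$abd$values[w], fs, "ohm")
      compute_spirometry(strain_volume_trace(model, rib, abd, starts[i]),
                         starts[i])
    })
    out$calc_fev1_l <- vapply(calc, `[[`, numeric(1), "fev1")
    out$calc_fvc_l <- vapply(calc, `[[`, numeric(1), "fvc")
    out$calc_fev1_pct <- vapply(calc, `[[`, numeric(1), "fev1_pct")
  }
  out
}
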