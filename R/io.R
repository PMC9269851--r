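#' Read a trace CSV
#'
#' Expects the header `t,ax,ay,az` with time in seconds and accelerations
#' in m/s^2; time must be strictly increasing and uniformly sampled
#' (within 1% of the median step). The sampling frequency is inferred from
#' the time column.
#'
#' @param path file path.
#' @return A [raw_trace()].
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!identical(names(d), c("t", "ax", "ay", "az")))
    stop("malformed header: expected 't,ax,ay,az', got '",
         paste(names(d), collapse = ","), "'")
  if (!all(vapply(d, is.numeric, TRUE)) || !all(is.finite(as.matrix(d))))
    stop("non-finite values in trace file")
  dt <- diff(d$t)
  if (any(dt <= 0)) stop("non-monotone time column")
  med <- stats::median(dt)
  if (any(abs(dt - med) > 0.01 * med))
    stop("non-uniform sampling: time steps deviate more than 1% from the median")
  raw_trace(as.matrix(d[, c("ax", "ay", "az")]), fs = 1 / med)
}

#' Write a trace CSV
#'
#' Inverse of [read_trace_csv()]; the round trip reproduces the trace to
#' better than 1e-9.
#'
#' @param trace a [raw_trace()].
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  t <- (seq_len(nrow(trace$data)) - 1) / trace$fs
  d <- data.frame(t = t, trace$data)
  utils::write.csv(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Emits `participants.csv`, `trials.csv` (with per-trial file names
#' `P<id>_<condition>_<trial>.csv`), one trace CSV per trial under
#' `traces/`, and per-trial ground-truth JSON (contact times and sides)
#' under `truth/`.
#'
#' @param cohort a [simulate_cohort()] result with traces kept.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  trials <- cohort$trials
  trials$file <- file.path("traces", paste0(trials$trial_id, ".csv"))
  utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  for (i in seq_len(nrow(trials)))
    write_trace_csv(cohort$traces[[trials$trial_id[i]]],
                    file.path(dir, trials$file[i]))
  if (length(cohort$truths)) {
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    for (tid in names(cohort$truths)) {
      tr <- cohort$truths[[tid]]
      jsonlite::write_json(list(ic_times = tr$ic$time, ic_sides = tr$ic$side,
                                duration = tr$duration,
                                true_mean_speed = tr$true_mean_speed),
                           file.path(dir, "truth", paste0(tid, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}

#' Read a cohort directory back into memory
#'
#' @param dir a directory written by [write_cohort()].
#' @return A list with `participants`, `trials` and `traces`, usable by
#'   [process_cohort()].
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("input directory does not exist: ", dir)
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  trials <- utils::read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
  traces <- lapply(stats::setNames(trials$file, trials$trial_id), function(f)
    read_trace_csv(file.path(dir, f)))
  list(participants = participants, trials = trials, traces = traces)
}

#' Run the whole pipeline end to end
#'
#' Simulate (optional, when `cohort` is `NULL`), process and analyse, with
#' outputs and a JSON run manifest (configuration echo, input checksums,
#' package version) written under `out_dir`. Re-running with the same
#' design, seed and configuration regenerates byte-identical outputs.
#'
#' @param out_dir output directory.
#' @param design a [cohort_design()] used when simulating.
#' @param seed master seed for the simulation.
#' @param config a [gait_config()].
#' @param cohort optionally, an existing cohort (as from [read_cohort()]
#'   or [simulate_cohort()]) to process instead of simulating.
#' @return The [analysis_report()] object, invisibly.
#' @export
run_pipeline <- function(out_dir, design = cohort_design(), seed = 1L,
                         config = gait_config(), cohort = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) cohort <- simulate_cohort(design, seed = seed)
  res <- process_cohort(cohort, config)
  utils::write.csv(res$trials, file.path(out_dir, "si_results.csv"), row.names = FALSE)
  utils::write.csv(res$table[, c("participant_id", "group", "condition",
                                 "observed_speed", "predicted_speed",
                                 "normalized_speed")],
                   file.path(out_dir, "speed_results.csv"), row.names = FALSE)
  report <- analysis_report(res$table, out_dir = file.path(out_dir, "report"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("gaitsym")),
    seed = seed,
    config = unclass(config),
    n_participants = nrow(cohort$participants),
    n_trials = nrow(res$trials),
    output_md5 = as.list(tools::md5sum(c(
      file.path(out_dir, "si_results.csv"),
      file.path(out_dir, "speed_results.csv")))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
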