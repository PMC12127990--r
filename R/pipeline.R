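#' Read gaze-sample and trial CSV files
#'
#' Readers for the schemas written by [write_cohort()] (and accepted from
#' user-supplied recordings): gaze samples with columns `participant_id`,
#' `sex` (optional), `trial_index`, `phase`, `cs_type`, `t_sec`, `aoi` (or
#' `x`, `y`); trials with `participant_id`, `trial_index`, `phase`,
#' `cs_type`, `rewarded`. Column presence and value domains are validated.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_gaze_csv <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "trial_index", "t_sec")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("read_gaze_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(g$aoi) && (is.null(g$x) || is.null(g$y)))
    stop("read_gaze_csv: need `aoi` or `x`/`y` columns", call. = FALSE)
  if (!is.null(g$aoi)) {
    bad <- setdiff(unique(g$aoi), c("cs", "reward", "background", "missing"))
    if (length(bad))
      stop("read_gaze_csv: unknown aoi label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(g$t_sec < 0)) stop("read_gaze_csv: negative t_sec", call. = FALSE)
  g$participant_id <- as.character(g$participant_id)
  g
}

#' @rdname read_gaze_csv
#' @export
read_trials_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "trial_index", "phase", "cs_type", "rewarded")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("read_trials_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tr$cs_type), c("csplus", "csminus"))
  if (length(bad))
    stop("read_trials_csv: cs_type must be csplus/csminus", call. = FALSE)
  if (any(tr$rewarded[tr$cs_type == "csminus"] != 0))
    stop("read_trials_csv: CS- trials must never be rewarded", call. = FALSE)
  tr$participant_id <- as.character(tr$participant_id)
  tr
}

#' Run the full phenotyping pipeline and write its artifacts
#'
#' One-call orchestration: simulate a cohort (or ingest gaze/trial CSV
#' files), compute dwell times, phenotype, run the statistical battery, and
#' write everything to `out_dir`:
#' `trials.csv`, `gaze.csv`/`dwell.csv`, `dwell_summary.csv`,
#' `phenotypes.csv`, `report.csv` (flat test table), `report.txt`
#' (human-readable battery) and `manifest.json` (configuration echo, seed
#' and package version — sufficient to reproduce the run). Runs with the
#' same configuration and seed produce byte-identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()] (simulate mode); ignored when files are
#'   given.
#' @param gaze_file,trials_file CSV paths (files mode).
#' @param output Simulated gaze representation, `"samples"` or `"dwell"`.
#' @param window,min_trials,max_missing,aggregate,outlier_k,sample_rate,aoi
#'   Passed to [signtrack()].
#' @return Invisibly, the fitted `signtrack` object, with the written paths
#'   in `attr(, "paths")`.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), gaze_file = NULL,
                         trials_file = NULL,
                         output = c("samples", "dwell"),
                         window = c(1, 5), min_trials = 5, max_missing = 0.5,
                         aggregate = "mean_of_trials", outlier_k = 1.5,
                         sample_rate = NULL, aoi = NULL) {
  output <- match.arg(output)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  simulate <- is.null(gaze_file)
  if (simulate) {
    cohort <- simulate_cohort(config, output = output)
    paths <- write_cohort(cohort, out_dir)
    fit <- signtrack(cohort, window = window, min_trials = min_trials,
                     max_missing = max_missing, aggregate = aggregate,
                     outlier_k = outlier_k, sample_rate = sample_rate)
  } else {
    if (is.null(trials_file))
      stop("run_pipeline: `trials_file` is required with `gaze_file`",
           call. = FALSE)
    gaze <- read_gaze_csv(gaze_file)
    trials <- read_trials_csv(trials_file)
    paths <- character()
    fit <- signtrack(gaze, trials = trials, window = window,
                     min_trials = min_trials, max_missing = max_missing,
                     aggregate = aggregate, outlier_k = outlier_k,
                     sample_rate = sample_rate, aoi = aoi)
  }
  p_dwell <- file.path(out_dir, "dwell_summary.csv")
  utils::write.csv(fit$dwell, p_dwell, row.names = FALSE)
  p_ph <- file.path(out_dir, "phenotypes.csv")
  utils::write.csv(fit$phenotypes, p_ph, row.names = FALSE)
  p_rep <- file.path(out_dir, "report.csv")
  p_txt <- file.path(out_dir, "report.txt")
  if (!is.null(fit$tests)) {
    utils::write.csv(as.data.frame(fit$tests), p_rep, row.names = FALSE)
    con <- file(p_txt, open = "wt")
    sink(con); print(fit$tests); sink(); close(con)
  }
  manifest <- list(
    package = "signtrack",
    version = as.character(utils::packageVersion("signtrack")),
    mode = if (simulate) "simulate" else "files",
    seed = if (simulate) config$seed else NULL,
    config = if (simulate) unclass(config) else
      list(gaze_file = gaze_file, trials_file = trials_file),
    settings = fit$settings,
    n_participants = nrow(fit$phenotypes),
    n_excluded = nrow(fit$excluded)
  )
  p_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA,
                       null = "null")
  attr(fit, "paths") <- c(paths, dwell_summary = p_dwell,
                          phenotypes = p_ph, report = p_rep,
                          report_txt = p_txt, manifest = p_man)
  invisible(fit)
}
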