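#' Area-of-interest screen geometry
#'
#' Defines the CS and reward rectangles on screen, in pixel coordinates with
#' the origin at the top-left corner. Rectangles are half-open:
#' `[x0, x1) x [y0, y1)`, so shared edges never double-assign a sample.
#'
#' @param cs_region,reward_region Numeric vectors `c(x0, y0, x1, y1)`.
#' @param screen Numeric `c(width, height)` in pixels.
#' @return An object of class `"aoi_config"`.
#' @examples
#' aoi <- aoi_config(cs_region = c(760, 100, 1160, 400),
#'                   reward_region = c(760, 680, 1160, 980),
#'                   screen = c(1920, 1080))
#' @export
aoi_config <- function(cs_region, reward_region, screen) {
  chk_rect <- function(r, name) {
    if (!is.numeric(r) || length(r) != 4L || any(!is.finite(r)) ||
        r[1L] >= r[3L] || r[2L] >= r[4L])
      stop("aoi_config: `", name, "` must be c(x0, y0, x1, y1) with x0 < x1, y0 < y1",
           call. = FALSE)
    if (r[1L] < 0 || r[2L] < 0 || r[3L] > screen[1L] || r[4L] > screen[2L])
      stop("aoi_config: `", name, "` extends outside the screen", call. = FALSE)
  }
  if (!is.numeric(screen) || length(screen) != 2L || any(screen <= 0))
    stop("aoi_config: `screen` must be c(width, height) > 0", call. = FALSE)
  chk_rect(cs_region, "cs_region")
  chk_rect(reward_region, "reward_region")
  overlap <- cs_region[1L] < reward_region[3L] &&
    reward_region[1L] < cs_region[3L] &&
    cs_region[2L] < reward_region[4L] &&
    reward_region[2L] < cs_region[4L]
  if (overlap)
    stop("aoi_config: cs_region and reward_region must be disjoint",
         call. = FALSE)
  structure(list(cs_region = cs_region, reward_region = reward_region,
                 screen = screen), class = "aoi_config")
}

#' Assign gaze coordinates to areas of interest
#'
#' Point-in-rectangle test against an [aoi_config()]. Rectangles are
#' half-open, so a point exactly on the right or bottom edge of a region
#' falls outside it. Off-screen or non-finite coordinates are `"missing"`.
#'
#' @param x,y Numeric vectors of pixel coordinates (top-left origin).
#' @param aoi An [aoi_config()].
#' @return Character vector over \{cs, reward, background, missing\}.
#' @examples
#' aoi <- aoi_config(c(0, 0, 100, 100), c(0, 200, 100, 300), c(800, 600))
#' assign_aoi(c(50, 100, -5), c(50, 100, 10), aoi)
#' @export
assign_aoi <- function(x, y, aoi) {
  if (!inherits(aoi, "aoi_config"))
    stop("assign_aoi: coordinates supplied but no valid `aoi_config`",
         call. = FALSE)
  if (length(x) != length(y))
    stop("assign_aoi: x and y lengths differ", call. = FALSE)
  in_rect <- function(r) {
    !is.na(x) & !is.na(y) & x >= r[1L] & x < r[3L] & y >= r[2L] & y < r[4L]
  }
  on_screen <- !is.na(x) & !is.na(y) & is.finite(x) & is.finite(y) &
    x >= 0 & x < aoi$screen[1L] & y >= 0 & y < aoi$screen[2L]
  out <- rep("missing", length(x))
  out[on_screen] <- "background"
  out[on_screen & in_rect(aoi$cs_region)] <- "cs"
  out[on_screen & in_rect(aoi$reward_region)] <- "reward"
  out
}

#' Dwell-time summary of one trial's gaze samples
#'
#' Accumulates AOI dwell times over an analysis window `[start, end)`
#' relative to CS onset. Each sample inside the window contributes one
#' sample period (`1/sample_rate`) to its AOI's total; samples outside the
#' window are ignored; `"missing"` samples are totalled separately.
#' The default window `[1, 5)` excludes the first second of the CS
#' presentation, removing the stimulus-driven orienting response.
#'
#' @param samples Data frame with columns `t_sec` (sorted, seconds from CS
#'   onset) and `aoi`.
#' @param window Numeric `c(start, end)`, half-open, seconds from CS onset.
#' @param sample_rate Sampling rate in Hz. If `NULL`, inferred from the
#'   median timestamp increment.
#' @return One-row data frame: `T_cs`, `T_reward`, `T_background`,
#'   `T_missing`, `window_start`, `window_end`.
#' @examples
#' s <- data.frame(t_sec = (0:299) / 60, aoi = "cs")
#' compute_trial_dwell(s, window = c(1, 5), sample_rate = 60)
#' @export
compute_trial_dwell <- function(samples, window = c(1, 5),
                                sample_rate = NULL) {
  if (length(window) != 2L || !is.numeric(window) || window[1L] >= window[2L])
    stop("compute_trial_dwell: `window` must be c(start, end) with start < end",
         call. = FALSE)
  t <- samples$t_sec
  if (is.unsorted(t))
    stop("compute_trial_dwell: timestamps must be sorted", call. = FALSE)
  if (is.null(sample_rate)) sample_rate <- infer_sample_rate(t)
  period <- 1 / sample_rate
  keep <- t >= window[1L] & t < window[2L]
  a <- samples$aoi[keep]
  data.frame(
    T_cs = sum(a == "cs") * period,
    T_reward = sum(a == "reward") * period,
    T_background = sum(a == "background") * period,
    T_missing = sum(a == "missing") * period,
    window_start = window[1L],
    window_end = window[2L]
  )
}

infer_sample_rate <- function(t) {
  d <- diff(t)
  d <- d[d > 0]
  if (!length(d))
    stop("cannot infer sample rate from timestamps; supply `sample_rate`",
         call. = FALSE)
  1 / stats::median(d)
}

#' Per-trial dwell summaries for a whole gaze table
#'
#' Applies [compute_trial_dwell()] to every (participant, trial) group of a
#' long gaze-sample table. If the table has `x`/`y` columns but no `aoi`
#' column, AOIs are first assigned with [assign_aoi()].
#'
#' @param gaze Data frame with `participant_id`, `trial_index`, `t_sec` and
#'   either `aoi` or `x`,`y` columns.
#' @param window Analysis window `c(start, end)` in seconds from CS onset.
#' @param sample_rate Sampling rate in Hz (inferred when `NULL`).
#' @param aoi An [aoi_config()], required only for coordinate input.
#' @return Data frame with one row per trial: `participant_id`,
#'   `trial_index`, `T_cs`, `T_reward`, `T_background`, `T_missing`,
#'   `window_start`, `window_end`.
#' @export
compute_dwell <- function(gaze, window = c(1, 5), sample_rate = NULL,
                          aoi = NULL) {
  req <- c("participant_id", "trial_index", "t_sec")
  miss <- setdiff(req, names(gaze))
  if (length(miss))
    stop("compute_dwell: gaze table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(gaze$aoi)) {
    if (is.null(gaze$x) || is.null(gaze$y))
      stop("compute_dwell: need either an `aoi` column or `x`/`y` coordinates",
           call. = FALSE)
    gaze$aoi <- assign_aoi(gaze$x, gaze$y, aoi)
  }
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("compute_dwell: invalid `window`", call. = FALSE)
  key <- paste(gaze$participant_id, gaze$trial_index, sep = "\r")
  # timestamps must be non-decreasing within each trial
  ord_ok <- unlist(lapply(split(gaze$t_sec, key), is.unsorted),
                   use.names = FALSE)
  if (any(ord_ok))
    stop("compute_dwell: unsorted timestamps within a trial", call. = FALSE)
  if (is.null(sample_rate)) sample_rate <- infer_sample_rate(gaze$t_sec[
    key == key[1L]])
  period <- 1 / sample_rate
  keep <- gaze$t_sec >= window[1L] & gaze$t_sec < window[2L]
  key_f <- factor(key, levels = unique(key))
  aoi_f <- factor(gaze$aoi, levels = c("cs", "reward", "background", "missing"))
  counts <- table(key_f[keep], aoi_f[keep])
  first <- !duplicated(key_f)
  out <- data.frame(
    participant_id = gaze$participant_id[first],
    trial_index = gaze$trial_index[first],
    T_cs = as.vector(counts[, "cs"]) * period,
    T_reward = as.vector(counts[, "reward"]) * period,
    T_background = as.vector(counts[, "background"]) * period,
    T_missing = as.vector(counts[, "missing"]) * period,
    window_start = window[1L],
    window_end = window[2L],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Filter trials by CS type and task phase
#'
#' The phenotype classification uses CS+ trials from the second half of the
#' task (phase 2), when the CS-reward contingencies have been learned; the
#' attentional-bias control additionally uses the phase-2 CS- trials.
#'
#' @param trials Data frame with at least `cs_type` and `phase` columns.
#' @param cs_type `"csplus"` or `"csminus"`.
#' @param phase Task half, `1` or `2`.
#' @return The matching rows of `trials`. Warns when the result is empty.
#' @examples
#' tr <- data.frame(cs_type = rep(c("csplus", "csminus"), 4),
#'                  phase = rep(1:2, each = 4))
#' select_trials(tr, "csplus", 2)
#' @export
select_trials <- function(trials, cs_type = c("csplus", "csminus"),
                          phase = 2) {
  cs_type <- match.arg(cs_type)
  if (!all(c("cs_type", "phase") %in% names(trials)))
    stop("select_trials: trials table needs `cs_type` and `phase` columns",
         call. = FALSE)
  if (!phase %in% c(1, 2))
    stop("select_trials: `phase` must be 1 or 2", call. = FALSE)
  out <- trials[trials$cs_type == cs_type & trials$phase == phase, ,
                drop = FALSE]
  if (!nrow(out))
    warning(sprintf("select_trials: no %s trials in phase %d", cs_type,
                    phase), call. = FALSE)
  rownames(out) <- NULL
  out
}
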