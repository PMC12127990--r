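#' Gaze index of a trial
#'
#' The sign-tracking statistic: dwell time on the CS location minus dwell
#' time on the reward location, divided by the summed dwell time on the CS,
#' reward and background areas. An index of 1 means the whole window was
#' spent on the CS (maximal sign-tracking); -1 means it was all spent on the
#' reward location (maximal goal-tracking). Missing time is excluded from
#' the denominator; a trial whose denominator is zero (all time missing)
#' yields `NA` and is excluded downstream rather than raising an error.
#'
#' @param T_cs,T_reward,T_background Dwell times in seconds (vectorised).
#'   Alternatively pass a dwell-summary data frame as `T_cs`.
#' @return Numeric vector in `[-1, 1]`, `NA` where undefined.
#' @examples
#' gaze_index(4, 0, 0)    # pure sign-tracker trial -> 1
#' gaze_index(0, 4, 0)    # pure goal-tracker trial -> -1
#' gaze_index(2, 1, 1)    # -> 0.25
#' @export
gaze_index <- function(T_cs, T_reward = NULL, T_background = NULL) {
  if (is.data.frame(T_cs)) {
    d <- T_cs
    T_cs <- d$T_cs; T_reward <- d$T_reward; T_background <- d$T_background
  }
  if (any(stats::na.omit(c(T_cs, T_reward, T_background)) < 0))
    stop("gaze_index: dwell times must be non-negative", call. = FALSE)
  den <- T_cs + T_reward + T_background
  out <- ifelse(den > 0, (T_cs - T_reward) / den, NA_real_)
  as.numeric(out)
}

#' Aggregate per-trial gaze indices to one value per participant
#'
#' Default aggregation is the unweighted mean of the per-trial indices;
#' `"pooled"` instead sums dwell times across trials before forming the
#' ratio, which down-weights trials with more missing time. Participants
#' with fewer than `min_trials` usable trials get `NA`.
#'
#' @param dwell Dwell-summary data frame (rows = trials of one or more
#'   participants) with `participant_id`, `T_cs`, `T_reward`, `T_background`.
#' @param min_trials Minimum usable trials for a defined index (default 5).
#' @param method `"mean_of_trials"` (default) or `"pooled"`.
#' @return Data frame: `participant_id`, `index`, `n_trials_used`.
#' @export
aggregate_participant <- function(dwell, min_trials = 5,
                                  method = c("mean_of_trials", "pooled")) {
  method <- match.arg(method)
  idx <- gaze_index(dwell)
  pid <- factor(dwell$participant_id, levels = unique(dwell$participant_id))
  usable <- !is.na(idx)
  n_used <- as.vector(tapply(usable, pid, sum))
  n_used[is.na(n_used)] <- 0L
  if (method == "mean_of_trials") {
    value <- as.vector(tapply(ifelse(usable, idx, NA_real_), pid, mean,
                              na.rm = TRUE))
  } else {
    sums <- function(v) as.vector(tapply(ifelse(usable, v, 0), pid, sum))
    den <- sums(dwell$T_cs) + sums(dwell$T_reward) + sums(dwell$T_background)
    value <- ifelse(den > 0,
                    (sums(dwell$T_cs) - sums(dwell$T_reward)) / den,
                    NA_real_)
  }
  value[n_used < min_trials] <- NA_real_
  data.frame(participant_id = levels(pid), index = value,
             n_trials_used = as.integer(n_used), stringsAsFactors = FALSE)
}

#' Rank-based tertile phenotype classification
#'
#' Participants are ranked by gaze index (descending) and split into
#' equal-count thirds: the top third are sign-trackers, the middle third
#' intermediates, the bottom third goal-trackers. When `N` is not divisible
#' by 3 the remainder is allocated deterministically: one extra member goes
#' to the top (sign-tracker) tertile; two extras go to the top and bottom
#' tertiles. Ties are broken by participant id in sorted order, so labels do
#' not depend on row order; a warning is raised if tied indices straddle a
#' tertile boundary.
#'
#' @param index Numeric vector of participant gaze indices (no `NA`).
#' @param id Participant identifiers, used for stable tie-breaking.
#' @return Factor with levels `sign_tracker`, `intermediate`, `goal_tracker`,
#'   in the order of the input.
#' @examples
#' classify_tertiles(c(0.9, 0.5, 0.1), id = c("a", "b", "c"))
#' @export
classify_tertiles <- function(index, id = seq_along(index)) {
  n <- length(index)
  if (n < 3L) stop("classify_tertiles: need at least 3 participants",
                   call. = FALSE)
  if (anyNA(index)) stop("classify_tertiles: `index` contains NA",
                         call. = FALSE)
  if (length(id) != n) stop("classify_tertiles: `id` length mismatch",
                            call. = FALSE)
  sizes <- rep(n %/% 3L, 3L)
  r <- n %% 3L
  if (r == 1L) sizes[1L] <- sizes[1L] + 1L
  if (r == 2L) sizes[c(1L, 3L)] <- sizes[c(1L, 3L)] + 1L
  o <- order(-index, xtfrm(id))
  lab_sorted <- rep(c("sign_tracker", "intermediate", "goal_tracker"), sizes)
  # a tie straddling a boundary means the split is order-dependent in the
  # index alone; the id tie-break keeps it deterministic but warn anyway
  bounds <- cumsum(sizes)[1:2]
  sorted_idx <- index[o]
  if (any(sorted_idx[bounds] == sorted_idx[bounds + 1L]))
    warning("classify_tertiles: tied indices at a tertile boundary; ",
            "split resolved by participant id order", call. = FALSE)
  out <- character(n)
  out[o] <- lab_sorted
  factor(out, levels = c("sign_tracker", "intermediate", "goal_tracker"))
}

#' Tukey boxplot outlier flags, per group
#'
#' Flags values outside `[Q1 - k*IQR, Q3 + k*IQR]` within each group
#' (default `k = 1.5`), with quartiles computed by linear interpolation
#' (`stats::quantile()` type 7) — the rule a standard boxplot displays.
#'
#' @param x Numeric values (e.g. participant gaze indices).
#' @param group Grouping vector (e.g. sex); a single group if `NULL`.
#' @param k IQR multiplier (default 1.5).
#' @return Logical vector of outlier flags, `NA` where `x` is `NA`.
#' @examples
#' detect_outliers(c(0.1, 0.2, 0.3, 0.4, 5), group = rep("f", 5))
#' @export
detect_outliers <- function(x, group = NULL, k = 1.5) {
  if (is.null(group)) group <- rep.int(1L, length(x))
  if (length(group) != length(x))
    stop("detect_outliers: `group` length mismatch", call. = FALSE)
  out <- rep(NA, length(x))
  for (g in unique(group[!is.na(x)])) {
    sel <- which(group == g & !is.na(x))
    q <- stats::quantile(x[sel], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2L] - q[1L]
    out[sel] <- x[sel] < q[1L] - k * iqr | x[sel] > q[2L] + k * iqr
  }
  out
}
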