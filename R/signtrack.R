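#' Phenotype a cohort as sign-trackers, intermediates and goal-trackers
#'
#' The main entry point. Takes gaze data from a Pavlovian conditioning task
#' — either a raw gaze-sample stream, a precomputed per-trial dwell table,
#' or an `st_cohort` from [simulate_cohort()] — and runs the full
#' phenotyping pipeline:
#'
#' 1. per-trial AOI dwell times over the analysis `window` (default
#'    `[1, 5)` s from CS onset, excluding the orienting response);
#' 2. the per-trial gaze index `(T_cs - T_reward) / (T_cs + T_reward +
#'    T_background)`, averaged per participant over phase-2 CS+ trials
#'    (classification pathway) and phase-2 CS- trials (attentional-bias
#'    control);
#' 3. rank-based tertile classification of the CS+ index into
#'    sign-trackers / intermediates / goal-trackers;
#' 4. per-sex Tukey outlier flagging of the CS+ index;
#' 5. the statistical battery: Pearson chi-squared on the sex-by-phenotype
#'    table, pooled-variance t-test (with Cohen's d) of the CS+ index
#'    between sexes — run again with outliers excluded — and the mixed
#'    2 x 2 ANOVA (CS type within, sex between) with partial eta squared.
#'
#' Trials with more than `max_missing` of the window missing are dropped;
#' participants with fewer than `min_trials` usable CS+ trials are excluded
#' from classification and the battery, and listed in the result.
#'
#' @param x An `st_cohort`, or a gaze-sample data frame (see
#'   [compute_dwell()] for required columns).
#' @param trials Trial-metadata data frame (`participant_id`, `trial_index`,
#'   `phase`, `cs_type`, `rewarded`). Taken from the cohort if `x` is an
#'   `st_cohort`.
#' @param dwell Optional precomputed dwell table (used instead of `x`).
#' @param sex Participant sex: a data frame with `participant_id` and `sex`,
#'   or a named vector. Taken from the cohort or from a `sex` column of the
#'   gaze table when available.
#' @param window Analysis window in seconds from CS onset (default
#'   `c(1, 5)`).
#' @param sample_rate Sampling rate in Hz; inferred from timestamps when
#'   `NULL`.
#' @param min_trials Minimum usable trials per pathway (default 5).
#' @param max_missing Maximum tolerated fraction of missing time per trial
#'   (default 0.5).
#' @param aggregate Participant aggregation, `"mean_of_trials"` (default) or
#'   `"pooled"`; see [aggregate_participant()].
#' @param outlier_k Tukey IQR multiplier (default 1.5).
#' @param aoi Optional [aoi_config()] when the gaze table carries raw
#'   coordinates.
#' @return An object of class `"signtrack"` with elements `phenotypes`
#'   (participant_id, sex, index_csplus, index_csminus, n_trials_used,
#'   label, outlier), `tests` (an `st_report`, see [test_battery()]),
#'   `dwell`, `excluded`, `settings`.
#' @examples
#' co <- simulate_cohort(sim_config(n_female = 6, n_male = 6, seed = 3),
#'                       output = "dwell")
#' fit <- signtrack(co)
#' fit
#' summary(fit)
#' @export
signtrack <- function(x = NULL, trials = NULL, dwell = NULL, sex = NULL,
                      window = c(1, 5), sample_rate = NULL, min_trials = 5,
                      max_missing = 0.5,
                      aggregate = c("mean_of_trials", "pooled"),
                      outlier_k = 1.5, aoi = NULL) {
  aggregate <- match.arg(aggregate)
  cl <- match.call()
  if (inherits(x, "st_cohort")) {
    trials <- trials %||% x$trials
    sex <- sex %||% x$participants[, c("participant_id", "sex")]
    sample_rate <- sample_rate %||% x$config$sample_rate_hz
    if (is.null(dwell)) {
      if (!is.null(x$dwell)) dwell <- x$dwell else x <- x$gaze
    }
  }
  if (is.null(trials))
    stop("signtrack: a `trials` table is required", call. = FALSE)
  if (is.null(dwell)) {
    if (!is.data.frame(x))
      stop("signtrack: supply gaze samples, a dwell table or an st_cohort",
           call. = FALSE)
    if (is.null(sex) && !is.null(x$sex))
      sex <- unique(x[, c("participant_id", "sex")])
    dwell <- compute_dwell(x, window = window, sample_rate = sample_rate,
                           aoi = aoi)
  }
  sex_map <- normalise_sex(sex)

  win_len <- dwell$window_end - dwell$window_start
  dropped_missing <- dwell$T_missing / win_len > max_missing
  dwell_ok <- dwell[!dropped_missing, , drop = FALSE]

  path_index <- function(cs) {
    sel <- select_trials(trials, cs, phase = 2)
    d <- merge(dwell_ok,
               sel[, c("participant_id", "trial_index")],
               by = c("participant_id", "trial_index"))
    aggregate_participant(d, min_trials = min_trials, method = aggregate)
  }
  agg_plus <- path_index("csplus")
  agg_minus <- suppressWarnings(path_index("csminus"))

  ids <- sort(unique(trials$participant_id))
  ph <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  ph$sex <- sex_map[ph$participant_id]
  ph$index_csplus <- agg_plus$index[match(ids, agg_plus$participant_id)]
  ph$index_csminus <- agg_minus$index[match(ids, agg_minus$participant_id)]
  n_used <- agg_plus$n_trials_used[match(ids, agg_plus$participant_id)]
  ph$n_trials_used <- ifelse(is.na(n_used), 0L, n_used)

  classifiable <- !is.na(ph$index_csplus)
  ph$label <- factor(NA_character_,
                     levels = c("sign_tracker", "intermediate",
                                "goal_tracker"))
  if (sum(classifiable) >= 3L)
    ph$label[classifiable] <- classify_tertiles(
      ph$index_csplus[classifiable], id = ph$participant_id[classifiable])
  ph$outlier <- detect_outliers(ph$index_csplus, group = ph$sex,
                                k = outlier_k)

  excluded <- ph$participant_id[!classifiable]
  tests <- try(test_battery(ph), silent = TRUE)
  if (inherits(tests, "try-error")) tests <- NULL

  structure(list(
    phenotypes = ph,
    tests = tests,
    dwell = dwell,
    excluded = data.frame(
      participant_id = excluded,
      reason = rep("insufficient_data", length(excluded)),
      stringsAsFactors = FALSE
    ),
    n_trials_dropped_missing = sum(dropped_missing),
    settings = list(window = window, min_trials = min_trials,
                    max_missing = max_missing, aggregate = aggregate,
                    outlier_k = outlier_k),
    call = cl
  ), class = "signtrack")
}

normalise_sex <- function(sex) {
  if (is.null(sex)) stop("signtrack: participant sex is required",
                         call. = FALSE)
  if (is.data.frame(sex)) {
    sex <- sex[!duplicated(sex$participant_id), ]
    out <- as.character(sex$sex)
    names(out) <- sex$participant_id
  } else {
    out <- as.character(sex)
    names(out) <- names(sex)
  }
  bad <- setdiff(unique(out), c("female", "male"))
  if (length(bad))
    stop("signtrack: sex must be 'female' or 'male', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  out
}

#' Statistical battery for a phenotyped cohort
#'
#' Assembles and tests the three results of the sign-tracking analysis from
#' a phenotype table: (i) Pearson chi-squared on the sex-by-phenotype
#' contingency table; (ii) pooled-variance t-test of the CS+ gaze index
#' between sexes with Cohen's d, run on all classified participants and
#' again with Tukey outliers removed; (iii) the mixed 2 x 2 ANOVA of the
#' gaze index with CS type (CS+/CS-) within and sex between subjects, with
#' partial eta squared. Also returns descriptives (mean/SD of the index by
#' CS type and by sex).
#'
#' @param phenotypes Data frame with `participant_id`, `sex`,
#'   `index_csplus`, `index_csminus`, `label`, `outlier` (as produced by
#'   [signtrack()]).
#' @param anova_ss `ss_type` passed to [mixed_anova_2x2()].
#' @return An object of class `"st_report"`: list with `contingency`,
#'   `chi2`, `ttest`, `ttest_no_outliers`, `anova`, `descriptives`, `n`.
#' @export
test_battery <- function(phenotypes, anova_ss = "unweighted") {
  ph <- phenotypes[!is.na(phenotypes$index_csplus), , drop = FALSE]
  if (!nrow(ph))
    stop("test_battery: no classified participants", call. = FALSE)
  ph$sex <- factor(ph$sex, levels = c("female", "male"))

  contingency <- table(sex = ph$sex, phenotype = ph$label)
  chi2 <- pearson_chi2(contingency)

  f_idx <- ph$index_csplus[ph$sex == "female"]
  m_idx <- ph$index_csplus[ph$sex == "male"]
  ttest <- independent_t(f_idx, m_idx)
  keep <- !ph$outlier
  tt2 <- independent_t(ph$index_csplus[ph$sex == "female" & keep],
                       ph$index_csplus[ph$sex == "male" & keep])

  both <- !is.na(ph$index_csminus)
  long <- data.frame(
    participant_id = rep(ph$participant_id[both], 2L),
    sex = rep(as.character(ph$sex[both]), 2L),
    cs_type = rep(c("csplus", "csminus"), each = sum(both)),
    index = c(ph$index_csplus[both], ph$index_csminus[both]),
    stringsAsFactors = FALSE
  )
  anova <- mixed_anova_2x2(long, dv = "index", within = "cs_type",
                           between = "sex", id = "participant_id",
                           ss_type = anova_ss)

  desc <- rbind(
    data.frame(group = "csplus", n = sum(both),
               mean = mean(ph$index_csplus[both]),
               sd = stats::sd(ph$index_csplus[both])),
    data.frame(group = "csminus", n = sum(both),
               mean = mean(ph$index_csminus[both]),
               sd = stats::sd(ph$index_csminus[both])),
    data.frame(group = "female", n = length(f_idx), mean = mean(f_idx),
               sd = stats::sd(f_idx)),
    data.frame(group = "male", n = length(m_idx), mean = mean(m_idx),
               sd = stats::sd(m_idx))
  )

  structure(list(contingency = contingency, chi2 = chi2, ttest = ttest,
                 ttest_no_outliers = tt2, anova = anova,
                 descriptives = desc, n = nrow(ph)),
            class = "st_report")
}

#' @export
print.st_report <- function(x, ...) {
  cat("Sign-/goal-tracking statistical battery (n =", x$n, ")\n\n")
  cat("Sex x phenotype contingency:\n")
  print(x$contingency)
  cat(sprintf("\nPearson chi-squared: X2(%d) = %.2f, p = %.3f\n",
              x$chi2$df, x$chi2$statistic, x$chi2$p))
  with(x$ttest, cat(sprintf(
    "\nCS+ gaze index, female vs male:\n  t(%d) = %.2f, p = %.3f, d = %.2f (M = %.2f vs %.2f)\n",
    df, t, p, d, mean[1], mean[2])))
  with(x$ttest_no_outliers, cat(sprintf(
    "  excluding outliers: t(%d) = %.2f, p = %.3f, d = %.2f\n",
    df, t, p, d)))
  cat("\nMixed 2 x 2 ANOVA (CS type within, sex between):\n")
  print(x$anova)
  cat("\nDescriptives (gaze index):\n")
  d <- x$descriptives
  d$mean <- round(d$mean, 3); d$sd <- round(d$sd, 3)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Flatten a test report to one row per test term
#'
#' @param x An `st_report`.
#' @param row.names,optional Ignored (S3 signature).
#' @param ... Ignored.
#' @return Data frame with columns `test`, `term`, `statistic`, `df1`,
#'   `df2`, `p`, `effect_size` — suitable for writing as a flat CSV.
#' @export
as.data.frame.st_report <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  an <- x$anova
  eff <- an[an$term %in% c("between", "within", "interaction"), ]
  term_names <- c(between = "sex", within = "cs_type",
                  interaction = "cs_type:sex")
  err_df <- c(between = an$df[an$term == "subjects"],
              within = an$df[an$term == "within_error"],
              interaction = an$df[an$term == "within_error"])
  out <- rbind(
    data.frame(test = "chi2", term = "sex:phenotype",
               statistic = x$chi2$statistic, df1 = x$chi2$df, df2 = NA,
               p = x$chi2$p, effect_size = NA),
    data.frame(test = "t", term = "sex", statistic = x$ttest$t,
               df1 = x$ttest$df, df2 = NA, p = x$ttest$p,
               effect_size = x$ttest$d),
    data.frame(test = "t_no_outliers", term = "sex",
               statistic = x$ttest_no_outliers$t,
               df1 = x$ttest_no_outliers$df, df2 = NA,
               p = x$ttest_no_outliers$p,
               effect_size = x$ttest_no_outliers$d),
    data.frame(test = "anova", term = term_names[eff$term],
               statistic = eff$F, df1 = eff$df, df2 = err_df[eff$term],
               p = eff$p, effect_size = eff$pes)
  )
  rownames(out) <- NULL
  out
}

#' @export
print.signtrack <- function(x, ...) {
  ph <- x$phenotypes
  cat("Sign-/goal-tracking phenotyping\n")
  cat(sprintf("  %d participants (%d classified, %d insufficient data)\n",
              nrow(ph), sum(!is.na(ph$label)), nrow(x$excluded)))
  if (any(!is.na(ph$label))) {
    tb <- table(ph$sex, ph$label)
    print(tb)
    cat(sprintf("  CS+ gaze index: M = %.3f, SD = %.3f; outliers flagged: %d\n",
                mean(ph$index_csplus, na.rm = TRUE),
                stats::sd(ph$index_csplus, na.rm = TRUE),
                sum(ph$outlier, na.rm = TRUE)))
  }
  cat("  (use summary() for the statistical battery)\n")
  invisible(x)
}

#' @export
summary.signtrack <- function(object, ...) {
  if (is.null(object$tests)) {
    cat("No statistical battery available (too few classified participants)\n")
    return(invisible(object))
  }
  print(object$tests)
  invisible(object$tests)
}

#' @export
coef.signtrack <- function(object, ...) {
  stats::setNames(object$phenotypes$index_csplus,
                  object$phenotypes$participant_id)
}

#' Plot a phenotyped cohort
#'
#' Two base-graphics panels: boxplots of the CS+ gaze index by sex (flagged
#' outliers drawn as open circles), and the sex-by-phenotype counts.
#'
#' @param x A `signtrack` object.
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, `x`.
#' @export
plot.signtrack <- function(x, ...) {
  ph <- x$phenotypes[!is.na(x$phenotypes$index_csplus), ]
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::boxplot(index_csplus ~ sex, data = ph,
                    ylab = "gaze index (CS+)", xlab = "", ...)
  graphics::barplot(table(ph$sex, ph$label), beside = TRUE,
                    legend.text = TRUE, ylab = "participants",
                    names.arg = c("sign", "interm.", "goal"))
  invisible(x)
}
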