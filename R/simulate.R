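#' AOI emission probabilities for a given latent trait
#'
#' Softmax over the three areas of interest with utilities `theta/2` (CS),
#' `-theta/2` (reward) and `log(bg_weight)` (background). The cs-vs-reward
#' log-odds therefore equal `theta`, and as `theta -> +/-Inf` all probability
#' mass moves onto the CS (resp. reward) AOI.
#'
#' @param theta Numeric vector of (trial-level) latent traits.
#' @param bg_weight Background softmax weight.
#' @return Matrix with columns `cs`, `reward`, `background`, rows summing to 1.
#' @keywords internal
aoi_probs <- function(theta, bg_weight) {
  # guard overflow: subtract the max utility before exponentiating
  u <- cbind(cs = theta / 2, reward = -theta / 2,
             background = log(bg_weight))
  m <- pmax(u[, 1L], u[, 2L], u[, 3L])
  e <- exp(u - m)
  p <- e / rowSums(e)
  # infinite trait: all mass on the favoured AOI (softmax limit)
  p[theta == Inf, ] <- rep(c(1, 0, 0), each = sum(theta == Inf))
  p[theta == -Inf, ] <- rep(c(0, 1, 0), each = sum(theta == -Inf))
  p
}

# vectorised draw of (n_cs, n_reward, n_background) counts from a
# per-sample categorical model: binomial chain over `n` samples per trial
draw_aoi_counts <- function(n, p_cs, p_reward) {
  n_cs <- stats::rbinom(length(p_cs), n, p_cs)
  rest <- n - n_cs
  p_rw_cond <- ifelse(p_cs >= 1, 0, pmin(1, p_reward / (1 - p_cs)))
  n_rw <- stats::rbinom(length(p_cs), rest, p_rw_cond)
  cbind(cs = n_cs, reward = n_rw, background = rest - n_rw)
}

# deterministic trial layout for one participant: CS types interleaved as
# evenly as possible (strict alternation when counts are equal), phase 1 =
# first half of the presentation order
trial_layout <- function(n_csplus, n_csminus) {
  pos <- c((seq_len(n_csplus) - 0.5) / n_csplus,
           (seq_len(n_csminus) - 0.5) / n_csminus)
  type <- rep(c("csplus", "csminus"), c(n_csplus, n_csminus))
  type <- type[order(pos)] # stable: CS+ first on exact ties
  n <- n_csplus + n_csminus
  data.frame(trial_index = seq_len(n),
             phase = ifelse(seq_len(n) <= ceiling(n / 2), 1L, 2L),
             cs_type = type,
             stringsAsFactors = FALSE)
}

# all random draws for one participant, in a fixed order shared by both
# output modes so that dwell-mode counts equal sample-mode counts exactly
participant_draws <- function(latent, layout, cfg) {
  n_tot <- nrow(layout)
  is_plus <- layout$cs_type == "csplus"
  rewarded <- integer(n_tot)
  rewarded[is_plus] <- stats::rbinom(sum(is_plus), 1L, cfg$reward_prob_csplus)
  theta <- latent + cfg$cs_effect * is_plus +
    stats::rnorm(n_tot, 0, cfg$noise_sd)
  n_samp <- round(cfg$cs_duration_s * cfg$sample_rate_hz)
  n_orient <- round(cfg$orienting_s * cfg$sample_rate_hz)
  p_or <- c(cfg$p_cs_orienting, (1 - cfg$p_cs_orienting) / 2)
  orient <- draw_aoi_counts(n_orient, rep(p_or[1L], n_tot),
                            rep(p_or[2L], n_tot))
  p <- aoi_probs(theta, cfg$bg_weight)
  window <- draw_aoi_counts(n_samp - n_orient, p[, "cs"], p[, "reward"])
  list(rewarded = rewarded, theta = theta, orient = orient, window = window,
       n_samp = n_samp, n_orient = n_orient)
}

#' Simulate a synthetic Pavlovian eye-tracking cohort
#'
#' Generates a seeded cohort of participants performing the conditioning
#' task: each trial presents a CS for `cs_duration_s` seconds while gaze is
#' sampled at `sample_rate_hz`; CS+ trials are rewarded with probability
#' `reward_prob_csplus`, CS- trials never. Gaze lands on the CS, reward or
#' background AOI according to the participant's latent tracking trait
#' (see [sim_config()]); the first `orienting_s` seconds are dominated by an
#' orienting response toward the CS irrespective of trait. CS+ and CS- trials
#' are interleaved and the first half of each participant's trial sequence is
#' phase 1, the second half phase 2.
#'
#' Randomness is split per participant: the master seed draws one sub-seed
#' per participant, so the cohort is reproducible and participant streams are
#' independent. `output = "samples"` emits the raw per-sample gaze stream;
#' `output = "dwell"` emits per-trial AOI dwell times over the post-orienting
#' analysis window directly. The two modes draw identical AOI counts under
#' the same seed (the sample stream is a uniformly random arrangement of the
#' counted samples), so the dwell mode is an exact fast path for the full
#' sample-level pipeline.
#'
#' @param config A [sim_config()] object.
#' @param output `"samples"` for the raw gaze stream, `"dwell"` for per-trial
#'   dwell summaries.
#' @return An object of class `"st_cohort"`: a list with elements
#'   `participants` (participant_id, sex, latent_trait), `trials`
#'   (participant_id, trial_index, phase, cs_type, rewarded), `config`, and
#'   either `gaze` (participant_id, sex, trial_index, phase, cs_type, t_sec,
#'   aoi) or `dwell` (participant_id, trial_index, T_cs, T_reward,
#'   T_background, T_missing, window_start, window_end).
#' @examples
#' co <- simulate_cohort(sim_config(n_female = 3, n_male = 3, seed = 7))
#' head(co$gaze)
#' table(co$trials$cs_type, co$trials$rewarded)
#' @export
simulate_cohort <- function(config = sim_config(),
                            output = c("samples", "dwell")) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  output <- match.arg(output)
  n_part <- config$n_female + config$n_male
  width <- max(3L, nchar(n_part))
  ids <- sprintf(paste0("P%0", width, "d"), seq_len(n_part))
  sex <- rep(c("female", "male"), c(config$n_female, config$n_male))
  mu <- ifelse(sex == "female", config$trait_mean_female,
               config$trait_mean_male)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_part)

  layout <- trial_layout(config$n_trials_csplus, config$n_trials_csminus)
  n_tot <- nrow(layout)
  rate <- config$sample_rate_hz

  latents <- numeric(n_part)
  rewarded_list <- vector("list", n_part)
  out_list <- vector("list", n_part)
  for (i in seq_len(n_part)) {
    set.seed(sub_seeds[i])
    latents[i] <- stats::rnorm(1L, mu[i], config$trait_sd)
    dr <- participant_draws(latents[i], layout, config)
    rewarded_list[[i]] <- dr$rewarded
    if (output == "dwell") {
      out_list[[i]] <- dr$window
    } else {
      out_list[[i]] <- expand_participant_samples(ids[i], sex[i], layout, dr,
                                                  rate)
    }
  }
  trials <- data.frame(
    participant_id = rep(ids, each = n_tot),
    trial_index = rep(layout$trial_index, n_part),
    phase = rep(layout$phase, n_part),
    cs_type = rep(layout$cs_type, n_part),
    rewarded = unlist(rewarded_list, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  res <- list(
    participants = data.frame(participant_id = ids, sex = sex,
                              latent_trait = latents,
                              stringsAsFactors = FALSE),
    trials = trials,
    config = config
  )
  if (output == "dwell") {
    counts <- do.call(rbind, out_list)
    res$dwell <- data.frame(
      participant_id = rep(ids, each = n_tot),
      trial_index = rep(layout$trial_index, n_part),
      T_cs = counts[, "cs"] / rate,
      T_reward = counts[, "reward"] / rate,
      T_background = counts[, "background"] / rate,
      T_missing = 0,
      window_start = config$orienting_s,
      window_end = config$cs_duration_s,
      stringsAsFactors = FALSE
    )
  } else {
    res$gaze <- do.call(rbind, out_list)
    rownames(res$gaze) <- NULL
  }
  structure(res, class = "st_cohort")
}

# expand one participant's drawn AOI counts into a time-stamped sample
# stream: within each trial segment the labels are uniformly shuffled,
# which together with multinomial counts reproduces i.i.d. sampling
expand_participant_samples <- function(id, sex, layout, dr, rate) {
  n_tot <- nrow(layout)
  lv <- c("cs", "reward", "background")
  per_trial <- vector("list", n_tot)
  t_all <- (seq_len(dr$n_samp) - 1L) / rate
  for (k in seq_len(n_tot)) {
    a_or <- rep(lv, dr$orient[k, ])
    if (length(a_or) > 1L) a_or <- sample(a_or)
    a_wi <- rep(lv, dr$window[k, ])
    if (length(a_wi) > 1L) a_wi <- sample(a_wi)
    per_trial[[k]] <- c(a_or, a_wi)
  }
  data.frame(
    participant_id = id,
    sex = sex,
    trial_index = rep(layout$trial_index, each = dr$n_samp),
    phase = rep(layout$phase, each = dr$n_samp),
    cs_type = rep(layout$cs_type, each = dr$n_samp),
    t_sec = rep(t_all, times = n_tot),
    aoi = unlist(per_trial, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Emit the gaze stream for a single trial
#'
#' Reference per-trial emission: draws the AOI of every gaze sample in the
#' CS window from the trait-dependent categorical model of [sim_config()],
#' with the orienting response governing the first `orienting_s` seconds.
#' Uses the current RNG state.
#'
#' @param participant A list or one-row data frame with at least
#'   `latent_trait` (and optionally `participant_id`, `sex`).
#' @param trial A list or one-row data frame with `trial_index`, `phase`,
#'   `cs_type` (`"csplus"` or `"csminus"`).
#' @param config A [sim_config()] object.
#' @return Data frame of gaze samples with strictly increasing `t_sec` and
#'   `aoi` in \{cs, reward, background\}.
#' @examples
#' set.seed(1)
#' tr <- emit_trial_gaze(list(latent_trait = 2), list(trial_index = 1,
#'   phase = 2, cs_type = "csplus"), sim_config())
#' table(tr$aoi)
#' @export
emit_trial_gaze <- function(participant, trial, config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  lat <- participant$latent_trait
  if (is.null(lat) || length(lat) != 1L || is.na(lat))
    stop("emit_trial_gaze: participant must carry a single `latent_trait`")
  if (is.null(trial$cs_type) || !trial$cs_type %in% c("csplus", "csminus"))
    stop("emit_trial_gaze: trial must have cs_type 'csplus' or 'csminus'")
  layout <- data.frame(trial_index = trial$trial_index %||% 1L,
                       phase = trial$phase %||% 1L,
                       cs_type = trial$cs_type, stringsAsFactors = FALSE)
  dr <- participant_draws(lat, layout, config)
  expand_participant_samples(participant$participant_id %||% "P001",
                             participant$sex %||% NA_character_,
                             layout, dr, config$sample_rate_hz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Write a simulated cohort to CSV files
#'
#' Writes `trials.csv`, `participants.csv` and either `gaze.csv` or
#' `dwell.csv` (whichever the cohort carries) into `dir`, plus a
#' `cohort_meta.json` echoing the generating configuration and seed.
#'
#' @param cohort An `st_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "st_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             participants = file.path(dir, "participants.csv"))
  utils::write.csv(cohort$trials, paths[["trials"]], row.names = FALSE)
  utils::write.csv(cohort$participants, paths[["participants"]],
                   row.names = FALSE)
  if (!is.null(cohort$gaze)) {
    paths <- c(paths, gaze = file.path(dir, "gaze.csv"))
    utils::write.csv(cohort$gaze, paths[["gaze"]], row.names = FALSE)
  }
  if (!is.null(cohort$dwell)) {
    paths <- c(paths, dwell = file.path(dir, "dwell.csv"))
    utils::write.csv(cohort$dwell, paths[["dwell"]], row.names = FALSE)
  }
  meta <- file.path(dir, "cohort_meta.json")
  jsonlite::write_json(unclass(cohort$config), meta, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, meta = meta))
}

#' @export
print.st_cohort <- function(x, ...) {
  n <- nrow(x$participants)
  cat(sprintf("Synthetic conditioning cohort: %d participants (%d female)\n",
              n, sum(x$participants$sex == "female")))
  cat(sprintf("  %d trials/participant; seed %d\n",
              nrow(x$trials) / n, x$config$seed))
  if (!is.null(x$gaze))
    cat(sprintf("  gaze stream: %d samples at %g Hz\n", nrow(x$gaze),
                x$config$sample_rate_hz))
  if (!is.null(x$dwell))
    cat(sprintf("  dwell summaries: %d trials over [%g, %g) s\n",
                nrow(x$dwell), x$dwell$window_start[1L],
                x$dwell$window_end[1L]))
  invisible(x)
}
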