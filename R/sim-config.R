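#' Simulation configuration for a synthetic conditioning cohort
#'
#' Builds and validates the parameter set controlling [simulate_cohort()].
#' Defaults reproduce the task structure of the motivating experiment: a 5 s
#' CS presentation sampled at `sample_rate_hz`, an orienting response
#' concentrated in the first second, CS+ trials rewarded on 80% of
#' presentations and CS- trials never rewarded, and a cohort of 119 female
#' and 113 male participants whose latent tracking trait differs between the
#' sexes by a standardized gaze-index difference of about d = 0.3.
#'
#' The latent trait `theta` is the participant's propensity to fixate the CS
#' location rather than the reward location. Each gaze sample is an
#' independent draw from a 3-way categorical distribution over
#' \{cs, reward, background\} with probabilities proportional to
#' `exp(theta/2)`, `exp(-theta/2)` and `bg_weight`, so the cs-vs-reward
#' log-odds equal `theta` and the gaze index saturates at +/-1 as
#' `theta -> +/-Inf`. During the first `orienting_s` seconds of each trial the
#' CS area of interest instead captures gaze with fixed probability
#' `p_cs_orienting`, regardless of trait.
#'
#' @param n_female,n_male Number of participants per sex. Must be > 0.
#' @param n_trials_csplus,n_trials_csminus Trials per CS type per participant.
#'   Must be > 0.
#' @param cs_duration_s CS presentation length in seconds (default 5).
#' @param orienting_s Initial orienting window in seconds (default 1);
#'   must be shorter than `cs_duration_s`.
#' @param reward_prob_csplus Probability that a CS+ trial ends in reward
#'   (default 0.8). CS- trials are never rewarded.
#' @param sample_rate_hz Gaze sampling rate in samples/second (default 60).
#' @param trait_mean_female,trait_mean_male Latent-trait means per sex.
#'   Defaults (2.375 / 1.825) give a cohort CS+ gaze-index mean near 0.6,
#'   SD near 0.37, a CS- mean near 0.55 and a between-sex d near 0.3.
#' @param trait_sd Between-participant trait SD (common to both sexes).
#' @param noise_sd Trial-to-trial SD of the trait perturbation.
#' @param cs_effect Additive trait shift applied on CS+ trials (default 0.25,
#'   about +0.05 on the gaze index), modelling greater engagement with the
#'   reward-predictive stimulus.
#' @param bg_weight Constant softmax weight of the background AOI
#'   (default 0.4).
#' @param p_cs_orienting Probability of a CS-AOI sample during the orienting
#'   window (default 0.8); the remainder is split evenly between the reward
#'   and background AOIs.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @seealso [simulate_cohort()], [emit_trial_gaze()]
#' @examples
#' cfg <- sim_config(n_female = 4, n_male = 4, seed = 1)
#' cfg
#' @export
sim_config <- function(n_female = 119L,
                       n_male = 113L,
                       n_trials_csplus = 20L,
                       n_trials_csminus = 20L,
                       cs_duration_s = 5,
                       orienting_s = 1,
                       reward_prob_csplus = 0.8,
                       sample_rate_hz = 60,
                       trait_mean_female = 2.375,
                       trait_mean_male = 1.825,
                       trait_sd = 1.7,
                       noise_sd = 0.5,
                       cs_effect = 0.25,
                       bg_weight = 0.4,
                       p_cs_orienting = 0.8,
                       seed = 1L) {
  cfg <- list(
    n_female = n_female, n_male = n_male,
    n_trials_csplus = n_trials_csplus, n_trials_csminus = n_trials_csminus,
    cs_duration_s = cs_duration_s, orienting_s = orienting_s,
    reward_prob_csplus = reward_prob_csplus, sample_rate_hz = sample_rate_hz,
    trait_mean_female = trait_mean_female, trait_mean_male = trait_mean_male,
    trait_sd = trait_sd, noise_sd = noise_sd, cs_effect = cs_effect,
    bg_weight = bg_weight, p_cs_orienting = p_cs_orienting,
    seed = seed
  )
  validate_sim_config(cfg)
  cfg$n_female <- as.integer(n_female)
  cfg$n_male <- as.integer(n_male)
  cfg$n_trials_csplus <- as.integer(n_trials_csplus)
  cfg$n_trials_csminus <- as.integer(n_trials_csminus)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
        v != floor(v)) {
      stop("sim_config: `", field, "` must be a positive integer count",
           call. = FALSE)
    }
  }
  for (f in c("n_female", "n_male", "n_trials_csplus", "n_trials_csminus"))
    chk_count(f)
  chk_num <- function(field, lo = -Inf, hi = Inf, strict_lo = FALSE) {
    v <- cfg[[field]]
    ok <- is.numeric(v) && length(v) == 1L && is.finite(v) &&
      (if (strict_lo) v > lo else v >= lo) && v <= hi
    if (!ok) stop("sim_config: `", field, "` out of range", call. = FALSE)
  }
  chk_num("reward_prob_csplus", 0, 1)
  chk_num("p_cs_orienting", 0, 1)
  chk_num("trait_sd", 0, strict_lo = TRUE)
  chk_num("noise_sd", 0)
  chk_num("bg_weight", 0)
  chk_num("cs_duration_s", 0, strict_lo = TRUE)
  chk_num("orienting_s", 0)
  chk_num("sample_rate_hz", 0, strict_lo = TRUE)
  chk_num("trait_mean_female"); chk_num("trait_mean_male")
  chk_num("cs_effect")
  if (cfg$cs_duration_s <= cfg$orienting_s)
    stop("sim_config: `cs_duration_s` must exceed `orienting_s`", call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed) ||
      cfg$seed != floor(cfg$seed))
    stop("sim_config: `seed` must be a single integer", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  participants: %d female + %d male\n", x$n_female, x$n_male))
  cat(sprintf("  trials/participant: %d CS+ (P(reward)=%.2f), %d CS-\n",
              x$n_trials_csplus, x$reward_prob_csplus, x$n_trials_csminus))
  cat(sprintf("  CS window: %g s at %g Hz (orienting: first %g s)\n",
              x$cs_duration_s, x$sample_rate_hz, x$orienting_s))
  cat(sprintf("  trait: N(%.3f, %.2f^2) female, N(%.3f, %.2f^2) male; trial noise SD %.2f\n",
              x$trait_mean_female, x$trait_sd, x$trait_mean_male, x$trait_sd,
              x$noise_sd))
  cat(sprintf("  emission: softmax(theta/2, -theta/2, log %.2f); CS+ shift %.2f\n",
              x$bg_weight, x$cs_effect))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
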