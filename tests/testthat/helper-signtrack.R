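# shared helpers: small constructors used across test files

# one dwell-summary row from explicit dwell times
dwell_row <- function(T_cs, T_reward, T_background, T_missing = 0,
                      participant_id = "P1", trial_index = 1L,
                      window = c(1, 5)) {
  data.frame(participant_id = participant_id, trial_index = trial_index,
             T_cs = T_cs, T_reward = T_reward, T_background = T_background,
             T_missing = T_missing, window_start = window[1L],
             window_end = window[2L], stringsAsFactors = FALSE)
}

# gaze-sample stream for one trial from per-AOI counts, in [1, 5) at `rate`,
# preceded by `n_pre` orienting samples in [0, 1)
gaze_stream <- function(cs = 0, reward = 0, background = 0, missing = 0,
                        rate = 100, n_pre = 0, pre_aoi = "cs",
                        participant_id = "P1", trial_index = 1L) {
  aoi <- c(rep(pre_aoi, n_pre),
           rep(c("cs", "reward", "background", "missing"),
               c(cs, reward, background, missing)))
  n <- length(aoi)
  t0 <- if (n_pre > 0) 1 - n_pre / rate else 1
  data.frame(participant_id = participant_id, trial_index = trial_index,
             t_sec = t0 + (seq_len(n) - 1L) / rate, aoi = aoi,
             stringsAsFactors = FALSE)
}

# balanced trial table: n_each trials per CS type, halves split evenly
trial_table <- function(n_each = 20, participant_id = "P1") {
  n <- 2L * n_each
  data.frame(participant_id = participant_id, trial_index = seq_len(n),
             phase = ifelse(seq_len(n) <= n / 2, 1L, 2L),
             cs_type = rep(c("csplus", "csminus"), n_each),
             rewarded = 0L, stringsAsFactors = FALSE)
}

# long-format table for the mixed ANOVA from per-sex participant values
anova_long <- function(yp_f, ym_f, yp_m, ym_m) {
  nf <- length(yp_f); nm <- length(yp_m)
  id <- c(sprintf("F%02d", seq_len(nf)), sprintf("M%02d", seq_len(nm)))
  sex <- rep(c("female", "male"), c(nf, nm))
  data.frame(participant_id = rep(id, 2L), sex = rep(sex, 2L),
             cs_type = rep(c("csplus", "csminus"), each = nf + nm),
             index = c(yp_f, yp_m, ym_f, ym_m), stringsAsFactors = FALSE)
}

# null-world configuration: no sex difference, no CS-type effect
null_config <- function(seed, ...) {
  sim_config(trait_mean_female = 2.1, trait_mean_male = 2.1, cs_effect = 0,
             seed = seed, ...)
}
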