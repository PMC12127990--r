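test_that("cohort has the configured composition and trial structure", {
  cfg <- sim_config(n_female = 119, n_male = 113, seed = 1)
  co <- simulate_cohort(cfg, output = "dwell")
  expect_equal(nrow(co$participants), 232)
  expect_equal(sum(co$participants$sex == "female"), 119)
  tr1 <- co$trials[co$trials$participant_id == co$participants$participant_id[1], ]
  expect_equal(nrow(tr1), 40)
  expect_equal(sum(tr1$phase == 1), 20)
  expect_equal(table(tr1$cs_type, tr1$phase)["csplus", "2"], 10)
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(sim_config(n_trials_csplus = 0), "n_trials_csplus")
  expect_error(sim_config(n_female = -1), "n_female")
  expect_error(sim_config(reward_prob_csplus = 1.4), "reward_prob_csplus")
  expect_error(sim_config(trait_sd = 0), "trait_sd")
  expect_error(sim_config(cs_duration_s = 1, orienting_s = 2), "cs_duration_s")
})

test_that("identical seeds give identical cohorts; different seeds differ", {
  cfg <- sim_config(n_female = 5, n_male = 5, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$gaze, b$gaze)
  expect_identical(a$trials, b$trials)
  c3 <- simulate_cohort(sim_config(n_female = 5, n_male = 5, seed = 12))
  expect_false(identical(a$gaze, c3$gaze))
})

test_that("reward contingency: CS- never rewarded, CS+ near reward_prob", {
  co <- simulate_cohort(sim_config(n_female = 30, n_male = 30, seed = 2),
                        output = "dwell")
  tr <- co$trials
  expect_identical(unique(tr$rewarded[tr$cs_type == "csminus"]), 0L)
  p_hat <- mean(tr$rewarded[tr$cs_type == "csplus"])
  n <- sum(tr$cs_type == "csplus") # 1200; binomial 99% CI half-width
  expect_lt(abs(p_hat - 0.8), 2.576 * sqrt(0.8 * 0.2 / n))
})

test_that("timing: every trial emits round(cs_duration * rate) samples", {
  cfg <- sim_config(n_female = 2, n_male = 2, n_trials_csplus = 3,
                    n_trials_csminus = 3, sample_rate_hz = 47,
                    cs_duration_s = 4.5, seed = 3)
  co <- simulate_cohort(cfg)
  per_trial <- table(paste(co$gaze$participant_id, co$gaze$trial_index))
  expect_true(all(per_trial == round(4.5 * 47)))
  # timestamps strictly increasing within a trial
  by_trial <- split(co$gaze$t_sec,
                    paste(co$gaze$participant_id, co$gaze$trial_index))
  expect_true(all(vapply(by_trial, function(t) all(diff(t) > 0), logical(1))))
})

test_that("dwell output mode equals dwell computed from the sample stream", {
  cfg <- sim_config(n_female = 3, n_male = 3, n_trials_csplus = 4,
                    n_trials_csminus = 4, seed = 21)
  dw_direct <- simulate_cohort(cfg, output = "dwell")$dwell
  gz <- simulate_cohort(cfg, output = "samples")$gaze
  dw_from_samples <- compute_dwell(gz, window = c(1, 5), sample_rate = 60)
  cols <- c("T_cs", "T_reward", "T_background")
  expect_equal(dw_direct[cols], dw_from_samples[cols],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("trait saturation drives the trial gaze index to +/-1", {
  cfg <- sim_config(seed = 1)
  set.seed(5)
  hi <- emit_trial_gaze(list(latent_trait = 60),
                        list(trial_index = 1, phase = 2, cs_type = "csplus"),
                        cfg)
  post <- hi$aoi[hi$t_sec >= 1]
  expect_true(all(post == "cs"))
  expect_equal(gaze_index(compute_trial_dwell(hi, c(1, 5), 60)), 1)
  lo <- emit_trial_gaze(list(latent_trait = -60),
                        list(trial_index = 1, phase = 2, cs_type = "csminus"),
                        cfg)
  expect_equal(gaze_index(compute_trial_dwell(lo, c(1, 5), 60)), -1)
})

test_that("expected gaze index increases monotonically in the latent trait", {
  # closed form under the softmax emission: E[index | theta] =
  # (e^{t/2} - e^{-t/2}) / (e^{t/2} + e^{-t/2} + w); check the Monte Carlo
  # mean tracks it and that it is strictly increasing on a trait grid
  cfg <- sim_config(noise_sd = 0, seed = 1)
  grid <- seq(-4, 6, by = 0.5)
  closed <- (exp(grid / 2) - exp(-grid / 2)) /
    (exp(grid / 2) + exp(-grid / 2) + cfg$bg_weight)
  expect_true(all(diff(closed) > 0))
  set.seed(8)
  emp <- vapply(grid, function(th) {
    mean(replicate(40, {
      s <- emit_trial_gaze(list(latent_trait = th),
                           list(trial_index = 1, phase = 2,
                                cs_type = "csminus"), cfg)
      gaze_index(compute_trial_dwell(s, c(1, 5), 60))
    }))
  }, numeric(1))
  expect_lt(max(abs(emp - closed)), 0.06)
})

test_that("orienting window concentrates gaze on the CS regardless of trait", {
  cfg <- sim_config(seed = 1)
  set.seed(9)
  s <- emit_trial_gaze(list(latent_trait = -8),
                       list(trial_index = 1, phase = 1, cs_type = "csplus"),
                       cfg)
  early <- s$aoi[s$t_sec < 1]
  late <- s$aoi[s$t_sec >= 1]
  expect_gt(mean(early == "cs"), 0.6) # emitted at p = 0.8
  expect_lt(mean(late == "cs"), 0.1)  # trait says reward
})

test_that("written cohort CSVs follow the documented schemas", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(n_female = 2, n_male = 2, seed = 4))
  paths <- write_cohort(co, dir)
  gz <- read_gaze_csv(paths[["gaze"]])
  expect_named(gz, c("participant_id", "sex", "trial_index", "phase",
                     "cs_type", "t_sec", "aoi"))
  expect_true(all(gz$aoi %in% c("cs", "reward", "background")))
  tr <- read_trials_csv(paths[["trials"]])
  expect_true(all(tr$rewarded %in% 0:1))
})
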