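test_that("Pearson chi-squared matches hand-computed tables", {
  u <- pearson_chi2(rbind(c(10, 10, 10), c(10, 10, 10)))
  expect_equal(u$statistic, 0)
  expect_equal(u$df, 2L)
  h <- pearson_chi2(rbind(c(20, 10), c(10, 20)))
  expect_equal(h$statistic, 20 / 3, tolerance = 1e-12) # all E = 15
  expect_equal(h$df, 1L)
  expect_error(pearson_chi2(rbind(c(0, 0), c(3, 4))), "margin")
  expect_error(pearson_chi2(rbind(c(0, 2), c(0, 4))), "margin")
})

test_that("chi-squared agrees with brute force and chisq.test on a grid of
           small 2x3 tables", {
  set.seed(42)
  brute <- function(tab) { # direct O/E accumulation, scalar loops
    n <- sum(tab); s <- 0
    for (i in 1:2) for (j in 1:3) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      s <- s + (tab[i, j] - e)^2 / e
    }
    s
  }
  for (rep in 1:200) {
    tab <- matrix(sample(0:6, 6, replace = TRUE), 2, 3)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- pearson_chi2(tab)
    expect_equal(got$statistic, brute(tab), tolerance = 1e-12)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("pooled t-test matches hand computation and t.test", {
  n <- independent_t(c(1, 2, 3), c(1, 2, 3) + 0)
  expect_equal(n$t, 0); expect_equal(n$d, 0)
  h <- independent_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(round(h$t, 4), -1.2247) # pooled SD = 1, se = sqrt(2/3)
  expect_equal(h$d, -1)
  expect_equal(h$df, 4L)
  set.seed(3)
  a <- rnorm(14); b <- rnorm(9, 0.4)
  got <- independent_t(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_error(independent_t(c(1, 1, 1), c(1, 1)), "pooled variance")
})

test_that("d = t * sqrt(1/n1 + 1/n2) holds as an identity of the pooled
           formulation", {
  set.seed(4)
  for (i in 1:20) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    r <- independent_t(rnorm(n1), rnorm(n2, 0.3))
    expect_equal(r$d, cohen_d_from_t(r$t, n1, n2), tolerance = 1e-12)
  }
  expect_equal(cohen_d_from_t(0, 10, 12), 0)
})

test_that("mixed ANOVA: no within-subject effect when CS+ equals CS-", {
  y <- c(0.6, 0.5, 0.4, 0.3, 0.5, 0.2)
  d <- anova_long(y[1:3], y[1:3], y[4:6], y[4:6])
  a <- mixed_anova_2x2(d)
  expect_equal(a$F[a$term == "within"], 0)
  expect_equal(a$F[a$term == "interaction"], 0)
})

test_that("mixed ANOVA reproduces the aov() decomposition on balanced
           constructed examples", {
  set.seed(5)
  for (n_per in c(2, 4, 6)) {
    d <- anova_long(rnorm(n_per, 0.6, 0.3), rnorm(n_per, 0.5, 0.3),
                    rnorm(n_per, 0.4, 0.3), rnorm(n_per, 0.45, 0.3))
    a <- mixed_anova_2x2(d) # unweighted = weighted when balanced
    ref <- summary(stats::aov(index ~ cs_type * sex +
                                Error(participant_id), data = d))
    btw <- ref[["Error: participant_id"]][[1]]
    wth <- ref[["Error: Within"]][[1]]
    rownames(btw) <- trimws(rownames(btw))
    rownames(wth) <- trimws(rownames(wth))
    expect_equal(a$SS[a$term == "between"], btw["sex", "Sum Sq"],
                 tolerance = 1e-10)
    expect_equal(a$SS[a$term == "subjects"], btw["Residuals", "Sum Sq"],
                 tolerance = 1e-10)
    expect_equal(a$F[a$term == "within"], wth["cs_type", "F value"],
                 tolerance = 1e-10)
    expect_equal(a$F[a$term == "interaction"],
                 wth["cs_type:sex", "F value"], tolerance = 1e-10)
    expect_equal(a$p[a$term == "within"], wth["cs_type", "Pr(>F)"],
                 tolerance = 1e-10)
  }
})

test_that("unweighted-means F statistics equal their closed-form contrast
           tests under unequal group sizes", {
  set.seed(6)
  for (i in 1:5) {
    nf <- sample(4:9, 1); nm <- sample(4:9, 1)
    d <- anova_long(rnorm(nf, 0.6, 0.3), rnorm(nf, 0.5, 0.3),
                    rnorm(nm, 0.4, 0.3), rnorm(nm, 0.45, 0.3))
    a <- mixed_anova_2x2(d, ss_type = "unweighted")
    w <- stats::reshape(d, idvar = c("participant_id", "sex"),
                        timevar = "cs_type", direction = "wide")
    dif <- w$index.csplus - w$index.csminus
    avg <- (w$index.csplus + w$index.csminus) / 2
    f <- w$sex == "female"
    # interaction F = pooled t^2 on difference scores
    expect_equal(a$F[a$term == "interaction"],
                 independent_t(dif[f], dif[!f])$t^2, tolerance = 1e-10)
    # between F = pooled t^2 on participant means
    expect_equal(a$F[a$term == "between"],
                 independent_t(avg[f], avg[!f])$t^2, tolerance = 1e-10)
    # within F = harmonic-n test of the unweighted mean difference score
    nh <- 2 / (1 / nf + 1 / nm)
    sp2 <- ((nf - 1) * stats::var(dif[f]) + (nm - 1) * stats::var(dif[!f])) /
      (nf + nm - 2)
    dbar <- (mean(dif[f]) + mean(dif[!f])) / 2
    expect_equal(a$F[a$term == "within"], dbar^2 / (sp2 / (2 * nh)),
                 tolerance = 1e-10)
  }
})

test_that("weighted decomposition is exactly additive and partial eta
           squared matches its F identity", {
  set.seed(8)
  d <- anova_long(rnorm(9, 0.6, 0.3), rnorm(9, 0.5, 0.3),
                  rnorm(6, 0.4, 0.3), rnorm(6, 0.45, 0.3))
  aw <- mixed_anova_2x2(d, ss_type = "weighted")
  sst <- sum((d$index - mean(d$index))^2)
  expect_equal(sum(aw$SS), sst, tolerance = 1e-10)
  for (a in list(aw, mixed_anova_2x2(d))) {
    for (tm in c("between", "within", "interaction")) {
      F <- a$F[a$term == tm]
      df2 <- if (tm == "between") a$df[a$term == "subjects"] else
        a$df[a$term == "within_error"]
      expect_equal(a$pes[a$term == tm], F / (F + df2), tolerance = 1e-12)
    }
  }
})

test_that("participants missing a within level are dropped with a warning", {
  d <- anova_long(c(0.6, 0.5, 0.7), c(0.5, 0.4, 0.6),
                  c(0.4, 0.3, 0.5), c(0.45, 0.35, 0.55))
  d <- d[!(d$participant_id == "F01" & d$cs_type == "csminus"), ]
  expect_warning(a <- mixed_anova_2x2(d), "dropping 1")
  expect_equal(a$df[a$term == "subjects"], 3L) # 5 subjects remain
})

test_that("the battery assembles all three tests with consistent sizes", {
  fit <- signtrack(simulate_cohort(
    sim_config(n_female = 15, n_male = 12, seed = 17), output = "dwell"))
  rep <- fit$tests
  expect_s3_class(rep, "st_report")
  expect_equal(sum(rep$contingency), 27)
  expect_equal(rep$ttest$df, 25L)
  expect_equal(rep$anova$df[rep$anova$term == "subjects"], 25L)
  flat <- as.data.frame(rep)
  expect_named(flat, c("test", "term", "statistic", "df1", "df2", "p",
                       "effect_size"))
  expect_equal(nrow(flat), 6L)
  expect_true(all(flat$p >= 0 & flat$p <= 1))
  expect_error(test_battery(data.frame(participant_id = character(),
                                       sex = character(),
                                       index_csplus = numeric())),
               "no classified")
})
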