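#' Pearson chi-squared test of independence
#'
#' Classic Pearson statistic `sum((O - E)^2 / E)` with expected counts from
#' the row/column margins, `df = (r - 1)(c - 1)` and the p-value from the
#' chi-squared survival function. No continuity correction is applied (the
#' sex-by-phenotype table has df = 2, where the Yates correction is
#' undefined anyway).
#'
#' @param tab Matrix (or table) of non-negative counts, e.g. sex by
#'   phenotype.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @examples
#' pearson_chi2(rbind(c(20, 10), c(10, 20)))
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || anyNA(tab))
    stop("pearson_chi2: counts must be non-negative and complete",
         call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0))
    stop("pearson_chi2: empty row margin: ",
         paste(rownames(tab)[rs == 0] %||% which(rs == 0), collapse = ", "),
         call. = FALSE)
  if (any(cs == 0))
    stop("pearson_chi2: empty column margin: ",
         paste(colnames(tab)[cs == 0] %||% which(cs == 0), collapse = ", "),
         call. = FALSE)
  expected <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), expected = expected)
}

#' Independent-samples t-test with Cohen's d (pooled variance)
#'
#' Two-sample pooled-variance t-test, `df = n1 + n2 - 2`, two-tailed
#' p-value, and Cohen's d computed from the pooled SD. With this
#' formulation `d = t * sqrt(1/n1 + 1/n2)` holds as an identity.
#'
#' @param group_a,group_b Numeric vectors (at least 2 values each).
#' @return List with `t`, `df`, `p`, `d`, and per-group `n`, `mean`, `sd`.
#' @examples
#' independent_t(c(1, 2, 3), c(2, 3, 4))
#' @export
independent_t <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L)
    stop("independent_t: each group needs at least 2 values", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0)
    stop("independent_t: zero pooled variance", call. = FALSE)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean(a) - mean(b)) / se
  df <- n1 + n2 - 2L
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
       d = (mean(a) - mean(b)) / sqrt(sp2),
       n = c(n1, n2), mean = c(mean(a), mean(b)),
       sd = c(stats::sd(a), stats::sd(b)))
}

#' Cohen's d from a pooled t statistic
#'
#' For the pooled-variance two-sample t-test,
#' `d = t * sqrt(1/n1 + 1/n2)` exactly. Useful for recovering the effect
#' size from a published t value and group sizes.
#'
#' @param t Pooled t statistic.
#' @param n1,n2 Group sizes (each at least 2).
#' @return Cohen's d.
#' @examples
#' cohen_d_from_t(2.2, 119, 113)  # ~0.29
#' @export
cohen_d_from_t <- function(t, n1, n2) {
  if (any(c(n1, n2) < 2)) stop("cohen_d_from_t: group sizes must be >= 2",
                               call. = FALSE)
  t * sqrt(1 / n1 + 1 / n2)
}

#' Mixed two-way ANOVA (one within-, one between-subjects factor, 2 x 2)
#'
#' Sums-of-squares decomposition for the classic mixed design: a
#' two-level within-subjects factor (CS type) crossed with a two-level
#' between-subjects factor (sex). The between-subjects effect is tested
#' against subjects-within-groups; the within-subjects main effect and the
#' interaction against the factor-by-subjects-within-groups error. With two
#' within levels sphericity holds trivially, so no correction is applied.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error_effect)`.
#'
#' With unequal group sizes the default `ss_type = "unweighted"` tests
#' unweighted-means hypotheses (cell means weighted equally, harmonic-mean
#' cell size; a Type-III-like solution), appropriate when the imbalance is
#' incidental. `ss_type = "weighted"` uses the hierarchical weighted-means
#' decomposition, which is exactly additive
#' (`SS_total = SS_between + SS_subj + SS_within-effects`) for any group
#' sizes; the two coincide for balanced groups.
#'
#' @param data Long-format data frame: one row per participant x within
#'   level.
#' @param dv,within,between,id Column names of the dependent variable, the
#'   within factor, the between factor and the participant identifier.
#' @param ss_type `"unweighted"` (default) or `"weighted"`.
#' @return An object of class `"st_anova"`: a data frame with one row per
#'   term (`between`, `subjects`, `within`, `interaction`,
#'   `within_error`) and columns `SS`, `df`, `MS`, `F`, `p`, `pes`.
#' @examples
#' d <- data.frame(id = rep(1:6, each = 2), sex = rep(c("f", "m"), each = 6),
#'                 cs = rep(c("plus", "minus"), 6),
#'                 y = c(5, 3, 6, 4, 4, 4, 2, 2, 3, 1, 2, 3))
#' mixed_anova_2x2(d, dv = "y", within = "cs", between = "sex", id = "id")
#' @export
mixed_anova_2x2 <- function(data, dv = "index", within = "cs_type",
                            between = "sex", id = "participant_id",
                            ss_type = c("unweighted", "weighted")) {
  ss_type <- match.arg(ss_type)
  need <- c(dv, within, between, id)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("mixed_anova_2x2: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  y <- data[[dv]]; w <- factor(data[[within]]); b <- factor(data[[between]])
  s <- factor(data[[id]])
  if (nlevels(w) != 2L || nlevels(b) != 2L)
    stop("mixed_anova_2x2: both factors must have exactly 2 levels",
         call. = FALSE)
  ok <- stats::complete.cases(y, w, b, s)
  y <- y[ok]; w <- droplevels(w[ok]); b <- droplevels(b[ok]); s <- factor(s[ok])
  # keep only participants contributing exactly one observation per level
  tab <- table(s, w)
  complete <- rownames(tab)[apply(tab == 1L, 1L, all)]
  if (length(complete) < length(levels(s)))
    warning("mixed_anova_2x2: dropping ",
            length(levels(s)) - length(complete),
            " participant(s) without both within-factor levels",
            call. = FALSE)
  keep <- s %in% complete
  y <- y[keep]; w <- droplevels(w[keep]); b <- droplevels(b[keep])
  s <- factor(s[keep])
  grp <- tapply(as.character(b), s, function(v) v[1L])
  n_j <- table(factor(grp, levels = levels(b)))
  if (any(n_j < 2L))
    stop("mixed_anova_2x2: need at least 2 participants per group",
         call. = FALSE)
  N <- length(levels(s)); K <- 2L; J <- 2L

  subj_mean <- tapply(y, s, mean)
  grp_of_subj <- factor(grp, levels = levels(b))
  cell_mean <- tapply(y, list(b, w), mean)        # J x K weighted cell means
  grp_mean <- tapply(y, b, mean)
  lev_mean <- tapply(y, w, mean)
  grand <- mean(y)

  # error strata (from the raw data, identical under both ss types)
  ss_subj <- K * sum((subj_mean - grp_mean[grp_of_subj])^2)
  resid_within <- y - subj_mean[s] - cell_mean[cbind(b, w)] + grp_mean[b]
  ss_werr <- sum(resid_within^2)

  if (ss_type == "weighted") {
    ss_b <- K * sum(n_j * (grp_mean - grand)^2)
    ss_w <- N * sum((lev_mean - grand)^2)
    int_dev <- sweep(sweep(cell_mean, 1L, grp_mean), 2L, lev_mean) + grand
    ss_int <- K / K * sum(rep(n_j, K) * int_dev^2)
  } else {
    n_h <- J / sum(1 / n_j)
    um_grp <- rowMeans(cell_mean); um_lev <- colMeans(cell_mean)
    um_grand <- mean(cell_mean)
    ss_b <- n_h * K * sum((um_grp - um_grand)^2)
    ss_w <- n_h * J * sum((um_lev - um_grand)^2)
    int_dev <- sweep(sweep(cell_mean, 1L, um_grp), 2L, um_lev) + um_grand
    ss_int <- n_h * sum(int_dev^2)
  }

  df <- c(between = 1L, subjects = N - 2L, within = 1L, interaction = 1L,
          within_error = N - 2L)
  ss <- c(ss_b, ss_subj, ss_w, ss_int, ss_werr)
  ms <- ss / df
  f <- c(ms[1L] / ms[2L], NA, ms[3L] / ms[5L], ms[4L] / ms[5L], NA)
  # a zero effect SS is a zero F even when the error SS is also zero
  eff <- c(1L, 3L, 4L)
  f[eff][ss[eff] == 0] <- 0
  p <- ifelse(is.na(f), NA,
              stats::pf(f, df, df[c(2L, NA, 5L, 5L, NA)], lower.tail = FALSE))
  pes <- c(ss[1L] / (ss[1L] + ss[2L]), NA,
           ss[3L] / (ss[3L] + ss[5L]), ss[4L] / (ss[4L] + ss[5L]), NA)
  pes[eff][ss[eff] == 0] <- 0
  out <- data.frame(term = names(df), SS = ss, df = as.integer(df), MS = ms,
                    F = f, p = p, pes = pes, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ss_type") <- ss_type
  attr(out, "n") <- as.vector(n_j)
  attr(out, "levels") <- list(between = levels(b), within = levels(w))
  class(out) <- c("st_anova", "data.frame")
  out
}

#' @export
print.st_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Mixed 2 x 2 ANOVA (%s means); n = %s\n",
              attr(x, "ss_type"),
              paste(attr(x, "n"), collapse = " + ")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
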