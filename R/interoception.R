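#' Heartbeat-tracking accuracy score
#'
#' Accuracy over a set of counting windows: the mean over trials of
#' \eqn{1 - |rec - count| / rec}, where `rec` is the number of R-peaks
#' recorded during the window and `count` the number of heartbeats the
#' subject reported. Higher scores indicate better interoceptive accuracy.
#' The formula is applied literally: values below 0 are possible when the
#' report overshoots by more than a factor of two, and no clamping is done.
#'
#' @param trials data frame with columns `rec` and `count`, or a vector of
#'   recorded beats when `count` is given separately.
#' @param count reported beats (if `trials` is a vector of recorded beats).
#' @return Scalar accuracy, at most 1.
#' @export
htt_score <- function(trials, count = NULL) {
  if (is.data.frame(trials)) {
    rec <- trials$rec; cnt <- trials$count
  } else {
    rec <- trials; cnt <- count
  }
  if (is.null(rec) || is.null(cnt) || length(rec) == 0L)
    stop_input("need a nonempty set of trials with 'rec' and 'count'")
  if (length(rec) != length(cnt)) stop_input("'rec' and 'count' lengths differ")
  if (any(!is.finite(rec)) || any(rec < 1)) stop_input("all 'rec' must be >= 1")
  if (any(!is.finite(cnt)) || any(cnt < 0)) stop_input("all 'count' must be >= 0")
  mean(1 - abs(rec - cnt) / rec)
}

#' Body-awareness questionnaire sum score
#'
#' Sum of the 26 awareness items, each scored on a 1-5 Likert scale
#' (range 26-130).
#'
#' @param items numeric vector of 26 item responses, or a matrix/data frame
#'   with 26 columns (one row per subject).
#' @return Sum score(s).
#' @export
bpq_awareness_score <- function(items) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.matrix(items)) {
    if (ncol(items) != 26L) stop_input("expected 26 items per subject")
    if (any(!is.finite(items)) || any(items < 1 | items > 5) || any(items != round(items)))
      stop_input("items must be integers in [1, 5]")
    return(rowSums(items))
  }
  if (length(items) != 26L) stop_input("expected 26 items")
  if (any(!is.finite(items)) || any(items < 1 | items > 5) || any(items != round(items)))
    stop_input("items must be integers in [1, 5]")
  sum(items)
}

#' Interoceptive trait prediction error
#'
#' Standardizes accuracy and self-reported awareness over the supplied sample
#' and returns, per subject, z(awareness) - z(accuracy). Positive values
#' indicate a tendency to overestimate one's interoceptive abilities. Within
#' the z-scoring sample the scores sum to zero by construction. Standard
#' deviations use the usual n-1 denominator.
#'
#' @param htt per-subject accuracy scores.
#' @param bpq per-subject awareness sum scores.
#' @param group optional group labels; with `scope = "group"`, z-scoring is
#'   done within each group.
#' @param scope `"combined"` (default; one z-scoring sample) or `"group"`.
#' @return Numeric vector of ITPE scores, same order as the inputs.
#' @export
itpe_scores <- function(htt, bpq, group = NULL, scope = c("combined", "group")) {
  scope <- match.arg(scope)
  if (length(htt) != length(bpq)) stop_input("'htt' and 'bpq' lengths differ")
  if (length(htt) < 2L) stop_input("need at least 2 subjects to z-score")
  if (any(!is.finite(htt)) || any(!is.finite(bpq)))
    stop_input("scores must be finite")
  zfun <- function(x) {
    s <- stats::sd(x)
    if (s < .Machine$double.eps * 100)
      stop_input("zero variance in a score over the z-scoring sample")
    (x - mean(x)) / s
  }
  if (scope == "combined" || is.null(group)) {
    zfun(bpq) - zfun(htt)
  } else {
    out <- numeric(length(htt))
    for (g in unique(group)) {
      i <- which(group == g)
      if (length(i) < 2L) stop_input("group '", g, "' has fewer than 2 subjects")
      out[i] <- zfun(bpq[i]) - zfun(htt[i])
    }
    out
  }
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-tailed p value.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return List with elements `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop_input("each sample needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop_input("samples must be finite")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
  fit <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter), p = fit$p.value)
}

#' Welch one-way ANOVA
#'
#' @param groups list of numeric samples (each n >= 2).
#' @return List with elements `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop_input("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2L)) stop_input("each group needs n >= 2")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (stats::sd(x) == 0)
    return(list(F = 0, df1 = length(groups) - 1, df2 = Inf, p = 1))
  fit <- stats::oneway.test(x ~ g, var.equal = FALSE)
  list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
       df2 = unname(fit$parameter[2]), p = fit$p.value)
}

#' Brown-Forsythe (median-centered) Levene test
#'
#' Variance-homogeneity gate for substituting Welch-adjusted statistics:
#' a one-way ANOVA on absolute deviations from the group medians.
#'
#' @param groups list of numeric samples.
#' @return List with elements `W` (the F statistic on deviations) and `p`.
#' @export
levene_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop_input("need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2L)) stop_input("each group needs n >= 2")
  d <- unlist(lapply(groups, function(x) abs(x - stats::median(x))), use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (stats::sd(d) == 0) return(list(W = 0, p = 1))
  tab <- stats::anova(stats::lm(d ~ g))
  list(W = tab[1, "F value"], p = tab[1, "Pr(>F)"])
}

#' ANCOVA group effect adjusting for body-mass index
#'
#' F test on the group term from the least-squares fit
#' `outcome ~ bmi + group` (group tested after the covariate).
#'
#' @param outcome per-subject score.
#' @param group group labels.
#' @param bmi covariate.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
ancova_group <- function(outcome, group, bmi) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop_input("need >= 2 groups")
  df <- data.frame(outcome = outcome, group = group, bmi = bmi)
  if (any(!stats::complete.cases(df))) stop_input("inputs contain missing values")
  full <- stats::lm(outcome ~ bmi + group, data = df)
  if (full$rank < nlevels(group) + 1L)
    stop_input("rank-deficient design (group confounded with BMI or intercept)")
  reduced <- stats::lm(outcome ~ bmi, data = df)
  tab <- stats::anova(reduced, full)
  list(F = tab[2, "F"], df1 = tab[2, "Df"], df2 = full$df.residual,
       p = tab[2, "Pr(>F)"])
}

#' Benjamini-Hochberg adjusted p values
#'
#' @param pvals vector of raw p values in \[0, 1\].
#' @return Adjusted p values (same order).
#' @export
fdr_bh <- function(pvals) {
  if (length(pvals) == 0L) stop_input("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop_input("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Score a cohort's heartbeat-tracking data
#'
#' Computes per-subject accuracy, awareness and trait-prediction-error scores
#' for all subjects with usable ECG, z-scoring over that combined sample.
#'
#' @param cohort cohort table (see [generate_cohort()]); needs `usable_ecg`
#'   and the 26 `bpq_*` item columns.
#' @param trials long trial table with columns `id`, `rec`, `count`.
#' @param scope passed to [itpe_scores()].
#' @return Data frame `id`, `group`, `htt`, `bpq_awareness`, `itpe` for the
#'   usable-ECG sample.
#' @export
score_cohort <- function(cohort, trials, scope = "combined") {
  usable <- cohort[cohort$usable_ecg, , drop = FALSE]
  if (nrow(usable) < 2L) stop_input("fewer than 2 subjects with usable ECG")
  htt <- vapply(usable$id, function(s) {
    tr <- trials[trials$id == s, , drop = FALSE]
    if (nrow(tr) == 0L) stop_input("no trials for subject ", s)
    htt_score(tr)
  }, 0)
  items <- as.matrix(usable[, sprintf("bpq_%02d", 1:26)])
  bpq <- bpq_awareness_score(items)
  data.frame(id = usable$id, group = usable$group, htt = htt,
             bpq_awareness = bpq,
             itpe = itpe_scores(htt, bpq, group = usable$group, scope = scope),
             row.names = NULL)
}

#' Behavioral group statistics with a variance-homogeneity gate
#'
#' For each score, compares patients (both subtypes pooled) against controls
#' and the three groups jointly. When the Brown-Forsythe test rejects
#' homogeneity at `levene_alpha`, the Welch-adjusted statistic replaces the
#' classical one. Accuracy and trait-prediction-error group effects are also
#' assessed by ANCOVA controlling for BMI. P values are FDR-adjusted across
#' the tested scores.
#'
#' @param scores output of [score_cohort()].
#' @param cohort cohort table (for BMI).
#' @param levene_alpha gate threshold (default 0.05).
#' @return Data frame of tests with raw and adjusted p values.
#' @export
behavioral_group_stats <- function(scores, cohort, levene_alpha = 0.05) {
  bmi <- cohort$bmi[match(scores$id, cohort$id)]
  patient <- scores$group != "HC"
  rows <- list()
  for (sc in c("htt", "bpq_awareness", "itpe")) {
    x <- scores[[sc]]
    a <- x[patient]; b <- x[!patient]
    lev <- levene_test(list(a, b))
    if (lev$p < levene_alpha) {
      tt <- welch_t(a, b); meth <- "welch_t"
    } else {
      f <- stats::t.test(a, b, var.equal = TRUE)
      tt <- list(t = unname(f$statistic), df = unname(f$parameter), p = f$p.value)
      meth <- "student_t"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      score = sc, test = meth, statistic = tt$t, df = tt$df, p = tt$p)
    grps <- split(x, scores$group)
    lev3 <- levene_test(grps)
    if (lev3$p < levene_alpha) {
      av <- welch_anova(grps); meth <- "welch_anova"
    } else {
      fit <- stats::oneway.test(x ~ factor(scores$group), var.equal = TRUE)
      av <- list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
                 df2 = unname(fit$parameter[2]), p = fit$p.value)
      meth <- "anova"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      score = sc, test = meth, statistic = av$F, df = av$df2, p = av$p)
  }
  for (sc in c("htt", "itpe")) {
    an <- ancova_group(scores[[sc]], patient, bmi)
    rows[[length(rows) + 1L]] <- data.frame(
      score = sc, test = "ancova_bmi", statistic = an$F, df = an$df2, p = an$p)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_bh(out$p)
  out
}
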