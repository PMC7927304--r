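#' Specification of a synthetic two-subtype patient/control cohort
#'
#' Defaults emulate the study conditions: 21 patients with functional
#' seizures (FND-seiz), 17 with functional movement disorder (FND-movt) and
#' 38 healthy controls (HC); covariate distributions follow the published
#' group summaries (age, sex ratio, BMI, depression and trait-anxiety
#' scores), head motion is an invented nuisance summary, and true
#' interoceptive accuracy follows the published heartbeat-tracking score
#' distributions truncated to \[0, 1\]. Exactly 3 + 2 patient and 4 control
#' ECG recordings are flagged unusable by default, reproducing the
#' exclusion bookkeeping (33 patients and 34 controls enter accuracy
#' analyses); a stochastic `ecg_dropout` probability can be used instead.
#'
#' @param n_seiz,n_movt,n_hc group sizes.
#' @param age list of `c(mean, sd)` per group (`seiz`, `movt`, `hc`), years.
#' @param sex_prop_f proportion of women per group.
#' @param bmi,head_motion,bdi,stai,accuracy lists of `c(mean, sd)` for
#'   patients (`pat`) and controls (`hc`); accuracy is truncated to \[0, 1\].
#' @param bpq list with `mean`/`sd` per class and `rho`, the latent
#'   correlation between awareness and true accuracy.
#' @param bpq_bias constant added to every subject's latent awareness score
#'   (an over-reporting offset).
#' @param ecg_unusable exact per-group counts of unusable ECGs
#'   (`c(seiz, movt, hc)`), or `NULL` to use `ecg_dropout`.
#' @param ecg_dropout probability any one subject's ECG is unusable (used
#'   when `ecg_unusable` is `NULL`).
#' @param hr_range heart-rate range, bpm (drawn uniformly per subject).
#' @param seed integer seed; every generated quantity is a pure function of
#'   the spec including this seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_seiz = 21, n_movt = 17, n_hc = 38,
                        age = list(seiz = c(23.0, 2.8), movt = c(44.0, 12.7),
                                   hc = c(34.8, 14.1)),
                        sex_prop_f = c(seiz = 19 / 21, movt = 13 / 17, hc = 32 / 38),
                        bmi = list(pat = c(24.3, 5.4), hc = c(23.5, 4.0)),
                        head_motion = list(pat = c(0.45, 0.15), hc = c(0.40, 0.12)),
                        bdi = list(pat = c(20.1, 11.5), hc = c(11.0, 6.9)),
                        stai = list(pat = c(39.0, 9.6), hc = c(32.9, 9.5)),
                        accuracy = list(pat = c(0.63, 0.26), hc = c(0.70, 0.21)),
                        bpq = list(pat = c(112.6, 28.1), hc = c(100.4, 26.8), rho = 0.3),
                        bpq_bias = 0,
                        ecg_unusable = c(seiz = 3, movt = 2, hc = 4),
                        ecg_dropout = NULL,
                        hr_range = c(55, 95),
                        seed = 1L) {
  for (n in c(n_seiz, n_movt, n_hc)) check_count(n, "group size")
  dists <- c(age, bmi, head_motion, bdi, stai, accuracy,
             list(bpq$pat, bpq$hc))
  for (d in dists) {
    if (length(d) != 2L || !all(is.finite(d)) || d[2] <= 0)
      stop_input("distribution parameters must be c(mean, sd) with sd > 0")
  }
  if (any(sex_prop_f < 0 | sex_prop_f > 1)) stop_input("sex proportions must be in [0, 1]")
  sex_prop_f <- stats::setNames(rep_len(unname(sex_prop_f), 3L), c("seiz", "movt", "hc"))
  if (!is.null(ecg_dropout)) check_number(ecg_dropout, "ecg_dropout", 0, 1)
  if (!is.null(ecg_unusable) && is.null(ecg_dropout)) {
    if (length(ecg_unusable) != 3L || any(ecg_unusable < 0) ||
        any(ecg_unusable > c(n_seiz, n_movt, n_hc)))
      stop_input("'ecg_unusable' must give per-group counts within the group sizes")
  }
  if (bpq$rho < -1 || bpq$rho > 1) stop_input("'rho' must be in [-1, 1]")
  structure(list(n_seiz = as.integer(n_seiz), n_movt = as.integer(n_movt),
                 n_hc = as.integer(n_hc), age = age, sex_prop_f = sex_prop_f,
                 bmi = bmi, head_motion = head_motion, bdi = bdi, stai = stai,
                 accuracy = accuracy, bpq = bpq, bpq_bias = bpq_bias,
                 ecg_unusable = ecg_unusable, ecg_dropout = ecg_dropout,
                 hr_range = hr_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

rtruncnorm01 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < 0 | x > 1)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# Distribute a total score S in [26, 130] over 26 items each in 1..5.
bpq_items_from_total <- function(total) {
  total <- max(26L, min(130L, as.integer(round(total))))
  k <- total - 26L
  items <- rep.int(1L + k %/% 26L, 26L)
  extra <- k %% 26L
  if (extra > 0L) items[seq_len(extra)] <- items[seq_len(extra)] + 1L
  items
}

#' Generate a synthetic cohort table
#'
#' One row per subject with group label, covariates, latent true
#' interoceptive accuracy, heart rate, 26 awareness item responses and a
#' usable-ECG flag. Deterministic given the spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return Data frame of subject records.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    groups <- rep(c("FND-seiz", "FND-movt", "HC"),
                  c(spec$n_seiz, spec$n_movt, spec$n_hc))
    n <- length(groups)
    patient <- groups != "HC"
    draw2 <- function(par, cls) stats::rnorm(sum(cls), par[1], par[2])
    age <- numeric(n)
    age[groups == "FND-seiz"] <- draw2(spec$age$seiz, groups == "FND-seiz")
    age[groups == "FND-movt"] <- draw2(spec$age$movt, groups == "FND-movt")
    age[groups == "HC"] <- draw2(spec$age$hc, groups == "HC")
    age <- pmax(18, round(age))
    pf <- spec$sex_prop_f[c("seiz", "movt", "hc")][match(groups, c("FND-seiz", "FND-movt", "HC"))]
    sex <- ifelse(stats::runif(n) < pf, "F", "M")
    patpar <- function(par) ifelse(patient,
                                   stats::rnorm(n, par$pat[1], par$pat[2]),
                                   stats::rnorm(n, par$hc[1], par$hc[2]))
    bmi <- pmax(15, patpar(spec$bmi))
    motion <- pmax(0.05, patpar(spec$head_motion))
    bdi <- pmax(0, round(patpar(spec$bdi)))
    stai <- pmax(20, round(patpar(spec$stai)))
    acc <- numeric(n)
    acc[patient] <- rtruncnorm01(sum(patient), spec$accuracy$pat[1], spec$accuracy$pat[2])
    acc[!patient] <- rtruncnorm01(sum(!patient), spec$accuracy$hc[1], spec$accuracy$hc[2])
    hr <- stats::runif(n, spec$hr_range[1], spec$hr_range[2])
    # latent awareness correlates weakly with true accuracy
    rho <- spec$bpq$rho
    z_acc <- (acc - mean(acc)) / stats::sd(acc)
    w <- rho * z_acc + sqrt(1 - rho^2) * stats::rnorm(n)
    bpq_mu <- ifelse(patient, spec$bpq$pat[1], spec$bpq$hc[1])
    bpq_sd <- ifelse(patient, spec$bpq$pat[2], spec$bpq$hc[2])
    bpq_total <- bpq_mu + bpq_sd * w + spec$bpq_bias
    items <- t(vapply(bpq_total, bpq_items_from_total, integer(26L)))
    colnames(items) <- sprintf("bpq_%02d", 1:26)
    usable <- rep(TRUE, n)
    if (!is.null(spec$ecg_dropout)) {
      usable <- stats::runif(n) >= spec$ecg_dropout
    } else if (!is.null(spec$ecg_unusable)) {
      cnt <- spec$ecg_unusable
      for (k in seq_along(cnt)) {
        g <- c("FND-seiz", "FND-movt", "HC")[k]
        idx <- which(groups == g)
        if (cnt[k] > 0) usable[sample(idx, cnt[k])] <- FALSE
      }
    }
    out <- data.frame(id = sprintf("S%03d", seq_len(n)), group = groups,
                      age = age, sex = sex, bmi = bmi, head_motion = motion,
                      bdi = bdi, stai_trait = stai, true_accuracy = acc,
                      heart_rate = hr, usable_ecg = usable,
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(items))
  })
}

#' Generate heartbeat-tracking trials for one subject
#'
#' Emulates the counting paradigm: 12 windows drawn from lengths
#' \{15, 18, 21, 24, 27, 30\} s (each length twice by default). Recorded
#' beats come from a fixed-rate beat train with a random phase; reported
#' counts follow `count = round(rec * (a + e))` with
#' `e ~ Normal(0, sigma_report)` truncated so counts are non-negative,
#' so the expected relative counting error is approximately `1 - a`.
#'
#' @param accuracy true accuracy `a` in \[0, 1\].
#' @param heart_rate beats per minute.
#' @param n_windows number of windows (default 12).
#' @param window_lengths window lengths in seconds; must come from the
#'   admissible set.
#' @param sigma_report SD of the multiplicative report noise.
#' @param seed integer seed.
#' @return Data frame with columns `window_s`, `rec`, `count`.
#' @export
generate_htt_trials <- function(accuracy, heart_rate, n_windows = 12,
                                window_lengths = NULL, sigma_report = 0.1,
                                seed = 1L) {
  n_windows <- check_count(n_windows, "n_windows", min = 1L)
  check_number(accuracy, "accuracy", 0, 1)
  check_number(heart_rate, "heart_rate", 20, 250)
  admissible <- c(15, 18, 21, 24, 27, 30)
  if (is.null(window_lengths))
    window_lengths <- rep_len(admissible, n_windows)
  if (!all(window_lengths %in% admissible))
    stop_input("window lengths must come from {15, 18, 21, 24, 27, 30} s")
  if (length(window_lengths) != n_windows)
    stop_input("'window_lengths' must have length n_windows")
  with_seed(seed, {
    ord <- sample.int(n_windows)
    win <- window_lengths[ord]
    phase <- stats::runif(n_windows)
    rec <- pmax(1L, as.integer(floor(win * heart_rate / 60 + phase)))
    eps <- stats::rnorm(n_windows, 0, sigma_report)
    count <- pmax(0L, as.integer(round(rec * (accuracy + eps))))
    data.frame(window_s = win, rec = rec, count = count)
  })
}

#' Generate heartbeat-tracking trials for a whole cohort
#'
#' @param cohort output of [generate_cohort()].
#' @param n_windows,sigma_report passed to [generate_htt_trials()].
#' @param seed integer seed; each subject gets a derived sub-seed.
#' @return Long data frame with columns `id`, `window_s`, `rec`, `count`.
#' @export
generate_cohort_trials <- function(cohort, n_windows = 12, sigma_report = 0.1,
                                   seed = 1L) {
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    tr <- generate_htt_trials(cohort$true_accuracy[i], cohort$heart_rate[i],
                              n_windows = n_windows, sigma_report = sigma_report,
                              seed = derive_seed(seed, paste0("htt", cohort$id[i])))
    cbind(id = cohort$id[i], tr)
  })
  do.call(rbind, out)
}

#' Packaged reproduction of the published patient demographics table
#'
#' Reads the per-patient demographic rows (group, sex, age, years of
#' education, symptoms, medication) shipped with the package.
#'
#' @param path optional alternative TSV path.
#' @return Data frame with one row per patient.
#' @export
example_cohort_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "demographics_table.tsv", package = "intertract",
                        mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
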