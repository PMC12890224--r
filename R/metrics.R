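# Evaluation metrics: concordance index, time-dependent AUC, and
# Kaplan-Meier risk stratification with a log-rank test.

#' Concordance index for right-censored survival data
#'
#' Fraction of comparable ordered pairs ranked correctly by the risk
#' scores. A pair `(i, j)` with `O_i < O_j` is comparable only when the
#' sample with the shorter time had its event observed (`Delta_i = 1`);
#' pairs where the shorter time is censored, or both are censored, are
#' excluded. A comparable pair is concordant when the shorter-surviving
#' sample has the higher risk score; tied scores count 0.5.
#'
#' @param scores Numeric risk scores (higher = higher predicted risk).
#' @param surv A [survival_table()] (or data frame with `time`, `event`)
#'   aligned with `scores`.
#' @return A list: `c_index` in `[0, 1]` and `n_pairs`, the number of
#'   comparable pairs. Zero comparable pairs is an error.
#' @export
concordance_index <- function(scores, surv) {
  time <- surv$time; event <- surv$event
  stopifnot(length(scores) == length(time))
  comp <- outer(time, time, "<") & (event == 1)   # row i shorter, event observed
  n_pairs <- sum(comp)
  if (n_pairs == 0)
    stop("concordance index undefined: no comparable pairs")
  conc <- sum(outer(scores, scores, ">")[comp])
  ties <- sum(outer(scores, scores, "==")[comp])
  list(c_index = (conc + 0.5 * ties) / n_pairs, n_pairs = n_pairs)
}

#' Time-dependent AUC pooled over event times
#'
#' At each distinct observed event time `t`, every sample with `O_i < t`
#' is compared against every sample with `O_j > t`; the pooled AUC is the
#' fraction of such pairs (across all event times) where the earlier
#' sample has the higher score, tied scores counting 0.5:
#' \deqn{\mathrm{AUC} = \frac{1}{N_{num}} \sum_{t \in Y} \sum_{i: O_i < t}
#'   \sum_{j: O_j > t} I(s_i > s_j).}
#' By default the earlier set is unrestricted; `cases = "events_only"`
#' restricts it to samples whose event was observed (the conventional
#' cumulative/dynamic reading).
#'
#' @inheritParams concordance_index
#' @param cases `"all"` (default) or `"events_only"`.
#' @return A list: `auc` and `n_pairs` (the pooled pair count `N_num`).
#'   Zero pairs is an error.
#' @export
time_dependent_auc <- function(scores, surv, cases = c("all", "events_only")) {
  cases <- match.arg(cases)
  time <- surv$time; event <- surv$event
  stopifnot(length(scores) == length(time))
  Y <- sort(unique(time[event == 1]))
  total <- 0; n_pairs <- 0
  for (t in Y) {
    i_idx <- if (cases == "all") time < t else time < t & event == 1
    j_idx <- time > t
    ni <- sum(i_idx); nj <- sum(j_idx)
    if (ni == 0 || nj == 0) next
    sj <- sort(scores[j_idx])
    si <- scores[i_idx]
    less <- findInterval(si, sj, left.open = TRUE)   # s_j <  s_i
    leq <- findInterval(si, sj)                      # s_j <= s_i
    total <- total + sum(less) + 0.5 * sum(leq - less)
    n_pairs <- n_pairs + ni * nj
  }
  if (n_pairs == 0)
    stop("time-dependent AUC undefined: no valid pairs")
  list(auc = total / n_pairs, n_pairs = n_pairs)
}

#' Kaplan-Meier risk stratification with a log-rank test
#'
#' Splits the cohort into high- and low-risk groups (by default at the
#' median score, scores strictly above the median going to the high-risk
#' group), estimates a Kaplan-Meier curve per group, and tests the
#' difference in survival distributions with a two-sample log-rank test
#' (chi-square, 1 degree of freedom).
#'
#' @inheritParams concordance_index
#' @param split Either `"median"` or a numeric threshold; scores strictly
#'   greater than the threshold define the high-risk group.
#' @return A list: `group` (factor `"high"`/`"low"` per sample), `curves`
#'   (named list of data frames `time`, `survival`, `at_risk`, `events`),
#'   `logrank_stat` and `logrank_p`.
#' @export
km_logrank <- function(scores, surv, split = "median") {
  time <- surv$time; event <- surv$event
  stopifnot(length(scores) == length(time))
  thr <- if (identical(split, "median")) stats::median(scores) else as.numeric(split)
  group <- factor(ifelse(scores > thr, "high", "low"), levels = c("low", "high"))
  if (any(table(group) == 0))
    stop("risk stratification failed: one group is empty (scores tied at the threshold?)")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd_$chisq
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- lapply(split(seq_along(fit$time), strata), function(ix)
    data.frame(time = fit$time[ix], survival = fit$surv[ix],
               at_risk = fit$n.risk[ix], events = fit$n.event[ix]))
  names(curves) <- sub("^group=", "", names(curves))
  list(group = group, curves = curves, logrank_stat = stat, logrank_p = p)
}
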