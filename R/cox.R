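# Cox proportional-hazards head: partial-likelihood loss (with analytic
# gradient for training), Breslow baseline cumulative hazard, and survival
# curve prediction.

# Sorted-time bookkeeping shared by loss, gradient and Breslow estimation.
# Returns everything indexed in time-ascending order plus tie-group bounds.
.cox_order <- function(time, event) {
  ord <- order(time)
  t_s <- time[ord]
  grp <- cumsum(c(TRUE, t_s[-1] != t_s[-length(t_s)]))  # tie-group id
  g_start <- match(unique(grp), grp)
  g_end <- c(g_start[-1] - 1L, length(t_s))
  list(ord = ord, t_s = t_s, e_s = event[ord], grp = grp,
       g_start = g_start, g_end = g_end)
}

# log of reverse cumulative sum of exp(s) (log-sum-exp from each index to
# the end), numerically stable.
.rev_logcumsumexp <- function(s) {
  m <- max(s)
  log(rev(cumsum(rev(exp(s - m))))) + m
}

#' Cox partial-likelihood loss
#'
#' Negative log partial likelihood of risk scores under the Cox
#' proportional-hazards model,
#' \deqn{-\sum_{i:\Delta_i=1}\Big[s_i - \log\sum_{j \in R(O_i)} e^{s_j}\Big],}
#' with Breslow handling of tied event times. The default risk set is the
#' standard inclusive one, `R(t) = {j : O_j >= t}`. `risk_set = "strict"`
#' uses `{j : O_j > t}` instead; events whose strict risk set is empty
#' (those at the maximum observed time) are skipped, since their
#' denominator is undefined.
#'
#' @param scores Numeric risk scores, one per sample.
#' @param surv A [survival_table()] (or any data frame with `time` and
#'   `event` columns) aligned with `scores`.
#' @param risk_set `"inclusive"` (default) or `"strict"`.
#' @return The scalar loss. With no events a warning is raised and 0 is
#'   returned.
#' @export
cox_partial_loss <- function(scores, surv, risk_set = c("inclusive", "strict")) {
  risk_set <- match.arg(risk_set)
  .cox_loss_grad(scores, surv$time, surv$event, risk_set, want_grad = FALSE)$loss
}

# Loss and gradient wrt scores in one pass; O(n log n).
.cox_loss_grad <- function(scores, time, event, risk_set = "inclusive",
                           want_grad = TRUE) {
  stopifnot(length(scores) == length(time), all(is.finite(scores)))
  n <- length(scores)
  if (sum(event) == 0) {
    warning("no events in batch")
    return(list(loss = 0, grad = numeric(n)))
  }
  ob <- .cox_order(time, event)
  s_s <- scores[ob$ord]
  lse <- .rev_logcumsumexp(s_s)                 # lse[k] over positions >= k
  ng <- length(ob$g_start)
  # log-denominator per tie group: inclusive uses the group start; strict
  # uses the next group's start (empty for the last group).
  ldenom_inc <- lse[ob$g_start]
  ldenom_str <- c(lse[ob$g_start[-1]], NA_real_)[seq_len(ng)]
  use_inc <- risk_set == "inclusive"
  ldenom <- if (use_inc) ldenom_inc else ldenom_str
  ev <- ob$e_s == 1
  g_of_pos <- ob$grp
  ld_pos <- ldenom[g_of_pos]
  valid <- ev & !is.na(ld_pos)                  # strict mode skips last-time events
  loss <- -sum(s_s[valid] - ld_pos[valid])
  if (!want_grad) return(list(loss = loss, grad = NULL))
  # gradient: dL/ds_k = -Delta_k [valid] + e^{s_k} * sum over events i with
  # O_i <= O_k (inclusive) or O_i < O_k (strict) of 1 / denom_i.
  inv_d <- ifelse(valid, exp(-ld_pos), 0)
  cum <- cumsum(inv_d)
  H_end <- cum[ob$g_end][g_of_pos]              # events with O_i <= O_k
  if (use_inc) {
    H <- H_end
  } else {
    H_before <- c(0, cum[ob$g_end])[g_of_pos]   # events with O_i < O_k
    H <- H_before
  }
  g_s <- -as.numeric(valid) + exp(s_s) * H
  grad <- numeric(n)
  grad[ob$ord] <- g_s
  list(loss = loss, grad = grad)
}

#' Breslow baseline cumulative hazard
#'
#' Nonparametric step estimator of the cumulative baseline hazard given
#' fitted risk scores: at each distinct event time `t` the increment is
#' `d(t) / sum_{j: O_j >= t} exp(s_j)` where `d(t)` counts events at `t`;
#' the cumulative hazard is the running sum. Jumps occur only at observed
#' event times.
#'
#' @inheritParams cox_partial_loss
#' @return An object of class `breslow_baseline`: a data frame with columns
#'   `time` (distinct event times), `increment` and `cum_hazard`.
#' @export
breslow_baseline <- function(scores, surv) {
  time <- surv$time; event <- surv$event
  stopifnot(length(scores) == length(time))
  if (sum(event) == 0) {
    warning("no events in batch")
    out <- data.frame(time = numeric(0), increment = numeric(0),
                      cum_hazard = numeric(0))
    class(out) <- c("breslow_baseline", "data.frame")
    return(out)
  }
  ob <- .cox_order(time, event)
  s_s <- scores[ob$ord]
  lse <- .rev_logcumsumexp(s_s)
  d_g <- vapply(seq_along(ob$g_start), function(g)
    sum(ob$e_s[ob$g_start[g]:ob$g_end[g]]), numeric(1))
  keep <- d_g > 0
  inc <- d_g[keep] * exp(-lse[ob$g_start][keep])
  out <- data.frame(time = ob$t_s[ob$g_start][keep], increment = inc,
                    cum_hazard = cumsum(inc))
  class(out) <- c("breslow_baseline", "data.frame")
  out
}

# Evaluate a Breslow cumulative hazard (right-continuous step function).
.cum_hazard_at <- function(baseline, times) {
  if (nrow(baseline) == 0) return(numeric(length(times)))
  idx <- findInterval(times, baseline$time)
  c(0, baseline$cum_hazard)[idx + 1L]
}

#' Write risk scores / baseline hazard as TSV
#'
#' `write_risk_scores` emits `sample_id  risk_score`;
#' `write_baseline_hazard` emits `time  cum_hazard`.
#'
#' @param scores Named or plain numeric risk scores.
#' @param sample_id Sample identifiers (defaults to names of `scores`).
#' @param baseline A `breslow_baseline`.
#' @param path Output path.
#' @export
write_risk_scores <- function(scores, path, sample_id = names(scores)) {
  if (is.null(sample_id)) sample_id <- paste0("S", seq_along(scores))
  utils::write.table(data.frame(sample_id = sample_id, risk_score = scores),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_risk_scores
#' @export
write_baseline_hazard <- function(baseline, path) {
  utils::write.table(data.frame(time = baseline$time,
                                cum_hazard = baseline$cum_hazard),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Predict survival curves from risk scores and a Breslow baseline
#'
#' Under proportional hazards, `S_i(t) = exp(-Lambda0(t) * exp(s_i))`.
#'
#' @param scores Risk scores for the samples to predict.
#' @param baseline A `breslow_baseline` fitted on training data.
#' @param times Evaluation time grid; defaults to the baseline jump times.
#' @return Matrix of survival probabilities, one row per sample, one
#'   column per time point.
#' @export
predict_survival <- function(scores, baseline, times = NULL) {
  if (!inherits(baseline, "breslow_baseline"))
    stop("survival curves require a fitted Breslow baseline; scores only are available")
  if (is.null(times)) times <- baseline$time
  L0 <- .cum_hazard_at(baseline, times)
  out <- exp(-outer(exp(scores), L0))
  colnames(out) <- signif(times, 8)
  out
}
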