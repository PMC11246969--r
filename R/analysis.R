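#' Split trials into labelled subsets
#'
#' Three grouping schemes used by the trial-grouped fidget analyses:
#' \describe{
#'   \item{correctness}{`correct` vs `incorrect` responded trials; omissions
#'     belong to neither subset;}
#'   \item{trial_type}{one subset per flanker trial type (congruent,
#'     incongruent, neutral);}
#'   \item{quartile}{`Q1`, the first quarter of trials in presentation order,
#'     vs `Q4`, the last quarter — for the default 120-trial session the
#'     first and last 30 trials.}
#' }
#'
#' @param events Trial-event data.frame sorted by presentation order.
#' @param scheme One of `"correctness"`, `"trial_type"`, `"quartile"`.
#' @return A named list of integer vectors of `trial_index` values.
#' @export
split_trials <- function(events,
                         scheme = c("correctness", "trial_type", "quartile")) {
  scheme <- match.arg(scheme)
  idx <- events$trial_index
  switch(scheme,
    correctness = {
      omitted <- events$response == "none"
      list(correct = idx[events$correct & !omitted],
           incorrect = idx[!events$correct & !omitted])
    },
    trial_type = split(idx, events$type),
    quartile = {
      q <- floor(nrow(events) / 4)
      list(Q1 = idx[seq_len(q)], Q4 = idx[seq.int(nrow(events) - q + 1,
                                                  nrow(events))])
    })
}

#' Compare two groups of per-participant values with a t test
#'
#' Paired comparisons (each participant contributes both conditions, e.g.
#' correct vs incorrect trials, or Q1 vs Q4) use the paired t statistic on
#' the differences; unpaired comparisons use Welch's t with
#' Welch-Satterthwaite degrees of freedom. Two-sided p values. The t sign
#' follows `mean(a) - mean(b)`.
#'
#' Degenerate inputs follow an explicit contract: zero variance with
#' identical means gives `t = 0, p = 1`; zero variance with differing means
#' gives an infinite t, flagged via `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors of per-participant values; `NA` pairs are
#'   dropped when paired, `NA`s dropped per group otherwise.
#' @param paired Logical; `a` and `b` must then be equal-length and matched
#'   in participant order.
#' @param labels Character length-2 group labels for reporting.
#' @return A `group_comparison`: list with per-group `mean`, `sd`, `n`,
#'   `t_value`, `df`, `p_value`, `paired`, `degenerate`.
#' @export
compare_groups <- function(a, b, paired = FALSE,
                           labels = c("a", "b")) {
  if (paired) {
    if (length(a) != length(b))
      stop("paired comparison needs equal-length, matched vectors")
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
  }
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (paired) {
    d <- a - b
    n <- length(d)
    sd_d <- stats::sd(d)
    df <- n - 1
    t_val <- if (sd_d == 0) { if (mean(d) == 0) 0 else Inf * sign(mean(d)) }
             else mean(d) / (sd_d / sqrt(n))
  } else {
    v1 <- stats::var(a) / length(a)
    v2 <- stats::var(b) / length(b)
    se <- sqrt(v1 + v2)
    df <- if (se == 0) length(a) + length(b) - 2 else
      (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
    dm <- mean(a) - mean(b)
    t_val <- if (se == 0) { if (dm == 0) 0 else Inf * sign(dm) } else dm / se
  }
  p <- if (is.infinite(t_val)) 0 else 2 * stats::pt(-abs(t_val), df)
  structure(list(labels = labels,
                 mean = c(mean(a), mean(b)), sd = c(stats::sd(a), stats::sd(b)),
                 n = c(length(a), length(b)),
                 t_value = t_val, df = df, p_value = max(p, .Machine$double.xmin),
                 paired = paired, degenerate = is.infinite(t_val)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison%s> %s %.3g (%.3g, n=%d) vs %s %.3g (%.3g, n=%d): t = %.3g, p = %.3g\n",
              if (x$paired) ", paired" else "",
              x$labels[1], x$mean[1], x$sd[1], x$n[1],
              x$labels[2], x$mean[2], x$sd[2], x$n[2],
              x$t_value, x$p_value))
  invisible(x)
}

#' Median split of a cohort on a reaction-time parameter
#'
#' Participants with a key value strictly below the cohort median form the
#' low group; values at or above the median form the high group. With an
#' even cohort and distinct values the groups are equal-sized (35/35 for a
#' cohort of 70). Ties straddling the median all go to the high group and a
#' warning records the imbalance.
#'
#' @param cohort Data.frame of participant records.
#' @param key Column to split on, typically `"mu"`, `"sigma"` or `"tau"`.
#' @return A list of two data.frames, `low` and `high`.
#' @export
median_split <- function(cohort, key = c("mu", "sigma", "tau")) {
  key <- if (is.character(key) && length(key) == 1L &&
             !key %in% c("mu", "sigma", "tau")) key else match.arg(key)
  if (nrow(cohort) < 4L) stop("median split needs a cohort of at least 4")
  v <- cohort[[key]]
  med <- stats::median(v)
  low <- cohort[v < med, , drop = FALSE]
  high <- cohort[v >= med, , drop = FALSE]
  if (abs(nrow(low) - nrow(high)) > nrow(cohort) %% 2L)
    warning(sprintf("ties at the median leave unbalanced groups (%d/%d)",
                    nrow(low), nrow(high)))
  list(low = low, high = high)
}

#' Six-predictor linear model against a rating-scale total
#'
#' Ordinary least squares of a scale total on exactly six per-participant
#' predictors (for the fidget model: the arm and leg values of the three
#' fidget variables; for the task-performance baseline: digit span, the two
#' Stroop scores, flanker total, mu and tau). Reports the multiple
#' correlation `R = sqrt(1 - RSS/TSS)` and the overall F-test p value with
#' `(p, n - p - 1)` degrees of freedom.
#'
#' @param predictors Data.frame or matrix of 6 numeric columns.
#' @param response Numeric vector, the scale totals.
#' @return A `linear_fit_result`: list with `coefficients` (intercept first),
#'   `R`, `r_squared`, `f_value`, `df`, `p_value`, `n`, `rank_deficient`.
#' @export
fit_linear_model <- function(predictors, response) {
  predictors <- as.data.frame(predictors)
  p <- ncol(predictors)
  n <- length(response)
  if (nrow(predictors) != n) stop("predictor/response length mismatch")
  if (n <= p + 1L) stop("need more observations than predictors + intercept")
  fit <- stats::lm(response ~ ., data = predictors)
  rank_deficient <- fit$rank < p + 1L
  if (rank_deficient) warning("predictors are rank deficient")
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((response - mean(response))^2)
  r2 <- 1 - rss / tss
  dfn <- fit$rank - 1L
  dfd <- n - fit$rank
  f_val <- (r2 / dfn) / ((1 - r2) / dfd)
  structure(list(coefficients = stats::coef(fit),
                 R = sqrt(max(r2, 0)), r_squared = r2,
                 f_value = f_val, df = c(dfn, dfd),
                 p_value = stats::pf(f_val, dfn, dfd, lower.tail = FALSE),
                 n = n, rank_deficient = rank_deficient),
            class = "linear_fit_result")
}

#' @export
print.linear_fit_result <- function(x, ...) {
  cat(sprintf("<linear_fit_result> R = %.3f (R^2 = %.3f), F(%d, %d) = %.3g, p = %.3g, n = %d\n",
              x$R, x$r_squared, x$df[1], x$df[2], x$f_value, x$p_value, x$n))
  invisible(x)
}

# item count and per-item legal range for each rating scale
scale_items <- list(baars = list(n = 18L, range = c(1, 4)),
                    bdefs_sec5 = list(n = 13L, range = c(1, 4)),
                    ari = list(n = 6L, range = c(0, 2)))

#' Rating-scale total score
#'
#' Plain item sums with fixed legal layouts: BAARS-IV self-report, 18 items
#' scored 1-4 (total 18-72); BDEFS section 5 (self-regulation of emotion),
#' 13 items scored 1-4 (total 13-52); ARI, 6 items scored 0-2 (total 0-12).
#'
#' @param items Integer item scores.
#' @param scale One of `"baars"`, `"bdefs_sec5"`, `"ari"`.
#' @return The total score.
#' @export
scale_total <- function(items, scale = c("baars", "bdefs_sec5", "ari")) {
  scale <- match.arg(scale)
  spec <- scale_items[[scale]]
  if (length(items) != spec$n)
    stop(sprintf("%s expects %d items, got %d", scale, spec$n, length(items)))
  if (any(items < spec$range[1] | items > spec$range[2] | items != round(items)))
    stop(sprintf("%s items must be integers in [%g, %g]",
                 scale, spec$range[1], spec$range[2]))
  sum(items)
}

#' Cohort-level trial-grouped comparisons
#'
#' Runs the standard battery on a table of per-participant, per-condition
#' aggregates: paired correct-vs-incorrect and Q1-vs-Q4 comparisons of each
#' fidget variable. Participants lacking a condition (e.g. no incorrect
#' trials) are dropped from that comparison only. No multiple-testing
#' correction is applied; the result records how many comparisons were run.
#'
#' @param per_participant Data.frame with one row per participant and columns
#'   `<variable>_<condition>` for conditions `correct`, `incorrect`, `Q1`,
#'   `Q4` and variables `n_fidgets`, `variability_ms2`, `intensity`.
#' @return A list of `group_comparison` objects plus `n_comparisons`.
#' @export
cohort_comparisons <- function(per_participant) {
  vars <- c("n_fidgets", "variability_ms2", "intensity")
  out <- list()
  for (v in vars) {
    ci <- paste0(v, c("_correct", "_incorrect"))
    if (all(ci %in% names(per_participant)))
      out[[paste0(v, ".correct_vs_incorrect")]] <-
        compare_groups(per_participant[[ci[1]]], per_participant[[ci[2]]],
                       paired = TRUE, labels = c("correct", "incorrect"))
    qq <- paste0(v, c("_Q4", "_Q1"))
    if (all(qq %in% names(per_participant)))
      out[[paste0(v, ".Q4_vs_Q1")]] <-
        compare_groups(per_participant[[qq[1]]], per_participant[[qq[2]]],
                       paired = TRUE, labels = c("Q4", "Q1"))
  }
  out$n_comparisons <- length(out)
  out
}
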