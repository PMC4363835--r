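#' Group summary container
#'
#' A minimal summary-statistics triple (n, mean, sd) with a label, the unit
#' of input for the summary-statistic effect-size and t-test functions, so
#' published tables can be re-analysed without raw data.
#'
#' @param label Group label.
#' @param n Group size (>= 2).
#' @param mean,sd Group mean and standard deviation.
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(label = label, n = as.integer(n), mean = as.numeric(mean),
                 sd = as.numeric(sd)), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, %.2f +- %.2f\n", x$label, x$n, x$mean, x$sd))
  invisible(x)
}

#' Summarize a numeric vector as a group_summary
#'
#' @param x Numeric vector (NAs dropped).
#' @param label Group label.
#' @export
summarize_group <- function(x, label = "group") {
  x <- x[!is.na(x)]
  group_summary(label, length(x), mean(x), stats::sd(x))
}

#' Cohen's d from group summaries, with noncentral-t confidence interval
#'
#' Standardized mean difference between two groups. The default
#' `"unweighted_sd"` standardizer is the root mean of the two variances,
#' \eqn{\sqrt{(s_a^2 + s_b^2)/2}}; `"pooled_sd"` uses the sample-size
#' weighted pooled SD. The confidence interval inverts the noncentral-t
#' distribution of the standardized difference (asymmetric around d), with a
#' symmetric normal approximation available via `ci_method`.
#'
#' @param a,b [group_summary()] objects (both SDs must be positive).
#' @param method `"unweighted_sd"` (default) or `"pooled_sd"`.
#' @param ci_method `"noncentral_t"` (default) or `"normal"`.
#' @param conf.level Confidence level, default 0.95.
#' @return Object of class `effect_size`: list with `d`, `ci_low`, `ci_high`,
#'   `method`, `ci_method`, `conf.level`.
#' @examples
#' rural <- group_summary("rural", 96, 70.2, 9.8)
#' municipal <- group_summary("municipal", 729, 62.6, 11.1)
#' cohens_d(rural, municipal)   # d = 0.73
#' @export
cohens_d <- function(a, b, method = c("unweighted_sd", "pooled_sd"),
                     ci_method = c("noncentral_t", "normal"),
                     conf.level = 0.95) {
  method <- match.arg(method)
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$sd <= 0 || b$sd <= 0) stop("group SDs must be positive")
  s <- if (method == "unweighted_sd") {
    sqrt((a$sd^2 + b$sd^2) / 2)
  } else {
    sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
  }
  d <- (a$mean - b$mean) / s
  nt <- a$n * b$n / (a$n + b$n)   # effective n of the standardized difference
  df <- a$n + b$n - 2
  alpha <- 1 - conf.level
  if (ci_method == "noncentral_t") {
    tstat <- d * sqrt(nt)
    lo <- ncp_search(tstat, df, 1 - alpha / 2) / sqrt(nt)
    hi <- ncp_search(tstat, df, alpha / 2) / sqrt(nt)
  } else {
    se <- sqrt((a$n + b$n) / (a$n * b$n) + d^2 / (2 * df))
    z <- stats::qnorm(1 - alpha / 2)
    lo <- d - z * se
    hi <- d + z * se
  }
  structure(list(d = d, ci_low = lo, ci_high = hi, method = method,
                 ci_method = ci_method, conf.level = conf.level),
            class = "effect_size")
}

# noncentrality parameter lambda with P(T_{df,lambda} <= t) = prob;
# pt()'s noncentral tail emits precision warnings far beyond the accuracy
# needed here, so they are muffled
ncp_search <- function(t, df, prob) {
  f <- function(ncp) suppressWarnings(stats::pt(t, df, ncp = ncp)) - prob
  lim <- abs(t) + 10
  stats::uniroot(f, lower = -lim, upper = lim, tol = 1e-10,
                 extendInt = "downX")$root
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (%d%% CI %.3f, %.3f; %s, %s)\n",
              x$d, round(100 * x$conf.level), x$ci_low, x$ci_high,
              x$method, x$ci_method))
  invisible(x)
}

#' Two-sample t-test from summary statistics
#'
#' @param a,b [group_summary()] objects.
#' @param variant `"pooled"` (equal-variance, default) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
ttest_from_summary <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  dm <- a$mean - b$mean
  if (variant == "pooled") {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- dm / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pool group summaries into one
#'
#' Exact reconstruction of the total-sample mean and SD from subgroup
#' summaries: mean is the size-weighted mean, and the pooled variance adds
#' the within-group sums of squares and the between-group dispersion,
#' \eqn{[\sum (n_i - 1) s_i^2 + \sum n_i (m_i - m)^2] / (\sum n_i - 1)}.
#'
#' @param groups List of [group_summary()] objects.
#' @param label Label for the pooled summary.
#' @return A [group_summary()].
#' @export
pool_groups <- function(groups, label = "total") {
  stopifnot(length(groups) >= 1)
  if (length(groups) == 1) return(groups[[1]])
  n <- vapply(groups, `[[`, integer(1), "n")
  m <- vapply(groups, `[[`, numeric(1), "mean")
  s <- vapply(groups, `[[`, numeric(1), "sd")
  N <- sum(n)
  M <- sum(n * m) / N
  V <- (sum((n - 1) * s^2) + sum(n * (m - M)^2)) / (N - 1)
  group_summary(label, N, M, sqrt(V))
}

#' Linear age trend of a phenotype
#'
#' Ordinary least-squares regression of score on age, the cohort-level
#' check that morningness increases with age. Also the data behind the
#' age-score scatter.
#'
#' @param records Data frame with columns `age` and `meq_total`.
#' @return List with `slope` (score units/year), `intercept`, `p` (two-sided
#'   slope p-value), `r_squared`, `n`, and the `lm` fit in `$fit`.
#' @export
age_trend <- function(records) {
  stopifnot(all(c("age", "meq_total") %in% names(records)))
  records <- records[stats::complete.cases(records[c("age", "meq_total")]), ]
  if (length(unique(records$age)) < 2) stop("age is constant; no trend estimable")
  if (nrow(records) < 3) stop("need at least 3 records")
  fit <- stats::lm(meq_total ~ age, data = records)
  cf <- summary(fit)$coefficients
  list(slope = cf["age", "Estimate"], intercept = cf["(Intercept)", "Estimate"],
       p = cf["age", "Pr(>|t|)"], r_squared = summary(fit)$r.squared,
       n = nrow(records), fit = fit)
}

#' Normal Q-Q coordinates
#'
#' Ordered observations paired with standard-normal quantiles at plotting
#' positions \eqn{(i - 0.5)/n}. On a ceiling-censored phenotype the upper
#' tail drops below the line through the bulk of the points.
#'
#' @param values Numeric vector, n >= 3.
#' @return Data frame with `theoretical` (standard-normal quantile) and
#'   `observed` (sorted values).
#' @export
qq_coordinates <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             observed = sort(values))
}

#' Per-score histogram counts, optionally by group
#'
#' Exact integer counts per MEQ score (16..86), the data behind a stacked
#' score histogram.
#'
#' @param values Integer scores in 16..86.
#' @param by Optional group labels (same length as `values`).
#' @param complete Emit all 71 scores including zero counts? Default `FALSE`
#'   (only observed score/group combinations).
#' @return Data frame with `score`, `group`, `count`.
#' @export
histogram_counts <- function(values, by = NULL, complete = FALSE) {
  values <- as.numeric(values)
  if (any(is.na(values)) || any(values != floor(values)) ||
      any(values < 16 | values > 86))
    stop("scores must be integers in 16..86")
  if (is.null(by)) by <- rep("all", length(values))
  groups <- sort(unique(as.character(by)))
  scores <- if (complete) 16:86 else sort(unique(values))
  out <- expand.grid(score = scores, group = groups, stringsAsFactors = FALSE)
  tab <- table(factor(values, levels = scores), factor(by, levels = groups))
  out$count <- as.vector(tab)
  if (!complete) out <- out[out$count > 0 | complete, , drop = FALSE]
  rownames(out) <- NULL
  out
}
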