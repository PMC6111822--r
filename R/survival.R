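#' Dichotomize a cohort at the median expression of a gene
#'
#' Samples with expression strictly above the gene's median are labelled
#' `"high"`, the rest `"low"`. With ties at the median the tied samples go
#' to the low group; for a constant gene every sample is "low" and a warning
#' is raised.
#'
#' @param cohort An `expression_cohort`.
#' @param gene Gene symbol to stratify on.
#' @return An object of class `stratified_cohort`: list with `labels` (named
#'   character vector over samples), `cut_value` (the median) and `gene`.
#' @export
median_split <- function(cohort, gene) {
  values <- cohort$values
  if (!gene %in% rownames(values)) {
    stop("gene not found in cohort: ", gene, call. = FALSE)
  }
  x <- values[gene, ]
  cut <- stats::median(x)
  labels <- ifelse(x > cut, "high", "low")
  names(labels) <- colnames(values)
  if (all(labels == "low")) {
    warning("gene '", gene, "' has no expression above its median; ",
            "all samples labelled 'low'", call. = FALSE)
  }
  structure(list(labels = labels, cut_value = cut, gene = gene),
            class = "stratified_cohort")
}

#' @export
print.stratified_cohort <- function(x, ...) {
  cat(sprintf("median split on %s (cut %.4g): %d high / %d low\n",
              x$gene, x$cut_value, sum(x$labels == "high"),
              sum(x$labels == "low")))
  invisible(x)
}

#' Kaplan-Meier estimate with Greenwood variance and restricted mean
#'
#' Product-limit estimate of the survival function from right-censored
#' times, with the Greenwood variance of S at each event time and the
#' restricted mean survival time (RMST): the area under the survival curve
#' up to the truncation time `tau` (by default the largest observed time,
#' event or censored). The RMST standard error is the usual sum over event
#' times of `A_i^2 * d_i / (n_i * (n_i - d_i))`, where `A_i` is the area
#' under the curve from the i-th event time to `tau`; event times where the
#' whole risk set dies contribute nothing.
#'
#' The product-limit components are computed with [survival::survfit()];
#' Greenwood variance and the RMST summaries are derived from them.
#'
#' @param times Positive observed times in months.
#' @param events 0/1 event indicators (1 = death); at least one event
#'   required.
#' @param tau Optional truncation time for the restricted mean.
#' @return An object of class `km_estimate`: list with `time`, `n_risk`,
#'   `n_event` (event times only), `surv`, `greenwood_var`, `rmst`,
#'   `rmst_se`, `tau`, `n` and `n_events`.
#' @examples
#' km <- km_estimate(c(5, 8, 12, 15, 20), c(1, 0, 1, 0, 1))
#' km$surv       # 0.8, 0.533, 0
#' km$rmst       # 14.87 months
#' @export
km_estimate <- function(times, events, tau = NULL) {
  if (any(times <= 0)) stop("all times must be positive", call. = FALSE)
  if (!all(events %in% c(0, 1))) {
    stop("events must be 0/1 indicators", call. = FALSE)
  }
  if (sum(events) == 0) {
    stop("cannot estimate a survival curve without any event",
         call. = FALSE)
  }
  if (is.null(tau)) tau <- max(times)
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)

  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  t_i <- fit$time[keep]
  n_i <- fit$n.risk[keep]
  d_i <- fit$n.event[keep]
  s_i <- fit$surv[keep]
  gw <- s_i^2 * cumsum(d_i / (n_i * (n_i - d_i)))
  gw[n_i == d_i] <- 0  # curve hits zero; Greenwood term degenerates

  rm <- .rmst(t_i, s_i, tau)
  structure(list(time = t_i, n_risk = n_i, n_event = d_i, surv = s_i,
                 greenwood_var = gw, rmst = rm$rmst, rmst_se = rm$se(n_i, d_i),
                 tau = tau, n = length(times), n_events = sum(events)),
            class = "km_estimate")
}

# Rectangle-sum RMST over the step function, plus a closure for its SE.
.rmst <- function(t_i, s_i, tau) {
  tt <- c(0, pmin(t_i, tau), tau)
  ss <- c(1, s_i, s_i[length(s_i)])
  widths <- diff(tt)
  heights <- ss[-length(ss)]
  rmst <- sum(widths * heights)
  # A_i = area from t_i to tau under the curve
  area_from <- function(t0) {
    if (t0 >= tau) return(0)
    ttc <- pmax(pmin(tt, tau), t0)
    sum(diff(ttc) * heights)
  }
  list(rmst = rmst,
       se = function(n_i, d_i) {
         use <- t_i < tau & n_i > d_i
         if (!any(use)) return(0)
         a <- vapply(t_i[use], area_from, numeric(1))
         sqrt(sum(a^2 * d_i[use] / (n_i[use] * (n_i[use] - d_i[use]))))
       })
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n", x$n,
              x$n_events))
  cat(sprintf("restricted mean survival to tau = %.4g months: %.4g (se %.4g)\n",
              x$tau, x$rmst, x$rmst_se))
  invisible(x)
}

#' @export
summary.km_estimate <- function(object, level = 0.95, ...) {
  ci <- mean_survival_ci(object, level = level)
  cat(sprintf("n = %d, events = %d, tau = %.4g months\n", object$n,
              object$n_events, object$tau))
  cat(sprintf("restricted mean survival %.4g months (%.0f%% CI %.4g-%.4g)\n",
              ci[1], 100 * level, ci[2], ci[3]))
  invisible(ci)
}

#' @export
plot.km_estimate <- function(x, xlab = "Months", ylab = "Survival probability",
                             ...) {
  tt <- c(0, x$time)
  ss <- c(1, x$surv)
  graphics::plot(tt, ss, type = "s", ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' Restricted mean survival with a normal confidence interval
#'
#' Returns the restricted mean survival time of a [km_estimate()] together
#' with a symmetric normal-approximation confidence interval on the RMST
#' scale.
#'
#' @param est A `km_estimate`.
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(mean, lo, hi)` in months.
#' @export
mean_survival_ci <- function(est, level = 0.95) {
  if (!inherits(est, "km_estimate")) {
    stop("'est' must be a km_estimate", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    stop("'level' must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(mean = est$rmst, lo = est$rmst - z * est$rmst_se,
    hi = est$rmst + z * est$rmst_se)
}

#' Two-group log-rank test
#'
#' Standard two-sample log-rank test via [survival::survdiff()], with the
#' p-value from a chi-square distribution on one degree of freedom.
#'
#' @param times_a,events_a Times and 0/1 event indicators for group A.
#' @param times_b,events_b Times and 0/1 event indicators for group B.
#' @return List with `chi_square` and `p_two_sided`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (sum(events_a) + sum(events_b) == 0) {
    stop("at least one event is required across the two groups",
         call. = FALSE)
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi <- unname(sd$chisq)
  list(chi_square = chi,
       p_two_sided = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Survival report for a median-split cohort
#'
#' Convenience wrapper running [median_split()], per-group [km_estimate()]
#' with [mean_survival_ci()], and the [logrank_test()] between the groups.
#'
#' @param cohort An `expression_cohort` with clinical annotations.
#' @param gene Gene to stratify on.
#' @param tau Optional RMST truncation time shared by both groups.
#' @param level Confidence level.
#' @return List with per-group summaries (`n`, `mean`, `ci_lo`, `ci_hi`),
#'   the log-rank `chi_square` and `p`, and the stratification `cut_value`.
#' @export
survival_report <- function(cohort, gene, tau = NULL, level = 0.95) {
  strat <- median_split(cohort, gene)
  clin <- cohort$clinical
  lab <- strat$labels[clin$sample_id]
  if (is.null(tau)) tau <- max(clin$time_months)
  groups <- lapply(c(high = "high", low = "low"), function(g) {
    idx <- lab == g
    if (!any(idx) || sum(clin$event[idx]) == 0) {
      return(list(n = sum(idx), mean = NA_real_, ci_lo = NA_real_,
                  ci_hi = NA_real_))
    }
    km <- km_estimate(clin$time_months[idx], clin$event[idx], tau = tau)
    ci <- mean_survival_ci(km, level = level)
    list(n = sum(idx), mean = unname(ci["mean"]), ci_lo = unname(ci["lo"]),
         ci_hi = unname(ci["hi"]))
  })
  lr <- logrank_test(clin$time_months[lab == "high"],
                     clin$event[lab == "high"],
                     clin$time_months[lab == "low"],
                     clin$event[lab == "low"])
  list(gene = gene, tau = tau, high = groups$high, low = groups$low,
       logrank_chi_square = lr$chi_square, logrank_p = lr$p_two_sided,
       cut_value = strat$cut_value)
}
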