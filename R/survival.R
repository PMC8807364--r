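#' Median split of a continuous marker into high/low groups
#'
#' Subjects with a marker value strictly above the median go to
#' \code{"high"}; values at or below the median (ties included) go to
#' \code{"low"}. With an even number of tie-free values the groups are
#' equal-sized.
#'
#' @param markers numeric vector (length >= 2).
#' @return character vector of \code{"high"}/\code{"low"} labels.
#' @export
median_split <- function(markers) {
  if (length(markers) < 2L)
    stop("need at least 2 subjects", call. = FALSE)
  if (anyNA(markers)) stop("markers must not be missing", call. = FALSE)
  med <- stats::median(markers)
  if (all(markers == markers[1L]))
    warning("all marker values identical; every subject labelled 'low'",
            call. = FALSE)
  ifelse(markers > med, "high", "low")
}

#' Kaplan-Meier product-limit estimator
#'
#' \deqn{\hat S(t) = \prod_{t_i \le t} \left(1 - d_i / n_i\right)}
#' over the distinct event times \eqn{t_i}, with \eqn{d_i} events among
#' \eqn{n_i} subjects at risk. Subjects censored exactly at an event time
#' count as at risk at that time.
#'
#' @param time positive event/censoring times.
#' @param event 1 = event observed, 0 = right-censored.
#' @return object of class \code{km_fit}: data.frame with columns
#'   \code{time} (distinct event times, ascending), \code{n_risk},
#'   \code{n_event}, \code{surv}; attribute \code{n} (subjects).
#' @export
km_fit <- function(time, event) {
  if (!length(time)) stop("empty survival table", call. = FALSE)
  if (length(time) != length(event))
    stop("time and event lengths differ", call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  etimes <- sort(unique(time[event == 1]))
  n_risk <- vapply(etimes, function(tt) sum(time >= tt), numeric(1))
  n_event <- vapply(etimes, function(tt) sum(time == tt & event == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = etimes, n_risk = n_risk, n_event = n_event,
                       surv = surv),
            n = length(time), class = c("km_fit", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param fit a \code{km_fit}.
#' @param t times at which to evaluate \eqn{\hat S}; \eqn{\hat S(t) = 1}
#'   before the first event.
#' @return numeric vector of survival probabilities.
#' @export
km_surv <- function(fit, t) {
  vapply(t, function(tt) {
    i <- sum(fit$time <= tt)
    if (i == 0L) 1 else fit$surv[i]
  }, numeric(1))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: %d subjects, %d events at %d distinct times\n",
              attr(x, "n"), sum(x$n_event), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Step-function plot of one or more Kaplan-Meier curves
#'
#' @param x a \code{km_fit}, or a named list of them (one per group).
#' @param ... graphics arguments passed through.
#' @export
plot.km_fit <- function(x, ...) {
  fits <- if (inherits(x, "km_fit")) list(estimate = x) else x
  xmax <- max(vapply(fits, function(f) max(f$time), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "time", ylab = "survival probability", ...)
  for (k in seq_along(fits)) {
    f <- fits[[k]]
    graphics::lines(stats::stepfun(f$time, c(1, f$surv)), do.points = FALSE,
                    col = k)
  }
  if (length(fits) > 1L)
    graphics::legend("bottomleft", legend = names(fits),
                     col = seq_along(fits), lty = 1, bty = "n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' At each distinct event time with \eqn{d} events among \eqn{n} at risk
#' (\eqn{n_1} in group 1), the expected group-1 events are
#' \eqn{d\,n_1/n} with hypergeometric variance
#' \eqn{d\,(n_1/n)(1 - n_1/n)(n - d)/(n - 1)}. The statistic
#' \eqn{(\sum O - \sum E)^2 / \sum V} is referred to a chi-square
#' distribution with 1 df; strata with a single subject at risk
#' contribute no variance and are skipped. An exact-style permutation
#' p-value (group labels permuted) is available for small samples.
#'
#' @param time,event as in [km_fit()].
#' @param group vector with exactly two distinct labels.
#' @param p_method \code{"chisq"} (default) or \code{"permutation"}.
#' @param n_perm number of label permutations when
#'   \code{p_method = "permutation"}.
#' @return object of class \code{logrank_test}: list with
#'   \code{statistic}, \code{p_value}, \code{observed}, \code{expected}
#'   (per group), \code{groups}, \code{method}.
#' @export
logrank_test <- function(time, event, group, p_method = c("chisq",
                                                          "permutation"),
                         n_perm = 2000L) {
  p_method <- match.arg(p_method)
  lev <- unique(group)
  if (length(lev) != 2L)
    stop("exactly two groups required", call. = FALSE)
  if (!all(table(group) >= 1L))
    stop("each group needs at least one subject", call. = FALSE)

  stat_fun <- function(grp) {
    g1 <- grp == lev[1L]
    etimes <- sort(unique(time[event == 1]))
    O <- E <- V <- 0
    for (tt in etimes) {
      at <- time >= tt
      n <- sum(at); n1 <- sum(at & g1)
      d <- sum(time == tt & event == 1)
      d1 <- sum(time == tt & event == 1 & g1)
      O <- O + d1
      E <- E + d * n1 / n
      if (n > 1L)
        V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    list(stat = if (V > 0) (O - E)^2 / V else 0, O = O, E = E)
  }
  obs <- stat_fun(group)
  p <- if (p_method == "chisq") {
    stats::pchisq(obs$stat, df = 1L, lower.tail = FALSE)
  } else {
    perm <- replicate(n_perm, stat_fun(sample(group))$stat)
    (1 + sum(perm >= obs$stat)) / (n_perm + 1)
  }
  tot_ev <- sum(event)
  structure(list(statistic = obs$stat, p_value = p,
                 observed = stats::setNames(c(obs$O, tot_ev - obs$O), lev),
                 expected = stats::setNames(c(obs$E, tot_ev - obs$E), lev),
                 groups = lev, method = p_method),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-group log-rank test (", x$method, " p-value)\n", sep = "")
  print(data.frame(group = x$groups, observed = unname(x$observed),
                   expected = round(unname(x$expected), 2)),
        row.names = FALSE)
  cat(sprintf("chi-square = %.4f (1 df), p = %.4g\n", x$statistic,
              x$p_value))
  invisible(x)
}

#' Median-split survival comparison
#'
#' The survival analysis applied per gene in expression cohorts: split
#' subjects into high/low marker groups at the median, estimate a
#' Kaplan-Meier curve per group, and compare them with a log-rank test.
#'
#' @param table data.frame with columns \code{time}, \code{event},
#'   \code{marker} (one expression value per subject).
#' @param p_method,n_perm passed to [logrank_test()].
#' @return list with \code{groups} (labels), \code{fits} (named list of
#'   \code{km_fit}), \code{test} (a \code{logrank_test}).
#' @export
survival_screen <- function(table, p_method = "chisq", n_perm = 2000L) {
  stopifnot(all(c("time", "event", "marker") %in% names(table)))
  grp <- median_split(table$marker)
  fits <- lapply(split(seq_len(nrow(table)), grp), function(i)
    km_fit(table$time[i], table$event[i]))
  test <- logrank_test(table$time, table$event, grp, p_method, n_perm)
  list(groups = grp, fits = fits, test = test)
}
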