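ENDPOINTS <- c("OS", "PFS", "PFS2")

#' Build a survival record for one endpoint
#'
#' Maps the per-patient endpoint columns (\code{<ep>_days},
#' \code{<ep>_event}) to a validated (time, event) record. OS is time from
#' treatment initiation to all-cause death; PFS is time to first
#' progression or death; PFS2 is time to second progression or death after
#' the next line of therapy, measured from treatment initiation. Death
#' counts as an event for all three endpoints.
#'
#' @param patient_row one row of the patient table.
#' @param endpoint \code{"OS"}, \code{"PFS"} or \code{"PFS2"}.
#' @return a one-row data frame: \code{patient_id}, \code{endpoint},
#'   \code{time} (days), \code{event} (logical; FALSE = censored).
#' @export
build_endpoint <- function(patient_row, endpoint) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  pre <- tolower(endpoint)
  tcol <- paste0(pre, "_days"); ecol <- paste0(pre, "_event")
  if (!all(c(tcol, ecol) %in% names(patient_row)))
    stop("patient row lacks columns ", tcol, "/", ecol)
  tm <- as.numeric(patient_row[[tcol]]); ev <- patient_row[[ecol]]
  if (!is.finite(tm) || tm < 0)
    stop("invalid ", tcol, ": ", patient_row[[tcol]])
  if (!ev %in% c(0, 1))
    stop("invalid ", ecol, ": must be 0/1")
  if (endpoint != "PFS" && "pfs_days" %in% names(patient_row) &&
      is.finite(as.numeric(patient_row[["pfs_days"]])) &&
      as.numeric(patient_row[["pfs_days"]]) > tm)
    stop("PFS time exceeds ", endpoint, " time for patient ",
         patient_row[["patient_id"]])
  data.frame(patient_id = as.character(patient_row[["patient_id"]]),
             endpoint = endpoint, time = tm, event = as.logical(ev),
             stringsAsFactors = FALSE)
}

#' Endpoint records for a whole cohort
#'
#' @param cohort a \code{tumor_cohort} (or its patient table).
#' @param endpoint \code{"OS"}, \code{"PFS"} or \code{"PFS2"}.
#' @return data frame of survival records, one per patient.
#' @export
cohort_endpoint <- function(cohort, endpoint) {
  pats <- if (inherits(cohort, "tumor_cohort")) cohort$patients else cohort
  endpoint <- match.arg(endpoint, ENDPOINTS)
  pre <- tolower(endpoint)
  data.frame(patient_id = pats$patient_id, endpoint = endpoint,
             time = as.numeric(pats[[paste0(pre, "_days")]]),
             event = as.logical(pats[[paste0(pre, "_event")]]),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival estimate
#' \deqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' over the distinct event times \eqn{t_i}, with \eqn{d_i} events among
#' \eqn{n_i} at risk. Ties among events at one time are handled jointly;
#' censorings tied with events are treated as occurring just after the
#' events (the standard convention).
#'
#' @param records data frame with columns \code{time} (days >= 0) and
#'   \code{event} (logical or 0/1; FALSE = right-censored).
#' @return an object of class \code{km_curve}: a list with
#'   \code{event_times} (sorted distinct event times), \code{survival}
#'   (the estimate just after each event time), \code{at_risk},
#'   \code{n_events}, and \code{n} (number of subjects).
#' @examples
#' km <- km_estimate(data.frame(time = c(10, 20, 30), event = TRUE))
#' km$survival  # 2/3, 1/3, 0
#' @export
km_estimate <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a nonempty data frame of (time, event)")
  time <- as.numeric(records$time); event <- as.logical(records$event)
  if (any(!is.finite(time)) || any(time < 0))
    stop("survival times must be finite and >= 0")
  et <- sort(unique(time[event]))
  if (length(et) == 0L) {
    curve <- list(event_times = numeric(0), survival = numeric(0),
                  at_risk = integer(0), n_events = integer(0),
                  n = length(time))
    return(structure(curve, class = "km_curve"))
  }
  n_risk <- vapply(et, function(t) sum(time >= t), integer(1))
  d <- vapply(et, function(t) sum(time == t & event), integer(1))
  surv <- cumprod(1 - d / n_risk)
  structure(list(event_times = et, survival = surv, at_risk = n_risk,
                 n_events = d, n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,", sum(x$n_events), "events\n")
  med <- median_survival(x)
  cat("  median survival:",
      if (is.na(med)) "not reached" else paste(med, "days"), "\n")
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$event_times, at_risk = x$at_risk,
             events = x$n_events, survival = x$survival)
}

#' @export
plot.km_curve <- function(x, xlab = "days", ylab = "survival probability",
                          col = "black", add = FALSE, ...) {
  tt <- c(0, rep(x$event_times, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[seq_len(2 * length(x$survival) - 1)])
  if (add) graphics::lines(tt, ss, col = col, ...)
  else graphics::plot(tt, ss, type = "l", ylim = c(0, 1), xlab = xlab,
                      ylab = ylab, col = col, ...)
  invisible(x)
}

#' Survival probability at a given time
#'
#' Step-function evaluation of a Kaplan-Meier curve: the estimate at the
#' largest event time at or before \code{t}, or 1 if \code{t} precedes all
#' events.
#'
#' @param curve a \code{km_curve}.
#' @param t evaluation time (days >= 0). The 3-year rates use t = 1095.
#' @return survival probability in [0, 1].
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), is.numeric(t), all(t >= 0))
  vapply(t, function(ti) {
    k <- sum(curve$event_times <= ti)
    if (k == 0L) 1 else curve$survival[k]
  }, numeric(1))
}

#' Median survival time
#'
#' The smallest event time at which the Kaplan-Meier estimate drops to 0.5
#' or below; \code{NA} ("not reached") if the estimate never does.
#'
#' @param curve a \code{km_curve}.
#' @return days, or \code{NA_real_} if the median is not reached.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  k <- which(curve$survival <= 0.5)
  if (length(k) == 0L) return(NA_real_)
  curve$event_times[min(k)]
}

#' Two-group log-rank test
#'
#' Mantel-Haenszel log-rank test comparing the survival experience of two
#' groups. At each distinct pooled event time the observed events in group
#' A are compared with their expectation under the pooled risk set, with
#' hypergeometric variance; the statistic
#' \eqn{(\sum (O - E))^2 / \sum Var} is referred to a chi-squared
#' distribution with 1 degree of freedom.
#'
#' @param group_a,group_b data frames with columns \code{time} and
#'   \code{event} (as in [km_estimate()]).
#' @return an object of class \code{logrank_test}: \code{statistic},
#'   \code{df} (1), \code{p_value}, \code{observed}/\code{expected} per
#'   group, \code{n_per_group}. With no events in either group the
#'   statistic is 0 and p = 1.
#' @examples
#' a <- data.frame(time = c(10, 20, 40), event = TRUE)
#' b <- data.frame(time = c(50, 60, 70), event = TRUE)
#' logrank_test(a, b)
#' @export
logrank_test <- function(group_a, group_b) {
  for (g in list(group_a, group_b))
    if (!is.data.frame(g) || nrow(g) == 0L)
      stop("both groups must be nonempty data frames of (time, event)")
  time <- c(as.numeric(group_a$time), as.numeric(group_b$time))
  event <- c(as.logical(group_a$event), as.logical(group_b$event))
  grp <- rep(c(0L, 1L), c(nrow(group_a), nrow(group_b)))
  res <- .logrank_core(time, event, grp)
  structure(c(res, list(n_per_group = c(a = nrow(group_a),
                                        b = nrow(group_b)))),
            class = "logrank_test")
}

# shared core so simulation loops avoid data-frame overhead
.logrank_core <- function(time, event, grp) {
  et <- sort(unique(time[event]))
  if (length(et) == 0L)
    return(list(statistic = 0, df = 1L, p_value = 1,
                observed = c(0, 0), expected = c(0, 0)))
  o_minus_e <- 0; vsum <- 0; o1 <- 0; e1 <- 0; o2 <- 0; e2 <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp == 0L)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & grp == 0L)
    e <- d * n1 / n
    v <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    o_minus_e <- o_minus_e + (d1 - e)
    vsum <- vsum + v
    o1 <- o1 + d1; e1 <- e1 + e; o2 <- o2 + (d - d1); e2 <- e2 + (d - e)
  }
  stat <- if (vsum > 0) o_minus_e^2 / vsum else 0
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = c(o1, o2), expected = c(e1, e2))
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-group log-rank test\n")
  cat(sprintf("  n = %d vs %d; observed events %g vs %g (expected %.2f vs %.2f)\n",
              x$n_per_group[1], x$n_per_group[2], x$observed[1],
              x$observed[2], x$expected[1], x$expected[2]))
  cat(sprintf("  chi-squared = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
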