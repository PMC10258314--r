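#' Quartile thresholds of the growth-rate distribution
#'
#' Sample quartiles (25th, 50th, 75th percentiles) of the per-patient
#' growth rates. The default convention is linear interpolation between
#' order statistics (\code{\link[stats]{quantile}} type 7, the common
#' default of mainstream numerical libraries); the convention is
#' configurable because published quartile values rarely state one.
#'
#' @param alphas numeric vector of growth rates (1/day); at least 4 values.
#' @param type quantile algorithm passed to \code{stats::quantile}.
#' @return named numeric vector \code{c(q1, q2, q3)}.
#' @examples
#' quartile_thresholds(1:8)  # q3 = 6.25
#' @export
quartile_thresholds <- function(alphas, type = 7) {
  alphas <- as.numeric(alphas)
  if (length(alphas) < 4L)
    stop("at least 4 growth-rate values are required for quartiles")
  if (any(!is.finite(alphas))) stop("'alphas' contains non-finite values")
  q <- stats::quantile(alphas, probs = c(0.25, 0.5, 0.75), type = type,
                       names = FALSE)
  stats::setNames(q, c("q1", "q2", "q3"))
}

#' Assign quartiles and the slow/fast dichotomy
#'
#' Patients are labelled by growth-rate quartile and dichotomized at a
#' threshold: \code{slow} iff \eqn{\alpha \le} threshold (the boundary
#' belongs to the slow-paced group), \code{fast} otherwise. With the
#' threshold at the upper quartile, the fast group is exactly Q4.
#'
#' @param alphas numeric vector of growth rates (1/day).
#' @param threshold dichotomization threshold (1/day); by default the upper
#'   quartile of \code{alphas}.
#' @param patient_ids optional character vector of ids (same length).
#' @param type quantile convention, as in [quartile_thresholds()].
#' @return data frame of class \code{strata_assignment}:
#'   \code{patient_id}, \code{alpha}, \code{quartile} (Q1-Q4),
#'   \code{group} (slow/fast), with the threshold as attribute
#'   \code{"threshold"}.
#' @export
assign_groups <- function(alphas, threshold = NULL, patient_ids = NULL,
                          type = 7) {
  alphas <- as.numeric(alphas)
  if (any(!is.finite(alphas))) stop("'alphas' contains non-finite values")
  if (is.null(patient_ids)) patient_ids <- as.character(seq_along(alphas))
  stopifnot(length(patient_ids) == length(alphas))
  q <- quartile_thresholds(alphas, type = type)
  if (is.null(threshold)) threshold <- q[["q3"]]
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  # manual binning: quantile breaks may be tied (e.g. all-equal alphas)
  quartile <- ifelse(alphas <= q[["q1"]], "Q1",
                     ifelse(alphas <= q[["q2"]], "Q2",
                            ifelse(alphas <= q[["q3"]], "Q3", "Q4")))
  out <- data.frame(patient_id = patient_ids, alpha = alphas,
                    quartile = quartile,
                    group = ifelse(alphas <= threshold, "slow", "fast"),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "quartiles") <- q
  class(out) <- c("strata_assignment", "data.frame")
  out
}

#' All pairwise quartile survival comparisons
#'
#' Log-rank comparisons for every pair of growth-rate quartiles plus the
#' fastest quartile against the pooled lower three (Q4 vs Q1-3).
#'
#' @param strata a \code{strata_assignment} (or data frame with
#'   \code{patient_id}, \code{quartile}).
#' @param records endpoint records with \code{patient_id}, \code{time},
#'   \code{event} (see [cohort_endpoint()]).
#' @return data frame: \code{comparison}, \code{n_1}, \code{n_2},
#'   \code{statistic}, \code{p_value}, \code{flagged} (TRUE when a side is
#'   empty and the test could not be computed).
#' @export
pairwise_quartile_comparisons <- function(strata, records) {
  stopifnot(all(c("patient_id", "quartile") %in% names(strata)),
            all(c("patient_id", "time", "event") %in% names(records)))
  rec <- merge(records, strata[c("patient_id", "quartile")],
               by = "patient_id")
  qs <- c("Q1", "Q2", "Q3", "Q4")
  pairs <- utils::combn(qs, 2, simplify = FALSE)
  pairs <- c(pairs, list(c("Q4", "Q1-3")))
  rows <- lapply(pairs, function(p) {
    sel1 <- if (p[1] == "Q1-3") rec$quartile %in% qs[1:3]
            else rec$quartile == p[1]
    sel2 <- if (p[2] == "Q1-3") rec$quartile %in% qs[1:3]
            else rec$quartile == p[2]
    lab <- paste(p[1], "vs", p[2])
    if (!any(sel1) || !any(sel2))
      return(data.frame(comparison = lab, n_1 = sum(sel1), n_2 = sum(sel2),
                        statistic = NA_real_, p_value = NA_real_,
                        flagged = TRUE))
    lr <- logrank_test(rec[sel1, ], rec[sel2, ])
    data.frame(comparison = lab, n_1 = sum(sel1), n_2 = sum(sel2),
               statistic = lr$statistic, p_value = lr$p_value,
               flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Oligometastatic vs polymetastatic subgrouping
#'
#' Partitions patients by baseline metastasis count, following the
#' conventional oligometastatic-disease definition of at most 5 lesions.
#'
#' @param cohort a \code{tumor_cohort} (or its patient table with
#'   \code{patient_id} and \code{n_met_baseline}).
#' @param cutoff inclusive upper lesion count for the oligometastatic
#'   group; default 5.
#' @return list with character vectors \code{oligo} (count <= cutoff) and
#'   \code{poly} (count > cutoff) of patient ids.
#' @export
subgroup_by_met_count <- function(cohort, cutoff = 5) {
  pats <- if (inherits(cohort, "tumor_cohort")) cohort$patients else cohort
  if (!"n_met_baseline" %in% names(pats) ||
      any(is.na(pats$n_met_baseline)))
    stop("baseline metastasis count (n_met_baseline) required for all patients")
  list(oligo = pats$patient_id[pats$n_met_baseline <= cutoff],
       poly = pats$patient_id[pats$n_met_baseline > cutoff])
}

#' Imputation sensitivity grid
#'
#' Re-runs the slow/fast survival comparison under a grid of pretreatment
#' imputation assumptions. For each cell (imputed volume, imputed offset):
#' de novo patients' growth rates are recomputed with that assumption
#' (measured patients' rates never change), the upper-quartile threshold is
#' re-derived on the full cohort (or held fixed), groups are re-assigned,
#' and the slow-vs-fast log-rank p-value is computed per endpoint.
#'
#' @param cohort a \code{tumor_cohort}.
#' @param volume_axis imputation volumes (cc); default \code{c(0.01, 0.1, 1)}.
#' @param offset_axis imputation offsets (days, negative); default 30-day
#'   steps over -150..-30.
#' @param endpoints endpoints to test; default OS, PFS, PFS2.
#' @param threshold \code{NULL} (default) to re-derive the upper quartile
#'   per cell, or a fixed numeric threshold (1/day).
#' @param type quantile convention for the per-cell threshold.
#' @return data frame of class \code{sensitivity_grid}, long format:
#'   \code{volume_cc}, \code{offset_days}, \code{endpoint},
#'   \code{threshold}, \code{n_slow}, \code{n_fast}, \code{statistic},
#'   \code{p_value}, \code{flagged}.
#' @export
run_sensitivity_grid <- function(cohort,
                                 volume_axis = c(0.01, 0.1, 1),
                                 offset_axis = seq(-150, -30, by = 30),
                                 endpoints = ENDPOINTS,
                                 threshold = NULL, type = 7) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  if (any(volume_axis <= 0)) stop("imputation volumes must be positive")
  if (any(offset_axis >= 0)) stop("imputation offsets must be negative")
  endpoints <- match.arg(endpoints, ENDPOINTS, several.ok = TRUE)

  pats <- cohort$patients
  de_novo <- pats$de_novo
  v0 <- vapply(cohort$timelines, function(tl) tl$total_volumes[["TP0"]],
               numeric(1))[pats$patient_id]
  # measured patients: alpha fixed across all cells
  alpha <- rep(NA_real_, nrow(pats))
  for (i in which(!de_novo)) {
    tl <- cohort$timelines[[pats$patient_id[i]]]
    alpha[i] <- log(tl$total_volumes[["TP0"]] / tl$total_volumes[["TP-1"]]) /
      abs(tl$offsets[["TP-1"]])
  }
  recs <- lapply(endpoints, function(ep) cohort_endpoint(cohort, ep))
  names(recs) <- endpoints

  rows <- list()
  for (vol in volume_axis) for (off in offset_axis) {
    a <- alpha
    a[de_novo] <- log(v0[de_novo] / vol) / abs(off)
    strata <- assign_groups(a, threshold = threshold,
                            patient_ids = pats$patient_id, type = type)
    thr <- attr(strata, "threshold")
    slow <- strata$group == "slow"
    for (ep in endpoints) {
      r <- recs[[ep]]
      if (all(slow) || !any(slow)) {
        rows[[length(rows) + 1L]] <-
          data.frame(volume_cc = vol, offset_days = off, endpoint = ep,
                     threshold = thr, n_slow = sum(slow),
                     n_fast = sum(!slow), statistic = NA_real_,
                     p_value = NA_real_, flagged = TRUE)
        next
      }
      lr <- logrank_test(r[slow, ], r[!slow, ])
      rows[[length(rows) + 1L]] <-
        data.frame(volume_cc = vol, offset_days = off, endpoint = ep,
                   threshold = thr, n_slow = sum(slow), n_fast = sum(!slow),
                   statistic = lr$statistic, p_value = lr$p_value,
                   flagged = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_grid", "data.frame")
  out
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat("Imputation sensitivity grid:",
      length(unique(x$volume_cc)), "volumes x",
      length(unique(x$offset_days)), "offsets x",
      length(unique(x$endpoint)), "endpoints\n")
  cat("  p <= 0.05 in", sum(x$p_value <= 0.05, na.rm = TRUE), "of",
      sum(!is.na(x$p_value)), "cells\n")
  invisible(x)
}
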