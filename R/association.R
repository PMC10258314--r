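#' Percentage tumor volume change from baseline
#'
#' \deqn{100 \times (V_{TP+1} - V_{TP0}) / V_{TP0}}
#' where \eqn{V_{TP+1}} is the total volume at the first on-treatment
#' response evaluation and \eqn{V_{TP0}} the baseline total volume.
#'
#' @param v_tp1 on-treatment total volume (cc) >= 0.
#' @param v_tp0 baseline total volume (cc) > 0.
#' @return percent change (>= -100 for nonnegative volumes).
#' @examples
#' tumor_volume_change(14.2, 28.4)  # -50
#' @export
tumor_volume_change <- function(v_tp1, v_tp0) {
  if (any(!is.finite(v_tp0)) || any(v_tp0 <= 0))
    stop("'v_tp0' (baseline volume) must be positive")
  if (any(!is.finite(v_tp1)) || any(v_tp1 < 0))
    stop("'v_tp1' must be nonnegative")
  100 * (v_tp1 - v_tp0) / v_tp0
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks for ties. The two-sided p-value uses the
#' exact null distribution for small untied samples (n <= 9) and the
#' t-approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{rho}, \code{p_value}, \code{n}, \code{method}.
#'   A constant input vector yields \code{rho = NA} (undefined-coefficient
#'   signal) with a warning.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop("at least 3 complete pairs are required")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("Spearman correlation undefined for a constant vector")
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "spearman"))
  }
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = (n <= 9 && !has_ties)))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       method = "spearman")
}

#' Cramer's V association between two categorical variables
#'
#' \deqn{V = \sqrt{\chi^2 / (n (\min(r, c) - 1))}}
#' with the Pearson chi-squared statistic of the r x c contingency table
#' (no continuity correction).
#'
#' @param labels_a,labels_b vectors of equal length (factors or characters),
#'   each with at least 2 observed levels; or a contingency table/matrix as
#'   \code{labels_a} with \code{labels_b} missing.
#' @return list with \code{v}, \code{chi_squared}, \code{n},
#'   \code{method}. A single-level variable yields \code{v = NA} with a
#'   warning.
#' @examples
#' cramers_v(matrix(c(20, 5, 5, 20), 2))  # V = 0.6
#' @export
cramers_v <- function(labels_a, labels_b = NULL) {
  tab <- if (is.null(labels_b)) {
    as.table(as.matrix(labels_a))
  } else {
    stopifnot(length(labels_a) == length(labels_b))
    table(as.character(labels_a), as.character(labels_b))
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    warning("Cramer's V undefined: a variable has fewer than 2 levels")
    return(list(v = NA_real_, chi_squared = NA_real_, n = sum(tab),
                method = "cramers_v"))
  }
  n <- sum(tab)
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  v <- sqrt(unname(chi2) / (n * (min(dim(tab)) - 1)))
  list(v = v, chi_squared = unname(chi2), n = n, method = "cramers_v")
}

#' Default interpretation guidelines for association strength
#'
#' Ordered (threshold, label) bands on the absolute coefficient, by method.
#' The defaults follow the conventional Akoglu-style bands for Spearman
#' coefficients and Kim-style bands for Cramer's V; both are configurable.
#'
#' @param method \code{"spearman"} or \code{"cramers_v"}.
#' @return data frame with columns \code{threshold} (inclusive lower bound
#'   on |coefficient|) and \code{label}, in decreasing threshold order.
#' @export
default_guideline <- function(method = c("spearman", "cramers_v")) {
  method <- match.arg(method)
  if (method == "spearman")
    data.frame(threshold = c(0.8, 0.6, 0.4, 0.2, 0),
               label = c("very strong", "strong", "moderate", "weak",
                         "negligible"))
  else
    data.frame(threshold = c(0.25, 0.15, 0.10, 0.05, 0),
               label = c("very strong", "strong", "moderate", "weak",
                         "negligible"))
}

#' Interpret an association coefficient
#'
#' @param value the coefficient (sign is ignored).
#' @param method \code{"spearman"} or \code{"cramers_v"} (selects the
#'   default guideline).
#' @param guideline optional data frame of (threshold, label) bands,
#'   decreasing, as from [default_guideline()].
#' @return the label of the first band whose threshold |value| reaches.
#' @export
interpret_coefficient <- function(value, method = c("spearman", "cramers_v"),
                                  guideline = NULL) {
  if (is.null(guideline)) guideline <- default_guideline(method)
  stopifnot(all(c("threshold", "label") %in% names(guideline)),
            !is.unsorted(rev(guideline$threshold)))
  if (is.na(value)) return(NA_character_)
  guideline$label[match(TRUE, abs(value) >= guideline$threshold)]
}

#' Waterfall table of volumetric response
#'
#' Per-patient percentage volume change at the first response evaluation,
#' sorted descending (the waterfall order), annotated with the best overall
#' response label and the pretreatment growth rate. Patients without a
#' TP+1 measurement are excluded with a message.
#'
#' @param cohort a \code{tumor_cohort}.
#' @param fits per-patient fit table from [compute_cohort_growth_rates()]
#'   (or any data frame with \code{patient_id} and \code{alpha}).
#' @return data frame: \code{patient_id}, \code{pct_change},
#'   \code{best_response}, \code{alpha}, sorted by decreasing
#'   \code{pct_change} (ties broken by patient id).
#' @export
waterfall_table <- function(cohort, fits) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  pats <- cohort$patients
  v_tp0 <- vapply(cohort$timelines, function(tl) tl$total_volumes[["TP0"]],
                  numeric(1))[pats$patient_id]
  v_tp1 <- vapply(cohort$timelines, function(tl) {
    if ("TP+1" %in% tl$timepoints) tl$total_volumes[["TP+1"]] else NA_real_
  }, numeric(1))[pats$patient_id]
  has <- !is.na(v_tp1)
  if (any(!has))
    message(sum(!has), " patient(s) without a TP+1 measurement excluded ",
            "from the waterfall table")
  out <- data.frame(patient_id = pats$patient_id[has],
                    pct_change = tumor_volume_change(v_tp1[has],
                                                     v_tp0[has]),
                    best_response = pats$best_response[has],
                    stringsAsFactors = FALSE)
  out$alpha <- fits$alpha[match(out$patient_id, fits$patient_id)]
  out[order(-out$pct_change, out$patient_id), , drop = FALSE]
}

#' Validate the growth rate against response and clinical covariates
#'
#' Runs the standard association panel for the pretreatment growth rate:
#' Spearman rank correlation of alpha with the percentage volume change at
#' first response evaluation and with the baseline metastasis count, and
#' Cramer's V of alpha (discretized into its cohort quartiles) with
#' organ-involvement flags and the primary-site category where present.
#'
#' @param cohort a \code{tumor_cohort}.
#' @param fits fit table from [compute_cohort_growth_rates()].
#' @param alpha_discretization \code{"quartile"} (default) to cross-tabulate
#'   alpha by cohort quartile, or \code{"group"} for the slow/fast binary.
#' @return data frame: \code{variable}, \code{method}, \code{coefficient},
#'   \code{p_value} (NA for Cramer's V), \code{interpretation}.
#' @export
validate_alpha <- function(cohort, fits,
                           alpha_discretization = c("quartile", "group")) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  alpha_discretization <- match.arg(alpha_discretization)
  pats <- cohort$patients
  alpha <- fits$alpha[match(pats$patient_id, fits$patient_id)]
  rows <- list()
  push <- function(variable, method, coefficient, p_value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, method = method, coefficient = coefficient,
      p_value = p_value,
      interpretation = interpret_coefficient(coefficient, method),
      stringsAsFactors = FALSE)
  }

  wf <- suppressMessages(waterfall_table(cohort, fits))
  if (nrow(wf) >= 3) {
    sp <- spearman_correlation(wf$alpha, wf$pct_change)
    push("volume_change_tp1", "spearman", sp$rho, sp$p_value)
  }
  sp <- spearman_correlation(alpha, as.numeric(pats$n_met_baseline))
  push("n_metastases", "spearman", sp$rho, sp$p_value)

  strata <- assign_groups(alpha, patient_ids = pats$patient_id)
  acat <- if (alpha_discretization == "quartile") strata$quartile
          else strata$group
  for (col in c("met_liver", "met_lung", "met_brain", "met_bone",
                "primary_site")) {
    if (!col %in% names(pats)) next
    cv <- suppressWarnings(cramers_v(acat, pats[[col]]))
    push(col, "cramers_v", cv$v, NA_real_)
  }
  do.call(rbind, rows)
}
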