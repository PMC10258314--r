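TIMEPOINTS <- c("TP-1", "TP0", "TP+1", "TP+2")
LESION_SITES <- c("brain", "liver", "bone", "lung", "lymph_node", "other")
RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD")

.LESION_COLS <- c("patient_id", "timepoint", "lesion_id", "volume_cc", "site")
.PATIENT_COLS <- c("patient_id", "de_novo", "tp_minus1_offset_days",
                   "os_days", "os_event", "pfs_days", "pfs_event",
                   "pfs2_days", "pfs2_event", "best_response")

#' Pretreatment imputation policy
#'
#' De novo metastatic patients present with measurable disease for the first
#' time at baseline (TP0); their pretreatment state is imputed as a minimal
#' detectable volume at a fixed interval before baseline. The conventional
#' default is 0.1 cc at -90 days, reflecting a routine three-monthly imaging
#' schedule and the smallest volume reliably resolved on CT.
#'
#' @param volume imputed pretreatment volume (cc), > 0. Default 0.1.
#' @param offset imputed day offset of the pretreatment scan relative to
#'   baseline; must be negative. Default -90.
#' @return a list of class \code{imputation_policy}.
#' @export
imputation_policy <- function(volume = 0.1, offset = -90) {
  if (!is.numeric(volume) || length(volume) != 1L || !is.finite(volume) ||
      volume <= 0)
    stop("imputation 'volume' must be a single positive number (cc)")
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset) ||
      offset >= 0)
    stop("imputation 'offset' must be a single negative number (days)")
  structure(list(volume = volume, offset = offset),
            class = "imputation_policy")
}

#' Load a volumetric cohort from delimited files
#'
#' Reads and validates the two-file cohort schema: a long-format lesion
#' table (one contoured lesion volume per row) and a patient table
#' (covariates, endpoints, best response). All schema violations are
#' collected and reported together, with row numbers.
#'
#' @param lesions path to the lesion CSV (columns \code{patient_id},
#'   \code{timepoint} in \code{TP-1}/\code{TP0}/\code{TP+1}/\code{TP+2},
#'   \code{lesion_id}, \code{volume_cc} > 0, \code{site}) or an equivalent
#'   data frame.
#' @param patients path to the patient CSV (columns \code{patient_id},
#'   \code{de_novo} 0/1, \code{tp_minus1_offset_days} (negative days; NA for
#'   de novo patients), \code{os_days}, \code{os_event}, \code{pfs_days},
#'   \code{pfs_event}, \code{pfs2_days}, \code{pfs2_event},
#'   \code{best_response} in CR/PR/SD/PD; optionally \code{primary_site},
#'   \code{met_brain}/\code{met_liver}/\code{met_bone}/\code{met_lung}
#'   organ-involvement flags and \code{n_met_baseline}) or an equivalent
#'   data frame.
#' @param schema_version schema identifier; only \code{"1"} is defined.
#' @return an object of class \code{tumor_cohort}: a list with elements
#'   \code{lesions}, \code{patients} and \code{timelines} (one per patient:
#'   day offsets, total volumes per timepoint, imputation provenance).
#' @export
load_cohort <- function(lesions, patients, schema_version = "1") {
  if (!identical(as.character(schema_version), "1"))
    stop("unknown schema_version: ", schema_version)
  lesions <- .read_table(lesions, .LESION_COLS, "lesions")
  patients <- .read_table(patients, .PATIENT_COLS, "patients")
  errs <- character()
  add <- function(...) errs[[length(errs) + 1L]] <<- sprintf(...)

  ## lesion-level checks
  bad_tp <- which(!lesions$timepoint %in% TIMEPOINTS)
  for (i in bad_tp) add("lesions row %d: unknown timepoint label '%s'", i,
                        lesions$timepoint[i])
  bad_v <- which(!is.finite(lesions$volume_cc) | lesions$volume_cc <= 0)
  for (i in bad_v) add("lesions row %d: non-positive volume %s", i,
                       as.character(lesions$volume_cc[i]))
  bad_site <- which(!lesions$site %in% LESION_SITES)
  for (i in bad_site) add("lesions row %d: unknown site '%s'", i,
                          lesions$site[i])
  key <- paste(lesions$patient_id, lesions$timepoint, lesions$lesion_id)
  dup <- which(duplicated(key))
  for (i in dup) add("lesions row %d: duplicate lesion key (%s)", i, key[i])

  ## patient-level checks
  dup_p <- which(duplicated(patients$patient_id))
  for (i in dup_p) add("patients row %d: duplicate patient_id '%s'", i,
                       patients$patient_id[i])
  if (!all(patients$de_novo %in% c(0, 1, TRUE, FALSE)))
    add("patients: 'de_novo' must be 0/1")
  for (ep in c("os", "pfs", "pfs2")) {
    tcol <- paste0(ep, "_days"); ecol <- paste0(ep, "_event")
    bad_t <- which(!is.finite(patients[[tcol]]) | patients[[tcol]] < 0)
    for (i in bad_t) add("patients row %d: invalid %s %s", i, tcol,
                         as.character(patients[[tcol]][i]))
    bad_e <- which(!patients[[ecol]] %in% c(0, 1))
    for (i in bad_e) add("patients row %d: %s must be 0/1", i, ecol)
  }
  bad_ord <- which(patients$pfs_days > patients$os_days |
                     patients$pfs_days > patients$pfs2_days)
  for (i in bad_ord)
    add("patients row %d (%s): PFS time exceeds OS or PFS2 time", i,
        patients$patient_id[i])
  bad_resp <- which(!is.na(patients$best_response) &
                      !patients$best_response %in% RESPONSE_LEVELS)
  for (i in bad_resp) add("patients row %d: unknown best_response '%s'", i,
                          patients$best_response[i])

  ## cross-table checks
  lp <- unique(lesions$patient_id)
  orphan <- setdiff(lp, patients$patient_id)
  for (p in orphan) add("lesions reference unknown patient '%s'", p)
  no_tp0 <- setdiff(patients$patient_id,
                    unique(lesions$patient_id[lesions$timepoint == "TP0"]))
  for (p in no_tp0) add("patient '%s' has no TP0 lesion measurements", p)
  measured <- !(patients$de_novo %in% c(1, TRUE))
  has_tpm1 <- patients$patient_id %in%
    unique(lesions$patient_id[lesions$timepoint == "TP-1"])
  for (i in which(measured & !has_tpm1))
    add("patient '%s' is not de novo but has no TP-1 lesion measurements",
        patients$patient_id[i])
  for (i in which(!measured & has_tpm1))
    add("patient '%s' is flagged de novo but has TP-1 lesion measurements",
        patients$patient_id[i])
  bad_off <- which(measured & (!is.finite(patients$tp_minus1_offset_days) |
                                 patients$tp_minus1_offset_days >= 0))
  for (i in bad_off)
    add("patient '%s': tp_minus1_offset_days must be a negative day count",
        patients$patient_id[i])

  if (length(errs))
    stop("cohort validation failed:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)

  off <- patients$tp_minus1_offset_days[measured]
  outside <- which(off < -363 | off > -6)
  if (length(outside))
    warning(length(outside), " patient(s) have a TP-1 interval outside the ",
            "typical -363..-6 day range; admitted as-is")

  patients$de_novo <- as.logical(patients$de_novo)
  if (!"n_met_baseline" %in% names(patients)) {
    tp0 <- lesions[lesions$timepoint == "TP0", ]
    cnt <- table(tp0$patient_id)
    patients$n_met_baseline <-
      as.integer(cnt[match(patients$patient_id, names(cnt))])
  }
  cohort <- structure(list(lesions = lesions, patients = patients),
                      class = "tumor_cohort")
  cohort$timelines <- .build_timelines(cohort)
  cohort
}

.read_table <- function(x, required, what) {
  if (is.character(x)) {
    if (!file.exists(x)) stop(what, " file not found: ", x)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) stop("'", what, "' must be a path or a data frame")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  x$patient_id <- as.character(x$patient_id)
  x
}

.build_timelines <- function(cohort) {
  les <- cohort$lesions
  pats <- cohort$patients
  out <- vector("list", nrow(pats))
  names(out) <- pats$patient_id
  for (i in seq_len(nrow(pats))) {
    pid <- pats$patient_id[i]
    pl <- les[les$patient_id == pid, ]
    tps <- TIMEPOINTS[TIMEPOINTS %in% pl$timepoint]
    vols <- vapply(tps, function(tp) aggregate_lesions(pl, tp), numeric(1))
    offs <- vapply(tps, function(tp) {
      switch(tp,
             "TP-1" = pats$tp_minus1_offset_days[i],
             "TP0" = 0,
             "TP+1" = .opt_col(pats, "tp_plus1_offset_days", i),
             "TP+2" = .opt_col(pats, "tp_plus2_offset_days", i))
    }, numeric(1))
    out[[i]] <- structure(list(
      patient_id = pid,
      timepoints = tps,
      offsets = offs,
      total_volumes = vols,
      imputed = stats::setNames(rep(FALSE, length(tps)), tps),
      de_novo = pats$de_novo[i],
      n_met_baseline = pats$n_met_baseline[i],
      imputation_applied = FALSE), class = "patient_timeline")
  }
  out
}

.opt_col <- function(df, col, i) {
  if (col %in% names(df)) as.numeric(df[[col]][i]) else NA_real_
}

#' Total metastatic volume at a timepoint
#'
#' Exact sum of a patient's lesion volumes at one imaging timepoint.
#'
#' @param measurements lesion-level data frame for one patient (columns
#'   \code{timepoint}, \code{volume_cc}).
#' @param timepoint one of \code{"TP-1"}, \code{"TP0"}, \code{"TP+1"},
#'   \code{"TP+2"}.
#' @return the summed volume (cc), or \code{NA_real_} if the patient has no
#'   measurement at that timepoint (absent-timepoint signal, not an error).
#' @export
aggregate_lesions <- function(measurements, timepoint) {
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  v <- measurements$volume_cc[measurements$timepoint == timepoint]
  if (length(v) == 0L) return(NA_real_)
  sum(v)
}

#' Impute the pretreatment state of de novo patients
#'
#' Inserts an imputed TP-1 observation (\code{policy$offset} days,
#' \code{policy$volume} cc) into every timeline lacking pretreatment data.
#' Timelines with a measured TP-1 are returned unchanged. The operation is
#' idempotent.
#'
#' @param x a \code{tumor_cohort} or a single \code{patient_timeline}.
#' @param policy an [imputation_policy()].
#' @return the input with imputed TP-1 entries and
#'   \code{imputation_applied} flags set.
#' @export
impute_pretreatment <- function(x, policy = imputation_policy()) {
  stopifnot(inherits(policy, "imputation_policy"))
  if (inherits(x, "patient_timeline")) return(.impute_one(x, policy))
  if (!inherits(x, "tumor_cohort"))
    stop("'x' must be a tumor_cohort or patient_timeline")
  min_tp0 <- min(vapply(x$timelines,
                        function(tl) tl$total_volumes[["TP0"]], numeric(1)))
  if (policy$volume > min_tp0)
    warning(sprintf(paste0("imputation volume %g cc exceeds the smallest ",
                           "measured baseline volume %g cc; imputed growth ",
                           "rates will be forced negative"),
                    policy$volume, min_tp0))
  x$timelines <- lapply(x$timelines, .impute_one, policy = policy)
  x
}

.impute_one <- function(tl, policy) {
  if ("TP-1" %in% tl$timepoints) {
    if (!tl$imputation_applied) tl$imputation_applied <- FALSE
    return(tl)
  }
  tl$timepoints <- c("TP-1", tl$timepoints)
  tl$offsets <- c("TP-1" = policy$offset, tl$offsets)
  tl$total_volumes <- c("TP-1" = policy$volume, tl$total_volumes)
  tl$imputed <- c("TP-1" = TRUE, tl$imputed)
  tl$imputation_applied <- TRUE
  tl
}

#' Pretreatment growth rates for a whole cohort
#'
#' Applies the imputation policy, then fits the chosen growth model to each
#' patient's pretreatment series (TP-1 and TP0 only; on-treatment timepoints
#' are never used) and returns a flat per-patient fit table.
#'
#' @param cohort a \code{tumor_cohort}.
#' @param model growth model name; default \code{"exponential"} (whose
#'   single parameter is the pretreatment growth rate alpha, 1/day).
#' @param policy an [imputation_policy()].
#' @return a data frame with one row per patient (\code{patient_id}, model
#'   parameters, \code{alpha}, \code{rss}, \code{converged},
#'   \code{underdetermined}, \code{imputed}); the list of underlying
#'   \code{growth_fit} objects is attached as attribute \code{"fits"}.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 8, seed = 1))
#' fits <- compute_cohort_growth_rates(coh)
#' head(fits$alpha)
#' @export
compute_cohort_growth_rates <- function(cohort, model = "exponential",
                                        policy = imputation_policy()) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  cohort <- impute_pretreatment(cohort, policy)
  fits <- lapply(cohort$timelines, function(tl) {
    obs <- data.frame(t = c(tl$offsets[["TP-1"]], 0),
                      v = c(tl$total_volumes[["TP-1"]],
                            tl$total_volumes[["TP0"]]))
    tryCatch(fit_growth_model(model, obs),
             error = function(e) {
               f <- .new_growth_fit(model, c(a = NA_real_), obs,
                                    rss = NA_real_, converged = FALSE,
                                    underdetermined = TRUE,
                                    method = "failed")
               f$failure <- conditionMessage(e)
               f
             })
  })
  tab <- growth_fit_table(fits)
  tab$imputed <- vapply(cohort$timelines, function(tl)
    isTRUE(tl$imputed[["TP-1"]]), logical(1))
  attr(tab, "fits") <- fits
  tab
}

#' @export
print.tumor_cohort <- function(x, ...) {
  cat("Volumetric tumor cohort:", nrow(x$patients), "patients,",
      nrow(x$lesions), "lesion measurements\n")
  cat("  de novo (imputation required):", sum(x$patients$de_novo), "\n")
  tp_n <- table(factor(x$lesions$timepoint, levels = TIMEPOINTS))
  cat("  patients per timepoint:",
      paste(sprintf("%s=%d", names(tp_n),
                    vapply(TIMEPOINTS, function(tp)
                      length(unique(x$lesions$patient_id[
                        x$lesions$timepoint == tp])), integer(1))),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tumor_cohort <- function(object, ...) summarize_cohort(object)

#' Write a cohort to the two-file delimited schema
#'
#' @param cohort a \code{tumor_cohort}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths of \code{lesions.csv} and
#'   \code{patients.csv}.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lf <- file.path(dir, "lesions.csv")
  pf <- file.path(dir, "patients.csv")
  # serialize doubles at full (round-trip) precision
  fmt <- function(df) {
    for (col in names(df))
      if (is.double(df[[col]]))
        df[[col]] <- ifelse(is.na(df[[col]]), NA,
                            sprintf("%.17g", df[[col]]))
    df
  }
  utils::write.csv(fmt(cohort$lesions), lf, row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(cohort$patients), pf, row.names = FALSE, quote = FALSE)
  invisible(c(lesions = lf, patients = pf))
}
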