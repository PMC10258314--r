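.CONFIG_KEYS <- c("inputs", "model", "imputation", "quantile_type",
                  "threshold", "subgroup_cutoff", "sensitivity",
                  "endpoints", "eval_horizon_days", "output_dir", "seed")

.default_config <- function() {
  list(inputs = list(lesions = NULL, patients = NULL),
       model = "exponential",
       imputation = list(volume = 0.1, offset = -90),
       quantile_type = 7,
       threshold = "derived",
       subgroup_cutoff = 5,
       sensitivity = list(volumes = c(0.01, 0.1, 1),
                          offsets = seq(-150, -30, by = 30)),
       endpoints = ENDPOINTS,
       eval_horizon_days = 1095,
       output_dir = "oligogrowth_out",
       seed = 1)
}

#' Validate a run configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), fills
#' defaults, and validates every field; all violations are reported
#' together. Unknown keys are rejected.
#'
#' @param config path to a YAML file, or a named list.
#' @return a validated configuration list of class \code{run_config}.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("'config' must be a path or a named list")
  errs <- character()
  add <- function(...) errs[[length(errs) + 1L]] <<- sprintf(...)
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  for (k in unknown) add("unknown configuration key '%s'", k)
  cfg <- utils::modifyList(.default_config(), config)

  if (!is.character(cfg$model) || !cfg$model %in% growth_models())
    add("unknown model '%s'; allowed: %s", as.character(cfg$model)[1],
        paste(growth_models(), collapse = ", "))
  if (!is.numeric(cfg$imputation$volume) || cfg$imputation$volume <= 0)
    add("imputation.volume must be a positive volume (cc)")
  if (!is.numeric(cfg$imputation$offset) || cfg$imputation$offset >= 0)
    add("imputation.offset must be a negative day count")
  if (!cfg$quantile_type %in% 1:9)
    add("quantile_type must be an integer 1-9")
  if (!(identical(cfg$threshold, "derived") ||
        (is.numeric(cfg$threshold) && is.finite(cfg$threshold))))
    add("threshold must be \"derived\" or a finite number (1/day)")
  if (!is.numeric(cfg$subgroup_cutoff) || cfg$subgroup_cutoff < 1)
    add("subgroup_cutoff must be a positive lesion count")
  if (!is.numeric(cfg$sensitivity$volumes) ||
      any(cfg$sensitivity$volumes <= 0))
    add("sensitivity.volumes must be positive volumes (cc)")
  if (!is.numeric(cfg$sensitivity$offsets) ||
      any(cfg$sensitivity$offsets >= 0))
    add("sensitivity.offsets must be negative day counts")
  if (!all(cfg$endpoints %in% ENDPOINTS))
    add("endpoints must be a subset of %s",
        paste(ENDPOINTS, collapse = ", "))
  if (!is.numeric(cfg$eval_horizon_days) || cfg$eval_horizon_days <= 0)
    add("eval_horizon_days must be positive")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || !is.finite(cfg$seed))
    add("seed must be a single number")
  if (length(errs))
    stop("invalid run configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  structure(cfg, class = c("run_config", "list"))
}

#' Run the end-to-end growth-rate survival analysis
#'
#' Orchestrates the full workflow on a validated cohort: per-patient
#' growth-rate fits under the configured imputation policy, quartile
#' stratification and the slow/fast dichotomy, Kaplan-Meier curves and
#' log-rank comparisons per endpoint (overall, oligometastatic and
#' polymetastatic subgroups, and all quartile pairs), the association
#' panel, the waterfall table, the imputation sensitivity grid, and a
#' machine-readable run manifest. Artifacts are written as delimited
#' tables to \code{config$output_dir}; any stage failure aborts with a
#' stage-named error and removes partial outputs.
#'
#' @param config a [validate_config()] result, YAML path, or list.
#' @param cohort optionally, an in-memory \code{tumor_cohort}; otherwise
#'   the cohort is loaded from \code{config$inputs}.
#' @return invisibly, a list of class \code{oligogrowth_run} with all
#'   computed tables and the manifest.
#' @export
run_analysis <- function(config = list(), cohort = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  written <- character()
  outdir <- config$output_dir
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop(sprintf("analysis stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    emit <- function(df, name) {
      path <- file.path(outdir, name)
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      written <<- c(written, path)
      path
    }

    stage <- "load"
    if (is.null(cohort))
      cohort <- load_cohort(config$inputs$lesions, config$inputs$patients)
    message(sprintf("[load] %d patients, %d lesion measurements, %d de novo",
                    nrow(cohort$patients), nrow(cohort$lesions),
                    sum(cohort$patients$de_novo)))

    stage <- "fit"
    policy <- imputation_policy(config$imputation$volume,
                                config$imputation$offset)
    fits <- compute_cohort_growth_rates(cohort, model = config$model,
                                        policy = policy)
    message(sprintf("[fit] model=%s, %d fits (%d imputed), median alpha=%.4g",
                    config$model, nrow(fits), sum(fits$imputed),
                    stats::median(fits$alpha, na.rm = TRUE)))
    emit(fits, "fits.csv")

    stage <- "stratify"
    thr <- if (identical(config$threshold, "derived")) NULL
           else config$threshold
    strata <- assign_groups(fits$alpha, threshold = thr,
                            patient_ids = fits$patient_id,
                            type = config$quantile_type)
    strata_out <- strata
    strata_out$threshold <- attr(strata, "threshold")
    message(sprintf("[stratify] threshold=%.4g /day, %d slow vs %d fast",
                    attr(strata, "threshold"),
                    sum(strata$group == "slow"),
                    sum(strata$group == "fast")))
    emit(strata_out, "strata.csv")

    stage <- "survival"
    sub <- subgroup_by_met_count(cohort, config$subgroup_cutoff)
    scopes <- list(overall = cohort$patients$patient_id,
                   oligo = sub$oligo, poly = sub$poly)
    km_rows <- list(); lr_rows <- list()
    for (ep in config$endpoints) {
      rec <- cohort_endpoint(cohort, ep)
      for (sc in names(scopes)) {
        ids <- scopes[[sc]]
        r <- rec[rec$patient_id %in% ids, ]
        s <- strata[strata$patient_id %in% ids, ]
        slow_ids <- s$patient_id[s$group == "slow"]
        for (g in c("slow", "fast")) {
          rg <- r[if (g == "slow") r$patient_id %in% slow_ids
                  else !r$patient_id %in% slow_ids, ]
          if (nrow(rg) == 0L) next
          km <- km_estimate(rg)
          if (length(km$event_times))
            km_rows[[length(km_rows) + 1L]] <-
              cbind(endpoint = ep, scope = sc, group = g,
                    as.data.frame(km))
        }
        ra <- r[r$patient_id %in% slow_ids, ]
        rb <- r[!r$patient_id %in% slow_ids, ]
        if (nrow(ra) && nrow(rb)) {
          lr <- logrank_test(ra, rb)
          lr_rows[[length(lr_rows) + 1L]] <- data.frame(
            endpoint = ep, scope = sc, comparison = "slow vs fast",
            n_1 = nrow(ra), n_2 = nrow(rb),
            statistic = lr$statistic, p_value = lr$p_value,
            surv_1 = survival_at(km_estimate(ra), config$eval_horizon_days),
            surv_2 = survival_at(km_estimate(rb), config$eval_horizon_days),
            flagged = FALSE)
        } else {
          lr_rows[[length(lr_rows) + 1L]] <- data.frame(
            endpoint = ep, scope = sc, comparison = "slow vs fast",
            n_1 = nrow(ra), n_2 = nrow(rb), statistic = NA_real_,
            p_value = NA_real_, surv_1 = NA_real_, surv_2 = NA_real_,
            flagged = TRUE)
        }
      }
      pq <- pairwise_quartile_comparisons(strata, rec)
      pq <- cbind(endpoint = ep, scope = "overall",
                  comparison = pq$comparison, pq[c("n_1", "n_2",
                                                   "statistic", "p_value")],
                  surv_1 = NA_real_, surv_2 = NA_real_,
                  flagged = pq$flagged)
      lr_rows[[length(lr_rows) + 1L]] <- pq
    }
    km_tab <- if (length(km_rows)) do.call(rbind, km_rows)
              else data.frame(endpoint = character(), scope = character(),
                              group = character(), time = numeric(),
                              at_risk = integer(), events = integer(),
                              survival = numeric())
    lr_tab <- do.call(rbind, lr_rows)
    message(sprintf("[survival] %d KM curves, %d log-rank comparisons",
                    length(km_rows), nrow(lr_tab)))
    emit(km_tab, "km_curves.csv")
    emit(lr_tab, "logrank_results.csv")

    stage <- "association"
    assoc <- validate_alpha(cohort, fits)
    emit(assoc, "associations.csv")

    stage <- "waterfall"
    wf <- suppressMessages(waterfall_table(cohort, fits))
    emit(wf, "waterfall.csv")

    stage <- "sensitivity"
    grid <- run_sensitivity_grid(cohort,
                                 volume_axis = config$sensitivity$volumes,
                                 offset_axis = config$sensitivity$offsets,
                                 endpoints = config$endpoints,
                                 threshold = thr,
                                 type = config$quantile_type)
    message(sprintf("[sensitivity] %d cells, p<=0.05 in %d",
                    nrow(grid), sum(grid$p_value <= 0.05, na.rm = TRUE)))
    emit(as.data.frame(grid), "sensitivity.csv")

    stage <- "manifest"
    cfg_plain <- unclass(config)
    manifest <- list(
      package = "oligogrowth",
      package_version = as.character(utils::packageVersion("oligogrowth")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      config = cfg_plain,
      config_hash = .fnv1a(jsonlite::toJSON(cfg_plain, auto_unbox = TRUE)),
      n_patients = nrow(cohort$patients),
      n_imputed = sum(fits$imputed),
      threshold = attr(strata, "threshold"),
      artifacts = basename(written))
    mpath <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, mpath)

    res <- structure(list(config = config, fits = fits, strata = strata,
                          km = km_tab, logrank = lr_tab,
                          associations = assoc, waterfall = wf,
                          sensitivity = grid, manifest = manifest,
                          paths = written),
                     class = "oligogrowth_run")
    invisible(res)
  }, error = on_fail)
}

# deterministic polynomial hash of the UTF-8 bytes (mod 2^31 - 1), hex
.fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.oligogrowth_run <- function(x, ...) {
  cat("oligogrowth analysis run\n")
  cat("  patients:", nrow(x$fits), " threshold:",
      format(x$manifest$threshold, digits = 4), "/day\n")
  ov <- x$logrank[x$logrank$scope == "overall" &
                    x$logrank$comparison == "slow vs fast", ]
  for (i in seq_len(nrow(ov)))
    cat(sprintf("  %s slow vs fast: p = %.4g (S(%d d): %.2f vs %.2f)\n",
                ov$endpoint[i], ov$p_value[i], x$config$eval_horizon_days,
                ov$surv_1[i], ov$surv_2[i]))
  cat("  artifacts:", paste(x$manifest$artifacts, collapse = ", "), "\n")
  invisible(x)
}
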