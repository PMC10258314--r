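#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated metastatic melanoma
#' immunotherapy cohort: cohort size and de novo fraction, the
#' distribution of the true pretreatment growth rate alpha (log-normal
#' with a small negative tail), baseline volume and pretreatment interval
#' distributions, a metastasis-count model rank-correlated with alpha
#' through a shared latent normal, a proportional-hazards link of survival
#' to alpha, administrative censoring, and multiplicative measurement
#' noise on volumes.
#'
#' Defaults emulate the reference cohort structure: 86 patients, 51% de
#' novo, baseline volume median 28.4 cc clamped to 0.4-1194.8 cc,
#' metastasis count median 7 clamped to 1-73, pretreatment interval median
#' 90 days clamped to 6-363, alpha median 0.0471/day with a 5% negative
#' component on (-0.0062, 0), baseline death hazard 1/1500 per day with
#' log-hazard slope 15 per unit alpha, and a censoring pattern giving a
#' median follow-up near 35 months.
#'
#' @param n_patients cohort size.
#' @param de_novo_fraction probability a patient is de novo (no measurable
#'   pretreatment disease; TP-1 must be imputed downstream).
#' @param alpha_meanlog,alpha_sdlog log-normal parameters of positive alpha
#'   (1/day).
#' @param alpha_neg_prob,alpha_neg_range probability and uniform range of
#'   the negative-alpha component.
#' @param volume_meanlog,volume_sdlog,volume_range log-normal parameters
#'   and clamp range (cc) of the true baseline volume.
#' @param interval_meanlog,interval_sdlog,interval_range log-normal
#'   parameters and clamp range (days, positive magnitudes) of the
#'   TP-1 to TP0 interval for measured patients.
#' @param met_meanlog,met_sdlog,met_range log-normal parameters and clamp
#'   range of the baseline metastasis count.
#' @param met_alpha_corr latent-normal correlation between alpha and the
#'   metastasis count (Gaussian copula).
#' @param hazard_baseline baseline death hazard h0 (1/day).
#' @param hazard_slope log-hazard slope beta on alpha: death hazard is
#'   \code{h0 * exp(beta * alpha)}.
#' @param progression_mult progression hazard as a multiple of the death
#'   hazard.
#' @param gap_mult hazard of the second-progression gap as a multiple of
#'   the death hazard.
#' @param horizon_days administrative follow-up horizon (days from first
#'   accrual).
#' @param accrual_days accrual window; per-patient follow-up is uniform on
#'   \code{[horizon_days - accrual_days, horizon_days]}.
#' @param dropout_rate exponential dropout hazard (1/day); 0 disables.
#' @param sigma_v standard deviation of multiplicative log-normal
#'   measurement noise on observed volumes (0 = noise-free).
#' @param tp1_day,tp2_day days of the on-treatment response evaluations.
#' @param prob_tp1 probability a patient has a TP+1 measurement.
#' @param prob_tp2 probability of a TP+2 measurement given TP+1.
#' @param post_rate_shrink,post_rate_sd the on-treatment growth rate is
#'   \code{post_rate_shrink * alpha + N(0, post_rate_sd)}: treatment
#'   suppresses growth while preserving the rank link between alpha and
#'   early volume change.
#' @param seed integer seed; expanded into per-patient substreams.
#' @return a validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 86,
                          de_novo_fraction = 0.51,
                          alpha_meanlog = log(0.0471), alpha_sdlog = 1.0,
                          alpha_neg_prob = 0.05,
                          alpha_neg_range = c(-0.0062, 0),
                          volume_meanlog = log(28.4), volume_sdlog = 1.2,
                          volume_range = c(0.4, 1194.8),
                          interval_meanlog = log(90), interval_sdlog = 0.6,
                          interval_range = c(6, 363),
                          met_meanlog = log(7), met_sdlog = 0.9,
                          met_range = c(1, 73),
                          met_alpha_corr = 0.5,
                          hazard_baseline = 1 / 1500, hazard_slope = 15,
                          progression_mult = 0.7, gap_mult = 1,
                          horizon_days = 1825, accrual_days = 1520,
                          dropout_rate = 0,
                          sigma_v = 0.2,
                          tp1_day = 70, tp2_day = 135,
                          prob_tp1 = 0.71, prob_tp2 = 0.70,
                          post_rate_shrink = 0.07, post_rate_sd = 0.004,
                          seed = 1) {
  cfg <- as.list(environment())
  errs <- character()
  chk <- function(cond, msg) if (!cond) errs[[length(errs) + 1L]] <<- msg
  chk(n_patients >= 1, "n_patients must be >= 1")
  chk(de_novo_fraction >= 0 && de_novo_fraction <= 1,
      "de_novo_fraction must lie in [0, 1]")
  for (nm in c("alpha_sdlog", "volume_sdlog", "interval_sdlog", "met_sdlog",
               "hazard_baseline", "progression_mult", "gap_mult",
               "dropout_rate", "sigma_v", "post_rate_sd"))
    chk(is.numeric(cfg[[nm]]) && cfg[[nm]] >= 0,
        paste(nm, "must be nonnegative"))
  for (nm in c("volume_range", "interval_range", "met_range"))
    chk(diff(cfg[[nm]]) > 0 && cfg[[nm]][1] > 0,
        paste(nm, "must be a nonempty positive range"))
  chk(alpha_neg_prob >= 0 && alpha_neg_prob <= 1,
      "alpha_neg_prob must lie in [0, 1]")
  chk(diff(alpha_neg_range) > 0 && alpha_neg_range[2] <= 0,
      "alpha_neg_range must be a nonempty nonpositive range")
  chk(abs(met_alpha_corr) <= 1, "met_alpha_corr must lie in [-1, 1]")
  chk(prob_tp1 >= 0 && prob_tp1 <= 1 && prob_tp2 >= 0 && prob_tp2 <= 1,
      "prob_tp1/prob_tp2 must lie in [0, 1]")
  chk(accrual_days >= 0 && accrual_days < horizon_days,
      "accrual_days must lie in [0, horizon_days)")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
      "seed must be a single number")
  if (length(errs))
    stop("invalid cohort configuration:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  structure(cfg, class = "cohort_config")
}

.SITE_PROBS <- c(lung = 0.30, lymph_node = 0.20, liver = 0.15, bone = 0.15,
                 brain = 0.10, other = 0.10)
.PRIMARY_PROBS <- c(Cutaneous = 0.45, Mucosal = 0.30, Ocular = 0.15,
                    Unknown = 0.10)

# deterministic per-patient substream seed (< 2^31), so growing a cohort
# does not reshuffle existing patients
.patient_seed <- function(seed, i) {
  s <- (abs(as.numeric(seed)) %% 40009) * 48271 + i * 1299709
  as.integer(s %% 2147483647) + 1L
}

#' Generate a seeded synthetic cohort
#'
#' Draws a full synthetic cohort under a [cohort_config()]: per-patient
#' true growth rate, noise-free volumes at all timepoints, lesion-level
#' splits, survival endpoints linked to alpha through a proportional
#' hazard, and right censoring. The result passes [load_cohort()]
#' validation; the per-patient ground truth (true alpha, noise-free
#' volumes, uncensored event time, censoring time) is attached as
#' attribute \code{"truth"}.
#'
#' @param config a [cohort_config()].
#' @return a \code{tumor_cohort} with attributes \code{"truth"} (data
#'   frame) and \code{"config"}.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 10, seed = 42))
#' attr(coh, "truth")$alpha
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  lesions <- list(); patients <- list(); truth <- list()

  for (i in seq_len(n)) {
    set.seed(.patient_seed(cfg$seed, i))
    pid <- ids[i]

    ## true growth rate (mixture) + latent normal for the count copula
    z1 <- stats::rnorm(1)
    neg <- stats::runif(1) < cfg$alpha_neg_prob
    alpha <- if (neg) stats::runif(1, cfg$alpha_neg_range[1],
                                   cfg$alpha_neg_range[2])
             else exp(cfg$alpha_meanlog + cfg$alpha_sdlog * z1)

    zv <- stats::rnorm(1)
    v0_true <- .clamp(exp(cfg$volume_meanlog + cfg$volume_sdlog * zv),
                      cfg$volume_range)
    de_novo <- stats::runif(1) < cfg$de_novo_fraction
    interval <- if (de_novo) NA_real_ else
      round(.clamp(exp(cfg$interval_meanlog +
                         cfg$interval_sdlog * stats::rnorm(1)),
                   cfg$interval_range))
    if (de_novo) {
      # a de novo presentation means the disease grew from below the
      # detection limit within the surveillance interval: the true growth
      # rate is set by the baseline volume, so the imputed biomarker is a
      # consistent (noisy) estimate of it
      alpha <- log(v0_true / 0.1) / 90
    }

    z_driver <- if (de_novo) zv else z1
    z2 <- cfg$met_alpha_corr * z_driver +
      sqrt(1 - cfg$met_alpha_corr^2) * stats::rnorm(1)
    n_met <- as.integer(.clamp(round(exp(cfg$met_meanlog +
                                           cfg$met_sdlog * z2)),
                               cfg$met_range))

    ## noise-free volumes at every timepoint
    v_pre_true <- if (de_novo) NA_real_ else v0_true * exp(-alpha * interval)
    alpha_post <- cfg$post_rate_shrink * alpha +
      stats::rnorm(1, 0, cfg$post_rate_sd)
    v1_true <- v0_true * exp(alpha_post * cfg$tp1_day)
    v2_true <- v0_true * exp(alpha_post * cfg$tp2_day)
    has_tp1 <- stats::runif(1) < cfg$prob_tp1
    has_tp2 <- has_tp1 && stats::runif(1) < cfg$prob_tp2

    noise <- function() exp(cfg$sigma_v * stats::rnorm(1))
    v0_obs <- v0_true * noise()
    v_pre_obs <- if (de_novo) NA_real_ else v_pre_true * noise()
    v1_obs <- if (has_tp1) v1_true * noise() else NA_real_
    v2_obs <- if (has_tp2) v2_true * noise() else NA_real_

    ## survival linked to alpha
    h_d <- cfg$hazard_baseline * exp(cfg$hazard_slope * alpha)
    t_death <- stats::rexp(1, h_d)
    t_prog <- stats::rexp(1, cfg$progression_mult * h_d)
    gap <- stats::rexp(1, cfg$gap_mult * h_d)
    pfs_t <- min(t_prog, t_death)
    pfs2_t <- if (t_prog < t_death) min(t_prog + gap, t_death) else t_death
    cens <- cfg$horizon_days - stats::runif(1, 0, cfg$accrual_days)
    if (cfg$dropout_rate > 0)
      cens <- min(cens, stats::rexp(1, cfg$dropout_rate))

    ev <- function(t) c(time = round(min(t, cens)), event = as.numeric(t <= cens))
    os <- ev(t_death); pfs <- ev(pfs_t); pfs2 <- ev(pfs2_t)

    ## lesion-level split per available timepoint
    sites0 <- sample(names(.SITE_PROBS), n_met, replace = TRUE,
                     prob = .SITE_PROBS)
    les <- list(.lesion_rows(pid, "TP0", v0_obs, n_met, sites0))
    if (!de_novo) {
      n_pre <- max(1L, as.integer(round(n_met * stats::runif(1, 0.2, 0.8))))
      sites_pre <- sample(sites0, n_pre, replace = n_pre > n_met)
      les <- c(les, list(.lesion_rows(pid, "TP-1", v_pre_obs, n_pre,
                                      sites_pre)))
    }
    if (has_tp1)
      les <- c(les, list(.lesion_rows(pid, "TP+1", v1_obs, n_met, sites0)))
    if (has_tp2)
      les <- c(les, list(.lesion_rows(pid, "TP+2", v2_obs, n_met, sites0)))
    lesions[[i]] <- do.call(rbind, les)

    best_pct <- 100 * (exp(alpha_post * cfg$tp2_day) - 1)
    best_response <-
      if (best_pct <= -99) "CR" else if (best_pct <= -30) "PR"
      else if (best_pct >= 20) "PD" else "SD"

    patients[[i]] <- data.frame(
      patient_id = pid, de_novo = as.integer(de_novo),
      tp_minus1_offset_days = if (de_novo) NA_real_ else -interval,
      tp_plus1_offset_days = if (has_tp1) cfg$tp1_day else NA_real_,
      tp_plus2_offset_days = if (has_tp2) cfg$tp2_day else NA_real_,
      primary_site = sample(names(.PRIMARY_PROBS), 1,
                            prob = .PRIMARY_PROBS),
      met_brain = as.integer("brain" %in% sites0),
      met_liver = as.integer("liver" %in% sites0),
      met_bone = as.integer("bone" %in% sites0),
      met_lung = as.integer("lung" %in% sites0),
      n_met_baseline = n_met,
      os_days = os[["time"]], os_event = os[["event"]],
      pfs_days = pfs[["time"]], pfs_event = pfs[["event"]],
      pfs2_days = pfs2[["time"]], pfs2_event = pfs2[["event"]],
      best_response = best_response,
      stringsAsFactors = FALSE)

    truth[[i]] <- data.frame(
      patient_id = pid, alpha = alpha, alpha_post = alpha_post,
      de_novo = de_novo,
      v_tpm1_true = v_pre_true, v_tp0_true = v0_true,
      v_tp1_true = v1_true, v_tp2_true = v2_true,
      event_time = t_death, censor_time = cens,
      stringsAsFactors = FALSE)
  }

  cohort <- suppressWarnings(
    load_cohort(do.call(rbind, lesions), do.call(rbind, patients)))
  attr(cohort, "truth") <- do.call(rbind, truth)
  attr(cohort, "config") <- cfg
  cohort
}

.clamp <- function(x, range) pmin(pmax(x, range[1]), range[2])

.lesion_rows <- function(pid, tp, total, n, sites) {
  v <- generate_lesion_split(total, n)
  data.frame(patient_id = pid, timepoint = tp,
             lesion_id = sprintf("L%02d", seq_len(n)),
             volume_cc = v, site = sites, stringsAsFactors = FALSE)
}

#' Split a total volume into lesion volumes
#'
#' Dirichlet-style split: gamma weights normalized to sum exactly to the
#' total, all strictly positive.
#'
#' @param total_volume total volume (cc) > 0.
#' @param n_lesions number of lesions >= 1.
#' @param seed optional seed for a reproducible stand-alone split; by
#'   default the current RNG stream is used.
#' @return numeric vector of \code{n_lesions} positive volumes summing to
#'   \code{total_volume}.
#' @export
generate_lesion_split <- function(total_volume, n_lesions, seed = NULL) {
  if (!is.numeric(total_volume) || total_volume <= 0)
    stop("'total_volume' must be positive")
  if (!is.numeric(n_lesions) || n_lesions < 1)
    stop("'n_lesions' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_lesions)
  if (n == 1L) return(total_volume)
  w <- pmax(stats::rgamma(n, shape = 1), 1e-12)
  total_volume * w / sum(w)
}

#' Descriptive summary of a cohort
#'
#' Medians and ranges of the cohort descriptors: baseline cumulative
#' volume, baseline metastasis count, measured TP-1 interval, and the
#' pretreatment growth rate alpha computed under the default imputation
#' convention.
#'
#' @param cohort a \code{tumor_cohort}.
#' @param policy imputation policy used when computing alpha.
#' @return data frame with columns \code{quantity}, \code{n},
#'   \code{median}, \code{min}, \code{max}.
#' @export
summarize_cohort <- function(cohort, policy = imputation_policy()) {
  stopifnot(inherits(cohort, "tumor_cohort"))
  pats <- cohort$patients
  v0 <- vapply(cohort$timelines, function(tl) tl$total_volumes[["TP0"]],
               numeric(1))
  iv <- -pats$tp_minus1_offset_days[!pats$de_novo]
  fits <- compute_cohort_growth_rates(cohort, policy = policy)
  row <- function(q, x) data.frame(quantity = q, n = sum(is.finite(x)),
                                   median = stats::median(x, na.rm = TRUE),
                                   min = suppressWarnings(min(x, na.rm = TRUE)),
                                   max = suppressWarnings(max(x, na.rm = TRUE)))
  rbind(row("baseline_volume_cc", v0),
        row("n_metastases_baseline", as.numeric(pats$n_met_baseline)),
        row("tp_minus1_interval_days", as.numeric(iv)),
        row("alpha_per_day", fits$alpha))
}
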