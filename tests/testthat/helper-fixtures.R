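# tiny hand-built cohort: P1 measured at TP-1, P2 de novo, P3 measured with
# several lesions
tiny_lesions <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P3", "P3", "P3"),
    timepoint = c("TP-1", "TP0", "TP+1", "TP0", "TP-1", "TP0", "TP0"),
    lesion_id = c("L01", "L01", "L01", "L01", "L01", "L01", "L02"),
    volume_cc = c(5, 20, 10, 28.4, 2, 10, 18.4),
    site = c("lung", "lung", "lung", "liver", "bone", "bone", "lung"),
    stringsAsFactors = FALSE)
}

tiny_patients <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P3"),
    de_novo = c(0, 1, 0),
    tp_minus1_offset_days = c(-100, NA, -90),
    tp_plus1_offset_days = c(70, NA, NA),
    primary_site = c("Cutaneous", "Mucosal", "Ocular"),
    met_brain = c(0, 0, 0), met_liver = c(0, 1, 0),
    met_bone = c(0, 0, 1), met_lung = c(1, 0, 1),
    n_met_baseline = c(1L, 1L, 2L),
    os_days = c(800, 400, 1200), os_event = c(1, 1, 0),
    pfs_days = c(300, 200, 1200), pfs_event = c(1, 1, 0),
    pfs2_days = c(500, 350, 1200), pfs2_event = c(1, 1, 0),
    best_response = c("SD", "PD", "PR"),
    stringsAsFactors = FALSE)
}

tiny_cohort <- function() load_cohort(tiny_lesions(), tiny_patients())

# exact permutation log-rank p-value: enumerate all assignments of n1
# subjects to group A. The mid-p form (half-weight on ties with the
# observed statistic) is the standard comparator between a discrete exact
# null and a continuous asymptotic p-value.
perm_logrank_p <- function(time, event, n1) {
  n <- length(time)
  idx <- utils::combn(n, n1, simplify = FALSE)
  stat_of <- function(sel) {
    a <- data.frame(time = time[sel], event = event[sel])
    b <- data.frame(time = time[-sel], event = event[-sel])
    logrank_test(a, b)$statistic
  }
  obs <- stat_of(seq_len(n1))
  stats <- vapply(idx, stat_of, numeric(1))
  mean(stats > obs + 1e-12) + 0.5 * mean(abs(stats - obs) <= 1e-12)
}
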