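# Fixture builders: everything is constructed in code, no files.

patient_row <- function(id, anc = 2.5, hemoglobin = 12, platelets = 200,
                        crp = 1, ferritin = 300, lab_day = -1,
                        egfr = 80, ldh_above_uln = FALSE, ecog = 1,
                        bm = 5, prior_bcma = FALSE, crs = 1, icans = 0,
                        hosp = 8, pfs_time = 10, pfs_event = 0,
                        os_time = 12, os_event = 0, death_cause = "none",
                        response = "CR") {
  data.frame(
    patient_id = id, ld_day = -5L,
    anc = anc, anc_day = lab_day,
    hemoglobin = hemoglobin, hemoglobin_day = lab_day,
    platelets = platelets, platelets_day = lab_day,
    crp = crp, crp_day = lab_day,
    ferritin = ferritin, ferritin_day = lab_day,
    egfr = egfr, ldh_above_uln = ldh_above_uln, ecog = ecog,
    bm_plasma_cell_pct = bm, prior_bcma_therapy = prior_bcma,
    crs_max_grade = crs, icans_max_grade = icans, hospital_days = hosp,
    pfs_time = pfs_time, pfs_event = pfs_event,
    os_time = os_time, os_event = os_event, death_cause = death_cause,
    response = response, stringsAsFactors = FALSE)
}

lab_rows <- function(id, day, value, analyte = "anc", unit = "g_l") {
  data.frame(patient_id = id, day = day, analyte = analyte, value = value,
             unit = unit, stringsAsFactors = FALSE)
}

# three well-formed patients with simple series
tiny_cohort <- function() {
  patients <- rbind(
    patient_row("A"),
    patient_row("B", anc = 1.0, hemoglobin = 8.5, platelets = 60, crp = 4,
                ferritin = 2500, pfs_time = 5, pfs_event = 1, os_time = 8,
                os_event = 1, death_cause = "progression", response = "PD"),
    patient_row("C", platelets = 120))
  labs <- rbind(
    lab_rows("A", c(0, 5, 10, 30), c(2.0, 1.8, 2.2, 2.5)),
    lab_rows("B", c(0, 4, 12, 25), c(0.4, 0.3, 0.8, 1.6)),
    lab_rows("C", c(0, 7, 20), c(1.5, 0.6, 2.0)),
    lab_rows("A", c(0, 15), c(150, 180), analyte = "platelets"),
    lab_rows("B", c(0, 15, 40), c(40, 35, 60), analyte = "platelets"),
    lab_rows("C", c(0, 20), c(100, 140), analyte = "platelets"),
    lab_rows("A", c(0, 20), c(11, 12), analyte = "hemoglobin", unit = "g_dl"),
    lab_rows("B", c(0, 20, 50), c(8.5, 7.5, 9.0), analyte = "hemoglobin",
             unit = "g_dl"),
    lab_rows("C", c(0, 30), c(10, 11), analyte = "hemoglobin", unit = "g_dl"))
  infections <- data.frame(
    patient_id = "B", onset_day = 10L, category = "bacterial",
    source = "bloodstream", grade = 3L, stringsAsFactors = FALSE)
  events <- data.frame(
    patient_id = "B", day = 12L, event_type = "prbc_transfusion",
    stringsAsFactors = FALSE)
  ht_cohort(patients, labs, infections, events)
}

# independent LOCF oracle: for each grid day, scan backwards for the last
# measurement at or before it
locf_oracle <- function(day, value, window) {
  vapply(seq(window[1], window[2]), function(d) {
    prior <- which(day <= d)
    if (!length(prior)) NA_real_ else value[max(prior)]
  }, numeric(1))
}

# independent longest-run oracle: explicit day-by-day scan
max_run_oracle <- function(flag) {
  best <- 0L; cur <- 0L
  for (f in flag) {
    if (isTRUE(f)) { cur <- cur + 1L; best <- max(best, cur) }
    else cur <- 0L
  }
  best
}

# independent hand rubric for the 72-cell enumeration: explicit per-band
# point lookup, written without reference to the implementation
rubric_oracle <- function(anc, hb, plt, crp, fer) {
  pts <- 0
  if (anc <= 1.2) pts <- pts + 1
  if (hb <= 9.0) pts <- pts + 1
  pts <- pts + (if (plt <= 75) 2 else if (plt <= 175) 1 else 0)
  if (crp >= 3.0) pts <- pts + 1
  pts + (if (fer >= 2000) 2 else if (fer >= 650) 1 else 0)
}

# log-rank statistic by hand from hypergeometric expected counts
logrank_stat_oracle <- function(time, event, group) {
  group <- as.integer(factor(group)) == 1L
  tt <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in tt) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V == 0) 0 else (O - E)^2 / V
}
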