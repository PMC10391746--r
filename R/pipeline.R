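# End-to-end orchestration: score -> trajectory metrics -> infections ->
# outcome statistics, writing one CSV per result plus a JSON manifest with
# per-file checksums. Rendered summary tables re-use the CSV values; no
# number is computed twice.

#' Run the full risk-stratification pipeline
#'
#' Executes scoring, neutropenia/cytopenia metrics, infection summaries and
#' the outcome statistics on a cohort, and writes the result bundle to
#' \code{out_dir}: \code{scores.csv}, \code{metrics.csv},
#' \code{cytopenia.csv}, \code{infections.csv}, \code{incidence_*.csv},
#' \code{km_*.csv}, \code{nrm.csv}, \code{cox_*.csv}, \code{logistic_*.csv},
#' \code{group_tests.csv}, the rendered \code{table_baseline.csv} and
#' \code{table_hematotox.csv}, and \code{manifest.json}. Any stage failure
#' aborts with the stage name; partial outputs are removed.
#'
#' @param cohort an \code{\link{ht_cohort}}, or NULL to simulate.
#' @param out_dir output directory.
#' @param simulate_n,seed,config when \code{cohort} is NULL, a cohort of
#'   this size is generated first with \code{\link{simulate_cohort}}.
#' @param leniency_days,missing_policy scoring parameters.
#' @param horizon trajectory grid horizon in days (default 100).
#' @param followup_months NRM evaluation horizon (default 12).
#' @param figures write simple PNG figures of the curves (default FALSE;
#'   figures are presentation-only and carry no computation).
#' @return Invisibly, a list with every intermediate result object and the
#'   manifest.
#' @export
run_pipeline <- function(cohort = NULL, out_dir,
                         simulate_n = 200, seed = 1,
                         config = ht_sim_config(),
                         leniency_days = 3, missing_policy = "strict",
                         horizon = 100, followup_months = 12,
                         figures = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  tryCatch({
    stage <- "simulate"
    if (is.null(cohort)) cohort <- simulate_cohort(simulate_n, seed, config)

    stage <- "score"
    st <- ht_score(cohort, leniency_days, missing_policy)
    emit(st$scores, "scores.csv")
    risk <- risk_class(st)

    stage <- "hematotox"
    met <- neutropenia_metrics(cohort, horizon = horizon)
    emit(as.data.frame(met), "metrics.csv")
    cyto <- cytopenia_flags(cohort)
    emit(as.data.frame(cyto), "cytopenia.csv")

    stage <- "infections"
    infs <- summarize_infections(cohort)
    emit(infs$patients, "infections.csv")
    curves <- list()
    for (cat_ in c("any", "severe", "bacterial")) {
      ci <- infection_incidence(cohort, risk, cat_)
      curves[[cat_]] <- ci
      emit(ci$curve, paste0("incidence_", cat_, ".csv"))
    }

    stage <- "outcomes"
    p <- cohort$patients
    g <- risk[p$patient_id]
    km_out <- list()
    for (oc in c("pfs", "os")) {
      tm <- p[[paste0(oc, "_time")]]; evv <- p[[paste0(oc, "_event")]]
      per_group <- do.call(rbind, lapply(c("low", "high"), function(lv) {
        sel <- !is.na(g) & g == lv
        if (!any(sel)) return(NULL)
        km <- km_curve(tm[sel], evv[sel])
        cbind(group = lv, km$curve)
      }))
      km_out[[oc]] <- per_group
      emit(per_group, paste0("km_", oc, ".csv"))
    }
    nrm <- nrm_analysis(cohort, risk, followup_months)
    emit(data.frame(group = names(nrm$nrm_at_horizon),
                    nrm_incidence = unname(nrm$nrm_at_horizon)), "nrm.csv")

    covs <- ht_covariates(cohort, risk)
    pid <- attr(covs, "patient_id")
    idx <- match(pid, p$patient_id)
    reg <- list()
    notes <- character(0)
    # degenerate cohorts (constant covariates, separation, too few events)
    # get an empty coefficient table and a manifest note instead of a model
    empty_reg <- data.frame(term = character(0), estimate = numeric(0),
                            ratio = numeric(0), ci_lower = numeric(0),
                            ci_upper = numeric(0), p = numeric(0))
    try_reg <- function(name, expr) {
      fit <- tryCatch(expr, error = function(e) {
        notes <<- c(notes, paste0(name, ": ", conditionMessage(e)))
        empty_reg
      })
      reg[[name]] <<- fit
      emit(as.data.frame(fit), paste0(name, ".csv"))
    }
    for (oc in c("pfs", "os"))
      try_reg(paste0("cox_", oc),
              cox_model(p[[paste0(oc, "_time")]][idx],
                        p[[paste0(oc, "_event")]][idx], covs))
    midx <- match(met$patient_id, pid)
    apl <- met$phenotype == "aplastic"
    try_reg("logistic_aplastic",
            logistic_model(apl[!is.na(midx)],
                           covs[midx[!is.na(midx)], , drop = FALSE]))
    iidx <- match(infs$patients$patient_id, pid)
    sev <- infs$patients$severe_infection_d0_90[!is.na(iidx)]
    try_reg("logistic_infection",
            logistic_model(sev, covs[iidx[!is.na(iidx)], , drop = FALSE]))

    met_g <- g[met$patient_id]
    gt <- data.frame(
      comparison = c("severe_neutropenia_days", "severe_infection"),
      method = NA_character_, statistic = NA_real_, p = NA_real_)
    mw <- group_compare(met$severe_days_d0_60, met_g)
    gt[1, 2:4] <- list(mw$method, mw$statistic, mw$p)
    inf_g <- g[infs$patients$patient_id]
    tab <- table(factor(inf_g, c("low", "high")),
                 factor(infs$patients$severe_infection_d0_90, c(FALSE, TRUE)))
    fe <- group_compare(matrix(tab, 2))
    gt[2, 2:4] <- list(fe$method, fe$statistic, fe$p)
    emit(gt, "group_tests.csv")

    stage <- "report"
    emit(.table_baseline(cohort, g), "table_baseline.csv")
    emit(.table_hematotox(met, cyto, met_g, g), "table_hematotox.csv")

    if (figures) {
      for (cat_ in names(curves)) {
        fp <- file.path(out_dir, paste0("incidence_", cat_, ".png"))
        grDevices::png(fp, width = 600, height = 480)
        plot(curves[[cat_]], main = paste("First", cat_, "infection"))
        grDevices::dev.off()
        written <- c(written, fp)
      }
    }

    stage <- "manifest"
    manifest <- list(
      n_patients = n_patients(cohort),
      n_scored = nrow(st$scores),
      notes = as.list(notes),
      files = lapply(stats::setNames(nm = basename(written)), function(f)
        unname(tools::md5sum(file.path(out_dir, f)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    invisible(list(cohort = cohort, scores = st, metrics = met,
                   cytopenia = cyto, infections = infs, curves = curves,
                   km = km_out, nrm = nrm, regressions = reg,
                   group_tests = gt, manifest = manifest))
  }, error = on_fail)
}

# baseline table by computed risk group (rendered from the same values the
# CSVs carry)
.table_baseline <- function(cohort, g) {
  p <- cohort$patients
  med <- function(v, lv) stats::median(v[!is.na(g) & g == lv], na.rm = TRUE)
  pct <- function(v, lv) mean(v[!is.na(g) & g == lv], na.rm = TRUE) * 100
  rows <- rbind(
    data.frame(characteristic = "n", low = sum(g == "low", na.rm = TRUE),
               high = sum(g == "high", na.rm = TRUE)),
    data.frame(characteristic = "median_anc_gl", low = med(p$anc, "low"),
               high = med(p$anc, "high")),
    data.frame(characteristic = "median_hemoglobin_gdl",
               low = med(p$hemoglobin, "low"), high = med(p$hemoglobin, "high")),
    data.frame(characteristic = "median_platelets_gl",
               low = med(p$platelets, "low"), high = med(p$platelets, "high")),
    data.frame(characteristic = "median_crp_mgdl", low = med(p$crp, "low"),
               high = med(p$crp, "high")),
    data.frame(characteristic = "median_ferritin_ngml",
               low = med(p$ferritin, "low"), high = med(p$ferritin, "high")),
    data.frame(characteristic = "ecog_ge2_pct",
               low = pct(p$ecog >= 2, "low"), high = pct(p$ecog >= 2, "high")),
    data.frame(characteristic = "bm_gt50_pct",
               low = pct(p$bm_plasma_cell_pct > 50, "low"),
               high = pct(p$bm_plasma_cell_pct > 50, "high")))
  rows
}

.table_hematotox <- function(met, cyto, met_g, g) {
  pct <- function(v, grp, lv) {
    v <- v[!is.na(grp) & grp == lv]
    mean(v, na.rm = TRUE) * 100
  }
  cyto_g <- g[cyto$patient_id]
  phen <- function(ph, lv) pct(met$phenotype == ph, met_g, lv)
  data.frame(
    characteristic = c("severe_thrombocytopenia_d0_30",
                       "severe_thrombocytopenia_d31_100",
                       "severe_anemia_d0_30", "severe_anemia_d31_100",
                       "phenotype_quick", "phenotype_intermittent",
                       "phenotype_aplastic", "severe_neutropenia_d0_30",
                       "severe_neutropenia_d31_100", "protracted_severe",
                       "profound", "protracted_profound", "prolonged"),
    low = c(pct(cyto$severe_thrombocytopenia_d0_30, cyto_g, "low"),
            pct(cyto$severe_thrombocytopenia_d31_100, cyto_g, "low"),
            pct(cyto$severe_anemia_d0_30, cyto_g, "low"),
            pct(cyto$severe_anemia_d31_100, cyto_g, "low"),
            phen("quick", "low"), phen("intermittent", "low"),
            phen("aplastic", "low"),
            pct(met$severe_d0_30, met_g, "low"),
            pct(met$severe_d31_100, met_g, "low"),
            pct(met$protracted_severe, met_g, "low"),
            pct(met$profound_d0_100, met_g, "low"),
            pct(met$protracted_profound, met_g, "low"),
            pct(met$prolonged, met_g, "low")),
    high = c(pct(cyto$severe_thrombocytopenia_d0_30, cyto_g, "high"),
             pct(cyto$severe_thrombocytopenia_d31_100, cyto_g, "high"),
             pct(cyto$severe_anemia_d0_30, cyto_g, "high"),
             pct(cyto$severe_anemia_d31_100, cyto_g, "high"),
             phen("quick", "high"), phen("intermittent", "high"),
             phen("aplastic", "high"),
             pct(met$severe_d0_30, met_g, "high"),
             pct(met$severe_d31_100, met_g, "high"),
             pct(met$protracted_severe, met_g, "high"),
             pct(met$profound_d0_100, met_g, "high"),
             pct(met$protracted_profound, met_g, "high"),
             pct(met$prolonged, met_g, "high")))
}
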