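# CAR-HEMATOTOX rubric, applied to labs drawn before lymphodepletion:
#   ANC <= 1.2 G/l ............ 1 point
#   hemoglobin <= 9.0 g/dl .... 1 point
#   platelets  <= 75 G/l ...... 2 points;  (75, 175] G/l ... 1 point
#   CRP >= 3.0 mg/dl .......... 1 point
#   ferritin >= 2000 ng/ml .... 2 points;  [650, 2000) ..... 1 point
# Total 0-7; a total >= 2 is classified high risk.

#' Score the CAR-HEMATOTOX components
#'
#' Applies the 0-7 point rubric to pre-lymphodepletion labs in canonical
#' units (ANC and platelets in G/l, hemoglobin g/dl, CRP mg/dl, ferritin
#' ng/ml). The platelet bands are implemented as \code{<= 75} (2 points),
#' \code{(75, 175]} (1 point) and \code{> 175} (0), which reproduces the
#' printed integer bands "<= 75" / "76-175" exactly while leaving no gap at
#' non-integer counts; ferritin 2000 falls in the 2-point band.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param anc absolute neutrophil count, G/l.
#' @param hemoglobin g/dl.
#' @param platelets G/l.
#' @param crp C-reactive protein, mg/dl.
#' @param ferritin ng/ml.
#' @return data.frame of class \code{ht_score} with the five component
#'   points, \code{total} (0-7) and \code{risk_class} ("low" for 0-1,
#'   "high" for >= 2).
#' @examples
#' ht_score_components(anc = 2.5, hemoglobin = 12, platelets = 200,
#'                     crp = 1, ferritin = 2500)
#' @export
ht_score_components <- function(anc, hemoglobin, platelets, crp, ferritin) {
  n <- max(length(anc), length(hemoglobin), length(platelets), length(crp),
           length(ferritin))
  anc <- rep_len(anc, n); hemoglobin <- rep_len(hemoglobin, n)
  platelets <- rep_len(platelets, n); crp <- rep_len(crp, n)
  ferritin <- rep_len(ferritin, n)
  vals <- list(anc = anc, hemoglobin = hemoglobin, platelets = platelets,
               crp = crp, ferritin = ferritin)
  for (nm in names(vals)) {
    if (anyNA(vals[[nm]]))
      stop("missing value for analyte '", nm, "'")
    if (any(vals[[nm]] < 0))
      stop("negative value for analyte '", nm, "'")
  }
  res <- data.frame(
    points_anc = as.integer(anc <= 1.2),
    points_hb  = as.integer(hemoglobin <= 9.0),
    points_plt = ifelse(platelets <= 75, 2L,
                 ifelse(platelets <= 175, 1L, 0L)),
    points_crp = as.integer(crp >= 3.0),
    points_ferritin = ifelse(ferritin >= 2000, 2L,
                      ifelse(ferritin >= 650, 1L, 0L)))
  res$total <- res$points_anc + res$points_hb + res$points_plt +
    res$points_crp + res$points_ferritin
  res$risk_class <- ifelse(res$total >= 2, "high", "low")
  class(res) <- c("ht_score", "data.frame")
  res
}

#' Select baseline labs under the leniency rule
#'
#' The score is computed from labs drawn before lymphodepleting
#' chemotherapy, with a leniency period of up to \code{leniency_days} days:
#' for each analyte the value whose sample day (relative to lymphodepletion
#' start, day 0) is closest to day 0 within \code{[-leniency_days, 0]} is
#' used; ties break toward the later (closer) day. Values after the start of
#' chemotherapy are never scored. Set \code{direction = "both"} to accept a
#' window of \code{[-leniency_days, +leniency_days]} instead.
#'
#' @param baseline long data.frame with columns \code{analyte} (one of
#'   \code{anc}, \code{hemoglobin}, \code{platelets}, \code{crp},
#'   \code{ferritin}), \code{day} and \code{value}.
#' @param leniency_days non-negative integer window half-width (default 3).
#' @param missing_policy \code{"strict"} errors when an analyte has no
#'   in-window value; \code{"zero_points"} lets \code{\link{ht_score}} score
#'   the analyte as 0 points and flag the patient.
#' @param direction \code{"before"} (default) or \code{"both"}.
#' @return data.frame \code{analyte, day, value} with one row per analyte;
#'   analytes missing under \code{"zero_points"} carry \code{NA}.
#' @export
select_baseline_labs <- function(baseline, leniency_days = 3,
                                 missing_policy = c("strict", "zero_points"),
                                 direction = c("before", "both")) {
  missing_policy <- match.arg(missing_policy)
  direction <- match.arg(direction)
  analytes <- c("anc", "hemoglobin", "platelets", "crp", "ferritin")
  hi <- if (direction == "before") 0 else leniency_days
  out <- data.frame(analyte = analytes, day = NA_integer_,
                    value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(analytes)) {
    rows <- baseline[baseline$analyte == analytes[i] &
                     baseline$day >= -leniency_days & baseline$day <= hi, ,
                     drop = FALSE]
    if (nrow(rows)) {
      d <- abs(rows$day)
      cand <- rows[d == min(d), , drop = FALSE]
      pick <- cand[which.max(cand$day), ]  # tie -> later day
      out$day[i] <- pick$day
      out$value[i] <- pick$value
    }
  }
  if (missing_policy == "strict" && anyNA(out$value))
    stop("no baseline value within the leniency window for: ",
         paste(out$analyte[is.na(out$value)], collapse = ", "))
  out
}

#' Compute the CAR-HEMATOTOX score for a cohort
#'
#' Scores every patient from the baseline labs stored in the cohort's
#' \code{patients} table, enforcing the leniency window on each analyte's
#' recorded sample day. Patients that cannot be scored under
#' \code{missing_policy = "strict"} are collected (with reasons) rather than
#' raising an error; under \code{"zero_points"} missing analytes score 0 and
#' the patient is flagged.
#'
#' @param cohort an \code{\link{ht_cohort}}.
#' @param leniency_days leniency window, days before lymphodepletion start.
#' @param missing_policy \code{"strict"} or \code{"zero_points"}.
#' @return An object of class \code{ht_score_table}: list with
#'   \code{scores} (patient_id, component points, total, risk_class,
#'   flagged), \code{unscoreable} (patient_id, reason) and \code{summary}
#'   (counts of low/high).
#' @export
ht_score <- function(cohort, leniency_days = 3,
                     missing_policy = c("strict", "zero_points")) {
  stopifnot(inherits(cohort, "ht_cohort"))
  missing_policy <- match.arg(missing_policy)
  p <- cohort$patients
  analytes <- c("anc", "hemoglobin", "platelets", "crp", "ferritin")
  day_cols <- paste0(analytes, "_day")

  in_window <- vapply(seq_along(analytes), function(i) {
    d <- p[[day_cols[i]]]
    !is.na(p[[analytes[i]]]) & !is.na(d) & d >= -leniency_days & d <= 0
  }, logical(nrow(p)))
  in_window <- matrix(in_window, nrow = nrow(p))
  ok <- if (nrow(p)) apply(in_window, 1, all) else logical(0)

  scoreable <- if (missing_policy == "strict") ok else rep(TRUE, nrow(p))
  unscoreable <- data.frame(patient_id = character(), reason = character(),
                            stringsAsFactors = FALSE)
  if (any(!scoreable)) {
    reasons <- vapply(which(!scoreable), function(r) {
      miss <- analytes[!in_window[r, ]]
      paste0("no value within leniency window for: ",
             paste(miss, collapse = ", "))
    }, character(1))
    unscoreable <- data.frame(patient_id = p$patient_id[!scoreable],
                              reason = reasons, stringsAsFactors = FALSE)
  }

  q <- p[scoreable, , drop = FALSE]
  vals <- lapply(seq_along(analytes), function(i) {
    v <- q[[analytes[i]]]
    use <- in_window[scoreable, i]
    if (missing_policy == "zero_points") {
      # score as the neutral value 0 points: substitute a value outside
      # every scoring band for the missing analyte
      neutral <- c(anc = 99, hemoglobin = 99, platelets = 999, crp = 0,
                   ferritin = 0)
      v[!use] <- neutral[[analytes[i]]]
    }
    v
  })
  comp <- ht_score_components(vals[[1]], vals[[2]], vals[[3]], vals[[4]],
                              vals[[5]])
  flagged <- if (missing_policy == "zero_points" && nrow(q))
    !apply(in_window[scoreable, , drop = FALSE], 1, all) else
    rep(FALSE, nrow(q))
  scores <- cbind(data.frame(patient_id = q$patient_id,
                             stringsAsFactors = FALSE),
                  as.data.frame(comp), flagged = flagged)
  rownames(scores) <- NULL
  structure(list(scores = scores, unscoreable = unscoreable,
                 summary = c(low = sum(scores$risk_class == "low"),
                             high = sum(scores$risk_class == "high"),
                             unscoreable = nrow(unscoreable)),
                 leniency_days = leniency_days,
                 missing_policy = missing_policy),
            class = "ht_score_table")
}

#' @export
print.ht_score_table <- function(x, ...) {
  cat("CAR-HEMATOTOX scores\n")
  cat(sprintf("  scored: %d  (low %d / high %d); unscoreable: %d\n",
              nrow(x$scores), x$summary[["low"]], x$summary[["high"]],
              x$summary[["unscoreable"]]))
  if (nrow(x$scores)) {
    tab <- table(factor(x$scores$total, levels = 0:7))
    cat("  score distribution (0-7): ", paste(tab, collapse = " "), "\n")
  }
  invisible(x)
}

#' Risk class lookup for a cohort
#'
#' Convenience accessor: named character vector of risk classes
#' ("low"/"high") indexed by patient_id, for the scoreable patients.
#'
#' @param score_table result of \code{\link{ht_score}}.
#' @return named character vector.
#' @export
risk_class <- function(score_table) {
  stopifnot(inherits(score_table, "ht_score_table"))
  stats::setNames(score_table$scores$risk_class,
                  score_table$scores$patient_id)
}
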