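# Longitudinal cytopenia endpoints on an integer daily grid. Between lab
# draws the last observation is carried forward (LOCF); days before the
# first measurement are unknown and never count toward any threshold.

#' Expand a lab series onto an integer daily grid
#'
#' Last-observation-carried-forward expansion over the closed day window.
#' Measured days reproduce the raw series exactly; days after a measurement
#' copy the most recent prior value; days before the first measurement are
#' unknown (\code{NA}).
#'
#' @param day integer measurement days (relative to infusion, day 0),
#'   strictly increasing.
#' @param value measurements in canonical units; same length as \code{day}.
#' @param window closed integer interval \code{c(start, end)}.
#' @return data.frame \code{day, value, provenance} with provenance in
#'   \code{measured}, \code{carried_forward}, \code{unknown}.
#' @export
daily_grid <- function(day, value, window) {
  val <- .locf_values(day, value, window)
  days <- seq.int(window[1], window[2])
  prov <- ifelse(findInterval(days, day) == 0, "unknown",
          ifelse(days %in% day, "measured", "carried_forward"))
  data.frame(day = days, value = val, provenance = prov,
             stringsAsFactors = FALSE)
}

# fast path: LOCF-expanded values only
.locf_values <- function(day, value, window) {
  if (!length(day)) stop("empty lab series")
  if (length(day) != length(value)) stop("day and value lengths differ")
  if (is.unsorted(day, strictly = TRUE)) stop("days must be strictly increasing")
  days <- seq.int(window[1], window[2])
  idx <- findInterval(days, day)          # index of last measurement <= day
  out <- value[pmax(idx, 1L)]
  out[idx == 0] <- NA_real_
  out
}

#' Cumulative days of severe neutropenia
#'
#' Counts grid days with ANC below \code{threshold} (default 0.5 G/l, i.e.
#' 500/microliter) in the closed window, default days 0-60. Unknown days
#' contribute 0. \code{mode = "measured"} counts only measured days, as a
#' sensitivity analysis for the carried-forward default.
#'
#' @param day,value ANC series (days relative to infusion, G/l).
#' @param window closed integer day window, default \code{c(0, 60)}.
#' @param threshold G/l, default 0.5.
#' @param mode \code{"locf"} (default) or \code{"measured"}.
#' @return integer day count.
#' @export
severe_neutropenia_days <- function(day, value, window = c(0, 60),
                                    threshold = 0.5,
                                    mode = c("locf", "measured")) {
  mode <- match.arg(mode)
  inw <- day >= window[1] & day <= window[2]
  if (!any(inw)) stop("no ANC observation within day window [",
                      window[1], ", ", window[2], "]")
  if (mode == "measured")
    return(sum(value[inw] < threshold))
  g <- daily_grid(day, value, window)
  sum(g$value < threshold, na.rm = TRUE)
}

# longest run of consecutive grid days satisfying pred (NA breaks a run)
.max_run <- function(x) {
  x[is.na(x)] <- FALSE
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Classify the neutrophil-recovery phenotype
#'
#' Trajectories are classified, in order of precedence, as
#' \describe{
#'   \item{aplastic}{continuous severe neutropenia: a run of at least 14
#'     consecutive grid days with ANC < 0.5 G/l;}
#'   \item{intermittent}{neutrophil recovery (some day with ANC > 1.5 G/l)
#'     followed by a later second dip with ANC < 1.0 G/l after day 21
#'     (i.e. on a day >= 22);}
#'   \item{quick}{sustained recovery: neither of the above.}
#' }
#' Classification runs on the carried-forward daily grid over
#' \code{[0, horizon]}. With fewer than 22 days of observed follow-up the
#' class is still returned but marked low-confidence.
#'
#' @param day,value ANC series (days relative to infusion, G/l).
#' @param horizon last grid day considered (default 100).
#' @return list with \code{phenotype} (character) and
#'   \code{low_confidence} (logical).
#' @export
classify_neutrophil_phenotype <- function(day, value, horizon = 100) {
  g <- daily_grid(day, value, c(0, horizon))
  low_conf <- max(day[day <= horizon], -Inf) < 21
  v <- g$value
  if (.max_run(v < 0.5) >= 14)
    return(list(phenotype = "aplastic", low_confidence = low_conf))
  recov <- which(!is.na(v) & v > 1.5)
  if (length(recov)) {
    first_recov_day <- g$day[recov[1]]
    dip <- !is.na(v) & v < 1.0 & g$day >= 22 & g$day > first_recov_day
    if (any(dip))
      return(list(phenotype = "intermittent", low_confidence = low_conf))
  }
  list(phenotype = "quick", low_confidence = low_conf)
}

.neutropenia_one <- function(day, value, horizon = 100, mode = "locf") {
  v <- .locf_values(day, value, c(0, horizon))
  gd <- seq.int(0, horizon)
  sev <- v < 0.5
  prof <- v < 0.1
  sev_days <- if (mode == "measured")
    sum(value[day >= 0 & day <= 60] < 0.5)
  else sum(sev[gd <= 60], na.rm = TRUE)
  # phenotype on the shared grid (same decision order as the classifier)
  low_conf <- max(day[day <= horizon], -Inf) < 21
  phenotype <- if (.max_run(sev) >= 14) "aplastic" else {
    recov <- which(!is.na(v) & v > 1.5)
    dip_ok <- length(recov) &&
      any(!is.na(v) & v < 1.0 & gd >= 22 & gd > gd[recov[1]])
    if (dip_ok) "intermittent" else "quick"
  }
  list(
    severe_days_d0_60 = sev_days,
    phenotype = phenotype,
    phenotype_low_confidence = low_conf,
    severe_d0_30 = any(sev[gd <= 30], na.rm = TRUE),
    severe_d31_100 = any(sev[gd >= 31], na.rm = TRUE),
    protracted_severe = .max_run(sev) >= 7,
    profound_d0_100 = any(prof, na.rm = TRUE),
    protracted_profound = .max_run(prof) >= 7,
    prolonged = any(!is.na(v) & v < 1.0 & gd >= 21))
}

#' Neutropenia endpoints for a cohort
#'
#' One row per patient with an in-window ANC series: cumulative severe
#' neutropenia days over days 0-60 (ANC < 0.5 G/l), recovery phenotype
#' (quick / intermittent / aplastic), windowed severe flags (days 0-30 and
#' 31-100), protracted severe (>= 7 consecutive days < 0.5), profound
#' (any < 0.1 over days 0-100), protracted profound (>= 7 consecutive days
#' < 0.1) and prolonged (< 1.0 G/l on any day >= 21). Consecutive-day
#' requirements are evaluated as maximal runs on the carried-forward grid.
#'
#' @param cohort an \code{\link{ht_cohort}}.
#' @param horizon last grid day (default 100).
#' @param mode day-counting mode for the 0-60 duration, \code{"locf"} or
#'   \code{"measured"}.
#' @return data.frame of class \code{ht_neutropenia}, one row per evaluable
#'   patient; patients with no ANC data in the window are omitted and listed
#'   in \code{attr(, "not_evaluable")}.
#' @export
neutropenia_metrics <- function(cohort, horizon = 100, mode = "locf") {
  stopifnot(inherits(cohort, "ht_cohort"))
  ids <- cohort$patients$patient_id
  anc <- cohort$labs[cohort$labs$analyte == "anc", , drop = FALSE]
  by_pat <- split(anc[, c("day", "value")], anc$patient_id)
  rows <- vector("list", length(ids))
  skipped <- character(0)
  for (i in seq_along(ids)) {
    s <- by_pat[[ids[i]]]
    if (is.null(s) || !any(s$day >= 0 & s$day <= 60)) {
      skipped <- c(skipped, ids[i]); next
    }
    o <- order(s$day)
    rows[[i]] <- c(list(patient_id = ids[i]),
                   .neutropenia_one(s$day[o], s$value[o], horizon, mode))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows))
    do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  else data.frame()
  rownames(out) <- NULL
  attr(out, "not_evaluable") <- skipped
  class(out) <- c("ht_neutropenia", "data.frame")
  out
}

.flag_window <- function(day, value, window, threshold) {
  inw <- day >= window[1] & day <= window[2]
  if (!any(inw)) return(NA)  # not evaluable
  any(.locf_values(day, value, window) < threshold, na.rm = TRUE)
}

#' Severe thrombocytopenia and anemia flags
#'
#' Severe thrombocytopenia is a platelet count < 50 G/l; severe anemia is a
#' hemoglobin < 8 g/dl or a packed red-cell transfusion inside the window.
#' Both are evaluated over days 0-30 and 31-100 on the carried-forward
#' grid. Windows with no measurement (and, for anemia, no transfusion) are
#' not evaluable and return \code{NA}, distinct from \code{FALSE}.
#'
#' @param cohort an \code{\link{ht_cohort}}.
#' @return data.frame of class \code{ht_cytopenia}, one row per patient.
#' @export
cytopenia_flags <- function(cohort) {
  stopifnot(inherits(cohort, "ht_cohort"))
  ids <- cohort$patients$patient_id
  ev <- cohort$events
  plt_by <- split(cohort$labs[cohort$labs$analyte == "platelets",
                              c("day", "value")],
                  cohort$labs$patient_id[cohort$labs$analyte == "platelets"])
  hb_by <- split(cohort$labs[cohort$labs$analyte == "hemoglobin",
                             c("day", "value")],
                 cohort$labs$patient_id[cohort$labs$analyte == "hemoglobin"])
  prbc_all <- ev[ev$event_type == "prbc_transfusion", , drop = FALSE]
  prbc_by <- split(prbc_all$day, prbc_all$patient_id)
  empty_s <- data.frame(day = integer(0), value = numeric(0))
  out <- lapply(ids, function(id) {
    plt <- plt_by[[id]]; if (is.null(plt)) plt <- empty_s
    hb <- hb_by[[id]]; if (is.null(hb)) hb <- empty_s
    prbc <- prbc_by[[id]]; if (is.null(prbc)) prbc <- integer(0)
    anemia <- function(win) {
      hb_flag <- if (nrow(hb)) .flag_window(hb$day, hb$value, win, 8) else NA
      tx <- any(prbc >= win[1] & prbc <= win[2])
      if (tx) TRUE else hb_flag
    }
    data.frame(
      patient_id = id,
      severe_thrombocytopenia_d0_30 =
        if (nrow(plt)) .flag_window(plt$day, plt$value, c(0, 30), 50) else NA,
      severe_thrombocytopenia_d31_100 =
        if (nrow(plt)) .flag_window(plt$day, plt$value, c(31, 100), 50) else NA,
      severe_anemia_d0_30 = anemia(c(0, 30)),
      severe_anemia_d31_100 = anemia(c(31, 100)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("ht_cytopenia", "data.frame")
  out
}
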