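# Early infection events (days 0-90). Severity is graded 1-5 (mild,
# moderate, severe, life-threatening, fatal); severe means grade >= 3.
# Neutropenic fever alone is not an infection event and is dropped (and
# flagged) by the cohort reader.

.days_per_month <- 365.25 / 12

#' Per-patient and cohort-level infection summary
#'
#' Flags each patient for any, severe (grade >= 3), bacterial, viral and
#' fungal infection with onset in days 0-90, together with the first onset
#' day per category. A patient may contribute several events but each flag
#' counts once; events after day 90 are excluded from the flags but kept in
#' the raw event tallies by source and grade.
#'
#' @param cohort an \code{\link{ht_cohort}}.
#' @param horizon last onset day counted (default 90).
#' @return Object of class \code{ht_infections}: list with \code{patients}
#'   (one row per patient: flags and first onset days), \code{by_source} and
#'   \code{by_grade} (all-event tallies), \code{n_events} and
#'   \code{n_events_in_window}.
#' @export
summarize_infections <- function(cohort, horizon = 90) {
  stopifnot(inherits(cohort, "ht_cohort"))
  inf <- cohort$infections
  ids <- cohort$patients$patient_id
  inw <- inf[inf$onset_day >= 0 & inf$onset_day <= horizon, , drop = FALSE]
  first_day <- function(events) if (nrow(events)) min(events$onset_day) else NA_integer_
  per <- lapply(ids, function(id) {
    e <- inw[inw$patient_id == id, , drop = FALSE]
    sev <- e[e$grade >= 3, , drop = FALSE]
    data.frame(
      patient_id = id,
      any_infection_d0_90 = nrow(e) > 0,
      severe_infection_d0_90 = nrow(sev) > 0,
      bacterial = any(e$category == "bacterial"),
      viral = any(e$category == "viral"),
      fungal = any(e$category == "fungal"),
      first_any = first_day(e),
      first_severe = first_day(sev),
      first_bacterial = first_day(e[e$category == "bacterial", , drop = FALSE]),
      first_viral = first_day(e[e$category == "viral", , drop = FALSE]),
      first_fungal = first_day(e[e$category == "fungal", , drop = FALSE]),
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(
    patients = per,
    by_source = if (nrow(inf)) table(inf$source) else table(character(0)),
    by_grade = table(factor(inf$grade, levels = 1:5)),
    n_events = nrow(inf),
    n_events_in_window = nrow(inw)),
    class = "ht_infections")
}

#' @export
print.ht_infections <- function(x, ...) {
  p <- x$patients
  cat(sprintf("Infections d0-90: %d events in %d/%d patients (severe: %d)\n",
              x$n_events_in_window, sum(p$any_infection_d0_90), nrow(p),
              sum(p$severe_infection_d0_90)))
  invisible(x)
}

#' Cumulative incidence of first infection by risk group
#'
#' Time to the first qualifying infection (by category) over days 0-90,
#' estimated as one minus the Kaplan-Meier estimator per risk group. Death
#' before the first infection censors at the death day (competing-risks
#' treatment of death is available through \code{\link{nrm_cuminc}} for the
#' mortality endpoint); patients without an event are censored at
#' \code{min(death day, horizon)}. Groups are compared by log-rank test.
#'
#' @param cohort an \code{\link{ht_cohort}}.
#' @param group named character vector of group labels indexed by
#'   patient_id (e.g. \code{\link{risk_class}} output); patients missing
#'   from it are dropped.
#' @param category \code{"any"}, \code{"severe"}, \code{"bacterial"},
#'   \code{"viral"} or \code{"fungal"}.
#' @param horizon last day of the window (default 90).
#' @return Object of class \code{ht_cuminc_curve}: list with \code{curve}
#'   (group, day, estimate, n_risk), \code{logrank} (chisq, df, p; NULL for
#'   a single group) and \code{n} per group.
#' @export
infection_incidence <- function(cohort, group, category = c(
  "any", "severe", "bacterial", "viral", "fungal"), horizon = 90) {
  stopifnot(inherits(cohort, "ht_cohort"))
  category <- match.arg(category)
  s <- summarize_infections(cohort, horizon)$patients
  col <- switch(category, any = "first_any", severe = "first_severe",
                bacterial = "first_bacterial", viral = "first_viral",
                fungal = "first_fungal")
  p <- cohort$patients
  keep <- p$patient_id %in% names(group)
  if (!any(keep)) stop("no patients in the supplied groups")
  p <- p[keep, , drop = FALSE]
  s <- s[match(p$patient_id, s$patient_id), , drop = FALSE]
  g <- factor(group[p$patient_id])
  if (any(table(g) == 0)) stop("a risk group contains zero patients")

  death_day <- ifelse(p$os_event == 1, floor(p$os_time * .days_per_month),
                      Inf)
  onset <- s[[col]]
  has_event <- !is.na(onset)
  time <- ifelse(has_event, onset, pmin(death_day, horizon))
  time <- pmax(pmin(time, horizon), 0)
  status <- as.integer(has_event & onset <= horizon)

  fit <- survival::survfit(survival::Surv(time, status) ~ g)
  strata <- if (is.null(fit$strata)) rep(paste0("g=", levels(g)[1]),
                                         length(fit$time))
            else rep(names(fit$strata), fit$strata)
  curve <- data.frame(group = sub("^g=", "", strata), day = fit$time,
                      estimate = 1 - fit$surv, n_risk = fit$n.risk,
                      stringsAsFactors = FALSE)
  lr <- if (nlevels(g) > 1) logrank_test(time, status, g) else NULL
  structure(list(curve = curve, logrank = lr, n = table(g),
                 category = category, horizon = horizon),
            class = "ht_cuminc_curve")
}

#' @export
print.ht_cuminc_curve <- function(x, ...) {
  cat(sprintf("Cumulative incidence (d0-%d), category '%s'\n", x$horizon,
              x$category))
  for (grp in unique(x$curve$group)) {
    cc <- x$curve[x$curve$group == grp, ]
    cat(sprintf("  %s (n=%d): day-%d estimate %.3f\n", grp,
                x$n[[grp]], x$horizon, max(0, cc$estimate)))
  }
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank chisq = %.3f, p = %.4g\n", x$logrank$chisq,
                x$logrank$p))
  invisible(x)
}

#' @export
plot.ht_cuminc_curve <- function(x, col = NULL, xlab = "Days after infusion",
                                 ylab = "Cumulative incidence", ...) {
  groups <- unique(x$curve$group)
  if (is.null(col)) col <- seq_along(groups)
  plot(NA, xlim = c(0, x$horizon), ylim = c(0, 1), xlab = xlab, ylab = ylab,
       ...)
  for (i in seq_along(groups)) {
    cc <- x$curve[x$curve$group == groups[i], ]
    graphics::lines(stats::stepfun(cc$day, c(0, cc$estimate)), col = col[i],
                    do.points = FALSE)
  }
  graphics::legend("topleft", legend = groups, col = col, lty = 1, bty = "n")
  invisible(x)
}
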