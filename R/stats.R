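# Discrimination, correlation, survival and regression machinery used to
# validate the score against toxicity and outcome endpoints. Product-limit,
# log-rank, Aalen-Johansen and Cox computations are delegated to the
# survival package; the ROC is computed directly from the tie-corrected
# rank (Mann-Whitney) formulation so that AUC, operating point and p-value
# follow one documented convention.

#' Empirical ROC analysis of a score against a binary endpoint
#'
#' Higher scores are taken to predict the positive class (enforced, not
#' auto-detected). The AUC is the normalized, tie-corrected Mann-Whitney
#' statistic of the scores between outcome classes; the threshold table
#' enumerates the rule "positive if score >= cutoff" over all distinct
#' observed cutoffs, the operating point maximizes Youden's J
#' (sensitivity + specificity - 1), and the p-value against AUC = 0.5 uses
#' the tie-corrected normal approximation to the Mann-Whitney U.
#'
#' @param score numeric predictor.
#' @param outcome logical (or 0/1) endpoint; both classes must be present.
#' @return Object of class \code{ht_roc}: list with \code{auc},
#'   \code{thresholds} (cutoff, sensitivity, specificity), \code{youden}
#'   (the chosen operating point), \code{p_value}, \code{n_pos},
#'   \code{n_neg}.
#' @export
ht_roc <- function(score, outcome) {
  outcome <- as.logical(outcome)
  keep <- !is.na(score) & !is.na(outcome)
  score <- score[keep]; outcome <- outcome[keep]
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0)
    stop("both outcome classes must be present for ROC analysis")

  r <- rank(score)
  auc <- (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  cutoffs <- sort(unique(score))
  sens <- vapply(cutoffs, function(cc) mean(score[outcome] >= cc), numeric(1))
  spec <- vapply(cutoffs, function(cc) mean(score[!outcome] < cc), numeric(1))
  thresholds <- data.frame(cutoff = cutoffs, sensitivity = sens,
                           specificity = spec)
  j <- sens + spec - 1
  youden <- thresholds[which.max(j), ]

  # normal approximation to U with tie correction
  N <- n1 + n0
  U <- auc * n1 * n0
  ties <- table(score)
  sigma2 <- n1 * n0 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sigma2 > 0) (U - n1 * n0 / 2) / sqrt(sigma2) else 0
  p <- 2 * stats::pnorm(-abs(z))

  structure(list(auc = auc, thresholds = thresholds, youden = youden,
                 p_value = p, n_pos = n1, n_neg = n0),
            class = "ht_roc")
}

#' @export
print.ht_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (n+ = %d, n- = %d), p = %.4g vs AUC 0.5\n",
              x$auc, x$n_pos, x$n_neg, x$p_value))
  cat(sprintf("  operating point (Youden): cutoff %.3g, sens %.2f, spec %.2f\n",
              x$youden$cutoff, x$youden$sensitivity, x$youden$specificity))
  invisible(x)
}

#' Spearman correlation with a linear-slope summary
#'
#' Rank correlation (tie-handled, two-sided p) between paired observations,
#' together with the ordinary least-squares slope of \code{y} on \code{x} --
#' the association is summarized by a rank statistic but displayed against a
#' linear fit, so both are reported.
#'
#' @param x,y paired numeric vectors, n >= 3, neither constant.
#' @return list with \code{r}, \code{p}, \code{slope}, \code{intercept},
#'   \code{n}.
#' @export
spearman_slope <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation undefined for a constant variable")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  fit <- stats::lm.fit(cbind(1, x), y)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n = length(x))
}

#' Kaplan-Meier curve with Greenwood confidence intervals
#'
#' Product-limit estimator with pointwise 95\% intervals from the Greenwood
#' variance (log scale). The median follows the convention: the smallest
#' time with survival below 0.5; when the curve hits 0.5 exactly, the
#' midpoint between that time and the next event time (the time itself when
#' the curve never drops further); \code{NA} ("not reached") when the curve
#' never reaches 0.5.
#'
#' @param time nonnegative follow-up times (any unit; months in the
#'   cohort analyses).
#' @param event 0/1 or logical event indicator.
#' @return Object of class \code{ht_km}: list with \code{curve} (time,
#'   n_risk, n_event, surv, lower, upper), \code{median}, \code{median_ci}
#'   (95\% CI bounds, possibly NA), \code{n}, \code{n_events}.
#' @export
km_curve <- function(time, event) {
  if (!length(time)) stop("empty group")
  event <- as.integer(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "log")
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv,
                      lower = fit$lower, upper = fit$upper)
  structure(list(curve = curve, median = .km_median(fit$time, fit$surv),
                 median_ci = .km_median_ci(fit), n = length(time),
                 n_events = sum(event)),
            class = "ht_km")
}

.km_median <- function(t, s, level = 0.5) {
  eps <- 1e-9
  below <- which(s < level - eps)
  at <- which(abs(s - level) < eps)
  if (length(at)) {
    t_eq <- t[at[1]]
    nxt <- below[below > at[1]]
    if (length(nxt)) return((t_eq + t[nxt[1]]) / 2)
    return(t_eq)
  }
  if (length(below)) return(t[below[1]])
  NA_real_
}

.km_median_ci <- function(fit) {
  lo <- .km_median(fit$time, fit$upper)  # upper CI crosses 0.5 first
  hi <- .km_median(fit$time, fit$lower)
  c(lower = lo, upper = hi)
}

#' @export
print.ht_km <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else sprintf("%.2f", x$median)
  cat(sprintf("Kaplan-Meier: n = %d, events = %d, median = %s\n",
              x$n, x$n_events, med))
  invisible(x)
}

#' @export
plot.ht_km <- function(x, xlab = "Time", ylab = "Survival", ...) {
  cc <- x$curve
  plot(stats::stepfun(cc$time, c(1, cc$surv)), do.points = FALSE, ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  graphics::lines(stats::stepfun(cc$time, c(1, cc$lower)), do.points = FALSE,
                  lty = 3)
  graphics::lines(stats::stepfun(cc$time, c(1, cc$upper)), do.points = FALSE,
                  lty = 3)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Log-rank statistic from hypergeometric expected event counts at each
#' distinct event time. The p-value is the chi-square approximation by
#' default; with \code{exact = TRUE} (two groups, small samples) it is the
#' exact permutation p-value over all relabelings that preserve the group
#' sizes: the proportion of relabelings whose statistic is at least the
#' observed one.
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param group two-level grouping factor.
#' @param exact use the permutation null distribution (feasible for
#'   combined n up to ~12).
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
logrank_test <- function(time, event, group, exact = FALSE) {
  group <- factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2)
    stop("log-rank requires at least two non-empty groups")
  event <- as.integer(event)
  df <- nlevels(group) - 1
  if (sum(event) == 0)  # no events: groups indistinguishable
    return(list(chisq = 0, df = df, p = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  chisq <- unname(sd$chisq)
  if (!exact)
    return(list(chisq = chisq, df = df,
                p = stats::pchisq(chisq, df, lower.tail = FALSE)))
  if (nlevels(group) != 2)
    stop("exact mode supports two groups")
  n <- length(time)
  if (choose(n, sum(group == levels(group)[1])) > 1e6)
    stop("exact mode is infeasible at this sample size")
  idx_sets <- utils::combn(n, sum(group == levels(group)[1]),
                           simplify = FALSE)
  stat_of <- function(ix) {
    g2 <- factor(replace(rep(levels(group)[2], n), ix, levels(group)[1]),
                 levels = levels(group))
    if (length(unique(g2)) < 2) return(NA_real_)
    survival::survdiff(survival::Surv(time, event) ~ g2)$chisq
  }
  stats_perm <- vapply(idx_sets, stat_of, numeric(1))
  p <- mean(stats_perm >= chisq - 1e-9, na.rm = TRUE)
  list(chisq = chisq, df = df, p = p)
}

#' Aalen-Johansen cumulative incidence with competing causes
#'
#' Multi-state estimate of the cause-specific cumulative incidence
#' functions; at every time the event-free probability and the per-cause
#' incidences sum to one. For the non-relapse mortality endpoint the causes
#' are death without prior progression ("nrm") versus progression-related
#' death, with censoring at last follow-up.
#'
#' @param time follow-up times.
#' @param status factor (or character) with \code{"censor"} for censored
#'   observations and one level per competing cause.
#' @return Object of class \code{ht_cuminc}: list with \code{curve} (time,
#'   n_risk, one incidence column per cause, \code{event_free}) and
#'   \code{causes}.
#' @export
aj_cuminc <- function(time, status) {
  status <- as.character(status)
  causes <- setdiff(unique(status), "censor")
  if (!length(causes)) {
    curve <- data.frame(time = sort(unique(time)),
                        n_risk = NA_integer_, event_free = 1)
    return(structure(list(curve = curve, causes = character(0)),
                     class = "ht_cuminc"))
  }
  f <- factor(status, levels = c("censor", sort(causes)))
  fit <- survival::survfit(survival::Surv(time, f) ~ 1)
  states <- fit$states
  pstate <- fit$pstate
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk[, 1])
  for (cs in sort(causes)) curve[[cs]] <- pstate[, match(cs, states)]
  curve$event_free <- pstate[, match("(s0)", states)]
  structure(list(curve = curve, causes = sort(causes)),
            class = "ht_cuminc")
}

#' @export
print.ht_cuminc <- function(x, ...) {
  cat("Aalen-Johansen cumulative incidence; causes:",
      paste(x$causes, collapse = ", "), "\n")
  if (nrow(x$curve)) {
    last <- x$curve[nrow(x$curve), ]
    for (cs in x$causes)
      cat(sprintf("  %s at t=%.3g: %.4f\n", cs, last$time, last[[cs]]))
  }
  invisible(x)
}

#' Non-relapse mortality analysis for a cohort
#'
#' NRM is death after infusion without evidence of progression or relapse,
#' treated as a competing risk against progression-related death. Times are
#' administratively truncated at \code{horizon_months}. Reports the
#' Aalen-Johansen NRM incidence at the horizon, overall and per risk group,
#' with a cause-specific log-rank comparison (NRM events; progression
#' deaths censored).
#'
#' @param cohort an \code{\link{ht_cohort}}.
#' @param group optional named group vector (see
#'   \code{\link{infection_incidence}}).
#' @param horizon_months evaluation horizon, default 12 (one year).
#' @return list with \code{overall} (ht_cuminc), \code{nrm_at_horizon}
#'   (named incidence, overall and per group), \code{by_group} (list of
#'   ht_cuminc) and \code{logrank} when groups are given.
#' @export
nrm_analysis <- function(cohort, group = NULL, horizon_months = 12) {
  stopifnot(inherits(cohort, "ht_cohort"))
  p <- cohort$patients
  if (any(p$os_event == 1 & p$death_cause == "none"))
    stop("death recorded with cause 'none'")
  time <- pmin(p$os_time, horizon_months)
  died <- p$os_event == 1 & p$os_time <= horizon_months
  status <- ifelse(!died, "censor",
            ifelse(p$death_cause == "progression", "progression_death",
                   "nrm"))
  overall <- aj_cuminc(time, status)
  at_h <- function(obj) {
    cc <- obj$curve
    if (!"nrm" %in% names(cc) || !nrow(cc)) return(0)
    rows <- cc$time <= horizon_months + 1e-9
    if (!any(rows)) return(0)
    cc$nrm[max(which(rows))]
  }
  out <- list(overall = overall,
              nrm_at_horizon = c(overall = at_h(overall)),
              horizon_months = horizon_months)
  if (!is.null(group)) {
    keep <- p$patient_id %in% names(group)
    g <- factor(group[p$patient_id[keep]])
    by_group <- lapply(levels(g), function(lv) {
      sel <- which(keep)[g == lv]
      aj_cuminc(time[sel], status[sel])
    })
    names(by_group) <- levels(g)
    out$by_group <- by_group
    gh <- vapply(by_group, at_h, numeric(1))
    out$nrm_at_horizon <- c(out$nrm_at_horizon, gh)
    # cause-specific log-rank on the NRM hazard
    sel <- which(keep)
    out$logrank <- logrank_test(time[sel],
                                as.integer(status[sel] == "nrm"), g)
  }
  class(out) <- "ht_nrm"
  out
}

#' @export
print.ht_nrm <- function(x, ...) {
  cat(sprintf("Non-relapse mortality at %g months:\n", x$horizon_months))
  for (nm in names(x$nrm_at_horizon))
    cat(sprintf("  %s: %.1f%%\n", nm, 100 * x$nrm_at_horizon[[nm]]))
  if (!is.null(x$logrank))
    cat(sprintf("  cause-specific log-rank p = %.4g\n", x$logrank$p))
  invisible(x)
}

.tidy_fit <- function(est, se) {
  z <- est / se
  data.frame(term = names(est), estimate = unname(est),
             ratio = exp(unname(est)),
             ci_lower = exp(unname(est - 1.96 * se)),
             ci_upper = exp(unname(est + 1.96 * se)),
             p = 2 * stats::pnorm(-abs(unname(z))),
             stringsAsFactors = FALSE)
}

#' Cox proportional-hazards model for cohort outcomes
#'
#' Partial-likelihood fit with Efron tie handling and Wald intervals.
#' Covariates are supplied as a data.frame of numeric/binary columns (see
#' \code{\link{ht_covariates}} for the standard five-indicator adjustment
#' set); a single-column data.frame gives the univariate model.
#'
#' @param time,event outcome follow-up times and 0/1 indicators.
#' @param covariates data.frame of covariate columns.
#' @return Object of class \code{ht_regression} (data.frame with term,
#'   estimate (log-hazard), ratio (HR), 95\% CI bounds and p) with
#'   attributes \code{n}, \code{n_events}, \code{type}, \code{ties}.
#' @export
cox_model <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    if (is.logical(x)) covariates[[nm]] <- as.numeric(x)
    if (length(unique(covariates[[nm]])) < 2)
      stop("covariate '", nm, "' is constant: no information")
  }
  if (sum(event) < 1) stop("no events")
  dat <- cbind(data.frame(.time = time, .event = as.integer(event)),
               covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(covariates)),
                                       collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w)))
        stop("Cox model did not converge: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit)))
    stop("collinear covariates: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  se <- sqrt(diag(fit$var))
  res <- .tidy_fit(stats::coef(fit), se)
  attr(res, "n") <- fit$n
  attr(res, "n_events") <- fit$nevent
  attr(res, "type") <- "cox"
  attr(res, "ties") <- "efron"
  class(res) <- c("ht_regression", "data.frame")
  res
}

#' Binary logistic regression for toxicity endpoints
#'
#' Maximum-likelihood logistic fit with Wald inference, used for the
#' aplastic-phenotype and severe-infection endpoints adjusted for the same
#' baseline indicator set as the Cox models. Complete separation (detected
#' by non-convergence or exploding estimates) raises an error.
#'
#' @param outcome logical or 0/1 response.
#' @param covariates data.frame of covariate columns.
#' @return \code{ht_regression} data.frame as in \code{\link{cox_model}},
#'   with \code{ratio} holding odds ratios.
#' @export
logistic_model <- function(outcome, covariates) {
  covariates <- as.data.frame(covariates)
  y <- as.integer(outcome)
  if (length(unique(y)) < 2) stop("outcome has a single class")
  for (nm in names(covariates)) {
    x <- covariates[[nm]]
    if (is.logical(x)) covariates[[nm]] <- as.numeric(x)
    if (length(unique(covariates[[nm]])) < 2)
      stop("covariate '", nm, "' is constant: no information")
  }
  dat <- cbind(data.frame(.y = y), covariates)
  fml <- stats::as.formula(paste(".y ~",
                                 paste(sprintf("`%s`", names(covariates)),
                                       collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = dat))
  cf <- stats::coef(fit)[-1]
  se <- sqrt(diag(stats::vcov(fit)))[-1]
  if (!fit$converged || any(abs(cf) > 15) || any(se > 100))
    stop("logistic model did not converge (possible complete separation)")
  res <- .tidy_fit(cf, se)
  attr(res, "n") <- length(y)
  attr(res, "n_events") <- sum(y)
  attr(res, "type") <- "logistic"
  class(res) <- c("ht_regression", "data.frame")
  res
}

#' @export
print.ht_regression <- function(x, digits = 3, ...) {
  lab <- if (identical(attr(x, "type"), "cox")) "HR" else "OR"
  cat(sprintf("%s model: n = %d, events = %d\n",
              if (lab == "HR") "Cox (Efron ties)" else "Logistic",
              attr(x, "n"), attr(x, "n_events")))
  df <- as.data.frame(x)
  df$ratio <- sprintf(paste0("%.", digits, "g"), df$ratio)
  names(df)[names(df) == "ratio"] <- lab
  print(df, row.names = FALSE)
  invisible(x)
}

#' Standard multivariable adjustment set
#'
#' The five binary baseline indicators used in the multivariable models:
#' eGFR >= 60 ml/min, LDH above the upper limit of normal, ECOG performance
#' status >= 2, bone-marrow plasma-cell infiltration > 50\%, and
#' high-risk HT class.
#'
#' @param cohort an \code{\link{ht_cohort}}.
#' @param risk named risk-class vector (\code{\link{risk_class}}).
#' @return data.frame of 0/1 columns \code{egfr_ge60, ldh_above_uln,
#'   ecog_ge2, bm_gt50, ht_high}, rows aligned with (and restricted to)
#'   scored patients, with \code{patient_id} attribute.
#' @export
ht_covariates <- function(cohort, risk) {
  p <- cohort$patients
  keep <- p$patient_id %in% names(risk)
  p <- p[keep, , drop = FALSE]
  out <- data.frame(
    egfr_ge60 = as.numeric(p$egfr >= 60),
    ldh_above_uln = as.numeric(p$ldh_above_uln > 0),
    ecog_ge2 = as.numeric(p$ecog >= 2),
    bm_gt50 = as.numeric(p$bm_plasma_cell_pct > 50),
    ht_high = as.numeric(risk[p$patient_id] == "high"))
  attr(out, "patient_id") <- p$patient_id
  out
}

#' Two-group comparison: Mann-Whitney or Fisher exact
#'
#' Continuous inputs are compared by the two-sided Mann-Whitney test: exact
#' enumeration when the combined sample size is at most 12 and there are no
#' ties, otherwise the tie-corrected normal approximation (no continuity
#' correction). A 2x2 count table is compared by Fisher's exact test,
#' two-sided by summing hypergeometric probabilities no larger than that of
#' the observed table.
#'
#' @param x numeric values (with \code{group}), or a 2x2 matrix of counts.
#' @param group two-level factor when \code{x} is numeric.
#' @return list with \code{method}, \code{statistic} (U for Mann-Whitney,
#'   odds ratio estimate for Fisher) and \code{p}.
#' @export
group_compare <- function(x, group = NULL) {
  if (is.matrix(x)) {
    if (!all(dim(x) == 2)) stop("Fisher comparison expects a 2x2 table")
    ft <- stats::fisher.test(x)
    return(list(method = "fisher_exact", statistic = unname(ft$estimate),
                p = ft$p.value))
  }
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("need exactly two non-empty groups")
  a <- x[group == levels(group)[1]]
  b <- x[group == levels(group)[2]]
  exact <- (length(a) + length(b)) <= 12 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  list(method = if (exact) "mann_whitney_exact" else "mann_whitney_normal",
       statistic = unname(wt$statistic), p = wt$p.value)
}
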