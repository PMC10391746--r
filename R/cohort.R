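# Canonical units: ANC and platelets in G/l (10^9/l), hemoglobin in g/dl,
# CRP in mg/dl, ferritin in ng/ml. All study days are integers relative to
# CAR-T infusion (day 0); baseline sample days are relative to the start of
# lymphodepletion (<= 0 means at or before the first dose of chemotherapy).

.ht_analytes   <- c("anc", "platelets", "hemoglobin")
.ht_categories <- c("bacterial", "viral", "fungal", "clinical_syndrome")
.ht_event_types <- c("platelet_transfusion", "prbc_transfusion", "gcsf",
                     "tpo_agonist", "stem_cell_boost")
.ht_death_causes <- c("none", "progression", "infection", "CRS",
                      "cardiotoxicity", "other")
.ht_responses  <- c("sCR", "CR", "VGPR", "PR", "SD", "PD", "not_evaluable")

.patients_cols <- c(
  "patient_id", "ld_day",
  "anc", "anc_day", "hemoglobin", "hemoglobin_day",
  "platelets", "platelets_day", "crp", "crp_day", "ferritin", "ferritin_day",
  "egfr", "ldh_above_uln", "ecog", "bm_plasma_cell_pct", "prior_bcma_therapy",
  "crs_max_grade", "icans_max_grade", "hospital_days",
  "pfs_time", "pfs_event", "os_time", "os_event", "death_cause", "response")
.labs_cols       <- c("patient_id", "day", "analyte", "value", "unit")
.infections_cols <- c("patient_id", "onset_day", "category", "source", "grade")
.events_cols     <- c("patient_id", "day", "event_type")

#' Construct a CAR-T cohort object
#'
#' A cohort bundles four tables keyed by \code{patient_id}: per-patient
#' baseline labs, covariates and outcomes (\code{patients}); longitudinal
#' ANC/platelet/hemoglobin series (\code{labs}, canonical units, days relative
#' to infusion); infection events (\code{infections}); and supportive-care
#' events such as transfusions (\code{events}). Validation is performed on
#' construction and a data.frame of row-level flags (same-day duplicate lab
#' draws resolved to the minimum, excluded neutropenic-fever rows, late
#' infection events) is attached as \code{flags}.
#'
#' @param patients data.frame with one row per patient (see
#'   \code{\link{read_ht_cohort}} for the column contract).
#' @param labs long data.frame \code{patient_id, day, analyte, value, unit}.
#'   \code{analyte} is one of \code{anc}, \code{platelets}, \code{hemoglobin};
#'   \code{unit} is \code{g_l}, \code{per_ul} (divided by 1000 on read) or
#'   \code{g_dl}.
#' @param infections data.frame \code{patient_id, onset_day, category, source,
#'   grade}; grade is the 5-level infection severity (1 mild ... 5 fatal).
#' @param events data.frame \code{patient_id, day, event_type}.
#' @return An object of class \code{ht_cohort}.
#' @export
ht_cohort <- function(patients,
                      labs = empty_labs(),
                      infections = empty_infections(),
                      events = empty_events()) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  labs <- as.data.frame(labs, stringsAsFactors = FALSE)
  infections <- as.data.frame(infections, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)

  .check_columns(patients, .patients_cols, "patients")
  .check_columns(labs, .labs_cols, "labs")
  .check_columns(infections, .infections_cols, "infections")
  .check_columns(events, .events_cols, "events")

  flags <- .empty_flags()

  dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
  if (length(dup))
    stop("duplicate patient_id in patients table: ",
         paste(dup, collapse = ", "))

  known <- patients$patient_id
  for (nm in c("labs", "infections", "events")) {
    tab <- get(nm)
    bad <- setdiff(unique(tab$patient_id), known)
    if (length(bad))
      stop("unknown patient_id in ", nm, " table: ", paste(bad, collapse = ", "))
  }

  # --- labs -----------------------------------------------------------------
  if (nrow(labs)) {
    bad <- !labs$analyte %in% .ht_analytes
    if (any(bad))
      stop("unknown analyte in labs: ",
           paste(unique(labs$analyte[bad]), collapse = ", "))
    labs <- normalize_units(labs)
    if (any(!is.finite(labs$value)))
      stop("non-numeric or missing lab value for patient ",
           labs$patient_id[which(!is.finite(labs$value))[1]])
    if (any(labs$value < 0))
      stop("negative lab value for patient ",
           labs$patient_id[which(labs$value < 0)[1]])
    # same-day duplicate draws: keep the minimum (conservative) and flag
    key <- paste(labs$patient_id, labs$analyte, labs$day, sep = "\r")
    if (anyDuplicated(key)) {
      dup_keys <- unique(key[duplicated(key)])
      for (k in dup_keys) {
        rows <- which(key == k)
        flags <- rbind(flags, data.frame(
          patient_id = labs$patient_id[rows[1]],
          table = "labs", field = labs$analyte[rows[1]],
          reason = sprintf("duplicate draw on day %d resolved to minimum",
                           labs$day[rows[1]]),
          stringsAsFactors = FALSE))
      }
      keep <- stats::aggregate(value ~ patient_id + analyte + day, labs, min)
      labs <- keep[, c("patient_id", "day", "analyte", "value")]
      labs$unit <- "canonical"
    }
    labs <- labs[order(labs$patient_id, labs$analyte, labs$day), ]
    rownames(labs) <- NULL
  }

  # --- infections -----------------------------------------------------------
  if (nrow(infections)) {
    nf <- infections$category == "neutropenic_fever"
    if (any(nf)) {
      flags <- rbind(flags, data.frame(
        patient_id = infections$patient_id[nf], table = "infections",
        field = "category",
        reason = "neutropenic fever alone is not an infection event; dropped",
        stringsAsFactors = FALSE))
      infections <- infections[!nf, , drop = FALSE]
    }
  }
  if (nrow(infections)) {
    bad <- !infections$category %in% .ht_categories
    if (any(bad))
      stop("unknown infection category: ",
           paste(unique(infections$category[bad]), collapse = ", "))
    if (any(!infections$grade %in% 1:5))
      stop("infection grade outside 1-5 for patient ",
           infections$patient_id[which(!infections$grade %in% 1:5)[1]])
    infections <- infections[order(infections$patient_id,
                                   infections$onset_day), ]
    rownames(infections) <- NULL
  }

  # --- events ---------------------------------------------------------------
  if (nrow(events)) {
    bad <- !events$event_type %in% .ht_event_types
    if (any(bad))
      stop("unknown event_type: ",
           paste(unique(events$event_type[bad]), collapse = ", "))
    events <- events[order(events$patient_id, events$day), ]
    rownames(events) <- NULL
  }

  # --- outcome invariants ---------------------------------------------------
  if (nrow(patients)) {
    if (any(!is.na(patients$death_cause) &
            !patients$death_cause %in% .ht_death_causes))
      stop("unknown death_cause value")
    bad <- which(patients$pfs_time > patients$os_time + 1e-9)
    if (length(bad))
      stop("pfs_time exceeds os_time for patient ",
           patients$patient_id[bad[1]])
    bad <- which((patients$os_event == 0) != (patients$death_cause == "none"))
    if (length(bad))
      stop("death_cause must be 'none' exactly when os_event is 0 (patient ",
           patients$patient_id[bad[1]], ")")
    bad <- which(!patients$ecog %in% 0:4)
    if (length(bad))
      stop("ecog outside 0-4 for patient ", patients$patient_id[bad[1]])
    bad <- which(patients$bm_plasma_cell_pct < 0 |
                 patients$bm_plasma_cell_pct > 100)
    if (length(bad))
      stop("bm_plasma_cell_pct outside [0,100] for patient ",
           patients$patient_id[bad[1]])
  }

  structure(list(patients = patients, labs = labs, infections = infections,
                 events = events, flags = flags),
            class = "ht_cohort")
}

.check_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("table '", table, "' is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  invisible(df)
}

.empty_flags <- function() {
  data.frame(patient_id = character(), table = character(),
             field = character(), reason = character(),
             stringsAsFactors = FALSE)
}

#' @rdname ht_cohort
#' @export
empty_labs <- function() {
  data.frame(patient_id = character(), day = integer(), analyte = character(),
             value = numeric(), unit = character(), stringsAsFactors = FALSE)
}

#' @rdname ht_cohort
#' @export
empty_infections <- function() {
  data.frame(patient_id = character(), onset_day = integer(),
             category = character(), source = character(), grade = integer(),
             stringsAsFactors = FALSE)
}

#' @rdname ht_cohort
#' @export
empty_events <- function() {
  data.frame(patient_id = character(), day = integer(),
             event_type = character(), stringsAsFactors = FALSE)
}

#' Normalize lab units to the canonical scale
#'
#' ANC and platelet values recorded per microliter (\code{unit == "per_ul"})
#' are divided by 1000 to G/l; canonical values (\code{g_l}, \code{g_dl}) pass
#' through unchanged. Normalization is idempotent: the returned table carries
#' \code{unit == "canonical"}.
#'
#' @param labs a labs data.frame (see \code{\link{ht_cohort}}).
#' @return The labs table in canonical units.
#' @export
normalize_units <- function(labs) {
  if (!nrow(labs)) { labs$unit <- character(0); return(labs) }
  ok <- c("g_l", "per_ul", "g_dl", "canonical")
  bad <- !labs$unit %in% ok
  if (any(bad))
    stop("unknown lab unit: ", paste(unique(labs$unit[bad]), collapse = ", "))
  per_ul <- labs$unit == "per_ul"
  if (any(per_ul & labs$analyte == "hemoglobin"))
    stop("hemoglobin cannot be recorded per_ul")
  labs$value[per_ul] <- labs$value[per_ul] / 1000
  labs$unit <- "canonical"
  labs
}

#' Read a cohort from its CSV file set
#'
#' Reads \code{patients.csv}, \code{labs.csv}, \code{infections.csv} and
#' \code{events.csv} from a directory and assembles a validated
#' \code{\link{ht_cohort}}. Units are normalized on read; missing values must
#' be empty cells (never 0); validation failures raise errors naming the
#' column or patient, and soft issues (duplicate same-day draws, excluded
#' neutropenic-fever rows) are collected in the \code{flags} table.
#'
#' @param path directory containing the four CSV files.
#' @return An \code{ht_cohort}.
#' @export
read_ht_cohort <- function(path) {
  f <- function(name) file.path(path, name)
  if (!file.exists(f("patients.csv")))
    stop("patients.csv not found in ", path)
  patients <- utils::read.csv(f("patients.csv"), stringsAsFactors = FALSE,
                              colClasses = c(patient_id = "character"))
  read_opt <- function(name, empty) {
    if (file.exists(f(name)))
      utils::read.csv(f(name), stringsAsFactors = FALSE,
                      colClasses = c(patient_id = "character"))
    else empty
  }
  labs <- read_opt("labs.csv", empty_labs())
  if (nrow(labs) && !is.numeric(labs$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(labs$value))) &
                 !is.na(labs$value) & labs$value != "")
    if (length(bad))
      stop("non-numeric lab value for patient ", labs$patient_id[bad[1]],
           " (labs.csv line ", bad[1] + 1L, ")")
    labs$value <- as.numeric(labs$value)
  }
  infections <- read_opt("infections.csv", empty_infections())
  events <- read_opt("events.csv", empty_events())
  ht_cohort(patients, labs, infections, events)
}

#' Write a cohort to its CSV file set
#'
#' Inverse of \code{\link{read_ht_cohort}}: writes the four CSV files with a
#' fixed column order so that write followed by read is the identity on valid
#' cohorts, and repeated writes of the same cohort are byte-identical.
#'
#' @param cohort an \code{ht_cohort}.
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_ht_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ht_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory ", path)
  w <- function(df, cols, name) {
    utils::write.csv(df[, cols, drop = FALSE],
                     file.path(path, name), row.names = FALSE, quote = FALSE)
  }
  w(cohort$patients, .patients_cols, "patients.csv")
  w(cohort$labs, .labs_cols, "labs.csv")
  w(cohort$infections, .infections_cols, "infections.csv")
  w(cohort$events, .events_cols, "events.csv")
  invisible(path)
}

#' Extract one patient's longitudinal series
#'
#' @param cohort an \code{ht_cohort}.
#' @param patient_id patient identifier.
#' @param analyte one of \code{"anc"}, \code{"platelets"}, \code{"hemoglobin"}.
#' @return data.frame \code{day, value} sorted by day (possibly zero rows).
#' @export
patient_series <- function(cohort, patient_id, analyte = "anc") {
  analyte <- match.arg(analyte, .ht_analytes)
  s <- cohort$labs[cohort$labs$patient_id == patient_id &
                   cohort$labs$analyte == analyte, c("day", "value")]
  s[order(s$day), , drop = FALSE]
}

#' @export
print.ht_cohort <- function(x, ...) {
  cat(sprintf("CAR-T cohort: %d patients, %d lab rows, %d infection events, %d support events\n",
              nrow(x$patients), nrow(x$labs), nrow(x$infections),
              nrow(x$events)))
  if (nrow(x$flags))
    cat(sprintf("  %d validation flag(s); see $flags\n", nrow(x$flags)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort an \code{ht_cohort}.
#' @return integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)
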