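# Session-level CSV interchange.  One row = one subject-day.
.session_cols <- c("subject_id", "strain", "sex", "unit_dose_ug_kg",
                   "phase", "session_index", "fr_value",
                   "active_responses", "inactive_responses", "infusions")
.phases <- c("FR1_acq", "FR2_acq", "demand")

#' Validate a table of operant session records
#'
#' Enforces the session-record invariants: known phase labels, positive
#' session indices, `infusions <= active_responses` (post-infusion
#' timeout responses are recorded but unreinforced, so the reverse
#' inequality is *not* required), FR 1 in the first acquisition phase and
#' FR 2 in the second, and non-negative counts.  A subject with any
#' invalid row is rejected as a whole.
#'
#' @param sessions Data frame of session records.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_sessions <- function(sessions) {
  missing <- setdiff(.session_cols, names(sessions))
  if (length(missing) > 0)
    stop("session table is missing column(s): ",
         paste(missing, collapse = ", "))
  s <- sessions
  problems <- character(0)
  note <- function(bad, what) {
    if (any(bad))
      sprintf("%s (subject %s, session %s)", what,
              paste(unique(s$subject_id[bad]), collapse = ","),
              paste(s$session_index[bad], collapse = ","))
  }
  problems <- c(problems,
    note(!s$phase %in% .phases, "unknown phase"),
    note(s$session_index < 1, "session_index must be >= 1"),
    note(s$fr_value < 1, "fr_value must be >= 1"),
    note(s$active_responses < 0 | s$inactive_responses < 0 | s$infusions < 0,
         "negative counts"),
    note(s$infusions > s$active_responses,
         "infusions exceed active responses"),
    note(s$phase == "FR1_acq" & s$fr_value != 1, "FR1_acq rows must be FR 1"),
    note(s$phase == "FR2_acq" & s$fr_value != 2, "FR2_acq rows must be FR 2"),
    note(s$unit_dose_ug_kg < 0, "unit dose must be non-negative"))
  problems <- problems[!vapply(problems, is.null, logical(1))]
  if (length(problems) > 0)
    stop("invalid session records: ",
         paste(unlist(problems), collapse = "; "))
  invisible(sessions)
}

#' Load operant session records from CSV
#'
#' Reads a comma-separated, dot-decimal session table with the
#' documented header (`subject_id, strain, sex, unit_dose_ug_kg, phase,
#' session_index, fr_value, active_responses, inactive_responses,
#' infusions`) and validates every row; any subject with an invalid row
#' aborts the load with a message naming the subject and session.
#'
#' @param path CSV file path.
#' @return Validated data frame of session records.
#' @seealso [validate_sessions()], [write_sessions()]
#' @export
load_sessions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sessions <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(sessions) == 0) {
    missing <- setdiff(.session_cols, names(sessions))
    if (length(missing) > 0)
      stop("session table is missing column(s): ",
           paste(missing, collapse = ", "))
    return(sessions[, .session_cols])
  }
  validate_sessions(sessions)
  sessions[, .session_cols]
}

#' Write session records to CSV
#'
#' @param sessions Validated session table.
#' @param path Output CSV path.
#' @export
write_sessions <- function(sessions, path) {
  validate_sessions(sessions)
  utils::write.csv(sessions[, .session_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a demand parameter table with stratum summaries
#'
#' Writes one row per subject plus mean and SEM rows for each
#' strain-by-sex stratum and for each strain overall, in the layout of a
#' published individual-parameter table.  Summary rows are recomputed
#' from the data rows (`row_type` distinguishes them), so the file
#' round-trips: [read_parameter_table()] recovers the subject rows.
#'
#' @param params Data frame with columns `subject_id, strain, sex,
#'   alpha, q0, k, pmax_exact, pmax_approx, omax, r2, n_points`.
#' @param path Output CSV path.
#' @export
write_parameter_table <- function(params, path) {
  cols <- c("subject_id", "strain", "sex", "alpha", "q0", "k",
            "pmax_exact", "pmax_approx", "omax", "r2", "n_points")
  if (nrow(params) == 0) stop("empty parameter table")
  missing <- setdiff(cols, names(params))
  if (length(missing) > 0)
    stop("parameter table is missing column(s): ",
         paste(missing, collapse = ", "))
  num <- c("alpha", "q0", "k", "pmax_exact", "pmax_approx", "omax",
           "r2", "n_points")
  out <- cbind(row_type = "subject", params[, cols])

  summarize <- function(rows, strain, sex) {
    m <- rows[1, cols]
    m$subject_id <- NA_character_
    m$strain <- strain
    m$sex <- sex
    sem <- m
    for (v in num) {
      x <- rows[[v]]
      m[[v]] <- mean(x)
      sem[[v]] <- stats::sd(x) / sqrt(length(x))
    }
    rbind(cbind(row_type = "mean", m), cbind(row_type = "sem", sem))
  }
  for (st in unique(params$strain)) {
    for (sx in unique(params$sex[params$strain == st])) {
      rows <- params[params$strain == st & params$sex == sx, , drop = FALSE]
      out <- rbind(out, summarize(rows, st, sx))
    }
    out <- rbind(out, summarize(params[params$strain == st, , drop = FALSE],
                                st, "all"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a demand parameter table
#'
#' @param path CSV written by [write_parameter_table()].
#' @param subjects_only Drop the recomputed mean/SEM rows (default).
#' @return Data frame of parameters.
#' @export
read_parameter_table <- function(path, subjects_only = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (subjects_only) {
    tab <- tab[tab$row_type == "subject", , drop = FALSE]
    tab$row_type <- NULL
    rownames(tab) <- NULL
  }
  tab
}

#' Published reference demand parameters (SHR vs Wistar, 30 ug/kg)
#'
#' Individual best-fit exponential demand parameters for the 28
#' adolescent rats (14 Wistar, 14 SHR) that completed demand assessment
#' at the 30 ug/kg nicotine unit dose, with the globally fit k = 2.218:
#' per-subject alpha and Q0 together with the Pmax, Omax and r2 values as
#' printed in the source table.  Used as reference input for
#' cross-checks, worked examples and the strain comparison.
#'
#' @return Data frame with columns `subject_id, strain, sex, alpha, q0,
#'   pmax_printed, omax_printed, r2_printed`.
#' @examples
#' ref <- reference_demand_parameters()
#' omax(ref$q0, ref$alpha, 2.218)  # reproduces the printed Omax column
#' @export
reference_demand_parameters <- function() {
  path <- system.file("extdata", "shr_wistar_demand_params.csv",
                      package = "opdemand", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
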