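# Time-course tables and result archives.

#' @export
as.data.frame.flux_time_course <- function(x, row.names = NULL, optional = FALSE,
                                           ..., experiment_id = NULL) {
  if (is.null(experiment_id))
    experiment_id <- if (!is.null(x$metadata$experiment_id))
      x$metadata$experiment_id else "exp1"
  n_rep <- ncol(x$cpm)
  data.frame(
    experiment_id = experiment_id,
    voltage_mV = x$voltage,
    time_s = rep(x$time, times = n_rep),
    replicate = rep(seq_len(n_rep), each = length(x$time)),
    cpm = as.vector(x$cpm),
    stringsAsFactors = FALSE
  )
}

#' Write flux time courses to CSV
#'
#' Long format with columns `experiment_id`, `voltage_mV`, `time_s`,
#' `replicate`, `cpm`; round-trips exactly through
#' [parse_time_course_table()].
#'
#' @param courses A `flux_experiment`, a list of [flux_time_course()]
#'   objects, or a single course.
#' @param path Output CSV path.
#' @param experiment_id Identifier written to every row.
#' @return `path`, invisibly.
#' @export
write_time_courses <- function(courses, path, experiment_id = "exp1") {
  if (inherits(courses, "flux_experiment")) courses <- courses$courses
  if (inherits(courses, "flux_time_course")) courses <- list(courses)
  rows <- lapply(courses, as.data.frame, experiment_id = experiment_id)
  df <- do.call(rbind, rows)
  df <- df[order(df$voltage_mV, df$time_s, df$replicate), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read flux time courses from CSV
#'
#' Parses and validates a long-format time-course table (columns
#' `experiment_id`, `voltage_mV`, `time_s`, `replicate`, `cpm`), groups rows
#' into one [flux_time_course()] per (experiment, voltage), sorted by time,
#' independent of the input row order.
#'
#' @param path CSV file path.
#' @return A named list of [flux_time_course()] objects (names
#'   `"<experiment_id>:<voltage>"`).
#' @export
parse_time_course_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("experiment_id", "voltage_mV", "time_s", "replicate", "cpm")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("time-course table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in c("voltage_mV", "time_s", "replicate", "cpm")) {
    if (!is.numeric(df[[col]]))
      stop(sprintf("column '%s' must be numeric", col), call. = FALSE)
  }
  if (any(!is.finite(df$cpm)) || any(df$cpm < 0))
    stop("column 'cpm' must be finite and nonnegative", call. = FALSE)
  key <- paste(df$experiment_id, df$voltage_mV, df$time_s, df$replicate)
  if (anyDuplicated(key))
    stop("duplicated (experiment, voltage, time, replicate) rows", call. = FALSE)
  groups <- split(df, paste(df$experiment_id, df$voltage_mV, sep = ":"),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    times <- sort(unique(g$time_s))
    reps <- sort(unique(g$replicate))
    cpm <- matrix(NA_real_, nrow = length(times), ncol = length(reps))
    for (k in seq_len(nrow(g))) {
      cpm[match(g$time_s[k], times), match(g$replicate[k], reps)] <- g$cpm[k]
    }
    if (anyNA(cpm))
      stop("unequal replicate coverage across timepoints", call. = FALSE)
    flux_time_course(g$voltage_mV[1L], times, cpm,
                     metadata = list(experiment_id = g$experiment_id[1L]))
  })
  # stable ordering by voltage within experiment
  ord <- order(vapply(out, function(x) x$metadata$experiment_id, character(1L)),
               vapply(out, `[[`, numeric(1L), "voltage"))
  out[ord]
}

.result_as_list <- function(result) {
  est <- result$e_rev
  e_rev <- if (inherits(est, "erev_estimate"))
    list(estimate = est$estimate, bracket = est$bracket, method = est$method)
  else list(estimate = as.numeric(est), bracket = NULL, method = "given")
  list(
    calls = .calls_df(result$calls),
    e_rev = e_rev,
    assigned = if (is.null(result$assigned)) NULL
               else result$assigned[c("n", "m", "predicted_e_rev")],
    excluded = result$excluded,
    predictions = data.frame(n = result$predictions$n, m = result$predictions$m,
                             e_rev = result$predictions$e_rev,
                             electroneutral = result$predictions$electroneutral),
    tolerance_mV = result$tolerance_mV
  )
}

#' Write an inference result to JSON (+ deltaCPM CSV)
#'
#' Writes `<prefix>_result.json` holding the flux calls, reversal-potential
#' estimate with bracket, assigned stoichiometry (`null` when unassigned)
#' and per-candidate exclusion reasons; and, when the result carries a
#' voltage-deltaCPM table, `<prefix>_delta_cpm.csv` with columns `voltage`,
#' `mean`, `sem`. JSON output round-trips through [read_results()].
#'
#' @param result A `stoich_inference` or `stoich_fit`.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(result, prefix) {
  stopifnot(inherits(result, "stoich_inference"))
  if (length(result$calls) == 0L)
    stop("result contains no flux calls", call. = FALSE)
  lst <- .result_as_list(result)
  json_path <- paste0(prefix, "_result.json")
  jsonlite::write_json(lst, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null",
                       pretty = TRUE)
  written <- json_path
  if (!is.null(result$delta)) {
    csv_path <- paste0(prefix, "_delta_cpm.csv")
    utils::write.csv(result$delta[, c("voltage", "mean", "sem")], csv_path,
                     row.names = FALSE, quote = FALSE)
    written <- c(written, csv_path)
  }
  invisible(written)
}

#' Read an inference result written by [write_results()]
#'
#' @param path Path to the `*_result.json` file.
#' @return A list of class `stoich_inference` with the same fields that were
#'   written (calls are reconstituted as [flux_call()] objects).
#' @export
read_results <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  calls_df <- as.data.frame(lst$calls)
  calls <- lapply(seq_len(nrow(calls_df)), function(i) {
    flux_call(calls_df$voltage[i], calls_df$direction[i],
              slope = if (is.null(calls_df$slope[i])) NA_real_ else calls_df$slope[i],
              p = if (is.null(calls_df$p[i])) NA_real_ else calls_df$p[i])
  })
  est <- structure(list(estimate = lst$e_rev$estimate,
                        bracket = as.numeric(lst$e_rev$bracket),
                        method = lst$e_rev$method),
                   class = "erev_estimate")
  assigned <- if (is.null(lst$assigned) || length(lst$assigned) == 0L) NULL
              else as.list(lst$assigned)
  excluded <- as.data.frame(lst$excluded)
  if (!nrow(excluded))
    excluded <- data.frame(n = numeric(), m = numeric(), reason = character())
  preds <- as.data.frame(lst$predictions)
  class(preds) <- c("candidate_predictions", "data.frame")
  structure(list(predictions = preds, calls = calls, e_rev = est,
                 assigned = assigned, excluded = excluded,
                 tolerance_mV = lst$tolerance_mV),
            class = "stoich_inference")
}
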